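# independent oracles and small input builders used across the suite

random_mr_input <- function(J = 10, seed = NULL, theta = 0.1) {
  if (!is.null(seed)) set.seed(seed)
  beta_x <- rnorm(J, 0.1, 0.05)
  beta_x[beta_x == 0] <- 0.05
  se_x <- runif(J, 0.003, 0.01)
  se_y <- runif(J, 0.005, 0.05)
  beta_y <- theta * beta_x + rnorm(J, 0, se_y)
  mr_input(beta_x, se_x, beta_y, se_y)
}

# IVW oracle: weighted LS of beta_y on beta_x through the origin
oracle_ivw <- function(inp) {
  f <- lm(beta_y ~ beta_x - 1, data = as.data.frame(inp),
          weights = 1 / inp$se_y^2)
  s <- summary(f)
  J <- nrow(inp)
  se_fixed <- s$coefficients[1, 2] / s$sigma
  list(beta = unname(coef(f)[1]), se_fixed = se_fixed,
       se_random = se_fixed * max(1, s$sigma))
}

# Egger oracle: two-column weighted LS after orienting beta_x >= 0
oracle_egger <- function(inp) {
  flip <- ifelse(inp$beta_x < 0, -1, 1)
  d <- data.frame(bx = inp$beta_x * flip, by = inp$beta_y * flip)
  f <- lm(by ~ bx, data = d, weights = 1 / inp$se_y^2)
  s <- summary(f)
  se <- unname(s$coefficients[, 2]) / min(s$sigma, 1)
  list(intercept = unname(coef(f)[1]), slope = unname(coef(f)[2]),
       se_intercept = se[1], se_slope = se[2])
}

# joint maximum-likelihood oracle: optimize the full (theta, mu_1..mu_J)
# likelihood numerically, no profiling
oracle_ml <- function(inp) {
  bx <- inp$beta_x; by <- inp$beta_y
  sx2 <- inp$se_x^2; sy2 <- inp$se_y^2
  nll <- function(par) {
    theta <- par[1]; mu <- par[-1]
    sum((bx - mu)^2 / (2 * sx2) + (by - theta * mu)^2 / (2 * sy2))
  }
  start <- c(oracle_ivw(inp)$beta, bx)
  opt <- optim(start, nll, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-14))
  opt$par[1]
}

# cumulative-weight-walk oracle for the weighted median (explicit loop)
oracle_weighted_median <- function(ratio, w) {
  o <- order(ratio)
  r <- ratio[o]; w <- w[o]
  total <- sum(w)
  s <- numeric(length(r))
  acc <- 0
  for (j in seq_along(r)) {
    s[j] <- (acc + w[j] / 2) / total
    acc <- acc + w[j]
  }
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[length(s)]) return(r[length(r)])
  j <- max(which(s < 0.5))
  r[j] + (r[j + 1] - r[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}

# dense-grid KDE argmax oracle for the weighted mode
oracle_weighted_mode <- function(ratio, w, phi = 1, n_grid = 200001L) {
  w <- w / sum(w)
  h <- phi * 0.9 * min(sd(ratio), IQR(ratio) / 1.34) * length(ratio)^(-1 / 5)
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = n_grid)
  dens <- sapply(grid, function(t) sum(w * dnorm(t, ratio, h)))
  grid[which.max(dens)]
}

# HWE enumeration oracle with exact factorials (n <= 100)
oracle_hwe <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  if (nA == 0 || nA == 2 * n) return(1)
  rare <- min(nA, 2 * n - nA)
  hets <- seq.int(rare %% 2, rare, by = 2)
  probs <- sapply(hets, function(h) {
    aa <- (nA - h) / 2; bb <- (2 * n - nA - h) / 2
    2^h / (factorial(aa) * factorial(h) * factorial(bb))
  })
  probs <- probs / sum(probs)
  obs <- probs[hets == n_Aa]
  sum(probs[probs <= obs * (1 + 1e-12)])
}

# pseudoinverse OLS oracle with classical SEs
oracle_ols <- function(X, y) {
  b <- drop(MASS_ginv(X) %*% y)
  n <- nrow(X); k <- ncol(X)
  res <- y - X %*% b
  sigma2 <- sum(res^2) / (n - k)
  se <- unname(sqrt(sigma2 * diag(solve(crossprod(X)))))
  list(coef = unname(b), se = se)
}

# small Moore-Penrose pseudoinverse via SVD (avoid a MASS dependency)
MASS_ginv <- function(X, tol = 1e-12) {
  s <- svd(X)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# a tiny deterministic summary-stat world for study-level tests
tiny_study_cohort <- function(n = 300, theta = 0, seed = 42, n_snps = 8) {
  cfg <- sim_config(n_snps = n_snps, n_cohort = n, theta = theta, seed = seed)
  pan <- simulate_true_panel(cfg)
  list(config = cfg, panel = pan, cohort = simulate_cohort(pan),
       gwas = simulate_external_gwas(pan, seed = seed + 1))
}
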