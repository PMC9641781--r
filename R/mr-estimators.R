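#' Inverse-variance weighted causal estimate
#'
#' The IVW estimate is the inverse-variance weighted average of the per-SNP
#' Wald ratios, algebraically identical to weighted least squares of `beta_y`
#' on `beta_x` through the origin with weights `se_y^-2`. The fixed-effect
#' standard error is `(sum w)^(-1/2)`; the multiplicative random-effects SE
#' inflates it by `max(1, sqrt(Q/(J-1)))` where `Q` is Cochran's statistic, so
#' it can never fall below the fixed-effect SE. Wald normal p-value; 95% CI.
#'
#' @param input an [mr_input()].
#' @param model `"random"` (multiplicative random effects, the default) or
#'   `"fixed"`. Random effects requires `J >= 2`.
#' @return An object of class `"mr_estimate"`. `aux` carries the Q statistic
#'   and both SE flavors.
#' @export
ivw_estimate <- function(input, model = c("random", "fixed")) {
  model <- match.arg(model)
  re <- ratio_estimates(input)
  J <- nrow(re)
  if (model == "random" && J < 2L)
    stopf("random-effects IVW needs at least 2 SNPs")
  sw <- sum(re$w)
  beta <- sum(re$w * re$ratio) / sw
  se_fixed <- sw^-0.5
  Q <- sum(re$w * (re$ratio - beta)^2)
  infl <- if (J >= 2L) max(1, sqrt(Q / (J - 1))) else 1
  se <- if (model == "random") se_fixed * infl else se_fixed
  p <- 2 * pnorm(-abs(beta / se))
  new_mr_estimate(paste0("ivw_", model), beta, se, p, J,
                  aux = list(Q = Q, se_fixed = se_fixed,
                             se_random = se_fixed * infl))
}

#' Maximum-likelihood causal estimate
#'
#' Models the observed `beta_x` and `beta_y` as independent normals around
#' per-SNP true exposure effects `mu_j` and `theta * mu_j`, and maximizes the
#' joint likelihood over (`theta`, `mu_1..mu_J`). Unlike IVW it accounts for
#' the exposure-side sampling error `se_x`. The J nuisance means are profiled
#' out analytically: for fixed theta the optimal
#' `mu_j = (beta_x/se_x^2 + theta beta_y/se_y^2) / (1/se_x^2 + theta^2/se_y^2)`,
#' leaving a one-dimensional profile likelihood maximized numerically. The SE
#' comes from the curvature (observed information) of the profile at the
#' maximum; Wald normal p-value.
#'
#' @param input an [mr_input()] with `J >= 2`.
#' @return `"mr_estimate"`; `aux$loglik` holds the profile log-likelihood at
#'   the maximum.
#' @export
max_likelihood_estimate <- function(input) {
  input <- as_mr_input(input)
  J <- nrow(input)
  if (J < 2L) stopf("maximum likelihood needs at least 2 SNPs")
  bx <- input$beta_x; by <- input$beta_y
  sx2 <- input$se_x^2; sy2 <- input$se_y^2
  prof <- function(theta) {
    mu <- (bx / sx2 + theta * by / sy2) / (1 / sx2 + theta^2 / sy2)
    -sum((bx - mu)^2 / (2 * sx2) + (by - theta * mu)^2 / (2 * sy2))
  }
  start <- ivw_estimate(input, model = "fixed")
  width <- max(10 * start$se, 10 * abs(start$beta), 1)
  opt <- optimize(prof, interval = c(start$beta - width, start$beta + width),
                  maximum = TRUE, tol = 1e-12)
  theta <- opt$maximum
  # profile curvature by central differences
  h <- max(1e-6, abs(theta) * 1e-5)
  info <- -(prof(theta + h) - 2 * prof(theta) + prof(theta - h)) / h^2
  if (!is.finite(info) || info <= 0)
    stopf("maximum-likelihood estimate did not converge (non-positive curvature)")
  se <- 1 / sqrt(info)
  p <- 2 * pnorm(-abs(theta / se))
  new_mr_estimate("max_likelihood", theta, se, p, J,
                  aux = list(loglik = opt$objective))
}

# weighted median of `x` with weights `w`: sort, walk the standardized
# cumulative weights s_j = (cumsum(w) - w/2)/sum(w), interpolate at 0.5
weighted_median_point <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= s[1]) return(x[1])
  n <- length(x)
  if (0.5 >= s[n]) return(x[n])
  approx(s, x, xout = 0.5, ties = "ordered")$y
}

# parametric bootstrap SE shared by median and mode: resample the summary
# statistics from normals with the stated SEs and recompute the point estimate
bootstrap_se <- function(input, point_fun, n_boot, seed) {
  set_seed_if(seed)
  J <- nrow(input)
  bx <- matrix(rnorm(n_boot * J, rep(input$beta_x, each = n_boot),
                     rep(input$se_x, each = n_boot)), n_boot, J)
  by <- matrix(rnorm(n_boot * J, rep(input$beta_y, each = n_boot),
                     rep(input$se_y, each = n_boot)), n_boot, J)
  est <- numeric(n_boot)
  sey <- input$se_y
  for (b in seq_len(n_boot)) {
    bxb <- bx[b, ]
    keep <- bxb != 0
    r <- by[b, keep] / bxb[keep]
    w <- (sey[keep] / abs(bxb[keep]))^-2
    est[b] <- point_fun(r, w)
  }
  sd(est)
}

#' Weighted-median causal estimate
#'
#' Takes the weighted median of the per-SNP Wald ratios: ratios are sorted,
#' standardized cumulative weights `s_j = (cumsum(w) - w/2)/sum(w)` computed,
#' and the estimate is the linear interpolation of the ratios at `s = 0.5`.
#' Consistent when SNPs carrying at least half the weight are valid
#' instruments, so robust to up to 50% invalid weight. The SE is a parametric
#' bootstrap: `beta_x` and `beta_y` are resampled from normals with the stated
#' SEs and the weighted median recomputed.
#'
#' @param input an [mr_input()] with `J >= 3`.
#' @param n_boot bootstrap draws (default 1000).
#' @param seed RNG seed for the bootstrap, recorded in `aux`.
#' @return `"mr_estimate"`.
#' @export
weighted_median_estimate <- function(input, n_boot = 1000, seed = NULL) {
  input <- as_mr_input(input)
  if (nrow(input) < 3L) stopf("weighted median needs at least 3 SNPs")
  re <- ratio_estimates(input)
  beta <- weighted_median_point(re$ratio, re$w)
  se <- bootstrap_se(input, weighted_median_point, n_boot, seed)
  p <- 2 * pnorm(-abs(beta / se))
  new_mr_estimate("weighted_median", beta, se, p, nrow(re),
                  aux = list(n_boot = n_boot, seed = seed))
}

# argmax of the weighted Gaussian KDE over ratios; coarse grid then refine
weighted_mode_point <- function(x, w, phi = 1) {
  w <- w / sum(w)
  spread <- min(sd(x), IQR(x) / 1.34)
  if (!is.finite(spread) || spread == 0) spread <- sd(x)
  if (!is.finite(spread) || spread == 0) return(x[1])  # all ratios identical
  h <- phi * 0.9 * spread * length(x)^(-1 / 5)
  dens <- function(t) vapply(t, function(ti) sum(w * dnorm(ti, x, h)), 0)
  grid <- seq(min(x) - 3 * h, max(x) + 3 * h, length.out = 512L)
  i <- which.max(dens(grid))
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  optimize(dens, interval = c(lo, hi), maximum = TRUE, tol = 1e-10)$maximum
}

#' Weighted-mode causal estimate
#'
#' The mode-based estimate is the argmax of a weighted Gaussian kernel density
#' over the per-SNP Wald ratios, with weights `w/sum(w)` and bandwidth
#' `h = phi * 0.9 * min(sd, IQR/1.34) * J^(-1/5)` (a scaled Silverman rule on
#' the ratios). Consistent when the largest group of SNPs sharing a ratio
#' value is valid (ZEMPA assumption). If all ratios coincide their common
#' value is returned. SE by the same parametric bootstrap as the weighted
#' median.
#'
#' @param input an [mr_input()] with `J >= 3`.
#' @param phi bandwidth inflation factor (> 0, default 1).
#' @param n_boot,seed bootstrap settings as in [weighted_median_estimate()].
#' @return `"mr_estimate"`.
#' @export
weighted_mode_estimate <- function(input, phi = 1, n_boot = 1000, seed = NULL) {
  input <- as_mr_input(input)
  if (nrow(input) < 3L) stopf("weighted mode needs at least 3 SNPs")
  if (phi <= 0) stopf("bandwidth factor phi must be positive")
  re <- ratio_estimates(input)
  beta <- weighted_mode_point(re$ratio, re$w, phi)
  se <- bootstrap_se(input, function(r, w) weighted_mode_point(r, w, phi),
                     n_boot, seed)
  p <- 2 * pnorm(-abs(beta / se))
  new_mr_estimate("weighted_mode", beta, se, p, nrow(re),
                  aux = list(phi = phi, n_boot = n_boot, seed = seed))
}

# closed-form two-column weighted least squares of y on (1, x), weights w
wls_two_col <- function(x, y, w) {
  sw <- sum(w); sx <- sum(w * x); sxx <- sum(w * x^2)
  sy <- sum(w * y); sxy <- sum(w * x * y)
  det <- sw * sxx - sx^2
  if (!is.finite(det) || det <= 1e-12 * sw * sxx)
    stopf("design has no leverage (all beta_x identical)")
  a <- (sxx * sy - sx * sxy) / det     # intercept
  b <- (sw * sxy - sx * sy) / det      # slope
  # unscaled covariance (X'WX)^-1
  var_a <- sxx / det; var_b <- sw / det
  rss <- sum(w * (y - a - b * x)^2)
  list(intercept = a, slope = b, var_a = var_a, var_b = var_b, rss = rss)
}

#' MR-Egger regression
#'
#' Weighted least squares of `beta_y` on `beta_x` *with* an intercept, weights
#' `se_y^-2`, after orienting every SNP so `beta_x >= 0` (sign of the pair is
#' flipped as needed; the model is invariant to this but the intercept is only
#' interpretable under a common orientation). The slope is the
#' pleiotropy-adjusted causal estimate; the intercept estimates the average
#' directional pleiotropic effect and its test is the standard diagnostic for
#' directional pleiotropy. Standard errors use multiplicative overdispersion
#' floored at 1 (`max(1, sqrt(Q_egger/(J-2)))` times the theoretical weighted
#' LS standard error) and p-values are two-sided t on `J - 2` df.
#'
#' @param input an [mr_input()] with `J >= 3` and non-constant `beta_x`.
#' @return `"mr_estimate"` for the slope; `aux` carries `intercept`,
#'   `intercept_se`, `intercept_pval`, `Q_egger` and the 95% CI t-multiplier.
#'   With an exact fit (zero residual, only possible at `J = 3`), the
#'   intercept p-value is `NA` as the overdispersion scale is degenerate.
#' @export
egger_regression <- function(input) {
  input <- as_mr_input(input)
  J <- nrow(input)
  if (J < 3L) stopf("MR-Egger needs at least 3 SNPs")
  flip <- sign(input$beta_x)
  flip[flip == 0] <- 1
  bx <- input$beta_x * flip
  by <- input$beta_y * flip
  w <- input$se_y^-2
  fit <- wls_two_col(bx, by, w)
  df <- J - 2L
  sigma2 <- fit$rss / df               # Q_egger / (J - 2)
  scale <- max(1, sqrt(sigma2))
  se_slope <- sqrt(fit$var_b) * scale
  se_int <- sqrt(fit$var_a) * scale
  # only J = 3 can fit exactly with zero residual df left for the scale
  exact_fit <- J == 3L &&
    fit$rss <= 1e-10 * max(sum(w * by^2), .Machine$double.xmin)
  p_slope <- 2 * pt(-abs(fit$slope / se_slope), df)
  p_int <- if (exact_fit) NA_real_ else 2 * pt(-abs(fit$intercept / se_int), df)
  tmult <- qt(0.975, df)
  new_mr_estimate("egger", fit$slope, se_slope, p_slope, J, ci_mult = tmult,
                  aux = list(intercept = fit$intercept, intercept_se = se_int,
                             intercept_pval = p_int, Q_egger = fit$rss,
                             df = df, ci_mult = tmult))
}
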