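test_that("zscore standardizes with the n-1 denominator and propagates NA", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  z <- zscore(c(4, NA, 6))
  expect_true(is.na(z[2]))
  set.seed(1)
  x <- rnorm(50, 10, 3)
  expect_equal(zscore(zscore(x)), zscore(x), tolerance = 1e-12)  # idempotent
  expect_error(zscore(rep(2, 10)), "constant")
  expect_error(zscore(c(1, NA)), "2 non-missing")
})

test_that("mPACC and domain composites equal the spreadsheet oracle", {
  set.seed(2)
  tab <- data.frame(mbt_tp = c(10, 12, 14, 9, 15), mbt_df = c(5, 7, 6, 4, 8),
                    coding = c(40, 55, 60, 35, 50), fluency = c(18, 22, 25, 15, 20))
  mp <- compute_mpacc(tab$mbt_tp, tab$mbt_df, tab$coding, tab$fluency)
  oracle <- rowMeans(sapply(tab, function(c) (c - mean(c)) / sd(c)))
  expect_equal(mp, oracle, tolerance = 1e-12)

  # individual at the cohort mean of every component scores 0; 1 SD above -> 1
  m <- sapply(tab, mean); s <- sapply(tab, sd)
  tab2 <- rbind(tab, as.list(m), as.list(m + s))
  mp2 <- compute_mpacc(tab2$mbt_tp, tab2$mbt_df, tab2$coding, tab2$fluency)
  # recompute oracle on the extended sample
  z2 <- sapply(tab2, function(c) (c - mean(c)) / sd(c))
  expect_equal(mp2, rowMeans(z2), tolerance = 1e-12)

  # missingness rule: >= half components present -> mean of available
  tab3 <- tab
  tab3$mbt_tp[1] <- NA                      # 3 of 4 present
  mp3 <- compute_mpacc(tab3$mbt_tp, tab3$mbt_df, tab3$coding, tab3$fluency)
  z3 <- sapply(tab3, function(c) { o <- !is.na(c); (c - mean(c[o])) / sd(c[o]) })
  expect_equal(mp3[1], mean(z3[1, -1]), tolerance = 1e-12)
  tab4 <- tab
  tab4[1, c(1, 2, 3)] <- NA                 # 1 of 4 -> missing
  expect_true(is.na(compute_mpacc(tab4$mbt_tp, tab4$mbt_df, tab4$coding,
                                  tab4$fluency)[1]))

  expect_equal(compute_domain_composite(tab[, 1, drop = FALSE]),
               zscore(tab[, 1]))
  expect_equal(compute_domain_composite(cbind(a = tab$coding, b = tab$coding)),
               zscore(tab$coding))
  set.seed(3)
  mat <- matrix(rnorm(30), 10, 3)
  expect_equal(compute_domain_composite(mat),
               rowMeans(apply(mat, 2, function(c) (c - mean(c)) / sd(c))),
               tolerance = 1e-12)
  # component order does not matter
  expect_equal(compute_domain_composite(mat[, 3:1]),
               compute_domain_composite(mat))
  expect_error(compute_domain_composite(cbind(mat, 1)), "constant")
})

test_that("thickness signatures are bilateral means then region means", {
  regions <- ad_signature_regions()
  expect_length(regions, 9)
  expect_length(aging_signature_regions(), 8)
  n <- 6
  L <- matrix(2.5, n, 9, dimnames = list(NULL, regions))
  R <- L
  expect_equal(compute_signature(L, R, regions), rep(2.5, n))
  expect_equal(compute_signature(L - 0.5, R + 0.5, regions), rep(2.5, n))

  set.seed(4)
  L <- matrix(rnorm(n * 9, 2.5, 0.2), n, 9, dimnames = list(NULL, regions))
  R <- matrix(rnorm(n * 9, 2.5, 0.2), n, 9, dimnames = list(NULL, regions))
  expect_equal(compute_signature(L, R, regions), rowMeans((L + R) / 2),
               tolerance = 1e-12)

  L[2, 4] <- NA
  expect_warning(sig <- compute_signature(L, R, regions), "incomplete")
  expect_true(is.na(sig[2]) && !any(is.na(sig[-2])))
  expect_error(compute_signature(L[, -1], R, regions), "absent")
})

test_that("amyloid ratio is elementwise and guarded", {
  expect_equal(compute_abeta_ratio(600, 12000), 0.05)
  expect_equal(compute_abeta_ratio(8, 8), 1)
  ab40 <- c(9000, 12000, 15000); ab42 <- c(500, 700, 650)
  expect_equal(compute_abeta_ratio(ab42, ab40) * ab40, ab42, tolerance = 1e-12)
  expect_error(compute_abeta_ratio(1, 0), "positive")
})

test_that("SNP-outcome regression matches the normal-equations oracle", {
  set.seed(5)
  n <- 200
  covs <- data.frame(age = runif(n, 45, 74), sex = rbinom(n, 1, 0.5),
                     education = round(rnorm(n, 12, 3)),
                     apoe_e4 = rbinom(n, 1, 0.3))
  g <- rbinom(n, 2, 0.4)
  y <- 0.2 * g - 0.01 * covs$age + 0.3 * covs$sex + rnorm(n)
  r <- snp_outcome_regression(g, y, covs, adjust_apoe = TRUE)
  X <- cbind(1, g, as.matrix(covs))
  o <- oracle_ols(X, y)
  expect_equal(r$beta_y, o$coef[2], tolerance = 1e-8)
  expect_equal(r$se_y, o$se[2], tolerance = 1e-8)
  expect_equal(r$n_used, n)

  # simple-regression identity without covariates
  r0 <- snp_outcome_regression(g, y, covariates = NULL)
  expect_equal(r0$beta_y, cov(g, y) / var(g), tolerance = 1e-12)

  # orthogonal covariates leave the slope unchanged (Frisch-Waugh)
  covo <- covs
  for (v in names(covo)) covo[[v]] <- residuals(lm(covo[[v]] ~ g))
  ro <- snp_outcome_regression(g, y, covo, adjust_apoe = TRUE)
  expect_equal(ro$beta_y, r0$beta_y, tolerance = 1e-8)

  # complete cases are per SNP
  g2 <- g; g2[1:10] <- NA
  r2 <- snp_outcome_regression(g2, y, covs)
  expect_equal(r2$n_used, n - 10)

  expect_error(snp_outcome_regression(rep(1, n), y, covs), "zero variance")
  expect_error(snp_outcome_regression(g[1:5], y[1:5], covs[1:5, ]), "complete cases")
})

test_that("regression equivariance: outcome shifts, scalings, dosage recode", {
  set.seed(6)
  n <- 150
  covs <- data.frame(age = runif(n, 45, 74), sex = rbinom(n, 1, 0.5),
                     education = round(rnorm(n, 12, 3)), apoe_e4 = rbinom(n, 1, 0.3))
  g <- rbinom(n, 2, 0.5)
  y <- 0.1 * g + rnorm(n)
  r <- snp_outcome_regression(g, y, covs)
  rs <- snp_outcome_regression(g, 3 * y + 7, covs)
  expect_equal(rs$beta_y, 3 * r$beta_y, tolerance = 1e-10)
  expect_equal(rs$se_y, 3 * r$se_y, tolerance = 1e-10)
  rf <- snp_outcome_regression(2 - g, y, covs)
  expect_equal(rf$beta_y, -r$beta_y, tolerance = 1e-10)
  expect_equal(rf$se_y, r$se_y, tolerance = 1e-10)
})
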