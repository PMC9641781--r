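test_that("ratio estimates are Wald ratios with first-order delta SEs", {
  inp <- mr_input(beta_x = c(0.1, 0.2), se_x = c(0.01, 0.01),
                  beta_y = c(0.2, 0), se_y = c(0.05, 0.03))
  re <- ratio_estimates(inp)
  expect_equal(re$ratio, c(2, 0))
  expect_equal(re$se, c(0.5, 0.15))
  expect_equal(re$w, c(4, 1 / 0.15^2))

  # beta_x sign flip flips the ratio, SE invariant
  inp2 <- mr_input(-inp$beta_x, inp$se_x, inp$beta_y, inp$se_y)
  re2 <- ratio_estimates(inp2)
  expect_equal(re2$ratio, -re$ratio)
  expect_equal(re2$se, re$se)

  inp3 <- mr_input(c(0.1, 0), c(0.01, 0.01), c(0.1, 0.1), c(0.02, 0.02),
                   rsid = c("a", "b"))
  expect_warning(re3 <- ratio_estimates(inp3), "b")
  expect_equal(attr(re3, "excluded"), "b")
  expect_equal(nrow(re3), 1)
})

test_that("IVW equals weighted least squares through the origin", {
  # degenerate J = 1: the single Wald ratio with its delta SE
  one <- mr_input(0.1, 0.01, 0.25, 0.04)
  e1 <- ivw_estimate(one, model = "fixed")
  expect_equal(e1$beta, 2.5)
  expect_equal(e1$se, 0.4)

  # homogeneous panel: beta = common ratio, fixed SE = (J w)^(-1/2)
  J <- 6
  hom <- mr_input(rep(0.1, J), rep(0.01, J), rep(0.05, J), rep(0.02, J))
  eh <- ivw_estimate(hom, model = "fixed")
  expect_equal(eh$beta, 0.5)
  expect_equal(eh$se, (J * (0.02 / 0.1)^-2)^-0.5)

  for (s in 1:20) {
    inp <- random_mr_input(10, seed = s)
    o <- oracle_ivw(inp)
    ef <- ivw_estimate(inp, model = "fixed")
    er <- ivw_estimate(inp, model = "random")
    expect_equal(ef$beta, o$beta, tolerance = 1e-10)
    expect_equal(ef$se, o$se_fixed, tolerance = 1e-10)
    expect_equal(er$beta, o$beta, tolerance = 1e-10)
    expect_equal(er$se, o$se_random, tolerance = 1e-10)
    expect_gte(er$se, ef$se)   # random-effects SE floored at fixed
  }
})

test_that("maximum likelihood matches the joint-optimization oracle", {
  # exposure measured without error -> collapses to fixed-effect IVW
  inp <- random_mr_input(8, seed = 31)
  noerr <- mr_input(inp$beta_x, rep(1e-8, 8), inp$beta_y, inp$se_y)
  expect_equal(max_likelihood_estimate(noerr)$beta,
               ivw_estimate(noerr, model = "fixed")$beta, tolerance = 1e-6)

  for (s in 1:10) {
    inp <- random_mr_input(5, seed = 100 + s)
    ml <- max_likelihood_estimate(inp)
    expect_equal(ml$beta, oracle_ml(inp), tolerance = 1e-6)
  }

  # permutation invariance
  inp <- random_mr_input(7, seed = 41)
  perm <- mr_input(inp$beta_x[7:1], inp$se_x[7:1], inp$beta_y[7:1],
                   inp$se_y[7:1])
  expect_equal(max_likelihood_estimate(perm)$beta,
               max_likelihood_estimate(inp)$beta, tolerance = 1e-10)
})

test_that("weighted median walks the cumulative weights and resists outliers", {
  eq <- mr_input(rep(0.1, 3), rep(0.01, 3), c(0.1, 0.2, 0.3), rep(0.02, 3))
  expect_equal(weighted_median_estimate(eq, n_boot = 100, seed = 1)$beta, 2)

  # a SNP holding > 50% of total weight pins the median near its ratio
  dom <- mr_input(rep(0.1, 4), rep(0.01, 4), c(0.05, 0.3, 0.32, 0.31),
                  se_y = c(0.005, 0.1, 0.1, 0.1))
  est <- weighted_median_estimate(dom, n_boot = 100, seed = 1)$beta
  expect_equal(est, 0.5, tolerance = 0.2)

  for (s in 1:30) {
    inp <- random_mr_input(sample(3:15, 1), seed = 200 + s)
    re <- ratio_estimates(inp)
    expect_equal(weighted_median_estimate(inp, n_boot = 100, seed = s)$beta,
                 oracle_weighted_median(re$ratio, re$w), tolerance = 1e-10)
  }

  # breakdown: one wild low-weight outlier barely moves the median, but IVW shifts
  set.seed(9)
  good <- mr_input(rep(0.1, 10), rep(0.005, 10),
                   beta_y = c(rep(0.02, 9), 1.0),
                   se_y = c(rep(0.01, 9), 0.25))
  wm <- weighted_median_estimate(good, n_boot = 100, seed = 2)$beta
  ivw <- ivw_estimate(good)$beta
  expect_lt(abs(wm - 0.2), 0.05)
  expect_gt(abs(ivw - 0.2), abs(wm - 0.2))
  expect_error(weighted_median_estimate(mr_input(1:2 / 10, c(.01, .01),
                                                 c(0, 0), c(.01, .01))),
               "at least 3")
})

test_that("weighted mode finds the dominant KDE peak", {
  same <- mr_input(rep(0.1, 4), rep(0.01, 4), rep(0.03, 4), rep(0.02, 4))
  expect_equal(weighted_mode_estimate(same, n_boot = 100, seed = 1)$beta, 0.3)

  # 7 high-weight SNPs at ratio 0.5 vs 3 low-weight at 3.0
  bx <- rep(0.1, 10)
  by <- c(rep(0.05, 7), rep(0.30, 3))
  sy <- c(rep(0.01, 7), rep(0.02, 3))
  clus <- mr_input(bx, rep(0.005, 10), by, sy)
  est <- weighted_mode_estimate(clus, n_boot = 100, seed = 3)
  expect_equal(est$beta, 0.5, tolerance = 0.05)
  expect_gt(abs(ivw_estimate(clus)$beta - est$beta), 0.1)  # mean is pulled away

  for (s in 1:10) {
    inp <- random_mr_input(sample(5:12, 1), seed = 300 + s)
    re <- ratio_estimates(inp)
    expect_lt(abs(weighted_mode_estimate(inp, n_boot = 100, seed = s)$beta -
                    oracle_weighted_mode(re$ratio, re$w)), 1e-3)
    perm <- mr_input(rev(inp$beta_x), rev(inp$se_x), rev(inp$beta_y),
                     rev(inp$se_y))
    expect_equal(weighted_mode_estimate(perm, n_boot = 100, seed = s)$beta,
                 weighted_mode_estimate(inp, n_boot = 100, seed = s)$beta,
                 tolerance = 1e-8)
  }
})

test_that("Egger regression equals two-column weighted least squares", {
  # exact line: three non-collinear points reproduce intercept and slope
  bx <- c(0.05, 0.1, 0.2)
  line <- mr_input(bx, rep(0.01, 3), beta_y = 0.03 + 0.7 * bx,
                   se_y = c(0.01, 0.02, 0.015))
  e <- egger_regression(line)
  expect_equal(e$beta, 0.7, tolerance = 1e-10)
  expect_equal(e$aux$intercept, 0.03, tolerance = 1e-10)
  expect_true(is.na(e$aux$intercept_pval))   # degenerate exact fit

  for (s in 1:20) {
    inp <- random_mr_input(10, seed = 400 + s)
    e <- egger_regression(inp)
    o <- oracle_egger(inp)
    expect_equal(e$beta, o$slope, tolerance = 1e-10)
    expect_equal(e$se, o$se_slope, tolerance = 1e-10)
    expect_equal(e$aux$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(e$aux$intercept_se, o$se_intercept, tolerance = 1e-10)
  }

  expect_error(egger_regression(random_mr_input(2, seed = 1)), "at least 3")
  flat <- mr_input(rep(0.1, 5), rep(0.01, 5), rnorm(5, 0, 0.01), rep(0.01, 5))
  expect_error(egger_regression(flat), "leverage")
})

test_that("estimators are scale-equivariant and sign-equivariant", {
  inp <- random_mr_input(12, seed = 77)
  fit <- mr_fit(inp, n_boot = 200, seed = 5)
  cc <- 3.5
  scaled <- mr_input(inp$beta_x, inp$se_x, cc * inp$beta_y, cc * inp$se_y)
  fit_s <- mr_fit(scaled, n_boot = 200, seed = 5)
  expect_equal(fit_s$estimates$beta, cc * fit$estimates$beta, tolerance = 1e-6)
  expect_equal(fit_s$estimates$se, cc * fit$estimates$se, tolerance = 1e-6)

  flipped <- mr_input(-inp$beta_x, inp$se_x, inp$beta_y, inp$se_y)
  fit_f <- mr_fit(flipped, n_boot = 200, seed = 5)
  expect_equal(fit_f$estimates$beta, -fit$estimates$beta, tolerance = 1e-6)
})

test_that("on valid instruments all five estimators agree", {
  agree <- 0
  n_rep <- 40
  for (r in 1:n_rep) {
    cfg <- sim_config(seed = 5000 + r)
    pan <- simulate_true_panel(cfg)
    inp <- simulate_summary_mr(pan, theta = 0.1, n_cohort = 5000,
                               seed = 6000 + r)
    fit <- mr_fit(inp, n_boot = 50, seed = r)
    est <- fit$estimates
    tol <- 2 * max(est$se)
    if (all(abs(est$beta - est$beta[est$method == "ivw"]) <= tol))
      agree <- agree + 1
  }
  expect_gte(agree / n_rep, 0.95)
})

test_that("mr_fit object supports the standard S3 surface", {
  inp <- random_mr_input(10, seed = 55)
  fit <- mr_fit(inp, n_boot = 100, seed = 2)
  expect_s3_class(fit, "mr_fit")
  expect_named(coef(fit), fit$estimates$method)
  ci <- confint(fit)
  expect_equal(unname(ci["ivw", ]),
               unname(c(fit$estimates["ivw", "ci_low"],
                        fit$estimates["ivw", "ci_high"])), tolerance = 1e-10)
  expect_output(print(fit), "ivw")
  expect_output(summary(fit), "Cochran Q")
  f <- tempfile(fileext = ".pdf")
  grDevices::pdf(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))

  # too few SNPs: methods are skipped with a warning, not an error
  two <- random_mr_input(2, seed = 56)
  w <- capture_warnings(f2 <- mr_fit(two, seed = 1))
  expect_true(any(grepl("skipping", w)))
  expect_true("ivw" %in% f2$estimates$method)
  expect_false("egger" %in% f2$estimates$method)
})
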