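#' Cochran Q heterogeneity statistic
#'
#' `Q = sum w_j (ratio_j - beta_ref)^2` over the per-SNP Wald ratios with
#' inverse-variance weights; under instrument validity Q is approximately
#' chi-square on `J - 1` degrees of freedom. The reference is the
#' fixed-effect IVW estimate by definition (even when the headline estimate is
#' random-effects), unless `beta_ref` is supplied.
#'
#' @param input an [mr_input()] with `J >= 2`.
#' @param beta_ref optional reference effect; default fixed-effect IVW.
#' @return list with `Q`, `df` (= J - 1) and upper-tail chi-square `pval`.
#' @export
cochran_q <- function(input, beta_ref = NULL) {
  re <- ratio_estimates(input)
  J <- nrow(re)
  if (J < 2L) stopf("Cochran Q needs at least 2 SNPs")
  if (is.null(beta_ref))
    beta_ref <- sum(re$w * re$ratio) / sum(re$w)
  Q <- sum(re$w * (re$ratio - beta_ref)^2)
  df <- J - 1L
  list(Q = Q, df = df, pval = pchisq(Q, df, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Two-sided t-test (`J - 2` df) of the MR-Egger intercept against zero; a
#' non-zero intercept indicates average directional pleiotropy across the
#' instruments.
#'
#' @param input an [mr_input()] with `J >= 3`.
#' @return list with `intercept`, `se`, `df` and `pval` (`NA` on an exact
#'   three-SNP fit, where the residual scale is degenerate).
#' @export
egger_intercept_test <- function(input) {
  e <- egger_regression(input)
  list(intercept = e$aux$intercept, se = e$aux$intercept_se,
       df = e$aux$df, pval = e$aux$intercept_pval)
}

# leave-one-out slopes of the origin-WLS fit, vectorized:
# slope^(-j) = (A - w_j bx_j by_j) / (B - w_j bx_j^2)
loo_slopes <- function(bx, by, w) {
  A <- sum(w * bx * by); B <- sum(w * bx^2)
  (A - w * bx * by) / (B - w * bx^2)
}

#' MR-PRESSO global pleiotropy and outlier test
#'
#' The observed global residual sum of squares is
#' `RSS = sum_j w_j (beta_y_j - slope^(-j) beta_x_j)^2`, where `slope^(-j)` is
#' the IVW (origin-WLS) slope fitted without SNP j and `w_j = se_y_j^-2`. Its
#' null distribution is simulated parametrically: `n_sim` draws of
#' `beta_x* ~ N(beta_x_j, se_x_j)` and `beta_y* ~ N(slope^(-j) beta_x_j,
#' se_y_j)`, with the RSS recomputed on each draw. The global p-value is the
#' smoothed empirical exceedance `(1 + #\{RSS* >= RSS\}) / (n_sim + 1)` (so
#' its floor is `1/(n_sim+1)`). Each SNP's observed residual contribution is
#' compared with its own simulated distribution to give a per-SNP outlier
#' p-value, Bonferroni-adjusted across J; SNPs below `outlier_alpha` are
#' flagged and an outlier-corrected IVW estimate on the remaining SNPs is
#' returned. A distortion test (is the corrected estimate further from the
#' original than random removal of as many SNPs would move it?) is reported
#' for information only.
#'
#' @param input an [mr_input()] with `J >= 4`.
#' @param n_sim parametric simulations (>= 100; default 1000).
#' @param seed RNG seed, recorded in the result.
#' @param outlier_alpha threshold on the Bonferroni-adjusted per-SNP p-values.
#' @param ivw_model flavor for the corrected estimate.
#' @return list of class `"mr_presso"`: `rss_obs`, `global_pval`,
#'   `outlier_pvals` (adjusted, named by rsid), `outliers`, `corrected`
#'   (an `mr_estimate` or `NULL` when no outliers), `distortion`
#'   (informational), `n_sim`, `seed`.
#' @export
mr_presso <- function(input, n_sim = 1000, seed = NULL, outlier_alpha = 0.05,
                      ivw_model = c("random", "fixed")) {
  input <- as_mr_input(input)
  ivw_model <- match.arg(ivw_model)
  J <- nrow(input)
  if (J < 4L) stopf("MR-PRESSO needs at least 4 SNPs (leave-one-out IVW needs 3)")
  if (n_sim < 100L) stopf("n_sim must be at least 100")
  set_seed_if(seed)
  bx <- input$beta_x; by <- input$beta_y
  sx <- input$se_x; sy <- input$se_y
  w <- sy^-2
  sl <- loo_slopes(bx, by, w)
  d_obs <- w * (by - sl * bx)^2
  rss_obs <- sum(d_obs)

  # simulate: rows = simulations, cols = SNPs
  bxs <- matrix(rnorm(n_sim * J, rep(bx, each = n_sim), rep(sx, each = n_sim)),
                n_sim, J)
  bys <- matrix(rnorm(n_sim * J, rep(sl * bx, each = n_sim),
                      rep(sy, each = n_sim)), n_sim, J)
  W <- matrix(w, n_sim, J, byrow = TRUE)
  A <- rowSums(W * bxs * bys)
  B <- rowSums(W * bxs^2)
  sls <- (A - W * bxs * bys) / (B - W * bxs^2)   # n_sim x J leave-one-out slopes
  d_sim <- W * (bys - sls * bxs)^2
  rss_sim <- rowSums(d_sim)

  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
  raw_p <- (1 + colSums(d_sim >= rep(d_obs, each = n_sim))) / (n_sim + 1)
  adj_p <- pmin(1, raw_p * J)
  names(adj_p) <- input$rsid
  outliers <- input$rsid[adj_p < outlier_alpha]

  corrected <- NULL
  distortion <- NULL
  if (length(outliers)) {
    keep <- !(input$rsid %in% outliers)
    if (sum(keep) >= 2L) {
      sub <- mr_input(bx[keep], sx[keep], by[keep], sy[keep],
                      rsid = input$rsid[keep],
                      outcome = attr(input, "outcome"),
                      stratum = attr(input, "stratum"))
      corrected <- ivw_estimate(sub, model = ivw_model)
      full <- ivw_estimate(input, model = ivw_model)
      obs_dist <- (corrected$beta - full$beta) / abs(full$beta)
      # informational: distortion expected from removing as many SNPs at random
      K <- length(outliers)
      nd <- min(n_sim, 500L)
      rand_dist <- vapply(seq_len(nd), function(i) {
        drop <- sample.int(J, K)
        kp <- setdiff(seq_len(J), drop)
        swk <- sum(w[kp] * bx[kp]^2)
        slk <- sum(w[kp] * bx[kp] * by[kp]) / swk
        (slk - full$beta) / abs(full$beta)
      }, 0)
      distortion <- list(coefficient = 100 * obs_dist,
                         pval = (1 + sum(abs(rand_dist) >= abs(obs_dist))) /
                                (nd + 1),
                         note = "informational only")
    }
  }
  structure(list(rss_obs = rss_obs, global_pval = global_p,
                 outlier_pvals = adj_p, outliers = outliers,
                 corrected = corrected, distortion = distortion,
                 n_sim = n_sim, seed = seed, outlier_alpha = outlier_alpha),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO: observed RSS = %.4g, global p = %.3g (n_sim = %d)\n",
              x$rss_obs, x$global_pval, x$n_sim))
  if (length(x$outliers)) {
    cat("outliers:", paste(x$outliers, collapse = ", "), "\n")
    if (!is.null(x$corrected))
      cat(sprintf("outlier-corrected IVW: beta = %.4g (SE %.4g), p = %.3g\n",
                  x$corrected$beta, x$corrected$se, x$corrected$pval))
  } else cat("no outliers detected\n")
  invisible(x)
}

#' Leave-one-SNP-out influence analysis
#'
#' Re-estimates the IVW effect with each instrument removed in turn, in the
#' input's rsid order. Rows whose p-value crosses the 0.05 line relative to
#' the full-panel estimate are flagged (`crosses_alpha`): a flagged row means
#' the headline significance hinges on that single SNP.
#'
#' @param input an [mr_input()] with `J >= 2` (each re-fit needs `J - 1 >= 1`;
#'   random-effects re-fits need `J - 1 >= 2`).
#' @param ivw_model IVW flavor, matching the main analysis.
#' @param alpha significance line for the crossing flag.
#' @return data frame (class `"mr_loo"`) with one row per removed rsid:
#'   `rsid_removed`, `beta`, `se`, `pval`, `crosses_alpha`; the full-panel
#'   estimate is in attributes `full_beta`, `full_pval`.
#' @export
leave_one_out <- function(input, ivw_model = c("random", "fixed"),
                          alpha = 0.05) {
  input <- as_mr_input(input)
  ivw_model <- match.arg(ivw_model)
  J <- nrow(input)
  min_left <- if (ivw_model == "random") 2L else 1L
  if (J - 1L < min_left) stopf("leave-one-out needs at least %d SNPs", min_left + 1L)
  full <- ivw_estimate(input, model = ivw_model)
  rows <- lapply(seq_len(J), function(j) {
    sub <- input[-j, , drop = FALSE]
    e <- ivw_estimate(mr_input(sub$beta_x, sub$se_x, sub$beta_y, sub$se_y,
                               rsid = sub$rsid), model = ivw_model)
    data.frame(rsid_removed = input$rsid[j], beta = e$beta, se = e$se,
               pval = e$pval, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$crosses_alpha <- (out$pval < alpha) != (full$pval < alpha)
  attr(out, "full_beta") <- full$beta
  attr(out, "full_pval") <- full$pval
  class(out) <- c("mr_loo", "data.frame")
  out
}

#' Full sensitivity report for one MR input
#'
#' Bundles Cochran Q, the MR-Egger intercept test, MR-PRESSO and the
#' leave-one-SNP-out table into one report, the "sensitivity methods" block
#' accompanying each causal estimate.
#'
#' @param input an [mr_input()].
#' @param n_sim MR-PRESSO simulations.
#' @param seed RNG seed (recorded).
#' @param outlier_alpha MR-PRESSO outlier threshold.
#' @param ivw_model IVW flavor used by PRESSO correction and leave-one-out.
#' @return list of class `"mr_sensitivity"` with elements `q`, `egger`,
#'   `presso`, `loo` (components `NULL` when J is too small, with a note in
#'   `skipped`).
#' @export
mr_sensitivity <- function(input, n_sim = 1000, seed = NULL,
                           outlier_alpha = 0.05,
                           ivw_model = c("random", "fixed")) {
  input <- as_mr_input(input)
  ivw_model <- match.arg(ivw_model)
  J <- nrow(input)
  skipped <- character()
  q <- if (J >= 2L) cochran_q(input) else { skipped <- c(skipped, "cochran_q"); NULL }
  eg <- if (J >= 3L) egger_intercept_test(input) else { skipped <- c(skipped, "egger_intercept"); NULL }
  pr <- if (J >= 4L) mr_presso(input, n_sim, seed, outlier_alpha, ivw_model)
        else { skipped <- c(skipped, "mr_presso"); NULL }
  lo <- if (J >= 3L || (J >= 2L && ivw_model == "fixed"))
          leave_one_out(input, ivw_model)
        else { skipped <- c(skipped, "leave_one_out"); NULL }
  structure(list(q = q, egger = eg, presso = pr, loo = lo,
                 skipped = skipped, seed = seed, n_sim = n_sim),
            class = "mr_sensitivity")
}

#' @export
print.mr_sensitivity <- function(x, ...) {
  cat("MR sensitivity report\n")
  if (!is.null(x$q))
    cat(sprintf("  Cochran Q: %.3f on %d df, p = %.3g\n", x$q$Q, x$q$df, x$q$pval))
  if (!is.null(x$egger))
    cat(sprintf("  Egger intercept: %.4g (SE %.4g), p = %.3g\n",
                x$egger$intercept, x$egger$se, x$egger$pval))
  if (!is.null(x$presso))
    cat(sprintf("  MR-PRESSO global p = %.3g, outliers: %s\n",
                x$presso$global_pval,
                if (length(x$presso$outliers))
                  paste(x$presso$outliers, collapse = ", ") else "none"))
  if (!is.null(x$loo))
    cat(sprintf("  leave-one-out: %d re-fits, %d cross alpha\n",
                nrow(x$loo), sum(x$loo$crosses_alpha)))
  if (length(x$skipped))
    cat("  skipped (too few SNPs):", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}
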