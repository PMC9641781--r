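#' Fit the causal effect of a genetically predicted exposure on one outcome
#'
#' The central fitting function: runs the requested summary-data MR estimators
#' on one [mr_input()] and returns a classed model object with the usual
#' accessor methods. Estimates are in outcome units per SD of the exposure
#' (per copy of the exposure-increasing allele on the exposure scale of the
#' external GWAS).
#'
#' @param input an [mr_input()] (or a data frame with columns `beta_x`,
#'   `se_x`, `beta_y`, `se_y` and optionally `rsid`).
#' @param methods subset of `c("ivw", "max_likelihood", "weighted_median",
#'   "weighted_mode", "egger")`; all five by default. Methods whose minimum
#'   SNP count exceeds `J` are skipped with a warning.
#' @param ivw_model `"random"` (default) or `"fixed"`; both SE flavors are
#'   kept in the estimates table either way.
#' @param n_boot parametric-bootstrap draws for the median/mode SEs.
#' @param seed RNG seed for the bootstraps (recorded in the object).
#' @param phi weighted-mode bandwidth factor.
#' @return An object of class `"mr_fit"`: a list with `estimates` (one row per
#'   method: method, beta, se, ci_low, ci_high, pval, J), `input`, `details`
#'   (the raw `mr_estimate` objects), `ivw_model`, `seed` and `call`. Methods:
#'   [print.mr_fit()], [summary.mr_fit()], [coef.mr_fit()],
#'   [confint.mr_fit()], [plot.mr_fit()].
#' @seealso [mr_sensitivity()] for heterogeneity/pleiotropy diagnostics.
#' @examples
#' set.seed(1)
#' inp <- mr_input(beta_x = abs(rnorm(10, 0.1, 0.02)), se_x = rep(0.005, 10),
#'                 beta_y = rnorm(10, 0.005, 0.01), se_y = rep(0.01, 10))
#' fit <- mr_fit(inp, seed = 7)
#' coef(fit)
#' @export
mr_fit <- function(input,
                   methods = c("ivw", "max_likelihood", "weighted_median",
                               "weighted_mode", "egger"),
                   ivw_model = c("random", "fixed"),
                   n_boot = 1000, seed = NULL, phi = 1) {
  input <- as_mr_input(input)
  ivw_model <- match.arg(ivw_model)
  methods <- match.arg(methods, several.ok = TRUE)
  J <- nrow(input)
  need <- c(ivw = if (ivw_model == "random") 2L else 1L, max_likelihood = 2L,
            weighted_median = 3L, weighted_mode = 3L, egger = 3L)
  details <- list()
  for (m in methods) {
    if (J < need[[m]]) {
      warnf("skipping %s: needs %d SNPs, have %d", m, need[[m]], J)
      next
    }
    details[[m]] <- switch(m,
      ivw = ivw_estimate(input, model = ivw_model),
      max_likelihood = max_likelihood_estimate(input),
      weighted_median = weighted_median_estimate(input, n_boot, seed),
      weighted_mode = weighted_mode_estimate(input, phi, n_boot, seed),
      egger = egger_regression(input))
  }
  if (!length(details)) stopf("no estimator could be run on %d SNP(s)", J)
  est <- do.call(rbind, lapply(names(details), function(m) {
    e <- details[[m]]
    data.frame(method = m, beta = e$beta, se = e$se, ci_low = e$ci_low,
               ci_high = e$ci_high, pval = e$pval, J = e$J,
               stringsAsFactors = FALSE)
  }))
  rownames(est) <- est$method
  structure(list(estimates = est, input = input, details = details,
                 ivw_model = ivw_model, seed = seed, call = match.call()),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Two-sample MR fit: %s | stratum %s | J = %d instruments\n",
              attr(x$input, "outcome"), attr(x$input, "stratum"),
              nrow(x$input)))
  tab <- x$estimates
  tab[c("beta", "se", "ci_low", "ci_high")] <-
    lapply(tab[c("beta", "se", "ci_low", "ci_high")], signif, digits)
  tab$pval <- signif(tab$pval, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Summary of an MR fit, including heterogeneity and pleiotropy diagnostics
#'
#' @param object an [mr_fit()].
#' @param ... passed on.
#' @return `object`, invisibly, after printing the estimates plus Cochran Q
#'   and (when available) the Egger intercept test.
#' @export
summary.mr_fit <- function(object, ...) {
  print(object, ...)
  if (nrow(object$input) >= 2L) {
    q <- cochran_q(object$input)
    cat(sprintf("Cochran Q = %.3f on %d df, p = %.3g\n", q$Q, q$df, q$pval))
  }
  if (!is.null(object$details$egger)) {
    a <- object$details$egger$aux
    cat(sprintf("Egger intercept = %.4g (SE %.4g), p = %.3g\n",
                a$intercept, a$intercept_se, a$intercept_pval))
  }
  invisible(object)
}

#' @export
coef.mr_fit <- function(object, ...) {
  setNames(object$estimates$beta, object$estimates$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  est <- object$estimates
  if (!missing(parm)) est <- est[est$method %in% parm, , drop = FALSE]
  out <- cbind(low = numeric(nrow(est)), high = numeric(nrow(est)))
  rownames(out) <- est$method
  for (i in seq_len(nrow(est))) {
    e <- object$details[[est$method[i]]]
    mult <- if (identical(e$method, "egger")) qt((1 + level) / 2, e$aux$df)
            else qnorm((1 + level) / 2)
    out[i, ] <- e$beta + c(-1, 1) * mult * e$se
  }
  out
}

#' Scatter plot of SNP-outcome vs SNP-exposure associations
#'
#' One point per instrument (`beta_x`, `beta_y`) with +/- 1 SE bars and the
#' fitted IVW line through the origin; the slope of the line is the IVW causal
#' estimate. If the fit includes MR-Egger its line (with intercept) is added
#' dashed.
#'
#' @param x an [mr_fit()].
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.mr_fit <- function(x, ...) {
  inp <- x$input
  graphics::plot(inp$beta_x, inp$beta_y,
                 xlab = "SNP-exposure effect (SD per allele)",
                 ylab = sprintf("SNP effect on %s", attr(inp, "outcome")),
                 pch = 19, ...)
  graphics::segments(inp$beta_x, inp$beta_y - inp$se_y,
                     inp$beta_x, inp$beta_y + inp$se_y, col = "grey60")
  graphics::segments(inp$beta_x - inp$se_x, inp$beta_y,
                     inp$beta_x + inp$se_x, inp$beta_y, col = "grey60")
  if (!is.null(x$details$ivw))
    graphics::abline(0, x$details$ivw$beta, col = "firebrick", lwd = 2)
  if (!is.null(x$details$egger))
    graphics::abline(x$details$egger$aux$intercept, x$details$egger$beta,
                     col = "steelblue", lty = 2)
  invisible(x)
}
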