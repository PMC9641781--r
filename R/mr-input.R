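#' Assemble harmonized summary data for one outcome in one stratum
#'
#' An `mr_input` is the unit of all estimation: aligned per-SNP vectors of
#' exposure associations (from an external GWAS, in SD of the exposure per
#' copy of the effect allele) and outcome associations (from in-sample linear
#' regressions, in outcome units per copy of the same allele), with their
#' standard errors. All downstream estimators and diagnostics consume this
#' object.
#'
#' @param beta_x,se_x per-SNP exposure effect and standard error; `se_x > 0`.
#' @param beta_y,se_y per-SNP outcome effect and standard error; `se_y > 0`.
#' @param rsid optional SNP identifiers; defaults to `snp1..snpJ`. Must be
#'   unique.
#' @param outcome,stratum labels carried through to estimates and reports.
#' @return A data frame of class `"mr_input"` with columns `rsid`, `beta_x`,
#'   `se_x`, `beta_y`, `se_y` and attributes `outcome` and `stratum`.
#' @examples
#' inp <- mr_input(beta_x = c(0.1, 0.08, 0.12), se_x = c(0.01, 0.01, 0.01),
#'                 beta_y = c(0.02, 0.01, 0.03), se_y = c(0.01, 0.01, 0.01))
#' mr_fit(inp, methods = "ivw")
#' @export
mr_input <- function(beta_x, se_x, beta_y, se_y, rsid = NULL,
                     outcome = "outcome", stratum = "whole") {
  J <- length(beta_x)
  if (J < 1L) stopf("mr_input needs at least one SNP")
  lens <- c(length(se_x), length(beta_y), length(se_y))
  if (any(lens != J)) stopf("beta_x, se_x, beta_y, se_y must have equal length")
  check_num(beta_x, "beta_x"); check_num(beta_y, "beta_y")
  check_num(se_x, "se_x", positive = TRUE)
  check_num(se_y, "se_y", positive = TRUE)
  if (is.null(rsid)) rsid <- paste0("snp", seq_len(J))
  if (length(rsid) != J) stopf("rsid must match the number of SNPs")
  if (anyDuplicated(rsid)) stopf("rsid values must be unique")
  out <- data.frame(rsid = as.character(rsid), beta_x = as.numeric(beta_x),
                    se_x = as.numeric(se_x), beta_y = as.numeric(beta_y),
                    se_y = as.numeric(se_y), stringsAsFactors = FALSE)
  attr(out, "outcome") <- outcome
  attr(out, "stratum") <- stratum
  class(out) <- c("mr_input", "data.frame")
  out
}

as_mr_input <- function(x) {
  if (inherits(x, "mr_input")) return(x)
  need <- c("beta_x", "se_x", "beta_y", "se_y")
  if (is.data.frame(x) && all(need %in% names(x)))
    return(mr_input(x$beta_x, x$se_x, x$beta_y, x$se_y, rsid = x$rsid,
                    outcome = attr(x, "outcome") %||% "outcome",
                    stratum = attr(x, "stratum") %||% "whole"))
  stopf("cannot interpret object as mr_input")
}

#' @export
print.mr_input <- function(x, ...) {
  cat(sprintf("mr_input: %d SNPs | outcome: %s | stratum: %s\n",
              nrow(x), attr(x, "outcome"), attr(x, "stratum")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Per-SNP Wald ratio estimates
#'
#' The causal effect attributed to each instrument is the ratio of its outcome
#' association to its exposure association, `beta_y / beta_x`, with a
#' first-order delta-method standard error `se_y / |beta_x|`. Inverse-variance
#' weights `w = se^-2` on these ratios are what every downstream estimator
#' uses. SNPs with `beta_x == 0` have an undefined ratio and are excluded with
#' a warning (their rsids are recorded in the `"excluded"` attribute).
#'
#' @param input an [mr_input()].
#' @return data frame with columns `rsid`, `ratio`, `se`, `w` and attribute
#'   `excluded`.
#' @export
ratio_estimates <- function(input) {
  input <- as_mr_input(input)
  bad <- input$beta_x == 0
  excluded <- input$rsid[bad]
  if (any(bad)) {
    warnf("excluding %d SNP(s) with beta_x = 0: %s",
          sum(bad), paste(excluded, collapse = ", "))
    input <- input[!bad, , drop = FALSE]
  }
  if (nrow(input) == 0L) stopf("no SNPs left after excluding beta_x = 0")
  se <- input$se_y / abs(input$beta_x)
  out <- data.frame(rsid = input$rsid,
                    ratio = input$beta_y / input$beta_x,
                    se = se, w = se^-2, stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  out
}

# container for a single estimator's result
new_mr_estimate <- function(method, beta, se, pval, J, ci_mult = qnorm(0.975),
                            aux = list()) {
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - ci_mult * se, ci_high = beta + ci_mult * se,
                 pval = pval, J = J, aux = aux),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("%s: beta = %.*g (SE %.*g), 95%% CI [%.*g, %.*g], p = %.3g, J = %d\n",
              x$method, digits, x$beta, digits, x$se, digits, x$ci_low,
              digits, x$ci_high, x$pval, x$J))
  invisible(x)
}
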