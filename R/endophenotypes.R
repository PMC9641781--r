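#' Within-cohort Z-score
#'
#' Centers and scales to the analysis sample's own mean and SD (n-1
#' denominator); missing values are ignored in the moments and propagated in
#' the output.
#'
#' @param x numeric vector with at least two non-missing values.
#' @return standardized vector of the same length.
#' @export
zscore <- function(x) {
  obs <- x[!is.na(x)]
  if (length(obs) < 2L) stopf("zscore needs at least 2 non-missing values")
  s <- sd(obs)
  if (!is.finite(s) || s == 0) stopf("zscore undefined for constant input")
  (x - mean(obs)) / s
}

# mean of z-scored columns, with the >= half-available missingness rule
composite_mean <- function(mat, min_prop = 0.5) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 1L) stopf("composite needs at least one component")
  z <- apply(mat, 2, zscore)
  if (is.null(dim(z))) z <- matrix(z, ncol = ncol(mat))
  k <- rowSums(!is.na(z))
  out <- rowMeans(z, na.rm = TRUE)
  out[k < ncol(mat) * min_prop | k == 0] <- NA_real_
  out
}

#' Modified preclinical Alzheimer cognitive composite (mPACC)
#'
#' Per-individual mean of the Z-scores of four components: memory-binding-test
#' immediate total paired recall, MBT delayed free recall, WAIS-IV coding and
#' semantic fluency. Higher is better. Individuals missing components keep a
#' composite when at least half the components are present (mean of the
#' available Z-scores), otherwise `NA`.
#'
#' @param mbt_total_paired,mbt_delayed_free,coding,semantic_fluency raw score
#'   vectors of equal length, each with positive variance.
#' @return numeric composite.
#' @export
compute_mpacc <- function(mbt_total_paired, mbt_delayed_free, coding,
                          semantic_fluency) {
  composite_mean(cbind(mbt_total_paired, mbt_delayed_free, coding,
                       semantic_fluency))
}

#' Cognitive domain composite
#'
#' Mean of the Z-scored subtest columns (episodic memory from the MBT
#' subtests, executive function from the WAIS-IV subtests). Same missingness
#' rule as [compute_mpacc()].
#'
#' @param subtest_matrix matrix/data frame, one column per subtest.
#' @return numeric composite, one value per row.
#' @export
compute_domain_composite <- function(subtest_matrix) {
  composite_mean(subtest_matrix)
}

#' Cortical-thickness region sets for the AD and aging signatures
#'
#' Region names of the two published thickness signatures: regions
#' preferentially thinned in Alzheimer's disease, and regions thinned in
#' normal aging. Higher signature values mean thicker cortex.
#' @return character vector of region names.
#' @export
ad_signature_regions <- function() {
  c("medial_temporal", "inferior_temporal", "temporal_pole",
    "superior_parietal", "precuneus", "angular", "supramarginal",
    "superior_frontal", "middle_frontal")
}

#' @rdname ad_signature_regions
#' @export
aging_signature_regions <- function() {
  c("calcarine", "caudal_insula", "cuneus", "caudal_fusiform",
    "dorsomedial_frontal", "lateral_occipital", "precentral",
    "inferior_frontal")
}

#' Cortical-thickness signature
#'
#' For each region the bilateral mean `(left + right)/2` is taken, and the
#' signature is the unweighted mean of the bilateral means over the region
#' set. Individuals missing either hemisphere of any region get `NA` (logged
#' via a warning count).
#'
#' @param thickness_left,thickness_right matrices/data frames of per-region
#'   cortical thickness (mm), columns named by region, rows by individual.
#' @param region_set regions to average; default all shared columns. Use
#'   [ad_signature_regions()] / [aging_signature_regions()].
#' @return numeric vector of signature values (mm).
#' @export
compute_signature <- function(thickness_left, thickness_right,
                              region_set = NULL) {
  L <- as.matrix(thickness_left); R <- as.matrix(thickness_right)
  if (is.null(region_set)) region_set <- intersect(colnames(L), colnames(R))
  miss <- setdiff(region_set, intersect(colnames(L), colnames(R)))
  if (length(miss))
    stopf("region(s) absent from thickness tables: %s",
          paste(miss, collapse = ", "))
  if (nrow(L) != nrow(R)) stopf("hemisphere tables must have equal rows")
  bilat <- (L[, region_set, drop = FALSE] + R[, region_set, drop = FALSE]) / 2
  out <- rowMeans(bilat)  # NA when any region is missing
  if (anyNA(out))
    warnf("signature missing for %d individual(s) with incomplete regions",
          sum(is.na(out)))
  out
}

#' CSF amyloid-beta 42/40 ratio
#'
#' Elementwise `ab42 / ab40`, the biomarker of amyloid pathology; lower values
#' indicate more amyloid deposition.
#'
#' @param ab42,ab40 analyte concentrations; `ab40` must be positive.
#' @return numeric ratio.
#' @export
compute_abeta_ratio <- function(ab42, ab40) {
  if (any(!is.na(ab40) & ab40 <= 0)) stopf("ab40 must be strictly positive")
  ab42 / ab40
}

#' Covariate-adjusted SNP-outcome regression
#'
#' Ordinary least squares of the outcome on (intercept, dosage, age, sex,
#' education, and optionally APOE-e4 carrier status). The dosage coefficient
#' is the per-allele SNP-outcome association `beta_y`; its SE comes from the
#' classical covariance `sigma^2 (X'X)^-1` with `n - k` denominator, and the
#' p-value from a two-sided t test. Complete cases only (per-SNP: individuals
#' missing this SNP's dosage or any regressor are dropped from this SNP's
#' regression only). The APOE covariate should be dropped
#' (`adjust_apoe = FALSE`) inside APOE-defined strata.
#'
#' @param dosage numeric vector in `[0, 2]`.
#' @param outcome numeric outcome vector.
#' @param covariates data frame with columns `age`, `sex`, `education` and,
#'   if `adjust_apoe`, `apoe_e4`; `NULL` for an unadjusted regression.
#' @param adjust_apoe include the APOE-e4 covariate (default TRUE).
#' @param rsid,outcome_name,stratum labels for the result row.
#' @return one-row data frame: `rsid`, `outcome`, `stratum`, `beta_y`, `se_y`,
#'   `pval`, `n_used`.
#' @export
snp_outcome_regression <- function(dosage, outcome, covariates,
                                   adjust_apoe = TRUE, rsid = "snp",
                                   outcome_name = "outcome",
                                   stratum = "whole") {
  if (is.null(covariates)) {
    covs <- character()
    X <- cbind(1, dosage)
  } else {
    covs <- c("age", "sex", "education", if (adjust_apoe) "apoe_e4")
    miss <- setdiff(covs, names(covariates))
    if (length(miss)) stopf("covariates missing: %s", paste(miss, collapse = ", "))
    X <- cbind(1, dosage, as.matrix(covariates[covs]))
  }
  colnames(X) <- c("(Intercept)", "dosage", covs)
  ok <- complete.cases(X) & !is.na(outcome)
  X <- X[ok, , drop = FALSE]; y <- outcome[ok]
  n <- nrow(X); k <- ncol(X)
  if (n < k + 2L) stopf("too few complete cases (%d) for %d regressors", n, k)
  if (var(X[, "dosage"]) == 0) stopf("dosage has zero variance in analysis set")
  # condition-number guard against collinear designs
  sv <- svd(scale(X[, -1], center = TRUE, scale = FALSE))$d
  if (sv[1] / max(sv[length(sv)], .Machine$double.eps) > 1e10)
    stopf("collinear design for %s on %s", rsid, outcome_name)
  XtXinv <- chol2inv(chol(crossprod(X)))
  b <- drop(XtXinv %*% crossprod(X, y))
  res <- y - X %*% b
  sigma2 <- sum(res^2) / (n - k)
  se <- sqrt(sigma2 * diag(XtXinv))
  i <- match("dosage", colnames(X))
  tval <- b[i] / se[i]
  data.frame(rsid = rsid, outcome = outcome_name, stratum = stratum,
             beta_y = b[i], se_y = se[i],
             pval = 2 * pt(-abs(tval), n - k), n_used = n,
             stringsAsFactors = FALSE)
}

#' Per-SNP outcome association scan
#'
#' Runs [snp_outcome_regression()] for every dosage column against one
#' outcome, the in-sample half of the two-sample MR design.
#'
#' @param dosages matrix/data frame of dosages, columns named by rsid.
#' @param outcome numeric outcome vector.
#' @param covariates,adjust_apoe,outcome_name,stratum see
#'   [snp_outcome_regression()].
#' @return data frame, one row per SNP.
#' @export
snp_outcome_scan <- function(dosages, outcome, covariates, adjust_apoe = TRUE,
                             outcome_name = "outcome", stratum = "whole") {
  dosages <- as.matrix(dosages)
  rows <- lapply(colnames(dosages), function(rs)
    snp_outcome_regression(dosages[, rs], outcome, covariates, adjust_apoe,
                           rsid = rs, outcome_name = outcome_name,
                           stratum = stratum))
  do.call(rbind, rows)
}
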