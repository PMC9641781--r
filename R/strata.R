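#' Classify APOE genotype from rs429358 and rs7412
#'
#' The epsilon haplotypes are defined by the two coding SNPs: rs429358-T with
#' rs7412-T is e2, T with C is e3, C with C is e4 (the e1 haplotype, C with T,
#' is assumed absent per the standard convention). Genotypes are unphased
#' two-allele strings (e.g. `"CT"`, order irrelevant); the double heterozygote
#' (C/T at both SNPs) is therefore phase-ambiguous between e2/e4 and e1/e3 and
#' is called e2/e4 under the no-e1 convention — which is exactly the
#' configuration excluded from analysis.
#'
#' @param g429358,g7412 character vectors of two-letter genotypes over
#'   \{C, T\}.
#' @return data frame: `rs429358`, `rs7412`, `epsilon` (e.g. `"e3/e4"`,
#'   alleles sorted), `e4_carrier` (any e4), `excluded` (the e2/e4 pair).
#' @examples
#' classify_apoe(c("TT", "CC", "CT"), c("CC", "CC", "CT"))
#' @export
classify_apoe <- function(g429358, g7412) {
  if (length(g429358) != length(g7412))
    stopf("genotype vectors must have equal length")
  norm <- function(g, snp) {
    g <- toupper(gsub("[/|]", "", g))
    if (any(is.na(g) | nchar(g) != 2L))
      stopf("%s genotypes must be two alleles", snp)
    al <- c(substr(g, 1, 1), substr(g, 2, 2))
    if (any(!al %in% c("C", "T")))
      stopf("%s allele outside {C, T}", snp)
    g
  }
  g1 <- norm(g429358, "rs429358")
  g2 <- norm(g7412, "rs7412")
  n1C <- nchar(gsub("[^C]", "", g1))  # count of C at rs429358 (e4-defining)
  n2T <- nchar(gsub("[^T]", "", g2))  # count of T at rs7412 (e2-defining)
  n <- length(g1)
  hap <- character(n)
  for (i in seq_len(n)) {
    e4 <- n1C[i]; e2 <- n2T[i]
    if (e4 + e2 > 2L)
      stopf("genotype pair (%s, %s) implies the e1 haplotype, unsupported",
            g1[i], g2[i])
    e3 <- 2L - e4 - e2
    hap[i] <- paste(rep(c("e2", "e3", "e4"), c(e2, e3, e4)), collapse = "/")
  }
  data.frame(rs429358 = g1, rs7412 = g2, epsilon = hap,
             e4_carrier = n1C > 0L,
             excluded = hap == "e2/e4", stringsAsFactors = FALSE)
}

#' Polygenic risk score
#'
#' Weighted allele sum `score_i = sum_k w_k g_ik` over risk-allele dosages
#' (weights are the per-allele effect sizes from the source GWAS, dosages
#' harmonized to the risk-increasing allele), then Z-standardized within the
#' cohort.
#'
#' @param dosages matrix/data frame (individuals x SNPs), columns named by
#'   rsid.
#' @param weights named numeric vector of per-allele weights; names must match
#'   the dosage columns (order-free).
#' @return data frame of class `"prs_result"`: `raw`, `z`.
#' @export
compute_prs <- function(dosages, weights) {
  dosages <- as.matrix(dosages)
  if (!all(is.finite(weights))) stopf("weights must be finite")
  if (is.null(names(weights))) {
    if (length(weights) != ncol(dosages))
      stopf("unnamed weights must match the number of dosage columns")
  } else {
    miss <- setdiff(names(weights), colnames(dosages))
    if (length(miss))
      stopf("weights name SNPs absent from dosages: %s",
            paste(miss, collapse = ", "))
    dosages <- dosages[, names(weights), drop = FALSE]
  }
  raw <- drop(dosages %*% weights)
  z <- if (length(unique(raw)) > 1L) zscore(raw) else {
    warnf("PRS is constant across the cohort; z-scores set to 0")
    rep(0, length(raw))
  }
  out <- data.frame(raw = raw, z = z)
  class(out) <- c("prs_result", "data.frame")
  out
}

#' Split a cohort at a PRS percentile
#'
#' The threshold is the stated percentile of the cohort's scores (type-7
#' linear-interpolation quantile); scores strictly above it are labeled
#' `"high"`, the rest `"low"`, so roughly 25% land in the high
#' genetic-predisposition group at the default 75th percentile. Ties sitting
#' exactly on the threshold go to `"low"` (strict inequality) with a warning
#' when that affects anyone.
#'
#' @param z_scores numeric scores (>= 4 values, not all identical).
#' @param percentile split point in (0, 100), default 75.
#' @return factor with levels `c("low", "high")`; the threshold is in
#'   attribute `"threshold"`.
#' @export
split_prs_groups <- function(z_scores, percentile = 75) {
  if (length(z_scores) < 4L) stopf("need at least 4 individuals to split")
  if (percentile <= 0 || percentile >= 100)
    stopf("percentile must be in (0, 100)")
  if (length(unique(z_scores)) == 1L)
    stopf("all scores identical: percentile threshold degenerate")
  thr <- quantile(z_scores, percentile / 100, type = 7, names = FALSE)
  g <- factor(ifelse(z_scores > thr, "high", "low"), levels = c("low", "high"))
  if (sum(z_scores == thr) > 1L)
    warnf("ties at the %gth-percentile threshold assigned to 'low'", percentile)
  attr(g, "threshold") <- thr
  g
}
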