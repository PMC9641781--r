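#' Load an exposure summary-statistics panel
#'
#' Reads a delimited table of per-SNP exposure associations (one row per
#' instrument SNP, effect sizes in SD of the exposure per copy of the effect
#' allele) and validates it into an instrument panel. Column names follow the
#' native convention `rsid, effect_allele, other_allele, beta, se, pval, eaf`;
#' other headers (e.g. GWAS-SSF style) are accepted through `column_map`.
#'
#' @param path TSV/CSV file path (delimiter sniffed from the extension; TSV
#'   default).
#' @param column_map named character vector mapping native names to the
#'   file's column names, e.g. `c(rsid = "variant_id", beta = "beta",
#'   se = "standard_error")`. Unmapped optional columns (`eaf`, `chr`, `pos`)
#'   are allowed to be absent.
#' @param provenance free-text source note stored on the panel.
#' @param threshold genome-wide selection threshold recorded on the panel
#'   (default `5e-8`); filtering itself is [filter_gw_significant()].
#' @return data frame of class `"instrument_panel"`: columns `rsid`,
#'   `effect_allele`, `other_allele`, `beta_x`, `se_x`, `pval`, `eaf`,
#'   `proxy_of`, `proxy_r2`; attributes `provenance`, `threshold`.
#'   Rows failing validation abort with messages naming the offending line.
#' @export
load_summary_stats <- function(path, column_map = NULL, provenance = path,
                               threshold = 5e-8) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
  native <- c(rsid = "rsid", effect_allele = "effect_allele",
              other_allele = "other_allele", beta = "beta", se = "se",
              pval = "pval", eaf = "eaf")
  if (!is.null(column_map)) native[names(column_map)] <- column_map
  required <- c("rsid", "effect_allele", "other_allele", "beta", "se", "pval")
  miss <- required[!(native[required] %in% names(raw))]
  if (length(miss))
    stopf("missing required column(s): %s (mapped to %s)",
          paste(miss, collapse = ", "),
          paste(native[miss], collapse = ", "))
  panel <- data.frame(
    rsid = as.character(raw[[native["rsid"]]]),
    effect_allele = toupper(as.character(raw[[native["effect_allele"]]])),
    other_allele = toupper(as.character(raw[[native["other_allele"]]])),
    beta_x = as.numeric(raw[[native["beta"]]]),
    se_x = as.numeric(raw[[native["se"]]]),
    pval = as.numeric(raw[[native["pval"]]]),
    eaf = if (native["eaf"] %in% names(raw))
            as.numeric(raw[[native["eaf"]]]) else NA_real_,
    proxy_of = "", proxy_r2 = NA_real_, stringsAsFactors = FALSE)
  validate_panel(panel)
  new_instrument_panel(panel, provenance = provenance, threshold = threshold)
}

new_instrument_panel <- function(df, provenance = "unspecified",
                                 threshold = 5e-8) {
  attr(df, "provenance") <- provenance
  attr(df, "threshold") <- threshold
  class(df) <- c("instrument_panel", "data.frame")
  df
}

validate_panel <- function(panel) {
  line <- seq_len(nrow(panel)) + 1L  # header is line 1
  dup <- duplicated(panel$rsid) | duplicated(panel$rsid, fromLast = TRUE)
  if (any(dup))
    stopf("duplicate rsid(s): %s (lines %s)",
          paste(unique(panel$rsid[dup]), collapse = ", "),
          paste(line[dup], collapse = ", "))
  bad_se <- !is.finite(panel$se_x) | panel$se_x <= 0
  if (any(bad_se))
    stopf("non-positive SE for %s (line %s)",
          paste(panel$rsid[bad_se], collapse = ", "),
          paste(line[bad_se], collapse = ", "))
  same <- panel$effect_allele == panel$other_allele
  if (any(same))
    stopf("effect and other allele identical for %s (line %s)",
          paste(panel$rsid[same], collapse = ", "),
          paste(line[same], collapse = ", "))
  bad_eaf <- !is.na(panel$eaf) & (panel$eaf <= 0 | panel$eaf >= 1)
  if (any(bad_eaf))
    stopf("eaf outside (0,1) for %s", paste(panel$rsid[bad_eaf], collapse = ", "))
  invisible(panel)
}

#' @export
print.instrument_panel <- function(x, ...) {
  cat(sprintf("instrument panel: %d SNPs | source: %s | threshold %g\n",
              nrow(x), attr(x, "provenance"), attr(x, "threshold")))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Keep genome-wide significant instruments
#'
#' Retains records with `pval` strictly below the threshold (the conventional
#' genome-wide line `5e-8`; a SNP at exactly the threshold is dropped).
#'
#' @param panel an `instrument_panel`.
#' @param threshold selection p-value in (0, 1].
#' @return filtered panel; a message reports the number removed and a warning
#'   is emitted when nothing survives.
#' @export
filter_gw_significant <- function(panel, threshold = 5e-8) {
  if (threshold <= 0 || threshold > 1) stopf("threshold must be in (0, 1]")
  keep <- panel$pval < threshold
  removed <- sum(!keep)
  if (removed) message(sprintf("filter_gw_significant: removed %d of %d SNPs",
                               removed, nrow(panel)))
  out <- panel[keep, , drop = FALSE]
  if (nrow(out) == 0L) warnf("no SNP passes the %g threshold", threshold)
  new_instrument_panel(out, attr(panel, "provenance"), threshold)
}

#' Default proxy whitelist
#'
#' Named r-squared values for proxy pairs accepted below the usual `r^2 >= 0.9`
#' rule; the defaults are the two documented exceptions in the telomere-length
#' panel.
#' @return named numeric vector (names = original rsids).
#' @export
default_proxy_whitelist <- function() {
  c(rs55749605 = 0.84, rs7705526 = 0.79)
}

#' Substitute a proxy SNP for an unavailable instrument
#'
#' Replaces a panel record with a linkage-disequilibrium proxy carrying its
#' own alleles and exposure statistics. The proxy is accepted iff
#' `r2 >= min_r2` (default 0.9) or the original rsid appears on the explicit
#' whitelist; otherwise the call fails.
#'
#' @param panel an `instrument_panel`.
#' @param missing_rsid the rsid to replace (must be in the panel).
#' @param proxy_record one-row data frame or named list with `rsid`,
#'   `effect_allele`, `other_allele`, `beta_x` (or `beta`), `se_x` (or `se`),
#'   `pval`, optionally `eaf`.
#' @param r2 LD between proxy and original, in `[0, 1]`.
#' @param whitelist named numeric vector as [default_proxy_whitelist()].
#' @param min_r2 acceptance threshold (default 0.9).
#' @return panel with the record replaced; `proxy_of` and `proxy_r2` set.
#' @export
substitute_proxy <- function(panel, missing_rsid, proxy_record, r2,
                             whitelist = default_proxy_whitelist(),
                             min_r2 = 0.9) {
  if (!missing_rsid %in% panel$rsid)
    stopf("%s is not in the panel", missing_rsid)
  if (r2 < 0 || r2 > 1) stopf("r2 must be in [0, 1]")
  pr <- as.list(proxy_record)
  pr$beta_x <- pr$beta_x %||% pr$beta
  pr$se_x <- pr$se_x %||% pr$se
  if (is.null(pr$rsid) || is.null(pr$beta_x) || is.null(pr$se_x))
    stopf("proxy_record needs rsid, beta and se")
  if (pr$rsid %in% panel$rsid) stopf("proxy %s already in the panel", pr$rsid)
  if (r2 < min_r2 && !missing_rsid %in% names(whitelist))
    stopf("proxy for %s rejected: r2 = %.3g < %.2g and pair not whitelisted",
          missing_rsid, r2, min_r2)
  i <- which(panel$rsid == missing_rsid)
  panel$rsid[i] <- pr$rsid
  panel$effect_allele[i] <- toupper(pr$effect_allele)
  panel$other_allele[i] <- toupper(pr$other_allele)
  panel$beta_x[i] <- pr$beta_x
  panel$se_x[i] <- pr$se_x
  panel$pval[i] <- pr$pval %||% panel$pval[i]
  panel$eaf[i] <- pr$eaf %||% NA_real_
  panel$proxy_of[i] <- missing_rsid
  panel$proxy_r2[i] <- r2
  validate_panel(panel)
  panel
}

#' Harmonize panel alleles against the cohort's genotype coding
#'
#' Fixes the allele reference so that the panel's effect allele (the
#' exposure-increasing allele) is the allele the cohort dosages count. For
#' each SNP the cohort's counted allele is compared with the panel alleles,
#' complementing for strand flips where needed:
#' \describe{
#'   \item{match}{cohort counts the effect allele; nothing to do.}
#'   \item{swap}{cohort counts the other allele; dosages must be recoded
#'     `2 - g` downstream (`flip_dosage = TRUE`).}
#'   \item{strand_flip / strand_flip_swap}{cohort alleles are the Watson-Crick
#'     complements; resolved by complement matching, then as match/swap.}
#'   \item{drop}{alleles irreconcilable, or a strand-ambiguous (A/T, C/G) SNP
#'     that cannot be resolved by allele-frequency comparison.}
#' }
#' Strand-ambiguous SNPs are resolved by comparing effect-allele frequencies
#' when both are available: orientation is accepted only when both
#' frequencies are outside the `[0.42, 0.58]` ambiguity band and agree on the
#' same side under exactly one orientation; otherwise the SNP is dropped with
#' a warning. Without frequencies they are dropped.
#'
#' @param panel an `instrument_panel`.
#' @param cohort_alleles data frame with columns `rsid`, `counted_allele`,
#'   `other_allele`, optionally `eaf` (frequency of the counted allele).
#' @return list with `panel` (harmonized, dropped SNPs removed), and `log`
#'   (data frame: rsid, action, flip_dosage, note).
#' @export
harmonize_alleles <- function(panel, cohort_alleles) {
  need <- c("rsid", "counted_allele", "other_allele")
  if (!all(need %in% names(cohort_alleles)))
    stopf("cohort_alleles needs columns %s", paste(need, collapse = ", "))
  m <- match(panel$rsid, cohort_alleles$rsid)
  log <- data.frame(rsid = panel$rsid, action = "drop", flip_dosage = FALSE,
                    note = "", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(panel))) {
    j <- m[i]
    if (is.na(j)) { log$note[i] <- "absent from cohort"; next }
    ea <- panel$effect_allele[i]; oa <- panel$other_allele[i]
    ca <- toupper(cohort_alleles$counted_allele[j])
    cb <- toupper(cohort_alleles$other_allele[j])
    if (is_palindromic(ea, oa)) {
      peaf <- panel$eaf[i]
      ceaf <- if ("eaf" %in% names(cohort_alleles))
                cohort_alleles$eaf[j] else NA_real_
      res <- resolve_palindromic(ea, oa, ca, cb, peaf, ceaf)
      log$action[i] <- res$action
      log$flip_dosage[i] <- res$flip
      log$note[i] <- res$note
      if (res$action == "drop")
        warnf("dropping strand-ambiguous SNP %s: %s", panel$rsid[i], res$note)
      next
    }
    if (ca == ea && cb == oa) {
      log$action[i] <- "match"
    } else if (ca == oa && cb == ea) {
      log$action[i] <- "swap"; log$flip_dosage[i] <- TRUE
    } else if (ca == dna_complement(ea) && cb == dna_complement(oa)) {
      log$action[i] <- "strand_flip"
    } else if (ca == dna_complement(oa) && cb == dna_complement(ea)) {
      log$action[i] <- "strand_flip_swap"; log$flip_dosage[i] <- TRUE
    } else {
      log$note[i] <- sprintf("irreconcilable alleles %s/%s vs %s/%s",
                             ea, oa, ca, cb)
      warnf("dropping %s: %s", panel$rsid[i], log$note[i])
    }
  }
  keep <- log$action != "drop"
  out <- panel[keep, , drop = FALSE]
  # allele info as it stands after the dosage recode: every kept SNP counts
  # the effect allele, so a second harmonization pass is a no-op
  harmonized_alleles <- data.frame(rsid = out$rsid,
                                   counted_allele = out$effect_allele,
                                   other_allele = out$other_allele,
                                   eaf = out$eaf, stringsAsFactors = FALSE)
  list(panel = new_instrument_panel(out, attr(panel, "provenance"),
                                    attr(panel, "threshold")),
       log = log, cohort_alleles = harmonized_alleles)
}

#' Apply a harmonization log to a dosage matrix
#'
#' Recodes dosage columns flagged `flip_dosage` as `2 - g` (so every column
#' counts the panel's effect allele) and drops columns for SNPs the
#' harmonization dropped.
#'
#' @param dosages matrix or data frame, columns named by rsid.
#' @param log the `log` component of [harmonize_alleles()].
#' @return dosage matrix restricted to kept SNPs, recoded.
#' @export
apply_harmonization <- function(dosages, log) {
  dosages <- as.matrix(dosages)
  keep <- log$rsid[log$action != "drop"]
  miss <- setdiff(keep, colnames(dosages))
  if (length(miss)) stopf("dosage columns missing: %s", paste(miss, collapse = ", "))
  out <- dosages[, keep, drop = FALSE]
  flip <- log$rsid[log$flip_dosage & log$action != "drop"]
  if (length(flip)) out[, flip] <- 2 - out[, flip]
  out
}

# ambiguity band per the conservative standard: both frequencies must sit
# outside [0.42, 0.58] and agree on orientation
resolve_palindromic <- function(ea, oa, ca, cb, peaf, ceaf) {
  if (!setequal(c(ca, cb), c(ea, oa)) &&
      !setequal(c(ca, cb), dna_complement(c(ea, oa))))
    return(list(action = "drop", flip = FALSE, note = "irreconcilable alleles"))
  if (is.na(peaf) || is.na(ceaf))
    return(list(action = "drop", flip = FALSE,
                note = "strand-ambiguous without allele frequencies"))
  band <- c(0.42, 0.58)
  inband <- function(f) f >= band[1] & f <= band[2]
  if (inband(peaf) || inband(ceaf))
    return(list(action = "drop", flip = FALSE,
                note = "frequency inside ambiguity band"))
  ceaf_for_effect <- if (ca == ea) ceaf else 1 - ceaf
  same_side <- (peaf > 0.5) == (ceaf_for_effect > 0.5)
  if (same_side) {
    if (ca == ea) list(action = "match", flip = FALSE, note = "freq-resolved")
    else list(action = "swap", flip = TRUE, note = "freq-resolved")
  } else {
    # frequencies only agree under the complemented orientation
    if (ca == ea) list(action = "strand_flip_swap", flip = TRUE,
                       note = "freq-resolved (flipped strand)")
    else list(action = "strand_flip", flip = FALSE,
              note = "freq-resolved (flipped strand)")
  }
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test for departure from Hardy-Weinberg proportions at a
#' biallelic locus: conditional on the observed allele counts, the p-value is
#' the sum of probabilities of all heterozygote counts whose conditional
#' probability does not exceed the observed one. Probabilities follow the
#' exact conditional distribution
#' `P(n_Aa | n_A, n) proportional to n! / (n_AA! n_Aa! n_aa!) * 2^n_Aa`.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, not all zero).
#' @return the exact p-value (1 for a monomorphic locus).
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0)) stopf("genotype counts must be non-negative")
  if (sum(counts) == 0) stopf("at least one genotype count must be positive")
  if (any(counts != round(counts))) stopf("genotype counts must be integers")
  n <- sum(counts)
  nA <- 2 * n_AA + n_Aa  # count of A alleles
  if (nA == 0 || nA == 2 * n) return(1)  # monomorphic: single configuration
  rare <- min(nA, 2 * n - nA)
  hets <- seq.int(rare %% 2, rare, by = 2)  # attainable heterozygote counts
  # log conditional probabilities, normalized below
  logp <- vapply(hets, function(h) {
    aa <- (nA - h) / 2; bb <- (2 * n - nA - h) / 2
    h * log(2) - lfactorial(aa) - lfactorial(h) - lfactorial(bb)
  }, 0)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, hets)]
  if (is.na(obs)) stopf("heterozygote count incompatible with allele totals")
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Effect-allele frequency from dosages
#'
#' `mean(dosage) / 2` over non-missing entries; dosages count copies of the
#' effect allele in `[0, 2]` (fractional for imputed data).
#'
#' @param dosages numeric vector in `[0, 2]`, `NA` allowed.
#' @return frequency in `[0, 1]`.
#' @export
effect_allele_freq <- function(dosages) {
  x <- dosages[!is.na(dosages)]
  if (!length(x)) stopf("all dosages missing")
  if (any(x < 0 | x > 2)) stopf("dosages must lie in [0, 2]")
  mean(x) / 2
}
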