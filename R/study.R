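#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment within one family of tests: sort
#' ascending, `q_(i) = min over k >= i of p_(k) * m / k`, capped at 1, mapped
#' back to the input order (delegated to [stats::p.adjust()], which implements
#' exactly this).
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return q-values in the original order.
#' @export
fdr_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stopf("p-values must lie in [0, 1] with no missing values")
  p.adjust(pvalues, method = "BH")
}

#' Significance label from nominal p and FDR q
#'
#' `fdr_significant` when `q < alpha`; otherwise `nominal` when `p < alpha`;
#' otherwise `null`. Mirrors the study's reporting convention (nominal
#' significance at p < 0.05, confirmed significance after within-family FDR).
#'
#' @param p,q nominal p-value and BH q-value, in `[0, 1]` (vectorized).
#' @param alpha significance level (default 0.05).
#' @return character vector of labels.
#' @export
classify_significance <- function(p, q, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE) || any(q < 0 | q > 1, na.rm = TRUE))
    stopf("p and q must lie in [0, 1]")
  ifelse(q < alpha, "fdr_significant", ifelse(p < alpha, "nominal", "null"))
}

# stratum definitions: label -> list(filter over per-individual data, apoe covariate)
study_strata <- function() {
  list(
    whole = list(select = function(d) rep(TRUE, nrow(d)), adjust_apoe = TRUE),
    apoe_carrier = list(select = function(d) d$apoe_e4 == 1, adjust_apoe = FALSE),
    apoe_noncarrier = list(select = function(d) d$apoe_e4 == 0, adjust_apoe = FALSE),
    prs_high = list(select = function(d) d$prs_group == "high", adjust_apoe = FALSE),
    prs_low = list(select = function(d) d$prs_group == "low", adjust_apoe = FALSE))
}

#' Run the full stratified MR study
#'
#' Orchestrates the whole analysis on a cohort: APOE-e2/e4 individuals are
#' excluded from every analysis; polygenic-risk-score groups are formed at the
#' 75th percentile; then for each stratum (whole sample, APOE-e4 carriers and
#' non-carriers, high and low PRS) and each outcome, the per-SNP
#' covariate-adjusted outcome regressions are refit on that stratum's
#' individuals (the APOE covariate only in the whole sample), the five MR
#' estimators are run, the sensitivity suite is computed, and
#' Benjamini-Hochberg q-values are attached within each (endophenotype
#' family, stratum, method) block. Strata too small to regress yield
#' not-estimable cells and the run continues with a warning.
#'
#' @param cohort a [simulate_cohort()] result, or a list with the same
#'   components (`dosages`, `covariates` incl. `apoe_e4`, `outcomes`,
#'   optionally `apoe` with `excluded`, `prs_dosages` + `prs_weights`).
#' @param panel exposure-side summary statistics: a data frame with `rsid`,
#'   `beta_x`, `se_x` (an `instrument_panel` works), aligned to the dosage
#'   columns by rsid.
#' @param outcome_families named character vector mapping outcome columns to
#'   families (`cognition`, `imaging`, `csf`); defaults to the synthetic
#'   cohort's three outcomes.
#' @param methods,ivw_model,n_boot,phi passed to [mr_fit()].
#' @param n_sim MR-PRESSO simulations per cell.
#' @param seed master seed; per-cell seeds are derived deterministically.
#' @param alpha significance level.
#' @param fdr_mode `"per_method"` (default: q-values within family x stratum,
#'   separately per estimator) or `"pooled"` (all methods' p-values of a
#'   family x stratum corrected together).
#' @param prs_percentile PRS split point.
#' @return data frame of class `"mr_study"`: one row per (outcome, family,
#'   stratum, method) with `beta`, `se`, `ci_low`, `ci_high`, `pval`, `qval`,
#'   `significance`, `J`, `n`, `estimable`; attributes `sensitivity` (named
#'   list of [mr_sensitivity()] reports per cell), `seed`, `alpha`.
#' @export
run_study <- function(cohort, panel, outcome_families = NULL,
                      methods = c("ivw", "max_likelihood", "weighted_median",
                                  "weighted_mode", "egger"),
                      ivw_model = c("random", "fixed"), n_boot = 1000,
                      n_sim = 1000, phi = 1, seed = 1, alpha = 0.05,
                      fdr_mode = c("per_method", "pooled"),
                      prs_percentile = 75) {
  ivw_model <- match.arg(ivw_model)
  fdr_mode <- match.arg(fdr_mode)
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(outcome_families)) {
    outcome_families <- c(cognition = "cognition", thickness = "imaging",
                          csf = "csf")
    outcome_families <- outcome_families[names(outcome_families) %in%
                                           names(cohort$outcomes)]
  }
  pan <- as.data.frame(panel)
  need <- c("rsid", "beta_x", "se_x")
  if (!all(need %in% names(pan)))
    stopf("panel needs columns %s", paste(need, collapse = ", "))
  G <- as.matrix(cohort$dosages)
  miss <- setdiff(pan$rsid, colnames(G))
  if (length(miss))
    stopf("panel SNPs absent from dosages: %s", paste(miss, collapse = ", "))
  G <- G[, pan$rsid, drop = FALSE]

  covs <- cohort$covariates
  n_all <- nrow(covs)
  # e2/e4 individuals are excluded from all analyses
  excluded <- if (!is.null(cohort$apoe)) cohort$apoe$excluded else
    rep(FALSE, n_all)
  keep <- !excluded

  # e2/e4 exclusion first; the PRS is standardized and split on the analysis sample
  d <- covs[keep, , drop = FALSE]
  d$prs_group <- NA_character_
  if (!is.null(cohort$prs_dosages)) {
    prs <- compute_prs(cohort$prs_dosages[keep, , drop = FALSE],
                       cohort$prs_weights)
    d$prs_z <- prs$z
    d$prs_group <- as.character(split_prs_groups(prs$z, prs_percentile))
  }
  G <- G[keep, , drop = FALSE]
  outc <- cohort$outcomes[keep, , drop = FALSE]

  strata <- study_strata()
  if (all(is.na(d$prs_group)))
    strata <- strata[!names(strata) %in% c("prs_high", "prs_low")]

  rows <- list()
  sens_store <- list()
  input_store <- list()
  cell <- 0L
  for (sname in names(strata)) {
    sdef <- strata[[sname]]
    in_s <- sdef$select(d)
    in_s[is.na(in_s)] <- FALSE
    for (oname in names(outcome_families)) {
      cell <- cell + 1L
      cell_seed <- (as.integer(seed) + 1009L * cell) %% .Machine$integer.max
      fam <- outcome_families[[oname]]
      base <- data.frame(outcome = oname, family = fam, stratum = sname,
                         method = methods, beta = NA_real_, se = NA_real_,
                         ci_low = NA_real_, ci_high = NA_real_,
                         pval = NA_real_, J = NA_integer_,
                         n = sum(in_s), estimable = FALSE,
                         stringsAsFactors = FALSE)
      k_req <- 3L + sdef$adjust_apoe + 2L  # intercept + dosage + covariates
      if (sum(in_s) < k_req + 2L) {
        warnf("stratum %s too small (n = %d) for %s: cells marked not estimable",
              sname, sum(in_s), oname)
        rows[[length(rows) + 1L]] <- base
        next
      }
      assoc <- tryCatch(
        snp_outcome_scan(G[in_s, , drop = FALSE], outc[[oname]][in_s],
                         d[in_s, , drop = FALSE],
                         adjust_apoe = sdef$adjust_apoe,
                         outcome_name = oname, stratum = sname),
        error = function(e) NULL)
      if (is.null(assoc)) {
        warnf("regressions failed in stratum %s for %s", sname, oname)
        rows[[length(rows) + 1L]] <- base
        next
      }
      inp <- mr_input(pan$beta_x, pan$se_x, assoc$beta_y, assoc$se_y,
                      rsid = pan$rsid, outcome = oname, stratum = sname)
      fit <- mr_fit(inp, methods = methods, ivw_model = ivw_model,
                    n_boot = n_boot, seed = cell_seed, phi = phi)
      key <- paste(oname, sname, sep = ".")
      input_store[[key]] <- inp
      sens_store[[key]] <-
        mr_sensitivity(inp, n_sim = n_sim, seed = cell_seed,
                       ivw_model = ivw_model)
      est <- fit$estimates
      m <- match(base$method, est$method)
      got <- !is.na(m)
      for (col in c("beta", "se", "ci_low", "ci_high", "pval"))
        base[[col]][got] <- est[[col]][m[got]]
      base$J[got] <- est$J[m[got]]
      base$estimable[got] <- TRUE
      rows[[length(rows) + 1L]] <- base
    }
  }
  grid <- do.call(rbind, rows)
  grid$qval <- NA_real_
  block <- if (fdr_mode == "per_method")
    interaction(grid$family, grid$stratum, grid$method, drop = TRUE)
  else interaction(grid$family, grid$stratum, drop = TRUE)
  for (b in levels(block)) {
    i <- which(block == b & grid$estimable & !is.na(grid$pval))
    if (length(i)) grid$qval[i] <- fdr_adjust(grid$pval[i])
  }
  grid$significance <- NA_character_
  ok <- grid$estimable & !is.na(grid$qval)
  grid$significance[ok] <- classify_significance(grid$pval[ok],
                                                 grid$qval[ok], alpha)
  attr(grid, "sensitivity") <- sens_store
  attr(grid, "inputs") <- input_store
  attr(grid, "seed") <- seed
  attr(grid, "alpha") <- alpha
  attr(grid, "fdr_mode") <- fdr_mode
  class(grid) <- c("mr_study", "data.frame")
  grid
}

#' @export
print.mr_study <- function(x, ...) {
  cat(sprintf("MR study grid: %d cells (%d outcomes x %d strata x %d methods)\n",
              nrow(x), length(unique(x$outcome)), length(unique(x$stratum)),
              length(unique(x$method))))
  sig <- x[!is.na(x$significance) & x$significance == "fdr_significant", ,
           drop = FALSE]
  if (nrow(sig)) {
    cat("FDR-significant cells:\n")
    print(as.data.frame(sig[c("outcome", "stratum", "method", "beta", "se",
                              "pval", "qval")]), row.names = FALSE)
  } else cat("no FDR-significant cells\n")
  invisible(x)
}

#' Write study tables and scatter-plot data
#'
#' One TSV per (family, stratum) in the causal-methods + sensitivity-methods
#' layout, and for every FDR-significant cell a scatter-data TSV of
#' (`beta_x`, `beta_y`) per SNP with the IVW slope (plot data rather than
#' rasters, so outputs are deterministic and diffable). Set `plots = TRUE` to
#' additionally render PDF scatter plots.
#'
#' @param grid an [run_study()] result.
#' @param dir output directory.
#' @param inputs optional named list of [mr_input()]s (`"outcome.stratum"`)
#'   for the scatter data; defaults to the grid's own stored inputs.
#' @param plots render PDFs too (default FALSE).
#' @return invisibly, character vector of files written.
#' @export
generate_report <- function(grid, dir, inputs = NULL, plots = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  sens <- attr(grid, "sensitivity")
  if (is.null(inputs)) inputs <- attr(grid, "inputs")
  combos <- unique(grid[c("family", "stratum")])
  for (i in seq_len(nrow(combos))) {
    fam <- combos$family[i]; st <- combos$stratum[i]
    sub <- grid[grid$family == fam & grid$stratum == st, , drop = FALSE]
    f <- file.path(dir, sprintf("table_%s_%s.tsv", fam, st))
    tab <- as.data.frame(sub[c("outcome", "method", "beta", "se", "ci_low",
                               "ci_high", "pval", "qval", "significance",
                               "J", "n")])
    # append the sensitivity block per outcome
    sens_rows <- do.call(rbind, lapply(unique(sub$outcome), function(o) {
      s <- sens[[paste(o, st, sep = ".")]]
      if (is.null(s)) return(NULL)
      data.frame(outcome = o,
                 method = c("cochran_q", "presso_global", "egger_intercept"),
                 beta = NA, se = NA, ci_low = NA, ci_high = NA,
                 pval = c(if (is.null(s$q)) NA else s$q$pval,
                          if (is.null(s$presso)) NA else s$presso$global_pval,
                          if (is.null(s$egger)) NA else s$egger$pval),
                 qval = NA, significance = NA, J = NA, n = NA)
    }))
    write.table(rbind(tab, sens_rows), f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- c(files, f)
  }
  sig <- grid[!is.na(grid$significance) &
                grid$significance == "fdr_significant" &
                grid$method == grid$method[1], , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    key <- paste(sig$outcome[i], sig$stratum[i], sep = ".")
    inp <- inputs[[key]]
    if (is.null(inp)) next
    f <- file.path(dir, sprintf("scatter_%s.tsv", key))
    dat <- as.data.frame(inp)
    dat$ivw_slope <- sig$beta[i]
    write.table(dat, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
    if (plots) {
      pf <- file.path(dir, sprintf("scatter_%s.pdf", key))
      grDevices::pdf(pf, width = 5, height = 5)
      plot(mr_fit(inp, methods = "ivw"))
      grDevices::dev.off()
      files <- c(files, pf)
    }
  }
  invisible(files)
}

#' Write a study grid as a TSV
#'
#' Deterministic serialization of the results grid (used by the end-to-end
#' reproducibility checks: identical config + seed must give byte-identical
#' files).
#'
#' @param grid an [run_study()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_study_grid <- function(grid, path) {
  df <- as.data.frame(grid)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.12g", x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
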