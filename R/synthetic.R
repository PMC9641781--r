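#' Configuration for the synthetic-cohort generator
#'
#' Collects every knob of the simulated world: a panel of independent
#' instrument SNPs for a unit-variance latent exposure (genetically predicted
#' telomere length, in SD units), an external exposure GWAS, and an
#' individual-level cohort with covariates and three endophenotype families.
#' Defaults mirror the study setting being emulated: 20 instrument SNPs from
#' an external meta-GWAS of 78,592 individuals, a cohort of 2,233 genotyped
#' middle-aged adults aged 45-74, and an elevated APOE-e4 haplotype frequency
#' of 0.20.
#'
#' @param n_snps instrument SNPs (default 20).
#' @param n_external external exposure-GWAS sample size (default 78,592).
#' @param n_cohort cohort size (default 2,233; must exceed the regression
#'   minimum of regressors + 2).
#' @param theta causal effect of the exposure on each outcome, in that
#'   outcome's native units per SD of exposure (default 0).
#' @param freq_range effect-allele frequency range, uniform draw (default
#'   `c(0.05, 0.95)`).
#' @param beta_x_scale half-normal scale of the true per-allele exposure
#'   effects, SD of exposure per allele before standardization (default 0.1,
#'   the magnitude of telomere-length GWAS hits).
#' @param confounder_exposure,confounder_outcome loadings of a standard-normal
#'   confounder on exposure and (cognition-scale) outcome (defaults 0.3:
#'   confounding present, which MR is built to tolerate).
#' @param exposure_noise_sd non-genetic, non-confounder exposure noise SD
#'   (default 1; the exposure is rescaled to unit variance afterwards).
#' @param pleiotropy_mode one of `"none"`, `"balanced"` (zero-mean direct
#'   SNP-outcome effects), `"directional"` (positive-mean, half-normal), or
#'   `"single_outlier"` (all zero except one SNP).
#' @param pleiotropy_scale scale of the direct effects (outcome units per
#'   allele); for `"single_outlier"` it is the outlier's direct effect.
#' @param outlier_index which SNP carries the single outlier effect (default
#'   the last).
#' @param beta_age,beta_sex,beta_edu covariate effects on the outcomes, per
#'   unit of covariate and per SD of outcome noise.
#' @param noise_sd named noise SDs for the three outcome families:
#'   `cognition` (unit scale), `thickness` (mm), `csf_log` (log-normal sigma
#'   of the biomarker noise).
#' @param apoe_freqs haplotype frequencies for (e2, e3, e4), summing to 1.
#' @param n_prs_snps,prs_weight_sd independent polygenic-risk-score SNP set
#'   (disjoint from the instruments) and the SD of its per-allele weights.
#' @param dosage_mode `"hard"` (0/1/2 calls) or `"fractional"` (imputed-style
#'   dosages with jitter).
#' @param seed RNG seed recorded in every derived object.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(n_snps = 20, n_external = 78592, n_cohort = 2233,
                       theta = 0, freq_range = c(0.05, 0.95),
                       beta_x_scale = 0.1, confounder_exposure = 0.3,
                       confounder_outcome = 0.3, exposure_noise_sd = 1,
                       pleiotropy_mode = c("none", "balanced", "directional",
                                           "single_outlier"),
                       pleiotropy_scale = 0.02, outlier_index = NULL,
                       beta_age = -0.02, beta_sex = 0.1, beta_edu = 0.03,
                       noise_sd = c(cognition = 1, thickness = 0.1,
                                    csf_log = 0.35),
                       apoe_freqs = c(e2 = 0.08, e3 = 0.72, e4 = 0.20),
                       n_prs_snps = 15, prs_weight_sd = 0.15,
                       dosage_mode = c("hard", "fractional"), seed = NULL) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  dosage_mode <- match.arg(dosage_mode)
  if (n_snps < 1) stopf("n_snps must be >= 1")
  if (n_external < 1 || n_cohort < 1) stopf("sample sizes must be >= 1")
  if (pleiotropy_scale < 0) stopf("pleiotropy scale must be >= 0")
  if (any(noise_sd <= 0) || exposure_noise_sd <= 0)
    stopf("noise SDs must be > 0")
  if (abs(sum(apoe_freqs) - 1) > 1e-8)
    stopf("APOE haplotype frequencies must sum to 1")
  structure(list(n_snps = as.integer(n_snps),
                 n_external = as.integer(n_external),
                 n_cohort = as.integer(n_cohort), theta = theta,
                 freq_range = freq_range, beta_x_scale = beta_x_scale,
                 confounder_exposure = confounder_exposure,
                 confounder_outcome = confounder_outcome,
                 exposure_noise_sd = exposure_noise_sd,
                 pleiotropy_mode = pleiotropy_mode,
                 pleiotropy_scale = pleiotropy_scale,
                 outlier_index = outlier_index %||% as.integer(n_snps),
                 beta_age = beta_age, beta_sex = beta_sex,
                 beta_edu = beta_edu, noise_sd = noise_sd,
                 apoe_freqs = apoe_freqs,
                 n_prs_snps = as.integer(n_prs_snps),
                 prs_weight_sd = prs_weight_sd, dosage_mode = dosage_mode,
                 seed = seed),
            class = "sim_config")
}

#' Simulate the true instrument panel
#'
#' Draws the ground truth behind the simulated world: effect-allele
#' frequencies uniform on the configured range, true per-allele exposure
#' effects half-normal (all positive, so the effect allele is the
#' exposure-increasing allele, matching the harmonization convention), and
#' direct SNP-outcome (pleiotropic) effects according to the pleiotropy mode.
#' Non-palindromic allele pairs are attached for harmonization exercises.
#' The panel also records the standardized per-allele effects `beta_x_std`
#' (after the exposure is rescaled to unit variance given the configured
#' confounder and noise), which is the scale the external GWAS reports.
#'
#' @param config a [sim_config()].
#' @return data frame of class `"true_panel"`: `rsid`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta_x_true`, `beta_x_std`, `alpha_pleio`;
#'   attributes `config` and `exposure_sd` (the standardization factor).
#' @export
simulate_true_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set_seed_if(config$seed)
  J <- config$n_snps
  eaf <- runif(J, config$freq_range[1], config$freq_range[2])
  beta <- abs(rnorm(J, 0, config$beta_x_scale))
  alpha <- switch(config$pleiotropy_mode,
    none = rep(0, J),
    balanced = rnorm(J, 0, config$pleiotropy_scale),
    directional = abs(rnorm(J, 0, config$pleiotropy_scale)),
    single_outlier = {
      a <- rep(0, J)
      a[config$outlier_index] <- config$pleiotropy_scale
      a
    })
  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
  pick <- pairs[sample.int(4, J, replace = TRUE), , drop = FALSE]
  s <- sqrt(sum(2 * eaf * (1 - eaf) * beta^2) +
            config$confounder_exposure^2 + config$exposure_noise_sd^2)
  out <- data.frame(rsid = sprintf("snp%02d", seq_len(J)),
                    effect_allele = pick[, 1], other_allele = pick[, 2],
                    eaf = eaf, beta_x_true = beta, beta_x_std = beta / s,
                    alpha_pleio = alpha, stringsAsFactors = FALSE)
  attr(out, "config") <- config
  attr(out, "exposure_sd") <- s
  class(out) <- c("true_panel", "data.frame")
  out
}

#' Simulate external exposure-GWAS summary statistics
#'
#' Emulates the exposure side of the two-sample design without simulating the
#' external sample itself: each reported effect is the true standardized
#' per-allele effect plus normal noise with the unit-variance-exposure
#' standard error `se = 1/sqrt(2 p (1-p) n_external)`; p-values come from the
#' Wald statistic. `exact = TRUE` instead simulates `n_external` individuals
#' (genotypes, exposure) and runs the per-SNP regressions — identical
#' first-order behavior, for small `n_external` only.
#'
#' @param panel a [simulate_true_panel()] result.
#' @param n_external external sample size (default from the panel's config).
#' @param seed RNG seed.
#' @param exact simulate the external sample explicitly (slow for large n).
#' @return `instrument_panel` data frame (columns as [load_summary_stats()]).
#' @export
simulate_external_gwas <- function(panel, n_external = NULL, seed = NULL,
                                   exact = FALSE) {
  config <- attr(panel, "config")
  n_external <- n_external %||% config$n_external
  if (n_external < 1) stopf("n_external must be >= 1")
  if (any(panel$eaf <= 0 | panel$eaf >= 1))
    stopf("allele frequencies must be strictly inside (0, 1)")
  set_seed_if(seed)
  J <- nrow(panel)
  if (exact) {
    G <- matrix(rbinom(n_external * J, 2, rep(panel$eaf, each = n_external)),
                n_external, J)
    gen <- drop(sweep(G, 2, 2 * panel$eaf) %*% panel$beta_x_true)
    xs <- attr(panel, "exposure_sd")
    x <- (gen + config$confounder_exposure * rnorm(n_external) +
          rnorm(n_external, 0, config$exposure_noise_sd)) / xs
    est <- vapply(seq_len(J), function(j) {
      f <- lm(x ~ G[, j])
      coef(summary(f))[2, 1:2]
    }, c(0, 0))
    beta <- est[1, ]; se <- est[2, ]
  } else {
    se <- 1 / sqrt(2 * panel$eaf * (1 - panel$eaf) * n_external)
    beta <- rnorm(J, panel$beta_x_std, se)
  }
  out <- data.frame(rsid = panel$rsid, effect_allele = panel$effect_allele,
                    other_allele = panel$other_allele, beta_x = beta,
                    se_x = se, pval = 2 * pnorm(-abs(beta / se)),
                    eaf = panel$eaf, proxy_of = "", proxy_r2 = NA_real_,
                    stringsAsFactors = FALSE)
  new_instrument_panel(out,
    provenance = sprintf("synthetic exposure GWAS, n = %s, seed = %s",
                         format(n_external, scientific = FALSE),
                         format(seed %||% config$seed %||% "none")))
}

#' Simulate APOE genotypes from two-SNP haplotypes
#'
#' Draws two epsilon haplotypes per individual (independently, at the given
#' frequencies) and emits the implied rs429358/rs7412 genotypes; labels come
#' from [classify_apoe()] applied to those genotypes, so generator and
#' classifier are consistent by construction. Default frequencies
#' (0.08, 0.72, 0.20) reproduce the elevated e4 rate of an enriched-risk
#' cohort (carrier fraction `1 - 0.80^2 = 0.36`).
#'
#' @param n individuals.
#' @param haplotype_freqs frequencies of (e2, e3, e4), summing to 1.
#' @param seed RNG seed.
#' @return data frame: haplotypes `hap1`, `hap2`, genotypes `rs429358`,
#'   `rs7412`, plus `epsilon`, `e4_carrier`, `excluded` from
#'   [classify_apoe()].
#' @export
simulate_apoe <- function(n, haplotype_freqs = c(e2 = 0.08, e3 = 0.72,
                                                 e4 = 0.20), seed = NULL) {
  if (abs(sum(haplotype_freqs) - 1) > 1e-8)
    stopf("haplotype frequencies must sum to 1")
  set_seed_if(seed)
  haps <- c("e2", "e3", "e4")
  # haplotype -> (rs429358 allele, rs7412 allele); e1 (C, T) assumed absent
  a429358 <- c(e2 = "T", e3 = "T", e4 = "C")
  a7412 <- c(e2 = "T", e3 = "C", e4 = "C")
  h1 <- sample(haps, n, replace = TRUE, prob = haplotype_freqs)
  h2 <- sample(haps, n, replace = TRUE, prob = haplotype_freqs)
  sortg <- function(a, b) paste0(pmin(a, b), pmax(a, b))
  g1 <- sortg(a429358[h1], a429358[h2])
  g2 <- sortg(a7412[h1], a7412[h2])
  calls <- classify_apoe(g1, g2)
  cbind(data.frame(hap1 = h1, hap2 = h2, stringsAsFactors = FALSE), calls)
}

#' Simulate an individual-level cohort
#'
#' The stated generative world of the pipeline: genotypes are drawn
#' `binomial(2, eaf)` per SNP independently (Hardy-Weinberg holds by
#' construction); a standard-normal confounder loads on both the exposure and
#' the outcomes; the latent exposure is the allele-count-centered genetic
#' score plus confounder and noise, rescaled to unit population variance; each
#' outcome is `theta * exposure + direct pleiotropic SNP effects + confounder
#' + covariate effects + family-specific noise`. Covariates: age uniform on
#' 45-74, sex Bernoulli(0.5), years of education approximately normal(12,
#' 3.5); APOE genotypes come from [simulate_apoe()] and an independent
#' polygenic-score SNP set with its own weights is attached for
#' stratification.
#'
#' Outcome families: `cognition` (unit-SD composite-like score), `thickness`
#' (cortical-thickness-like, mean 2.5 mm, noise SD 0.1), `csf` (biomarker-like
#' raw units, right-skewed via log-normal noise around baseline 85).
#'
#' @param panel a [simulate_true_panel()] result.
#' @param config the matching [sim_config()] (defaults to the panel's).
#' @return list of class `"synthetic_cohort"`: `dosages` (n x J, named by
#'   rsid), `covariates` (`age`, `sex`, `education`, `apoe_e4`), `apoe`,
#'   `outcomes` (`cognition`, `thickness`, `csf`), `exposure`, `confounder`,
#'   `prs_dosages`, `prs_weights`, `truth` (config, panel, per-outcome true
#'   effects, seed).
#' @export
simulate_cohort <- function(panel, config = attr(panel, "config")) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_cohort
  if (n < 8L) stopf("n_cohort = %d is below the regression minimum", n)
  set_seed_if(config$seed)
  J <- nrow(panel)
  G <- matrix(rbinom(n * J, 2, rep(panel$eaf, each = n)), n, J,
              dimnames = list(NULL, panel$rsid))
  if (config$dosage_mode == "fractional") {
    G <- pmin(2, pmax(0, G + matrix(rnorm(n * J, 0, 0.08), n, J)))
  }
  C <- rnorm(n)
  gen <- drop(sweep(G, 2, 2 * panel$eaf) %*% panel$beta_x_true)
  s <- attr(panel, "exposure_sd")
  x <- (gen + config$confounder_exposure * C +
        rnorm(n, 0, config$exposure_noise_sd)) / s

  age <- runif(n, 45, 74)
  sex <- rbinom(n, 1, 0.5)
  education <- pmin(25, pmax(0, round(rnorm(n, 12, 3.5))))
  apoe <- simulate_apoe(n, config$apoe_freqs)

  pleio <- drop(G %*% panel$alpha_pleio)
  covar_lin <- config$beta_age * (age - 60) + config$beta_sex * sex +
    config$beta_edu * (education - 12)
  nd <- config$noise_sd
  csf_noise_sd <- 85 * sqrt(exp(nd[["csf_log"]]^2) - 1)  # SD of the log-normal part
  outcomes <- data.frame(
    cognition = config$theta * x + pleio + config$confounder_outcome * C +
      covar_lin + rnorm(n, 0, nd[["cognition"]]),
    thickness = 2.5 + config$theta * x + pleio * nd[["thickness"]] +
      config$confounder_outcome * nd[["thickness"]] * C +
      covar_lin * nd[["thickness"]] +
      rnorm(n, 0, nd[["thickness"]]),
    csf = config$theta * x + pleio * csf_noise_sd +
      config$confounder_outcome * csf_noise_sd * C +
      covar_lin * csf_noise_sd +
      85 * exp(rnorm(n, -nd[["csf_log"]]^2 / 2, nd[["csf_log"]])))

  # independent PRS SNP set, disjoint from the instruments
  pk <- config$n_prs_snps
  prs_eaf <- runif(pk, 0.1, 0.9)
  prs_G <- matrix(rbinom(n * pk, 2, rep(prs_eaf, each = n)), n, pk,
                  dimnames = list(NULL, sprintf("prs%02d", seq_len(pk))))
  prs_w <- setNames(rnorm(pk, 0, config$prs_weight_sd), colnames(prs_G))

  structure(list(dosages = G, covariates = data.frame(
                   age = age, sex = sex, education = education,
                   apoe_e4 = as.integer(apoe$e4_carrier)),
                 apoe = apoe, outcomes = outcomes, exposure = x,
                 confounder = C, prs_dosages = prs_G, prs_weights = prs_w,
                 truth = list(config = config, panel = as.data.frame(panel),
                              exposure_sd = s,
                              theta = c(cognition = config$theta,
                                        thickness = config$theta,
                                        csf = config$theta),
                              seed = config$seed)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "synthetic cohort: n = %d | %d instrument SNPs | %d PRS SNPs | theta = %g | pleiotropy %s\n",
    nrow(x$dosages), ncol(x$dosages), ncol(x$prs_dosages),
    x$truth$config$theta, x$truth$config$pleiotropy_mode))
  invisible(x)
}

#' Analytic summary-statistic shortcut for replicate simulations
#'
#' Generates an [mr_input()] directly on the summary-statistic scale, without
#' individual-level data: observed exposure effects are
#' `N(beta_x_std, 1/sqrt(2p(1-p) n_external))` and observed outcome effects
#' are `N(theta * beta_x_std + alpha_pleio,
#' sigma_y/sqrt(2p(1-p) n_cohort))`. First-order identical to running the
#' regressions on a simulated cohort; used for calibration studies where
#' thousands of replicates are needed.
#'
#' @param panel a [simulate_true_panel()] result.
#' @param theta causal effect (outcome units per SD exposure).
#' @param n_cohort outcome-sample size.
#' @param sigma_y residual outcome SD (default 1).
#' @param n_external exposure-GWAS size (default from the panel's config).
#' @param seed RNG seed.
#' @return an [mr_input()].
#' @export
simulate_summary_mr <- function(panel, theta, n_cohort, sigma_y = 1,
                                n_external = NULL, seed = NULL) {
  config <- attr(panel, "config")
  n_external <- n_external %||% config$n_external
  set_seed_if(seed)
  J <- nrow(panel)
  v <- 2 * panel$eaf * (1 - panel$eaf)
  se_x <- 1 / sqrt(v * n_external)
  se_y <- sigma_y / sqrt(v * n_cohort)
  beta_x <- rnorm(J, panel$beta_x_std, se_x)
  beta_y <- rnorm(J, theta * panel$beta_x_std + panel$alpha_pleio, se_y)
  mr_input(beta_x, se_x, beta_y, se_y, rsid = panel$rsid)
}

#' Write a synthetic cohort to disk
#'
#' Emits the plain-text artifacts downstream tools expect: dosage TSV, a
#' PLINK `.raw`-compatible dosage export (FID/IID header then
#' `<rsid>_<effectallele>` columns), covariate and outcome TSVs, the exposure
#' summary-statistics TSV, and a truth JSON recording all true parameters and
#' the seed.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param gwas an `instrument_panel` from [simulate_external_gwas()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of files written.
#' @export
write_cohort <- function(cohort, gwas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  iid <- sprintf("id%05d", seq_len(nrow(cohort$dosages)))
  files <- c(dosages = file.path(dir, "dosages.tsv"),
             raw = file.path(dir, "dosages.raw"),
             covariates = file.path(dir, "covariates.tsv"),
             outcomes = file.path(dir, "outcomes.tsv"),
             sumstats = file.path(dir, "exposure_sumstats.tsv"),
             truth = file.path(dir, "truth.json"))
  wt <- function(d, f) write.table(d, f, sep = "\t", quote = FALSE,
                                   row.names = FALSE)
  wt(cbind(data.frame(iid = iid), as.data.frame(cohort$dosages)),
     files["dosages"])
  pan <- cohort$truth$panel
  raw <- as.data.frame(cohort$dosages)
  names(raw) <- paste0(pan$rsid, "_", pan$effect_allele)
  wt(cbind(data.frame(FID = iid, IID = iid, PAT = 0, MAT = 0,
                      SEX = cohort$covariates$sex + 1, PHENOTYPE = -9), raw),
     files["raw"])
  wt(cbind(data.frame(iid = iid), cohort$covariates), files["covariates"])
  wt(cbind(data.frame(iid = iid), cohort$outcomes), files["outcomes"])
  ss <- as.data.frame(gwas)
  names(ss)[names(ss) == "beta_x"] <- "beta"
  names(ss)[names(ss) == "se_x"] <- "se"
  wt(ss[c("rsid", "effect_allele", "other_allele", "beta", "se", "pval",
          "eaf")], files["sumstats"])
  truth <- cohort$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, files["truth"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(files)
}

#' Read a PLINK `.raw`-style dosage export
#'
#' @param path whitespace-delimited file with FID/IID/PAT/MAT/SEX/PHENOTYPE
#'   then `<rsid>_<allele>` dosage columns.
#' @return list with `dosages` (matrix, columns named by rsid) and
#'   `counted_allele` (named by rsid).
#' @export
read_dosage_raw <- function(path) {
  raw <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  meta <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  snp_cols <- setdiff(names(raw), meta)
  rsid <- sub("_[ACGT]$", "", snp_cols)
  allele <- sub("^.*_", "", snp_cols)
  G <- as.matrix(raw[snp_cols])
  colnames(G) <- rsid
  list(dosages = G, counted_allele = setNames(allele, rsid))
}
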