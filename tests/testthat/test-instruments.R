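write_panel_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

demo_panel_df <- function(J = 20) {
  set.seed(99)
  data.frame(rsid = sprintf("rs%03d", seq_len(J)),
             effect_allele = rep(c("A", "T"), length.out = J),
             other_allele = rep(c("G", "C"), length.out = J),
             beta = abs(rnorm(J, 0.05, 0.02)), se = runif(J, 0.003, 0.01),
             pval = 10^-runif(J, 8.5, 20), eaf = runif(J, 0.1, 0.9))
}

test_that("summary-statistic loader validates the panel", {
  df <- demo_panel_df()
  panel <- load_summary_stats(write_panel_tsv(df))
  expect_s3_class(panel, "instrument_panel")
  expect_equal(nrow(panel), 20)
  expect_equal(panel$beta_x, df$beta)

  bad <- df; bad$se[3] <- 0
  expect_error(load_summary_stats(write_panel_tsv(bad)), "rs003")

  dup <- df; dup$rsid[5] <- dup$rsid[2]
  err <- tryCatch(load_summary_stats(write_panel_tsv(dup)),
                  error = function(e) conditionMessage(e))
  expect_match(err, "rs002")
  expect_match(err, "3")  # header-aware line numbers
  expect_match(err, "6")

  # GWAS-SSF-like headers via column_map
  ssf <- df
  names(ssf) <- c("variant_id", "effect_allele", "other_allele", "beta",
                  "standard_error", "p_value", "effect_allele_frequency")
  panel2 <- load_summary_stats(write_panel_tsv(ssf),
    column_map = c(rsid = "variant_id", se = "standard_error",
                   pval = "p_value", eaf = "effect_allele_frequency"))
  expect_equal(panel2$se_x, df$se)

  expect_error(load_summary_stats(write_panel_tsv(df[, -4]), ), "beta")
})

test_that("genome-wide filtering is strictly below threshold", {
  df <- demo_panel_df(3)
  df$pval <- c(1e-9, 4.9e-8, 5e-8)
  panel <- load_summary_stats(write_panel_tsv(df))
  kept <- suppressMessages(filter_gw_significant(panel, 5e-8))
  expect_identical(kept$rsid, c("rs001", "rs002"))
  expect_identical(suppressMessages(filter_gw_significant(panel, 1))$rsid,
                   panel$rsid)
  expect_warning(suppressMessages(filter_gw_significant(panel, 1e-30)),
                 "no SNP")
})

test_that("proxy substitution enforces the r2 rule with its whitelist", {
  df <- demo_panel_df(4)
  df$rsid[1] <- "rs55749605"; df$rsid[2] <- "rs7705526"
  panel <- load_summary_stats(write_panel_tsv(df))
  proxy <- list(rsid = "rs999", effect_allele = "A", other_allele = "G",
                beta = 0.04, se = 0.005, pval = 1e-10)

  ok <- substitute_proxy(panel, "rs003", proxy, r2 = 0.92)
  expect_true("rs999" %in% ok$rsid)
  i <- which(ok$rsid == "rs999")
  expect_equal(ok$proxy_of[i], "rs003")
  expect_equal(ok$proxy_r2[i], 0.92)

  # the documented low-r2 exception passes only via the whitelist
  wl <- substitute_proxy(panel, "rs7705526", proxy, r2 = 0.79)
  expect_true("rs999" %in% wl$rsid)
  expect_error(substitute_proxy(panel, "rs7705526", proxy, r2 = 0.79,
                                whitelist = c()), "not whitelisted")
  expect_error(substitute_proxy(panel, "rs003", proxy, r2 = 0.5), "rejected")
  expect_error(substitute_proxy(panel, "rs003",
                                modifyList(proxy, list(rsid = "rs004")),
                                r2 = 0.95), "already in the panel")
})

test_that("allele harmonization resolves swaps, strand flips and ambiguity", {
  panel <- load_summary_stats(write_panel_tsv(data.frame(
    rsid = c("s1", "s2", "s3", "s4", "s5", "s6"),
    effect_allele = c("A", "A", "A", "A", "A", "C"),
    other_allele = c("G", "G", "G", "G", "T", "G"),
    beta = rep(0.05, 6), se = rep(0.005, 6), pval = rep(1e-9, 6),
    eaf = c(0.3, 0.3, 0.3, 0.3, 0.2, 0.3))))
  cohort <- data.frame(
    rsid = c("s1", "s2", "s3", "s4", "s5", "s6"),
    counted_allele = c("A", "G", "T", "C", "A", "C"),
    other_allele = c("G", "A", "C", "T", "T", "A"),
    eaf = c(0.31, 0.69, 0.29, 0.71, 0.21, 0.5))
  h <- suppressWarnings(harmonize_alleles(panel, cohort))
  expect_identical(h$log$action,
                   c("match", "swap", "strand_flip", "strand_flip_swap",
                     "match", "drop"))           # s5 freq-resolved, s6 irreconcilable
  expect_identical(h$log$flip_dosage, c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_false("s6" %in% h$panel$rsid)

  # ambiguous SNP without frequencies is dropped
  p5 <- panel[5, , drop = FALSE]
  attr(p5, "provenance") <- "x"; attr(p5, "threshold") <- 5e-8
  class(p5) <- class(panel)
  p5$eaf <- NA
  expect_warning(h5 <- harmonize_alleles(p5, cohort), "strand-ambiguous")
  expect_equal(h5$log$action, "drop")

  # idempotence: re-harmonizing the harmonized data is all "match"
  h2 <- harmonize_alleles(h$panel, h$cohort_alleles)
  expect_true(all(h2$log$action == "match"))
  expect_true(all(!h2$log$flip_dosage))
})

test_that("dosage recode and allele swap leave MR estimates invariant", {
  world <- tiny_study_cohort(n = 400, theta = 0.1, seed = 5, n_snps = 6)
  G <- world$cohort$dosages
  gwas <- world$gwas
  covs <- world$cohort$covariates

  run_one <- function(G, panel) {
    a <- snp_outcome_scan(G, world$cohort$outcomes$cognition, covs)
    ivw_estimate(mr_input(panel$beta_x, panel$se_x, a$beta_y, a$se_y,
                          rsid = panel$rsid))
  }
  base <- run_one(G, gwas)
  # swap SNP 3's coded allele: dosage 2-g and a record with alleles swapped,
  # beta sign flipped (the harmonization log says flip -> recode downstream)
  G2 <- G; G2[, 3] <- 2 - G2[, 3]
  swapped <- gwas
  swapped$effect_allele[3] <- gwas$other_allele[3]
  swapped$other_allele[3] <- gwas$effect_allele[3]
  swapped$beta_x[3] <- -swapped$beta_x[3]
  alt <- run_one(G2, swapped)
  expect_equal(alt$beta, base$beta, tolerance = 1e-12)
  expect_equal(alt$se, base$se, tolerance = 1e-12)
})

test_that("HWE exact test agrees with the enumeration oracle", {
  expect_equal(hwe_exact_test(100, 0, 0), 1)
  expect_equal(hwe_exact_test(0, 0, 57), 1)
  expect_equal(hwe_exact_test(5, 10, 5), oracle_hwe(5, 10, 5), tolerance = 1e-12)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-10)

  set.seed(14)
  for (i in 1:200) {
    n <- sample(2:100, 1)
    aa <- sample(0:n, 1)
    ab <- sample(0:(n - aa), 1)
    bb <- n - aa - ab
    expect_equal(hwe_exact_test(aa, ab, bb), oracle_hwe(aa, ab, bb),
                 tolerance = 1e-12)
  }
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
})

test_that("effect-allele frequency is mean dosage over two", {
  expect_equal(effect_allele_freq(c(2, 2, 2)), 1)
  expect_equal(effect_allele_freq(c(0, 1, 2, 1)), 0.5)
  expect_equal(effect_allele_freq(c(0, NA, 2)), 0.5)
  expect_error(effect_allele_freq(c(NA_real_, NA_real_)), "missing")
  expect_error(effect_allele_freq(c(1, 3)), "\\[0, 2\\]")
})
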