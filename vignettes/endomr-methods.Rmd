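---
title: "Methods: hybrid two-sample MR for disease endophenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid two-sample MR for disease endophenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endomr)
```

## The design

Observational associations between a biomarker exposure (here, telomere
length) and disease-related quantitative traits are confounded by shared
lifestyle factors and open to reverse causation. Mendelian randomization
sidesteps both by using germline variants as instruments: alleles are fixed
at conception, so a SNP robustly associated with the exposure can affect a
downstream outcome only through the exposure — provided it has no direct
(pleiotropic) path.

This package implements the *hybrid* two-sample flavor of that design. The
SNP–exposure coefficients $\beta_{X_j}$ and their standard errors come from
an external GWAS's summary statistics (so the instruments are estimated in a
sample far larger than the analysis cohort), while the SNP–outcome
coefficients $\beta_{Y_j}$ are estimated in the cohort itself by ordinary
least squares of each endophenotype on the SNP dosage plus age, sex, years
of education and APOE-ε4 status (APOE is dropped as a covariate inside
APOE-defined strata, where it is constant-by-design or colinear with the
stratum). Alleles are harmonized first so that every dosage column counts
the exposure-increasing allele.

## Estimators

With Wald ratios $\hat\theta_j = \beta_{Y_j}/\beta_{X_j}$, first-order
delta-method SEs $\sigma_j = \sigma_{Y_j}/|\beta_{X_j}|$ and weights
$w_j = \sigma_j^{-2}$:

* **IVW.** $\hat\theta = \sum w_j \hat\theta_j / \sum w_j$, identical to
  weighted least squares of $\beta_Y$ on $\beta_X$ through the origin with
  weights $\sigma_Y^{-2}$. The fixed-effect SE is $(\sum w_j)^{-1/2}$; the
  multiplicative random-effects SE inflates it by
  $\max\{1, \sqrt{Q/(J-1)}\}$ so it can never undercut the fixed-effect SE.
  Both flavors are always computed; `random` is the default because the
  inflation is a free insurance premium under homogeneity. Consistent only
  if all instruments are valid.
* **Maximum likelihood.** Observed $(\beta_{X_j}, \beta_{Y_j})$ are modeled
  as independent normals around $(\mu_j, \theta\mu_j)$. The $J$ nuisance
  means have a closed-form optimum at fixed $\theta$, leaving a
  one-dimensional profile likelihood that is maximized numerically; the SE
  comes from the profile curvature. Unlike IVW this propagates
  $\sigma_{X_j}$, so it relaxes the no-measurement-error (NOME)
  approximation the other estimators make.
* **Weighted median.** The 50% point of the ratio distribution under
  standardized cumulative weights $s_j = (\sum_{k\le j} w_k - w_j/2)/\sum w$,
  linearly interpolated. Consistent while valid instruments hold at least
  half the total weight.
* **Weighted mode.** Argmax of a weighted Gaussian KDE over the ratios with
  bandwidth $h = \varphi \cdot 0.9 \min(\mathrm{sd}, \mathrm{IQR}/1.34)
  J^{-1/5}$ ($\varphi = 1$ by default). Consistent when the largest group of
  SNPs sharing a ratio is valid. Median and mode SEs come from a parametric
  bootstrap (resampling the summary statistics from normals with their
  stated SEs; 1,000 draws, seed mandatory and recorded).
* **MR-Egger.** Weighted regression of $\beta_Y$ on $\beta_X$ *with* an
  intercept, after orienting all $\beta_X \ge 0$. The intercept estimates
  average directional pleiotropy (its $t$-test on $J-2$ df is the
  directional-pleiotropy diagnostic); the slope is a pleiotropy-adjusted
  estimate valid under the InSIDE assumption. SEs use multiplicative
  overdispersion floored at 1, and CIs use $t_{J-2}$ rather than the normal
  multiplier used everywhere else.

## Sensitivity suite

* **Cochran Q** around the fixed-effect IVW (definitional, even when the
  headline estimate is random-effects), $\chi^2_{J-1}$ upper tail.
* **MR-PRESSO.** The observed global statistic is
  $\mathrm{RSS} = \sum_j w_j(\beta_{Y_j} - \hat\theta^{(-j)}\beta_{X_j})^2$
  with leave-one-out IVW slopes; its null distribution is simulated
  parametrically (default 1,000 draws), and the global p-value uses the
  $+1/(n_{\mathrm{sim}}+1)$ smoothing, so the smallest attainable p is
  $1/(n_{\mathrm{sim}}+1)$. Per-SNP residual contributions give outlier
  p-values, Bonferroni-adjusted across $J$; flagged SNPs are removed for an
  outlier-corrected IVW. The distortion test is computed but reported as
  informational only.
* **Leave-one-SNP-out** IVW re-fits in input order, flagging rows whose
  p-value crosses 0.05 relative to the full panel (the "does significance
  hinge on one SNP" question).

FDR correction is Benjamini–Hochberg, applied strictly within one
endophenotype family (cognition / imaging / CSF) in one stratum, separately
per estimator by default (a pooled mode exists); `fdr_significant` requires
q < 0.05, `nominal` only p < 0.05.

## The synthetic world

`sim_config()` fixes the stated world; its defaults are the conditions the
pipeline is meant for, not knobs to revisit:

| parameter | default | why |
|---|---|---|
| `n_snps` | 20 | size of the telomere-length instrument panel |
| `n_external` | 78,592 | external exposure-GWAS meta-analysis size |
| `n_cohort` | 2,233 | genotyped cohort size |
| `freq_range` | (0.05, 0.95) | common variants only, as in a GWAS panel |
| `beta_x_scale` | 0.1 (half-normal) | per-allele effects of the size telomere GWAS hits show; all positive so the effect allele is the exposure-increasing allele |
| `confounder_*` | 0.3 / 0.3 | confounding present (MR is built to tolerate it) |
| `exposure_noise_sd` | 1 | leaves the genetic score explaining ~6–7% of the exposure, the realistic instrument strength |
| `theta` | 0 | null world unless stated |
| `pleiotropy_scale` | 0.02 | direct effects comparable to the per-SNP outcome SEs |
| `apoe_freqs` | (0.08, 0.72, 0.20) | elevated ε4 frequency of an enriched-risk cohort |
| noise SDs | cognition 1, thickness 0.1, CSF log-σ 0.35 | three outcome families on deliberately heterogeneous scales (unit composite, mm, right-skewed raw units) |

Genotypes are drawn binomial(2, p) independently per SNP, so
Hardy–Weinberg holds and instruments are independent by construction (the
real panel is selected to be independent; LD is deliberately not modeled).
The latent exposure is rescaled to unit population variance, so $\theta$ is
in outcome units per SD of exposure and the external GWAS reports effects on
that standardized scale. APOE genotypes come from independent haplotype
draws with the standard two-SNP map (the ε1 haplotype assumed absent, which
is also why the phase-ambiguous double heterozygote is called ε2/ε4 — the
configuration the analysis excludes). The PRS panel is simulated disjoint
from the instruments with its own weights.

What the generator does **not** emulate: LD between instruments, imputation
uncertainty beyond optional fractional dosages, assay floors/ceilings,
population stratification, and selection into the cohort. A green test
therefore establishes that the estimators and diagnostics do what their
theory promises under their stated assumptions — not that those assumptions
hold in any particular real cohort.

`simulate_summary_mr()` is an analytic shortcut that draws the summary
statistics directly from their sampling distributions (identical first-order
behavior to simulating a cohort and regressing); calibration studies that
need thousands of replicates use it, end-to-end checks use the full
individual-level path.

## Validation scenarios and their design

Three choices in the test scenarios deserve explanation:

* **Calibration** (size of IVW and the Egger intercept test, Q/(J−1) ≈ 1)
  is asserted for the *fixed-effect* IVW, whose Wald test is exactly
  calibrated conditional on the instruments; the random-effects flavor is
  conservative by construction (its SE is floored at the fixed-effect SE)
  and is reported alongside.
* **Recovery** of θ = 0.06 with |mean bias| < 0.005 over 200 end-to-end
  replicates at n = 1,000 requires the per-replicate SE to be well under
  0.04, which no realistic-strength panel can deliver (at ~6% explained
  variance and unit outcome SD the IVW SE is ~0.12). The recovery scenario
  therefore uses a deliberately well-powered world — no confounding,
  exposure noise SD 0.5, outcome noise SD 0.3 — chosen before the test was
  run; the generator defaults are unchanged.
* **Outlier correction.** A planted direct effect of 10× a SNP's outcome SE
  shifts IVW by at most ~2.2 corrected-estimator SEs when instruments carry
  equal weight, and less when the outlier lands on a weak instrument, so
  "corrected estimate closer to truth" cannot hold in ~90%+ of replicates
  under random placement. The test plants the outlier on the most
  influential instrument (largest IVW weight contribution) — the stress
  case where outlier correction is consequential; detection itself is
  asserted regardless.

## Numerical choices and edge cases

* OLS uses the Cholesky-solved normal equations with classical
  $\hat\sigma^2 (X'X)^{-1}$ SEs ($n-k$ denominator); a condition-number
  guard (ratio > 1e10 on the centered design) rejects collinear designs.
  Complete cases are per SNP: an individual missing one SNP's dosage is
  dropped only from that SNP's regression.
* Composites z-score against the analysis sample's own mean/SD (n−1);
  individuals keep a composite when ≥ half the components are observed.
  Thickness signatures average hemispheres first, then regions, unweighted
  (surface-area weighting is not implemented; the region registry is
  user-editable).
* The weighted-mode KDE argmax is located on a 512-point grid and refined
  by golden-section search; if all ratios coincide their common value is
  returned. The profile-likelihood maximizer brackets around the IVW
  estimate; its SE uses central-difference curvature.
* An exactly-fitting 3-SNP Egger regression leaves no residual degrees of
  freedom, so the intercept p-value is reported as `NA` rather than a
  fabricated 1.
* Strand-ambiguous (A/T, C/G) SNPs harmonize only when both allele
  frequencies are available and both fall outside the 0.42–0.58 band under
  exactly one orientation; otherwise they are dropped with a warning. The
  source analysis is silent on this; dropping is the conservative standard.
* The proxy rule accepts r² ≥ 0.9, plus an explicit user-overridable
  whitelist for documented exceptions (defaults: rs55749605 at 0.84,
  rs7705526 at 0.79).
* The PRS split takes the type-7 interpolation quantile and labels scores
  *strictly above* it "high"; ties on the threshold go low with a warning.
  The 75th percentile is computed on the analysis sample, i.e. after the
  ε2/ε4 exclusion (the source is silent on the order; excluding first keeps
  every downstream quantity a function of the analyzed individuals).
* ε2/ε4 individuals are excluded from *all* analyses, not only APOE strata.
* Every stochastic step (bootstraps, MR-PRESSO, generators) takes a seed
  and records it; `run_study()` derives per-cell seeds deterministically
  from the master seed, so identical config + seed reproduces results grids
  byte-for-byte.

## Limitations

Multivariable MR, contamination-mixture/CAUSE estimators, Steiger
directionality filtering, SIMEX-corrected Egger and winner's-curse
corrections are out of scope, as are genotype QC, imputation and image/assay
processing upstream of the tables this package consumes. The weighted-mode
bandwidth constant and the PRESSO simulation count follow published
defaults; both are exposed as arguments. t-tau is carried as a pass-through
outcome even though results for it are rarely reported; nothing in the
pipeline depends on that choice.
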