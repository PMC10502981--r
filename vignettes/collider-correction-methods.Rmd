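---
title: "One-sample MR with multivariable Collider-Correction: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{One-sample MR with multivariable Collider-Correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrcollide)
```

# The scientific problem

Observational associations between correlated biomarkers — say adiposity and
low-grade inflammation — and a disease outcome are confounded by environment
and behaviour. One-sample Mendelian randomisation (MR) uses genetic variants
as instrumental variables measured in the same cohort as the exposures and
outcome: because alleles are fixed at conception, a variant that raises the
exposure supports a causal reading of the downstream association, provided
the instrumental-variable assumptions hold. The third of those assumptions —
exclusion, i.e. the variant affects the outcome *only* through the
instrumented exposure — is the fragile one: pleiotropic variants violate it
and bias two-stage least squares (TSLS).

`mrcollide` implements the individual-level estimator stack for this
setting: observational baselines, univariable and multivariable TSLS,
instrument-strength and over-identification diagnostics, a multivariable
Collider-Correction estimator that lets pleiotropy-robust summary-data
methods be used on one-sample data, difference-method mediation with
bootstrap uncertainty, and stratified/moderated estimation. A synthetic
cohort generator reproduces the data-generating designs these estimators are
validated against, so everything here runs without access-controlled cohort
data.

# Models

## Two-stage least squares

For exposures $X_1,\dots,X_K$ instrumented by dosages $G$ with covariates
$C$, stage 1 fits $X_k \sim G + C$ and stage 2 fits
$Y \sim \hat X_1 + \dots + \hat X_K + C$ (linear for continuous outcomes,
logistic for binary — two-stage predictor substitution, so binary effects
are log odds ratios per 1 SD of exposure). Continuous-outcome standard
errors are proper IV standard errors: residuals are formed with the
*observed* exposures. Stage-2 logistic SEs do not propagate stage-1
uncertainty, the standard practice for predictor substitution; a bootstrap
over individuals is available where that matters.

Instrument strength is reported as the per-instrument mean F and joint F
(univariable) and the Sanderson–Windmeijer conditional F (multivariable),
computed from per-SNP exposure associations with profile weights that
account for the other exposures' association uncertainty; conditionally
collinear exposures drive it toward 1 (or 0 for exact collinearity, with a
warning). Residual pleiotropy is flagged by the Sargan statistic
$n R^2$ from regressing the TSLS residuals on the instruments,
$\chi^2_{m-K}$ under the null.

## Multivariable Collider-Correction

TSLS has no defence against directional pleiotropy. The Collider-Correction
device transfers that defence from two-sample summary methods into the
one-sample setting:

1. Fit the observational model $Y \sim X_1 + \dots + X_K + C$; its
   coefficient vector $\beta_{obs}$ is collider-biased (conditioning on the
   exposures opens confounder paths) but extremely precise.
2. For each SNP $j$, obtain the *conditional* outcome association
   $\hat\alpha^*_j$ (coefficient of $G_j$ in $Y \sim G_j + X_1 + \dots +
   X_K + C$, SNP at a time) and the marginal exposure associations
   $\hat\gamma_{kj}$ from $X_k \sim G_j + C$.
3. Under the linear model,
   $E[\hat\alpha^*_j] = \sum_k \gamma_{kj}(\beta_k - \beta_{obs,k}) +
   \alpha_j$, where $\alpha_j$ is the direct (pleiotropic) effect. A
   summary-data multivariable regression of $\hat\alpha^*$ on $\hat\gamma$
   therefore estimates the correction $\Delta = \beta - \beta_{obs}$, and
   any pleiotropy-robust summary estimator can be used.
4. Report $\hat\beta = \beta_{obs} + \hat\Delta$; the additivity is exact by
   construction. SEs combine both stages (analytic default; bootstrap over
   individuals available).

The summary stage minimises $\sum_j \rho(t_j)$ with
$t_j = (\hat\alpha^*_j - \hat\gamma_j\Delta)/s_j(\Delta)$ and profile
variance $s_j^2 = se^2_{\alpha_j} + \sum_k \Delta_k^2 se^2_{\gamma_{kj}}$.
Including the $\gamma$ uncertainty in $s_j$ is what removes
weak-instrument dilution: at the truth the score is unbiased even when
per-SNP F statistics are modest. Choices made here:

- **Losses.** `squared` is fixed-weight multi-exposure IVW (weights
  $1/se^2_\alpha$), kept exactly equal to the textbook estimator so it can
  serve as an oracle anchor; `huber` (k = 1.345) and the default `tukey`
  biweight (c = 4.685, ~95% Gaussian efficiency) down-weight outlying
  SNPs, the robust losses using the profile variance above.
- **Optimisation.** The Tukey objective is non-convex, so the estimator is
  optimised from several deterministic starts (IVW, the Huber solution, and
  zero correction) and the lowest objective wins; single-start runs were
  observed to land in a wrong basin in roughly 1% of weak-instrument
  replicates, and the multi-start removes those.
- **Overlap correlation.** The correlation between the $\hat\alpha^*$ and
  $\hat\gamma$ errors defaults to 0: conditioning the outcome association on
  the observed exposures makes the two stages' errors uncorrelated to first
  order in the one-sample setting. The parameter is exposed for two-sample
  style inputs.
- **SNP-at-a-time** conditional associations (rather than one joint fit over
  all SNPs): scales to large panels and matches univariable precedent.
- **Standard errors** for the robust stage come from a sandwich over the
  per-SNP scores with numerical derivatives.

The univariable reverse-direction analyses use the same profile idea as an
adjusted-profile-score estimator (`mr_raps_uv`) with an additive
overdispersion parameter $\tau^2 \ge 0$ for random pleiotropy, solved by a
moment condition on the (possibly Huberised) squared residuals and truncated
at zero.

## Mediation

The difference method: total effect of $X$ on $Y$ by univariable MR, direct
effect by multivariable MR adding the genetically proxied mediator, indirect
effect by subtraction, and mediated proportion $\pi_m = (\beta_{total} -
\beta_{direct})/\beta_{total}$. Uncertainty comes from refitting every stage
under per-person weights: non-parametric bootstrap weights (multinomial
counts / n — identical to resampling with replacement) or Bayesian bootstrap
weights (Dirichlet(1, ..., 1), i.e. normalised unit exponentials). The
Bayesian weights keep every observation in every refit with strictly
positive weight, which is why they behave better when the binary outcome is
very sparse and a resample can lose most cases.

Summaries follow the per-draw-ratio convention: $\pi_m$ is the median of the
per-draw ratios and the interval the 2.5th/97.5th percentiles, so asymmetry
in the draw distribution is preserved. $\pi_m$ is only interpretable as a
proportion when indirect and total effects share sign; the result carries a
flag and is reported unchanged (no truncation or winsorising) when they do
not. Refits that fail (e.g. separation in a sparse weighted logistic fit)
are dropped and counted, and more than 5% failures is an error rather than a
silently biased interval. B defaults to 1000.

## Moderation

Stratified estimation runs any estimator per stratum with identical
instruments. Two strata are compared with the Fisher z statistic
$(b_1-b_2)/\sqrt{se_1^2+se_2^2}$. For ordered strata (5-year age bins,
midpoint coding) a fixed-effect inverse-variance meta-regression on the
centred moderator (optionally plus its centred square, which decorrelates
the terms) is fitted via `metafor::rma(method = "FE")`; the moderator's
contribution is judged by $Q_{diff} = Q(\text{intercept-only}) -
Q(\text{moderator model})$ on as many df as added terms, the nested pair
implied by asking whether age explains effect heterogeneity. Fixed rather
than random effects keeps $Q$ interpretable as residual heterogeneity;
over-dispersion is visible in the reported $Q$.

# The synthetic cohort generator

`sim_config()` fixes the study conditions; every draw is determined by its
seed. Genotypes are Hardy–Weinberg dosages (two Bernoulli(maf) draws), SNPs
independent except duplicates constructed for pruning tests — no LD
structure, realistic frequency spectra, or assortative mating, so passing
tests validate estimator behaviour under the stated model, not robustness to
those real-data features. Confounder and noise terms are standard normal
(closed-form oracles); pleiotropic direct effects are
$N(\mu_\alpha, \sigma_\alpha)$, directional when $\mu_\alpha \ne 0$.
Binary outcomes use a logistic link whose intercept is solved by
root-finding so the expected prevalence matches the target to 1e-6.

Two designs are built in:

- **Two-exposure**: correlated exposures via an overlapping instrument
  fraction and a shared confounder; a stated fraction of exposure-1 SNPs
  carries direct outcome effects.
- **Mediation**: $X \to M \to Y$ with disjoint instrument sets and a direct
  $X \to Y$ path; the truth record carries the exact identity
  $\beta_{total} = \beta_{direct} + \beta_{XM}\beta_{MY}$ and
  $\pi_m^{true}$.

A deliberate design choice: exposures are built with *analytic unit
variance* (the residual noise variance is solved so Var(X) = 1) instead of
being empirically re-standardised after generation. This keeps the
generating coefficients exactly equal to the per-SD estimands, so recovery
tests have exact targets; the rank-based inverse-normal transform
(Blom offsets 3/8 and 1/4, average ranks for ties) is provided separately
for real phenotypes, which is where such a transform belongs. If the
systematic variance budget exceeds 1 the generator refuses rather than
silently rescaling.

Default study conditions, chosen once: cohorts of n = 10,000 with 25 SNPs
per exposure, 20% shared; per-allele effects `gamma_scale * U(0.5, 1.5)`
with `gamma_scale = 0.07`, giving per-SNP first-stage F near 10 — the
weak-instrument regime of interest; confounder loadings (0.4, 0.4, 0.4);
directional pleiotropy on 20% of exposure-1 SNPs with effects
N(0.15, 0.02), large enough to be individually detectable (standardised
residuals near 8) so robust losses must actually reject them. The mediation
study uses n = 2,000 (continuous) / 4,000 (binary), 8 SNPs per set,
`gamma_scale = 0.17` (strong instruments), direct effect 0.2 and indirect
effect 0.5 × 0.4 = 0.2, hence a true mediated proportion of 0.5.

# Validation experiments

The replicate studies are exported so the analysis drivers, the test suite
and the acceptance script all run the same code:

- `cc_recovery_study()` — 500 replicates of the two-exposure design;
  collider-corrected means should sit within Monte-Carlo error (4 SEs of
  the replicate mean, the convention used throughout) of the generating
  (1, 0.5) while naive TSLS MVMR is materially biased.
- `mediation_coverage_study()` — interval coverage of $\pi_m$; 500
  replicates at B = 500 in the continuous regime (scaled down from a
  larger-scale design of the same structure; the Monte-Carlo binomial bound
  widens accordingly), and a Bayesian-vs-non-parametric comparison at
  prevalence 0.02.
- `sargan_calibration_study()` / `fisher_z_calibration_study()` — type-I
  error of the two tests at 1000 replicates.

# Numerical choices and degenerate inputs

- Clump ties in p broken by (chrom, pos, id); windows are symmetric on
  1-based positions.
- The pairwise prune rule keeps the smaller discovery p of a violating pair
  by default; `literal = TRUE` keeps the larger, reproducing a printed rule
  that contradicts universal practice — retained as an option for exact
  reproducibility rather than silently corrected.
- Steiger comparisons use point r-squared values only (no z test), in
  individual-level (squared partial correlation) or summary
  ($2f(1-f)\beta^2/\mathrm{Var}$) mode; summary mode refuses absent allele
  frequencies.
- Harmonisation aligns external weights to cohort effect alleles by allele
  matching with sign flip; palindromic variants with allele frequency in
  (0.42, 0.58) are dropped by default.
- cis-PC MR ridge-regularises the LD matrix (1e-6 on the diagonal); the
  default component count retains 99% cumulative variance of the
  precision-weighted LD matrix, `k` can be fixed (e.g. 10).
- Monomorphic dosages, zero-variance exposures, just-identified Sargan
  requests, single-exposure conditional F, B < 1, prevalence outside (0,1)
  and total effect 0 in $\pi_m$ are all refused with explicit errors.
- Missing dosages are mean-imputed with a logged count; analyses are
  complete-case with per-analysis n reported.

# Known limitations

- The collider-correction reconstruction is validated against its own
  simulation designs, not against the original supplement's code; every
  stage is a separate exported function so divergences are auditable.
- Binary-outcome MR is non-collapsible: log-odds estimands from predictor
  substitution attenuate relative to the latent generating coefficients.
  Ratios such as $\pi_m$ largely cancel this, which the sparse-binary
  coverage study relies on.
- No LD-structured genotype simulation; the cis-PC module is exercised on
  constructed correlation matrices.
- Sample sizes in the shipped studies are desk-scale by design; they
  validate calibration and bias properties, not power at biobank scale.

# A worked run

```{r example, eval = FALSE}
library(mrcollide)

cfg <- cc_study_config(seed = 1)           # weak instruments, 20% pleiotropy
sim <- simulate_two_exposure_cohort(cfg)
X <- as.matrix(sim$cohort[c("x1", "x2")])

tsls_mvmr(sim$genotypes, X, sim$cohort$y)  # naive: biased upward on x1
collider_correction_mvmr(sim$genotypes, X, sim$cohort$y, loss = "tukey")
```

The `analysis/` directory contains the numbered drivers that run the full
sequence (simulation, instrument QC, MR models, collider correction,
mediation, moderation) and write their tables under `results/`.
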