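# Synthetic cohort generator.
#
# Emulates the statistical structure of an individual-level biobank MR study:
# Hardy-Weinberg allele dosages, two correlated continuous exposures with
# partially overlapping instrument sets, an unmeasured confounder, direct
# SNP -> outcome (pleiotropic) paths, a mediation chain X -> M -> Y, and
# continuous or sparse binary outcomes with a target prevalence.

#' Simulation configuration
#'
#' Bundles every generating parameter for the synthetic cohorts. Defaults
#' realise the weak-instrument, directional-pleiotropy regime used in the
#' package's recovery studies: per-SNP first-stage F around 10 and a fifth of
#' exposure-1 SNPs carrying a clearly separated direct outcome effect.
#'
#' @param n_individuals Cohort size.
#' @param n_snps_per_exposure Number of instruments per exposure.
#' @param shared_snp_fraction Fraction of each exposure's SNPs shared with the
#'   other exposure (two-exposure design only).
#' @param maf_range Lower/upper bound for per-SNP minor allele frequencies,
#'   within (0, 0.5].
#' @param gamma_scale Typical per-allele SNP -> exposure effect (exposure-SD
#'   units); individual effects are drawn uniformly in
#'   `gamma_scale * [0.5, 1.5]`.
#' @param beta_x1,beta_x2 Causal effects of exposures 1 and 2 on the outcome,
#'   per 1 SD of exposure.
#' @param beta_xm,beta_my,beta_xy_direct Mediation-chain effects: exposure on
#'   mediator, mediator on outcome, and the direct exposure-outcome path.
#' @param pleiotropy_fraction Fraction of exposure-1 SNPs with a direct
#'   outcome effect (exclusion-restriction violation).
#' @param pleiotropy_mean,pleiotropy_sd Normal law of the direct SNP ->
#'   outcome effects: nonzero mean gives directional pleiotropy, zero mean
#'   balanced pleiotropy.
#' @param confounder_effects Length-3 loadings of the standard-normal
#'   confounder on exposure 1 (or X), exposure 2 (or M), and the outcome.
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param prevalence Target case fraction, binary outcomes only.
#' @param n_replicates Replicates for simulation studies built on this config.
#' @param seed Integer seed; fully determines every draw.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_individuals = 10000,
                       n_snps_per_exposure = 25,
                       shared_snp_fraction = 0.2,
                       maf_range = c(0.1, 0.4),
                       gamma_scale = 0.07,
                       beta_x1 = 1,
                       beta_x2 = 0.5,
                       beta_xm = 0.5,
                       beta_my = 0.4,
                       beta_xy_direct = 0.2,
                       pleiotropy_fraction = 0,
                       pleiotropy_mean = 0.15,
                       pleiotropy_sd = 0.02,
                       confounder_effects = c(0.4, 0.4, 0.4),
                       outcome_type = c("continuous", "binary"),
                       prevalence = NULL,
                       n_replicates = 500,
                       seed = 1L) {
  outcome_type <- match.arg(outcome_type)
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_snps_per_exposure = as.integer(n_snps_per_exposure),
    shared_snp_fraction = shared_snp_fraction,
    maf_range = maf_range,
    gamma_scale = gamma_scale,
    beta_x1 = beta_x1, beta_x2 = beta_x2,
    beta_xm = beta_xm, beta_my = beta_my, beta_xy_direct = beta_xy_direct,
    pleiotropy_fraction = pleiotropy_fraction,
    pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
    confounder_effects = confounder_effects,
    outcome_type = outcome_type,
    prevalence = prevalence,
    n_replicates = as.integer(n_replicates),
    seed = as.integer(seed)
  )
  .validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @keywords internal
.validate_sim_config <- function(cfg) {
  if (cfg$n_individuals < 1L) .stopf("n_individuals must be >= 1")
  if (cfg$n_snps_per_exposure < 1L) .stopf("n_snps_per_exposure must be >= 1")
  .check_scalar_prob(cfg$shared_snp_fraction, "shared_snp_fraction", open = FALSE)
  .check_scalar_prob(cfg$pleiotropy_fraction, "pleiotropy_fraction", open = FALSE)
  .check_maf_range(cfg$maf_range)
  if (length(cfg$confounder_effects) != 3L) {
    .stopf("confounder_effects must have length 3 (exposure 1, exposure 2, outcome)")
  }
  if (cfg$outcome_type == "binary") {
    if (is.null(cfg$prevalence)) .stopf("binary outcomes require a prevalence")
    .check_scalar_prob(cfg$prevalence, "prevalence")
  } else if (!is.null(cfg$prevalence)) {
    .stopf("prevalence must be absent for continuous outcomes")
  }
  if (cfg$n_replicates < 1L) .stopf("n_replicates must be >= 1")
  invisible(cfg)
}

#' @keywords internal
.check_maf_range <- function(maf_range) {
  if (length(maf_range) != 2L || any(!is.finite(maf_range)) ||
      maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5) {
    .stopf("maf_range must be an increasing pair within (0, 0.5]")
  }
  invisible(maf_range)
}

#' Construct a genotype matrix object
#'
#' @param dosages Numeric n x m matrix of effect-allele dosages with SNP ids
#'   as column names.
#' @param info Data frame of per-variant metadata (`id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `maf`), one row per column of `dosages`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, info) {
  dosages <- as.matrix(dosages)
  if (is.null(colnames(dosages))) .stopf("dosage matrix needs SNP column names")
  if (nrow(info) != ncol(dosages)) .stopf("info rows must match dosage columns")
  if (!identical(info$id, colnames(dosages))) .stopf("info$id must match dosage column names")
  structure(list(dosages = dosages, info = info), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

# Raw generator that draws from the current RNG stream (no reseeding), so
# multi-stage cohort builds stay reproducible from one root seed.
#' @keywords internal
.gen_genotypes <- function(n, m, maf_range, ids = paste0("snp_", seq_len(m))) {
  maf <- stats::runif(m, maf_range[1], maf_range[2])
  dos <- matrix(stats::rbinom(n * m, size = 2L, prob = rep(maf, each = n)),
                nrow = n, ncol = m, dimnames = list(NULL, ids))
  info <- data.frame(
    id = ids,
    chrom = as.character(rep_len(1:22, m)),
    pos = 1000000L + 1000000L * (seq_len(m) - 1L),
    effect_allele = "A",
    other_allele = "G",
    maf = maf,
    stringsAsFactors = FALSE
  )
  genotype_matrix(dos, info)
}

#' Simulate Hardy-Weinberg allele dosages
#'
#' Dosages in \{0, 1, 2\} are two independent Bernoulli(maf) draws per person
#' per SNP; SNPs are mutually independent (no LD).
#'
#' @param n Number of individuals.
#' @param m Number of SNPs.
#' @param maf_range Minor-allele-frequency bounds within (0, 0.5]; each SNP's
#'   frequency is drawn uniformly in this range.
#' @param seed Optional integer seed.
#' @return A [genotype_matrix()] with the drawn `maf` in its metadata.
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.1, 0.4), seed = NULL) {
  if (n < 1 || m < 1) .stopf("n and m must be >= 1")
  .check_maf_range(maf_range)
  if (!is.null(seed)) set.seed(seed)
  .gen_genotypes(n, m, maf_range)
}

# Variance-budget helper: residual noise SD so the final variable has unit
# variance given its systematic components.
#' @keywords internal
.noise_sd <- function(explained, what) {
  v <- 1 - explained
  if (v <= 0) {
    .stopf("variance budget exceeded for %s (systematic variance %.3f >= 1); reduce gamma_scale or confounder loadings",
           what, explained)
  }
  sqrt(v)
}

#' Simulate a two-exposure cohort
#'
#' Generates the two-exposure design: `X1 = G1 gamma1 + c1 U + e1`,
#' `X2 = G2 gamma2 + c2 U + e2` with a stated fraction of SNPs shared between
#' the instrument sets, and
#' `Y = beta_x1 X1 + beta_x2 X2 + sum_j alpha_j G_j + c3 U + eY`, where a
#' `pleiotropy_fraction` of exposure-1 SNPs carry direct effects `alpha_j`
#' (exclusion-restriction violations). Noise variances are solved so each
#' exposure has unit variance, making the generating coefficients exactly the
#' per-SD estimands.
#'
#' @param config A [sim_config()].
#' @return A list with elements `genotypes` ([genotype_matrix()]), `cohort`
#'   (data frame with `x1`, `x2`, `y`, the latent `confounder`, and inert
#'   `age`/`sex` columns), and `truth` (generating parameters, class
#'   `sim_truth`).
#' @export
simulate_two_exposure_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  m <- config$n_snps_per_exposure
  n_shared <- round(config$shared_snp_fraction * m)
  m_tot <- 2L * m - n_shared
  idx1 <- seq_len(m)                    # instruments of X1
  idx2 <- (m - n_shared + 1L):m_tot     # instruments of X2 (overlap at the seam)

  geno <- .gen_genotypes(n, m_tot, config$maf_range)
  Gc <- sweep(geno$dosages, 2L, 2 * geno$info$maf)   # centred dosages
  c123 <- config$confounder_effects

  gamma1 <- .draw_gamma(m, config$gamma_scale)
  gamma2 <- .draw_gamma(m, config$gamma_scale)
  vg1 <- sum(2 * geno$info$maf[idx1] * (1 - geno$info$maf[idx1]) * gamma1^2)
  vg2 <- sum(2 * geno$info$maf[idx2] * (1 - geno$info$maf[idx2]) * gamma2^2)
  if (config$gamma_scale > 0 && (vg1 == 0 || vg2 == 0)) {
    .stopf("degenerate instrument variance: all gamma are zero")
  }

  U <- stats::rnorm(n)
  x1 <- drop(Gc[, idx1, drop = FALSE] %*% gamma1) + c123[1] * U +
    stats::rnorm(n, sd = .noise_sd(vg1 + c123[1]^2, "exposure 1"))
  x2 <- drop(Gc[, idx2, drop = FALSE] %*% gamma2) + c123[2] * U +
    stats::rnorm(n, sd = .noise_sd(vg2 + c123[2]^2, "exposure 2"))

  alpha <- numeric(m_tot)
  n_pleio <- round(config$pleiotropy_fraction * m)
  pleio_idx <- if (n_pleio > 0) sample(idx1, n_pleio) else integer(0)
  if (n_pleio > 0) {
    alpha[pleio_idx] <- stats::rnorm(n_pleio, config$pleiotropy_mean,
                                     config$pleiotropy_sd)
  }

  lp <- config$beta_x1 * x1 + config$beta_x2 * x2 +
    drop(Gc %*% alpha) + c123[3] * U + stats::rnorm(n)
  y <- if (config$outcome_type == "binary") {
    binary_from_latent(lp, config$prevalence)
  } else lp

  cohort <- data.frame(
    iid = seq_len(n), x1 = x1, x2 = x2, y = as.numeric(y),
    confounder = U,
    age = round(stats::runif(n, 40, 74)),
    sex = stats::rbinom(n, 1L, 0.5)
  )
  truth <- structure(list(
    design = "two_exposure",
    beta_x1 = config$beta_x1, beta_x2 = config$beta_x2,
    gamma1 = stats::setNames(gamma1, geno$info$id[idx1]),
    gamma2 = stats::setNames(gamma2, geno$info$id[idx2]),
    alpha = stats::setNames(alpha, geno$info$id),
    pleiotropic_snps = geno$info$id[pleio_idx],
    snps_x1 = geno$info$id[idx1], snps_x2 = geno$info$id[idx2],
    maf = stats::setNames(geno$info$maf, geno$info$id),
    confounder_effects = c123,
    outcome_type = config$outcome_type,
    prevalence = config$prevalence,
    seed = config$seed
  ), class = "sim_truth")
  list(genotypes = geno, cohort = cohort, truth = truth)
}

#' @keywords internal
.draw_gamma <- function(m, gamma_scale) {
  gamma_scale * stats::runif(m, 0.5, 1.5)
}

#' Simulate a mediation cohort
#'
#' Generates the mediation chain: `X` from its instruments plus confounder,
#' `M = beta_xm X + G_M gamma_M + c2 U + eM`, and
#' `Y = beta_xy_direct X + beta_my M + c3 U + eY` (binary outcomes through
#' [binary_from_latent()]). Instrument sets for X and M are disjoint. The
#' truth record carries the exact identity
#' `total = beta_xy_direct + beta_xm * beta_my` and the true mediated
#' proportion `pi_m_true = (beta_xm * beta_my) / total`.
#'
#' Because X and M are drawn before the outcome link is applied, cohorts
#' generated from the same seed share identical `x` and `m` columns whether
#' the outcome is continuous or binary.
#'
#' @inheritParams simulate_two_exposure_cohort
#' @return As [simulate_two_exposure_cohort()]; cohort columns are `x`, `m`,
#'   `y`.
#' @export
simulate_mediation_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  m <- config$n_snps_per_exposure
  idx_x <- seq_len(m)
  idx_m <- m + seq_len(m)
  geno <- .gen_genotypes(n, 2L * m, config$maf_range)
  Gc <- sweep(geno$dosages, 2L, 2 * geno$info$maf)
  c123 <- config$confounder_effects

  gamma_x <- .draw_gamma(m, config$gamma_scale)
  gamma_m <- .draw_gamma(m, config$gamma_scale)
  f <- geno$info$maf
  vg_x <- sum(2 * f[idx_x] * (1 - f[idx_x]) * gamma_x^2)
  vg_m <- sum(2 * f[idx_m] * (1 - f[idx_m]) * gamma_m^2)
  if (config$gamma_scale > 0 && (vg_x == 0 || vg_m == 0)) {
    .stopf("degenerate instrument variance: all gamma are zero")
  }

  U <- stats::rnorm(n)
  x <- drop(Gc[, idx_x, drop = FALSE] %*% gamma_x) + c123[1] * U +
    stats::rnorm(n, sd = .noise_sd(vg_x + c123[1]^2, "exposure"))
  # Var(M) budget includes 2 * beta_xm * c1 * c2 from cov(X, U) = c1
  med_sys <- config$beta_xm^2 + vg_m + c123[2]^2 +
    2 * config$beta_xm * c123[1] * c123[2]
  med <- config$beta_xm * x + drop(Gc[, idx_m, drop = FALSE] %*% gamma_m) +
    c123[2] * U + stats::rnorm(n, sd = .noise_sd(med_sys, "mediator"))

  alpha <- numeric(2L * m)
  n_pleio <- round(config$pleiotropy_fraction * m)
  pleio_idx <- if (n_pleio > 0) sample(idx_x, n_pleio) else integer(0)
  if (n_pleio > 0) {
    alpha[pleio_idx] <- stats::rnorm(n_pleio, config$pleiotropy_mean,
                                     config$pleiotropy_sd)
  }

  lp <- config$beta_xy_direct * x + config$beta_my * med +
    drop(Gc %*% alpha) + c123[3] * U + stats::rnorm(n)
  y <- if (config$outcome_type == "binary") {
    binary_from_latent(lp, config$prevalence)
  } else lp

  total <- config$beta_xy_direct + config$beta_xm * config$beta_my
  cohort <- data.frame(
    iid = seq_len(n), x = x, m = med, y = as.numeric(y),
    confounder = U,
    age = round(stats::runif(n, 40, 74)),
    sex = stats::rbinom(n, 1L, 0.5)
  )
  truth <- structure(list(
    design = "mediation",
    beta_xy_direct = config$beta_xy_direct,
    beta_xm = config$beta_xm, beta_my = config$beta_my,
    total_effect = total,
    pi_m_true = if (total != 0) config$beta_xm * config$beta_my / total else NA_real_,
    gamma_x = stats::setNames(gamma_x, geno$info$id[idx_x]),
    gamma_m = stats::setNames(gamma_m, geno$info$id[idx_m]),
    alpha = stats::setNames(alpha, geno$info$id),
    snps_x = geno$info$id[idx_x], snps_m = geno$info$id[idx_m],
    maf = stats::setNames(f, geno$info$id),
    confounder_effects = c123,
    outcome_type = config$outcome_type,
    prevalence = config$prevalence,
    seed = config$seed
  ), class = "sim_truth")
  list(genotypes = geno, cohort = cohort, truth = truth)
}

#' Draw a binary outcome from a latent linear predictor
#'
#' The outcome is Bernoulli(plogis(intercept + linear_predictor)) with the
#' intercept solved by monotone root finding so the expected case fraction
#' equals `prevalence` (to within 1e-8).
#'
#' @param linear_predictor Per-person latent score.
#' @param prevalence Target case fraction, strictly in (0, 1).
#' @param seed Optional integer seed; by default the current RNG stream is
#'   consumed.
#' @return Integer 0/1 vector with the solved intercept in
#'   `attr(, "intercept")`.
#' @export
binary_from_latent <- function(linear_predictor, prevalence, seed = NULL) {
  .check_scalar_prob(prevalence, "prevalence")
  if (!is.null(seed)) set.seed(seed)
  f <- function(a) mean(stats::plogis(a + linear_predictor)) - prevalence
  a <- stats::uniroot(f, interval = c(-40, 40), extendInt = "yes",
                      tol = 1e-10)$root
  y <- stats::rbinom(length(linear_predictor), 1L,
                     stats::plogis(a + linear_predictor))
  attr(y, "intercept") <- a
  y
}

#' Rank-based inverse normal transform
#'
#' Blom-offset transform `qnorm((rank - 3/8) / (n + 1/4))`; ties receive their
#' average rank, so the output is order-isomorphic to the input.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return Transformed vector, approximately standard normal.
#' @export
inverse_normal_transform <- function(values) {
  if (anyNA(values)) .stopf("values contain NA")
  if (length(unique(values)) < 2L) {
    .stopf("inverse normal transform is degenerate: all values identical")
  }
  n <- length(values)
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (n + 1 / 4))
}
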