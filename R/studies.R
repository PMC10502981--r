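# Replicate-level simulation studies: estimator recovery under pleiotropy,
# bootstrap interval coverage for the mediated proportion, and calibration of
# the Sargan and Fisher-z tests. These are the package's validation
# experiments; the analysis scripts and acceptance checks all run through
# them.

#' Study conditions: two-exposure recovery design
#'
#' The weak-instrument, directional-pleiotropy regime: generating effects
#' (1, 0.5), per-SNP first-stage F around 10, 20% of exposure-1 SNPs
#' pleiotropic with direct effects drawn from N(0.15, 0.02).
#'
#' @param seed Integer seed.
#' @param ... Overrides forwarded to [sim_config()].
#' @return A [sim_config()].
#' @export
cc_study_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(list(pleiotropy_fraction = 0.2, seed = seed),
                            list(...))
  do.call(sim_config, args)
}

#' Study conditions: mediation coverage design
#'
#' Strong-instrument mediation chain with direct effect 0.2 and indirect
#' effect 0.5 * 0.4 = 0.2, so the true total effect is 0.4 and the true
#' mediated proportion 0.5. Continuous regime at n = 2000; the sparse binary
#' regime uses n = 4000 at the requested prevalence.
#'
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param prevalence Case fraction for the binary regime (default 0.02).
#' @param seed Integer seed.
#' @param ... Overrides forwarded to [sim_config()].
#' @return A [sim_config()].
#' @export
mediation_study_config <- function(outcome_type = "continuous",
                                   prevalence = 0.02, seed = 1L, ...) {
  base <- list(
    n_individuals = if (outcome_type == "binary") 4000L else 2000L,
    n_snps_per_exposure = 8L,
    gamma_scale = 0.17,
    beta_xm = 0.5, beta_my = 0.4, beta_xy_direct = 0.2,
    pleiotropy_fraction = 0,
    outcome_type = outcome_type,
    prevalence = if (outcome_type == "binary") prevalence else NULL,
    seed = seed
  )
  do.call(sim_config, utils::modifyList(base, list(...)))
}

#' Collider-Correction recovery study
#'
#' Replicates the two-exposure design and, in each replicate, estimates the
#' direct effects by naive TSLS MVMR and by collider-corrected MVMR with the
#' requested robust loss. Under directional pleiotropy and weak instruments
#' the naive estimator is biased; the collider-corrected estimator should
#' recover the generating effects on average.
#'
#' @param reps Number of replicates.
#' @param config Generating [sim_config()] (default [cc_study_config()]).
#' @param loss Summary-stage loss for the collider correction.
#' @param seed Root seed; replicate r uses `seed + r`.
#' @return List with `draws` (per-replicate estimates) and `summary` (means,
#'   SDs and Monte-Carlo SEs per estimator and exposure, plus the truth).
#' @export
cc_recovery_study <- function(reps = 500, config = cc_study_config(),
                              loss = "tukey", seed = 1L) {
  draws <- vector("list", reps)
  for (r in seq_len(reps)) {
    cfg <- config
    cfg$seed <- as.integer(seed + r)
    sim <- simulate_two_exposure_cohort(cfg)
    X <- as.matrix(sim$cohort[c("x1", "x2")])
    naive <- suppressWarnings(
      tsls_mvmr(sim$genotypes, X, sim$cohort$y)
    )
    cc <- collider_correction_mvmr(sim$genotypes, X, sim$cohort$y, loss = loss)
    draws[[r]] <- data.frame(
      rep = r,
      naive_x1 = naive$beta[["x1"]], naive_x2 = naive$beta[["x2"]],
      cc_x1 = cc$beta[["x1"]], cc_x2 = cc$beta[["x2"]]
    )
  }
  draws <- do.call(rbind, draws)
  mom <- function(v) c(mean = mean(v), sd = stats::sd(v),
                       mc_se = stats::sd(v) / sqrt(reps))
  summary <- rbind(
    naive_x1 = mom(draws$naive_x1), naive_x2 = mom(draws$naive_x2),
    cc_x1 = mom(draws$cc_x1), cc_x2 = mom(draws$cc_x2)
  )
  list(draws = draws,
       summary = as.data.frame(summary),
       truth = c(x1 = config$beta_x1, x2 = config$beta_x2),
       reps = reps, loss = loss)
}

#' Bootstrap coverage study for the mediated proportion
#'
#' Replicates the mediation design; in each replicate, runs
#' [bootstrap_mediation()] with each requested bootstrap method on the same
#' cohort and records whether the 95% percentile interval covers the true
#' mediated proportion.
#'
#' @param reps Number of replicates.
#' @param B Bootstrap draws per replicate.
#' @param methods Bootstrap methods to compare (`"bb"`, `"np"`).
#' @param config Generating [sim_config()] (default
#'   [mediation_study_config()]).
#' @param seed Root seed; replicate r uses `seed + r` for both the cohort
#'   and the weight draws.
#' @return List with `coverage` (per-method coverage, Monte-Carlo SE, mean
#'   interval width, failure counts) and `draws` (per-replicate records).
#' @export
mediation_coverage_study <- function(reps = 500, B = 500, methods = "bb",
                                     config = mediation_study_config(),
                                     seed = 1L) {
  recs <- vector("list", reps * length(methods))
  k <- 0L
  for (r in seq_len(reps)) {
    cfg <- config
    cfg$seed <- as.integer(seed + r)
    sim <- simulate_mediation_cohort(cfg)
    pi_true <- sim$truth$pi_m_true
    for (mth in methods) {
      res <- tryCatch(
        bootstrap_mediation(sim$cohort, sim$genotypes, "x", "m", "y",
                            sim$truth$snps_x, sim$truth$snps_m,
                            outcome_type = cfg$outcome_type,
                            method = mth, B = B, seed = cfg$seed),
        error = function(e) NULL
      )
      k <- k + 1L
      recs[[k]] <- if (is.null(res)) {
        data.frame(rep = r, method = mth, pi_m = NA_real_,
                   lo = NA_real_, hi = NA_real_, covered = NA,
                   failed = TRUE)
      } else {
        data.frame(rep = r, method = mth, pi_m = res$pi_m,
                   lo = res$ci[1], hi = res$ci[2],
                   covered = res$ci[1] <= pi_true & pi_true <= res$ci[2],
                   failed = FALSE)
      }
    }
  }
  draws <- do.call(rbind, recs)
  cov <- do.call(rbind, lapply(split(draws, draws$method), function(d) {
    ok <- !d$failed & !is.na(d$covered)
    p <- mean(d$covered[ok])
    data.frame(method = d$method[1], coverage = p,
               mc_se = sqrt(p * (1 - p) / sum(ok)),
               mean_width = mean(d$hi[ok] - d$lo[ok]),
               n_used = sum(ok), n_failed = sum(d$failed))
  }))
  rownames(cov) <- NULL
  list(coverage = cov, draws = draws, pi_true = config$beta_xm * config$beta_my /
         (config$beta_xy_direct + config$beta_xm * config$beta_my),
       reps = reps, B = B)
}

#' Sargan test calibration study
#'
#' Univariable over-identified TSLS under a controllable pleiotropy regime:
#' with `pleiotropy_fraction = 0` the exclusion restriction holds and the
#' rejection rate at `alpha` estimates the type-I error; with a directional
#' pleiotropic fraction it estimates power.
#'
#' @param reps Replicates.
#' @param n Cohort size per replicate.
#' @param m Instruments.
#' @param pleiotropy_fraction Fraction of SNPs with direct outcome effects.
#' @param pleiotropy_mean Mean direct effect for the pleiotropic SNPs.
#' @param alpha Test level.
#' @param seed Root seed.
#' @return List with `rejection_rate`, `mc_se`, `alpha`, `p_values`.
#' @export
sargan_calibration_study <- function(reps = 1000, n = 2000, m = 30,
                                     pleiotropy_fraction = 0,
                                     pleiotropy_mean = 0.1,
                                     alpha = 0.05, seed = 1L) {
  pvals <- numeric(reps)
  for (r in seq_len(reps)) {
    set.seed(seed + r)
    geno <- .gen_genotypes(n, m, c(0.1, 0.4))
    Gc <- sweep(geno$dosages, 2L, 2 * geno$info$maf)
    gamma <- .draw_gamma(m, 0.15)
    U <- stats::rnorm(n)
    vg <- sum(2 * geno$info$maf * (1 - geno$info$maf) * gamma^2)
    x <- drop(Gc %*% gamma) + 0.4 * U +
      stats::rnorm(n, sd = .noise_sd(vg + 0.16, "exposure"))
    alpha_j <- numeric(m)
    n_pl <- round(pleiotropy_fraction * m)
    if (n_pl > 0) alpha_j[seq_len(n_pl)] <- pleiotropy_mean
    y <- 0.3 * x + drop(Gc %*% alpha_j) + 0.4 * U + stats::rnorm(n)
    pvals[r] <- sargan_test(geno$dosages, x, y)$p
  }
  rate <- mean(pvals < alpha)
  list(rejection_rate = rate, mc_se = sqrt(rate * (1 - rate) / reps),
       alpha = alpha, p_values = pvals)
}

#' Fisher-z heterogeneity test calibration study
#'
#' Two strata with the same true causal effect: per replicate, a cohort is
#' simulated, split in half, the effect estimated by TSLS UVMR in each half,
#' and the Fisher-z test applied. The rejection rate at `alpha` estimates
#' the type-I error of the sex-heterogeneity test.
#'
#' @param reps Replicates.
#' @param n Cohort size (split into two strata of n/2).
#' @param m Instruments.
#' @param alpha Test level.
#' @param seed Root seed.
#' @return List with `rejection_rate`, `mc_se`, `alpha`, `z_values`.
#' @export
fisher_z_calibration_study <- function(reps = 1000, n = 2000, m = 10,
                                       alpha = 0.05, seed = 1L) {
  zvals <- numeric(reps)
  for (r in seq_len(reps)) {
    set.seed(seed + r)
    geno <- .gen_genotypes(n, m, c(0.1, 0.4))
    Gc <- sweep(geno$dosages, 2L, 2 * geno$info$maf)
    gamma <- .draw_gamma(m, 0.15)
    vg <- sum(2 * geno$info$maf * (1 - geno$info$maf) * gamma^2)
    x <- drop(Gc %*% gamma) + stats::rnorm(n, sd = .noise_sd(vg, "exposure"))
    y <- 0.3 * x + stats::rnorm(n)
    half <- seq_len(n %/% 2)
    # single-score instrument keeps the per-stratum fits cheap
    score <- drop(Gc %*% gamma)
    f1 <- tsls_uvmr(score[half], x[half], y[half])
    f2 <- tsls_uvmr(score[-half], x[-half], y[-half])
    zvals[r] <- fisher_z_heterogeneity(f1$beta, f1$se, f2$beta, f2$se)$z
  }
  rate <- mean(abs(zvals) > stats::qnorm(1 - alpha / 2))
  list(rejection_rate = rate, mc_se = sqrt(rate * (1 - rate) / reps),
       alpha = alpha, z_values = zvals)
}
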