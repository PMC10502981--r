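# Collider-Correction stages, robust summary estimators, adjusted profile
# score.

# summary-level generator: gamma_hat = gamma + noise, alpha_hat =
# gamma %*% delta_true + pleiotropy + noise
make_summary_dgp <- function(m = 30, K = 2, delta = c(0.3, -0.2),
                             se_gamma = 0.01, se_alpha = 0.02,
                             outlier_frac = 0, outlier_size = 0.3, seed = 1) {
  set.seed(seed)
  gamma_true <- matrix(runif(m * K, 0.05, 0.15), m, K)
  gamma_se <- matrix(se_gamma, m, K)
  alpha_se <- rep(se_alpha, m)
  pleio <- numeric(m)
  n_out <- round(outlier_frac * m)
  if (n_out > 0) pleio[seq_len(n_out)] <- outlier_size
  gamma_hat <- gamma_true + matrix(rnorm(m * K, 0, se_gamma), m, K)
  alpha_hat <- drop(gamma_true %*% delta) + pleio + rnorm(m, 0, se_alpha)
  summary_associations(gamma_hat, gamma_se, alpha_hat, alpha_se)
}

test_that("conditional SNP-outcome associations vanish without pleiotropy or confounding", {
  cfg <- sim_config(n_individuals = 20000, n_snps_per_exposure = 15,
                    gamma_scale = 0.15, pleiotropy_fraction = 0,
                    confounder_effects = c(0, 0, 0), seed = 1)
  sim <- simulate_two_exposure_cohort(cfg)
  assoc <- collider_conditional_associations(
    sim$genotypes, as.matrix(sim$cohort[c("x1", "x2")]), sim$cohort$y)
  # alpha* should be null SNP by SNP: allow at most one |z| > 4
  z <- abs(assoc$alpha / assoc$alpha_se)
  expect_lte(sum(z > 4), 1)
  expect_error(collider_conditional_associations(
    sim$genotypes, cbind(a = sim$cohort$x1, b = rep(1, 20000)), sim$cohort$y),
    "zero-variance")
})

test_that("collider correction removes pure confounding bias at zero causal effect", {
  cfg <- sim_config(n_individuals = 20000, n_snps_per_exposure = 15,
                    gamma_scale = 0.15, beta_x1 = 0, beta_x2 = 0,
                    pleiotropy_fraction = 0,
                    confounder_effects = c(0.6, 0.6, 0.6), seed = 2)
  sim <- simulate_two_exposure_cohort(cfg)
  cc <- collider_correction_mvmr(sim$genotypes,
                                 as.matrix(sim$cohort[c("x1", "x2")]),
                                 sim$cohort$y, loss = "squared")
  # the observational coefficients are materially biased ...
  expect_true(all(abs(cc$beta_obs / cc$beta_obs_se) > 5))
  # ... and the corrected effects are centred on zero
  expect_true(all(abs(cc$beta) < 4 * cc$se))
  # additivity holds to machine precision
  expect_equal(unname(cc$beta - cc$beta_obs - cc$delta), c(0, 0))
})

test_that("robust losses agree with squared loss in the absence of pleiotropy", {
  assoc <- make_summary_dgp(outlier_frac = 0, seed = 3)
  sq <- robust_summary_mvmr(assoc, loss = "squared")
  hu <- robust_summary_mvmr(assoc, loss = "huber")
  tu <- robust_summary_mvmr(assoc, loss = "tukey")
  for (k in 1:2) {
    expect_lt(abs(hu$delta[k] - sq$delta[k]), sq$se[k])
    expect_lt(abs(tu$delta[k] - sq$delta[k]), sq$se[k])
  }
})

test_that("robust losses resist gross outlier SNPs better than squared loss", {
  delta_true <- c(0.3, -0.2)
  bias_sq <- bias_tu <- matrix(NA_real_, 200, 2)
  for (r in 1:200) {
    assoc <- make_summary_dgp(outlier_frac = 0.1, outlier_size = 0.3,
                              seed = 100 + r)
    bias_sq[r, ] <- robust_summary_mvmr(assoc, loss = "squared")$delta - delta_true
    bias_tu[r, ] <- robust_summary_mvmr(assoc, loss = "tukey")$delta - delta_true
  }
  for (k in 1:2) {
    expect_lt(abs(mean(bias_tu[, k])), abs(mean(bias_sq[, k])))
  }
  # the outliers are the down-weighted SNPs
  assoc <- make_summary_dgp(outlier_frac = 0.1, outlier_size = 0.3, seed = 7)
  tu <- robust_summary_mvmr(assoc, loss = "tukey")
  expect_true(all(tu$weights[1:3] < 0.01))
  expect_true(all(tu$weights >= 0 & tu$weights <= 1))
})

test_that("summary stage requires over-identification", {
  assoc <- make_summary_dgp(m = 2, K = 2, seed = 4)
  expect_error(robust_summary_mvmr(assoc), "more SNPs than exposures")
})

test_that("squared loss reproduces multi-exposure IVW exactly", {
  assoc <- make_summary_dgp(seed = 5)
  sq <- robust_summary_mvmr(assoc, loss = "squared")
  W <- diag(1 / assoc$alpha_se^2)
  ivw <- solve(t(assoc$gamma) %*% W %*% assoc$gamma,
               t(assoc$gamma) %*% W %*% assoc$alpha)
  expect_equal(unname(sq$delta), drop(ivw), tolerance = 1e-10)
})

test_that("huber weights are all 1 for small residuals and the fit matches squared loss", {
  # negligible gamma uncertainty makes the profile variance fixed, so the
  # huber objective with no large residuals is exactly the squared objective;
  # residual noise well below the stated SE keeps every |t| under the tuning
  # constant
  set.seed(6)
  m <- 30
  gamma_true <- matrix(runif(m * 2, 0.05, 0.15), m, 2)
  assoc <- summary_associations(
    gamma = gamma_true, gamma_se = matrix(1e-8, m, 2),
    alpha = drop(gamma_true %*% c(0.3, -0.2)) + rnorm(m, 0, 0.01),
    alpha_se = rep(0.05, m))
  hu <- robust_summary_mvmr(assoc, loss = "huber")
  sq <- robust_summary_mvmr(assoc, loss = "squared")
  expect_true(all(abs(hu$t) < 1.345))
  expect_true(all(hu$weights == 1))
  expect_equal(unname(hu$delta), unname(sq$delta), tolerance = 1e-4)
})

test_that("estimators are equivariant to SNP reordering", {
  assoc <- make_summary_dgp(outlier_frac = 0.1, seed = 8)
  perm <- sample(nrow(assoc$gamma))
  assoc_p <- summary_associations(assoc$gamma[perm, ], assoc$gamma_se[perm, ],
                                  assoc$alpha[perm], assoc$alpha_se[perm])
  a <- robust_summary_mvmr(assoc, loss = "tukey")
  b <- robust_summary_mvmr(assoc_p, loss = "tukey")
  expect_equal(unname(a$delta), unname(b$delta), tolerance = 1e-8)
})

test_that("collider-corrected MVMR matches naive TSLS when no pleiotropy is present", {
  agree <- sapply(1:20, function(r) {
    cfg <- sim_config(n_individuals = 20000, n_snps_per_exposure = 15,
                      gamma_scale = 0.15, pleiotropy_fraction = 0,
                      confounder_effects = c(0, 0, 0), seed = 400 + r)
    sim <- simulate_two_exposure_cohort(cfg)
    X <- as.matrix(sim$cohort[c("x1", "x2")])
    mv <- tsls_mvmr(sim$genotypes, X, sim$cohort$y)
    cc <- collider_correction_mvmr(sim$genotypes, X, sim$cohort$y,
                                   loss = "squared")
    all(abs(cc$beta - mv$beta) / sqrt(cc$se^2 + mv$se^2) < 2)
  })
  expect_gte(mean(agree), 0.9)
})

test_that("adjusted profile score agrees with IVW for strong instruments and beats it for weak ones", {
  set.seed(9)
  m <- 40
  gamma <- runif(m, 0.08, 0.2)
  se_g_strong <- rep(0.005, m); se_a <- rep(0.01, m)
  gh <- gamma + rnorm(m, 0, se_g_strong[1])
  ah <- 0.25 * gamma + rnorm(m, 0, se_a[1])
  raps <- mr_raps_uv(gh, se_g_strong, ah, se_a)
  ivw <- sum(gh * ah / se_a^2) / sum(gh^2 / se_a^2)
  expect_lt(abs(raps$beta - ivw), raps$se)

  # weak regime: mean F ~ 5 -> IVW dilutes toward zero, the profile score
  # does not (dilution-bias simulation, 200 replicates)
  est_ivw <- est_raps <- numeric(200)
  for (r in 1:200) {
    set.seed(1000 + r)
    se_g <- rep(0.045, m)  # (gamma / se)^2 ~ 5-10
    gh <- gamma + rnorm(m, 0, se_g[1])
    ah <- 0.25 * gamma + rnorm(m, 0, se_a[1])
    est_ivw[r] <- sum(gh * ah / se_a^2) / sum(gh^2 / se_a^2)
    est_raps[r] <- mr_raps_uv(gh, se_g, ah, se_a)$beta
  }
  expect_lt(abs(mean(est_raps) - 0.25), abs(mean(est_ivw) - 0.25))
  expect_gt(0.25 - mean(est_ivw), 0.01)  # the dilution being corrected is real

  expect_error(mr_raps_uv(gh[1:2], se_g_strong[1:2], ah[1:2], se_a[1:2]),
               "at least 3")
})
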