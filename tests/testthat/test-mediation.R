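# Difference-method mediation, bootstrap weight laws, mediated-proportion
# identities.

test_that("pi_m implements the difference-method ratio and the sign flag", {
  expect_equal(pi_m(0.2, 0.2)$pi_m, 0)
  expect_true(pi_m(0.2, 0.2)$sign_consistent)
  expect_equal(pi_m(0.2, 0.0)$pi_m, 1)
  expect_true(pi_m(0.2, 0.0)$sign_consistent)
  opp <- pi_m(0.1, 0.15)
  expect_equal(opp$pi_m, -0.5)
  expect_false(opp$sign_consistent)
  expect_error(pi_m(0, 0.1), "total effect is zero")
})

test_that("non-parametric bootstrap weights are normalised multinomial counts", {
  W <- draw_np_bootstrap(50, 100, seed = 1)
  expect_true(all(abs(rowSums(W) - 1) < 1e-12))
  expect_true(all(W >= 0))
  # expected weight per person is 1/n (multinomial moment oracle)
  W2 <- draw_np_bootstrap(20, 1e4, seed = 2)
  se <- sqrt((1 / 20) * (1 - 1 / 20) / 20 / 1e4)  # var of count/n over B draws
  expect_true(all(abs(colMeans(W2) - 1 / 20) < 4 * se + 1e-4))
  expect_identical(draw_np_bootstrap(10, 5, seed = 3),
                   draw_np_bootstrap(10, 5, seed = 3))
  expect_error(draw_np_bootstrap(10, 0), "B must be")
})

test_that("Bayesian bootstrap weights are Dirichlet(1,...,1) draws", {
  W <- draw_bayesian_bootstrap(50, 200, seed = 4)
  expect_true(all(W > 0))
  expect_true(all(abs(rowSums(W) - 1) < 1e-12))

  # variance of the weighted mean of a fixed vector: sum((x - xbar)^2) / (n (n + 1))
  set.seed(5)
  x <- rnorm(40)
  W2 <- draw_bayesian_bootstrap(40, 1e4, seed = 6)
  v_emp <- var(drop(W2 %*% x))
  v_true <- sum((x - mean(x))^2) / (40 * 41)
  expect_lt(abs(v_emp - v_true) / v_true, 0.1)

  # degenerate simplex
  W1 <- draw_bayesian_bootstrap(1, 5, seed = 7)
  expect_true(all(W1 == 1))
})

test_that("uniform weights reproduce the unweighted mediation estimate", {
  sim <- simulate_mediation_cohort(mediation_study_config(seed = 8))
  unw <- estimate_mediation(sim$cohort, sim$genotypes, "x", "m", "y",
                            sim$truth$snps_x, sim$truth$snps_m)
  n <- nrow(sim$cohort)
  wgt <- estimate_mediation(sim$cohort, sim$genotypes, "x", "m", "y",
                            sim$truth$snps_x, sim$truth$snps_m,
                            weights = rep(1 / n, n))
  expect_equal(unw, wgt, tolerance = 1e-10)
  # subtraction identity is exact
  expect_identical(unw[["beta_indirect"]],
                   unw[["beta_total"]] - unw[["beta_direct"]])
})

test_that("mediation recovers the generating total effect and the no-mediation null", {
  ests <- t(sapply(1:30, function(r) {
    sim <- simulate_mediation_cohort(mediation_study_config(
      seed = 100 + r, n_individuals = 4000))
    estimate_mediation(sim$cohort, sim$genotypes, "x", "m", "y",
                       sim$truth$snps_x, sim$truth$snps_m)
  }))
  expect_within(mean(ests[, "beta_total"]), 0.4,
                4 * sd(ests[, "beta_total"]) / sqrt(30))

  # beta_xm = 0: indirect effect centred on zero
  ests0 <- sapply(1:30, function(r) {
    sim <- simulate_mediation_cohort(mediation_study_config(
      seed = 300 + r, n_individuals = 4000, beta_xm = 0))
    estimate_mediation(sim$cohort, sim$genotypes, "x", "m", "y",
                       sim$truth$snps_x, sim$truth$snps_m)[["beta_indirect"]]
  })
  expect_within(mean(ests0), 0, 4 * sd(ests0) / sqrt(30))
})

test_that("bootstrap mediation: per-draw identity, outcome-scale invariance, B guard", {
  sim <- simulate_mediation_cohort(mediation_study_config(seed = 9))
  bm <- bootstrap_mediation(sim$cohort, sim$genotypes, "x", "m", "y",
                            sim$truth$snps_x, sim$truth$snps_m,
                            method = "bb", B = 100, seed = 10)
  expect_identical(bm$draws$beta_indirect,
                   bm$draws$beta_total - bm$draws$beta_direct)
  expect_lte(bm$ci[1], bm$pi_m)
  expect_gte(bm$ci[2], bm$pi_m)

  # pi_m is a ratio: rescaling the continuous outcome changes nothing
  cohort2 <- sim$cohort
  cohort2$y <- 2 * cohort2$y
  bm2 <- bootstrap_mediation(cohort2, sim$genotypes, "x", "m", "y",
                             sim$truth$snps_x, sim$truth$snps_m,
                             method = "bb", B = 100, seed = 10)
  expect_equal(bm2$pi_m, bm$pi_m, tolerance = 1e-12)
  expect_equal(bm2$ci, bm$ci, tolerance = 1e-12)
  expect_equal(bm2$draws$beta_total, 2 * bm$draws$beta_total, tolerance = 1e-10)

  expect_error(bootstrap_mediation(sim$cohort, sim$genotypes, "x", "m", "y",
                                   sim$truth$snps_x, sim$truth$snps_m, B = 0),
               "B must be")
})

test_that("Bayesian and non-parametric intervals converge on a fixed dataset", {
  sim <- simulate_mediation_cohort(mediation_study_config(
    seed = 11, n_individuals = 5000))
  bb <- bootstrap_mediation(sim$cohort, sim$genotypes, "x", "m", "y",
                            sim$truth$snps_x, sim$truth$snps_m,
                            method = "bb", B = 2000, seed = 12)
  np <- bootstrap_mediation(sim$cohort, sim$genotypes, "x", "m", "y",
                            sim$truth$snps_x, sim$truth$snps_m,
                            method = "np", B = 2000, seed = 12)
  width <- bb$ci[2] - bb$ci[1]
  expect_lt(abs(bb$ci[1] - np$ci[1]), 0.1 * width)
  expect_lt(abs(bb$ci[2] - np$ci[2]), 0.1 * width)
})

test_that("three-exposure mediation guards degenerate scores and recovers full mediation", {
  sim <- simulate_mediation_cohort(mediation_study_config(seed = 13))
  expect_error(three_exposure_mediation(
    sim$cohort, sim$genotypes, "x", "m", "m", "y",
    sim$truth$snps_x, sim$truth$snps_m, mediator_score = rep(0, nrow(sim$cohort))),
    "zero variance")

  # X1 acts on Y entirely through the mediator; X2 has a direct effect only
  set.seed(14)
  n <- 20000; m <- 8
  maf <- runif(3 * m, 0.1, 0.4)
  G <- matrix(rbinom(n * 3 * m, 2, rep(maf, each = n)), n, 3 * m,
              dimnames = list(NULL, paste0("g", 1:(3 * m))))
  Gc <- sweep(G, 2, 2 * maf)
  gam <- 0.17 * runif(3 * m, 0.5, 1.5)
  i1 <- 1:m; i2 <- m + 1:m; i3 <- 2 * m + 1:m
  x1 <- drop(Gc[, i1] %*% gam[i1]) + rnorm(n, sd = 0.9)
  x2 <- drop(Gc[, i2] %*% gam[i2]) + rnorm(n, sd = 0.9)
  med <- 0.5 * x1 + drop(Gc[, i3] %*% gam[i3]) + rnorm(n, sd = 0.8)
  y <- 0.6 * med + 0.3 * x2 + rnorm(n)
  cohort <- data.frame(x1 = x1, x2 = x2, med = med, y = y)
  score <- drop(Gc[, i3] %*% gam[i3])
  res <- three_exposure_mediation(cohort, G, "x1", "x2", "med", "y",
                                  paste0("g", i1), paste0("g", i2), score,
                                  method = "bb", B = 200, seed = 15)
  expect_within(res$exposure1$pi_m, 1, 0.2)     # full mediation for X1
  # X2: no mediation, direct ~ total within 2 bootstrap SEs
  sd2 <- sd(res$exposure2$draws$beta_indirect)
  expect_lt(abs(res$exposure2$beta_indirect), 2 * sd2)
})
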