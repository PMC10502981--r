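# Instrument toolkit: clumping, pruning, risk scores, F statistics, Steiger.

make_variants <- function(m, chrom = "1", pos = NULL, p = NULL) {
  data.frame(id = paste0("rs", seq_len(m)), chrom = chrom,
             pos = pos %||% (seq_len(m) * 10000L),
             p = p %||% (10^-runif(m, 4, 12)),
             beta = rnorm(m, 0.05, 0.01), stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("clumping keeps independent variants and enforces LD dominance", {
  set.seed(1)
  v <- make_variants(5)
  ld0 <- matrix(0, 5, 5, dimnames = list(v$id, v$id)); diag(ld0) <- 1
  kept <- clump(v, ld0)
  expect_setequal(kept$id, v$id)

  v2 <- data.frame(id = c("a", "b"), chrom = "1", pos = c(10000L, 20000L),
                   p = c(1e-10, 1e-8), stringsAsFactors = FALSE)
  ld <- matrix(c(1, 1, 1, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  kept2 <- clump(v2, ld)
  expect_identical(kept2$id, "a")
  expect_identical(attr(kept2, "dropped")$id, "b")

  # missing LD entry for an in-window pair is a data error
  expect_error(clump(v2, NULL), "missing LD entry")
})

test_that("clumping matches a brute-force enumeration of the greedy rule", {
  # independent oracle: explicit greedy walk over the sorted variant list
  greedy_oracle <- function(v, ld, window_bp, r2_thr) {
    v <- v[order(v$p, v$chrom, v$pos, v$id), ]
    kept <- character(0); removed <- character(0)
    for (i in seq_len(nrow(v))) {
      id <- v$id[i]
      if (id %in% removed) next
      kept <- c(kept, id)
      for (j in seq_len(nrow(v))) {
        jd <- v$id[j]
        if (jd %in% c(kept, removed)) next
        if (v$chrom[j] == v$chrom[i] && abs(v$pos[j] - v$pos[i]) <= window_bp &&
            ld[id, jd] > r2_thr) removed <- c(removed, jd)
      }
    }
    sort(kept)
  }
  for (seed in 1:5) {
    set.seed(seed)
    m <- 10
    v <- make_variants(m, chrom = sample(c("1", "2"), m, replace = TRUE),
                       pos = sample.int(100000L, m))
    R <- matrix(runif(m * m), m)
    ld <- (R + t(R)) / 2; diag(ld) <- 1
    dimnames(ld) <- list(v$id, v$id)
    got <- clump(v, ld, window_kb = 30, r2_threshold = 0.4)
    expect_identical(sort(got$id), greedy_oracle(v, ld, 30000, 0.4))
  }
})

test_that("pairwise pruning keeps the smaller p (or larger under the literal rule)", {
  set.seed(2)
  g <- make_test_geno(n = 300, m = 3, seed = 2)
  # duplicate column: rs1 and rs2 identical
  g$dosages[, 2] <- g$dosages[, 1]
  inst <- data.frame(id = c("rs1", "rs2", "rs3"), chrom = "1",
                     p = c(1e-9, 1e-6, 1e-4), stringsAsFactors = FALSE)
  pr <- ld_prune_pairwise(inst, g, r2_threshold = 0.05)
  expect_true("rs1" %in% pr$id && !"rs2" %in% pr$id)
  pr_lit <- ld_prune_pairwise(inst, g, r2_threshold = 0.05, literal = TRUE)
  expect_true("rs2" %in% pr_lit$id && !"rs1" %in% pr_lit$id)

  # all r2 below threshold: no-op
  g2 <- make_test_geno(n = 2000, m = 4, seed = 3)
  inst2 <- data.frame(id = paste0("rs", 1:4), chrom = "1",
                      p = c(1e-8, 1e-7, 1e-6, 1e-5), stringsAsFactors = FALSE)
  expect_setequal(ld_prune_pairwise(inst2, g2, r2_threshold = 0.9)$id, inst2$id)

  # monomorphic column is a data error
  g3 <- make_test_geno(n = 100, m = 2, seed = 4)
  g3$dosages[, 2] <- 1
  expect_error(ld_prune_pairwise(
    data.frame(id = c("rs1", "rs2"), chrom = "1", p = c(1e-8, 1e-7)),
    g3), "monomorphic")
})

test_that("pruning a correlation chain retains the ends (iterate until stable)", {
  set.seed(5)
  n <- 500
  a <- rbinom(n, 2, 0.3)
  b <- ifelse(runif(n) < 0.4, a, rbinom(n, 2, 0.3))   # corr ~0.4 with a
  cc <- ifelse(runif(n) < 0.4, b, rbinom(n, 2, 0.3))  # corr ~0.4 with b
  dos <- cbind(A = a, B = b, C = cc)
  info <- data.frame(id = c("A", "B", "C"), chrom = "1", pos = c(1, 2, 3) * 1000L,
                     effect_allele = "A", other_allele = "G",
                     maf = colMeans(dos) / 2, stringsAsFactors = FALSE)
  g <- genotype_matrix(dos, info)
  r2 <- cor(dos)^2
  # chain construction: adjacent pairs in LD, ends nearly independent
  expect_true(r2["A", "B"] > 0.05 && r2["B", "C"] > 0.05 && r2["A", "C"] < 0.05)
  inst <- data.frame(id = c("A", "B", "C"), chrom = "1",
                     p = c(1e-10, 1e-8, 1e-6), stringsAsFactors = FALSE)
  pr <- ld_prune_pairwise(inst, g, r2_threshold = 0.05)
  expect_setequal(pr$id, c("A", "C"))
  # idempotent
  expect_setequal(ld_prune_pairwise(pr, g, r2_threshold = 0.05)$id, pr$id)
})

test_that("genetic risk score is the weighted dosage sum and is linear", {
  g <- make_test_geno(n = 5, m = 3, seed = 6)
  w0 <- setNames(rep(0, 3), paste0("rs", 1:3))
  expect_identical(genetic_risk_score(g, w0), rep(0, 5))
  w1 <- setNames(c(1, 0, 0), paste0("rs", 1:3))
  expect_equal(genetic_risk_score(g, w1), as.numeric(g$dosages[, 1]))

  set.seed(7)
  w <- setNames(rnorm(3), paste0("rs", 1:3))
  # independent elementwise-product-and-sum oracle
  oracle <- sapply(1:5, function(i) sum(g$dosages[i, ] * w[colnames(g$dosages)]))
  expect_equal(genetic_risk_score(g, w), oracle, tolerance = 1e-12)
  # linearity
  w2 <- setNames(rnorm(3), paste0("rs", 1:3))
  expect_equal(genetic_risk_score(g, w + w2),
               genetic_risk_score(g, w) + genetic_risk_score(g, w2),
               tolerance = 1e-12)

  # allele mismatch is a harmonisation error
  inst <- instrument_set(data.frame(id = "rs1", beta = 1, effect_allele = "G"))
  expect_error(genetic_risk_score(g, inst), "harmonise")
})

test_that("mean F is centred at 1 under the null and equals t^2 for one instrument", {
  means <- sapply(1:20, function(r) {
    d <- make_iv_dgp(n = 5000, m = 20, beta = 0, gamma_scale = 0, seed = 100 + r)
    mean_f_statistic(d$G, d$x)$mean_f
  })
  # E[F(1, k)] ~ 1; MC tolerance 4 SEs of the grand mean
  expect_within(mean(means), 1, 4 * sd(means) / sqrt(length(means)))

  d <- make_iv_dgp(n = 500, m = 1, seed = 8)
  t_stat <- summary(lm(d$x ~ d$G))$coefficients[2, "t value"]
  expect_equal(mean_f_statistic(d$G, d$x)$mean_f, t_stat^2, tolerance = 1e-10)
})

test_that("joint F matches the closed-form F-R2 relation", {
  d <- make_iv_dgp(n = 5000, m = 12, seed = 9)
  r2 <- summary(lm(d$x ~ d$G))$r.squared  # independent fit
  n <- 5000; m <- 12
  f_oracle <- (r2 / (1 - r2)) * ((n - m - 1) / m)
  expect_equal(mean_f_statistic(d$G, d$x)$joint_f, f_oracle, tolerance = 1e-8)
})

test_that("conditional F detects conditional weakness and matches marginal F for disjoint sets", {
  set.seed(10)
  n <- 8000; m <- 10
  d1 <- make_iv_dgp(n = n, m = m, seed = 11)
  d2 <- make_iv_dgp(n = n, m = m, seed = 12)
  G <- cbind(d1$G, d2$G); colnames(G) <- paste0("g", 1:(2 * m))
  X <- cbind(x1 = d1$x, x2 = d2$x)
  cf <- conditional_f(G, X)
  f1 <- mean_f_statistic(G, d1$x)$joint_f
  f2 <- mean_f_statistic(G, d2$x)$joint_f
  expect_lt(abs(cf[["x1"]] - f1) / f1, 0.10)
  expect_lt(abs(cf[["x2"]] - f2) / f2, 0.10)

  # both exposures built from the same SNPs with proportional gamma:
  # conditionally unidentified, so conditional F collapses while each
  # marginal joint F stays large
  set.seed(13)
  xa <- drop(d1$Gc %*% d1$gamma) + 0.5 * rnorm(n)
  xb <- drop(d1$Gc %*% (1.5 * d1$gamma)) + 0.5 * rnorm(n)
  cf2 <- conditional_f(d1$G, cbind(a = xa, b = xb))
  expect_gt(mean_f_statistic(d1$G, xa)$joint_f, 20)
  expect_true(all(cf2 < 2))

  expect_error(conditional_f(d1$G, matrix(d1$x, ncol = 1)), "single exposure")
})

test_that("Steiger filter compares variance explained and respects direction", {
  r2t <- c(s1 = 0.01, s2 = 0.001)
  r2c <- c(s1 = 0.001, s2 = 0.01)
  kept <- steiger_filter(c("s1", "s2"), r2t, r2c)
  expect_equal(kept, "s1", ignore_attr = TRUE)
  # rescaling both traits by a common factor changes nothing
  expect_equal(steiger_filter(c("s1", "s2"), 7 * r2t, 7 * r2c), "s1",
               ignore_attr = TRUE)
  expect_length(steiger_filter(character(0), r2t, r2c), 0)
  expect_error(steiger_filter(c("s1", "s3"), r2t, r2c), "missing target")

  # chain G -> X -> Y: r2 with X exceeds r2 with Y (attenuation by beta^2 < 1)
  d <- make_iv_dgp(n = 1e5, m = 10, beta = 0.5, seed = 14)
  r2x <- snp_trait_r2(d$G, d$x)
  r2y <- snp_trait_r2(d$G, d$y)
  ids <- names(r2x) <- names(r2y) <- colnames(d$G)
  keep_x <- steiger_filter(ids, r2x, r2y)
  keep_y <- steiger_filter(ids, r2y, r2x)
  expect_gte(length(keep_x), 9)
  expect_lte(length(keep_y), 1)
})

test_that("summary-mode r2 follows 2f(1-f)beta^2 and refuses missing eaf", {
  expect_equal(summary_r2(0.3, 0.2, trait_var = 2), 2 * 0.3 * 0.7 * 0.04 / 2)
  expect_error(summary_r2(NA_real_, 0.2), "eaf unavailable")
})
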