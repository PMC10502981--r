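# I/O round trips, summary-stat schema, harmonisation, pipeline contract.

test_that("PLINK .raw round trip reproduces dosages exactly", {
  g <- make_test_geno(n = 20, m = 4, seed = 1)
  path <- withr::local_tempfile(fileext = ".raw")
  write_dosage_raw(g, path)
  g2 <- read_dosage_raw(path)
  expect_equal(unname(g2$dosages), unname(g$dosages))
  expect_identical(g2$info$id, g$info$id)
  expect_identical(g2$info$effect_allele, g$info$effect_allele)
  expect_identical(attr(g2, "n_imputed"), 0L)
})

test_that("missing dosage cells are mean-imputed and counted", {
  path <- withr::local_tempfile(fileext = ".raw")
  writeLines(c("FID IID PAT MAT SEX PHENOTYPE rs1_A rs2_G",
               "1 1 0 0 1 -9 2 1",
               "2 2 0 0 1 -9 NA 0",
               "3 3 0 0 2 -9 0 1"), path)
  g <- read_dosage_raw(path)
  expect_identical(attr(g, "n_imputed"), 1L)
  expect_equal(unname(g$dosages[2, "rs1"]), 1)  # mean of 2 and 0

  # non-numeric dosage names the offending line
  path2 <- withr::local_tempfile(fileext = ".raw")
  writeLines(c("FID IID PAT MAT SEX PHENOTYPE rs1_A",
               "1 1 0 0 1 -9 2",
               "2 2 0 0 1 -9 oops"), path2)
  expect_error(read_dosage_raw(path2), "non-numeric dosage.*line 3")
})

test_that("summary-statistic reader enforces its schema", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tCHR\tPOS\tEA\tNEA\tEAF\tBETA\tSE\tP",
               "rs1\t1\t100\tA\tG\t0.2\t0.05\t0.01\t1e-9",
               "rs2\t1\t200\tC\tT\t0.3\t-0.04\t0.02\t1e-8",
               "rs3\t2\t300\tG\tA\t0.4\t0.03\t0.01\t1e-7"), path)
  v <- read_summary_stats(path)
  expect_identical(nrow(v), 3L)
  expect_identical(v$id, c("rs1", "rs2", "rs3"))
  expect_equal(v$beta, c(0.05, -0.04, 0.03))
  expect_equal(v$eaf, c(0.2, 0.3, 0.4))

  # duplicate SNP ids rejected
  path_dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tEA\tNEA\tBETA\tSE\tP",
               "rs1\tA\tG\t0.05\t0.01\t1e-9",
               "rs1\tA\tG\t0.04\t0.01\t1e-8"), path_dup)
  expect_error(read_summary_stats(path_dup), "duplicated SNP")

  # missing required column named in the error
  path_miss <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tEA\tNEA\tBETA\tP", "rs1\tA\tG\t0.05\t1e-9"), path_miss)
  expect_error(read_summary_stats(path_miss), "SE")

  # absent EAF loads as NA, and summary-mode r2 then refuses
  path_noeaf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tEA\tNEA\tBETA\tSE\tP", "rs1\tA\tG\t0.05\t0.01\t1e-9"),
             path_noeaf)
  v2 <- read_summary_stats(path_noeaf)
  expect_true(is.na(v2$eaf))
  expect_error(summary_r2(v2$eaf, v2$beta), "eaf unavailable")
})

test_that("harmonisation flips swapped alleles and drops ambiguous palindromes", {
  g <- make_test_geno(n = 10, m = 3, seed = 2)  # cohort EA is A, other G
  v <- data.frame(id = c("rs1", "rs2", "rs3"),
                  effect_allele = c("A", "G", "A"),
                  other_allele = c("G", "A", "T"),   # rs2 swapped, rs3 palindromic
                  eaf = c(0.3, 0.3, 0.5),
                  beta = c(0.05, 0.04, 0.03), stringsAsFactors = FALSE)
  h <- harmonize_weights(v, g)
  expect_identical(attr(h, "flipped"), "rs2")
  expect_identical(attr(h, "dropped"), "rs3")
  expect_equal(h$beta[h$id == "rs2"], -0.04)  # sign-flip oracle
  expect_equal(h$beta[h$id == "rs1"], 0.05)
  expect_identical(h$effect_allele[h$id == "rs2"], "A")

  v_bad <- data.frame(id = "rs1", effect_allele = "C", other_allele = "T",
                      eaf = 0.3, beta = 0.05, stringsAsFactors = FALSE)
  expect_error(harmonize_weights(v_bad, g), "allele mismatch")
})

test_that("pipeline runs end to end deterministically and honours stage flags", {
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  config <- list(
    seed = 42,
    data = list(simulate = list(design = "two_exposure", n_individuals = 1500,
                                n_snps_per_exposure = 8, gamma_scale = 0.15)),
    exposures = c("x1", "x2"), outcome = "y", outcome_type = "continuous",
    stages = list(mediation = FALSE, moderation = TRUE),
    moderation = list(by = "sex", exposure = "x1")
  )
  config$out_dir <- out1
  m1 <- run_pipeline(config)
  config$out_dir <- out2
  m2 <- run_pipeline(config)
  expect_identical(readLines(file.path(out1, "results.tsv")),
                   readLines(file.path(out2, "results.tsv")))
  expect_true(file.exists(file.path(out1, "manifest.json")))
  expect_identical(m1$stages$mediation$note, "skipped (disabled)")
  # row counts balance per stage
  for (st in m1$stages) expect_identical(st$n_in, st$n_out + st$n_excluded)
  # all main estimators present in the results table
  tab <- read.delim(file.path(out1, "results.tsv"))
  expect_true(all(c("observational", "tsls_uvmr", "tsls_mvmr", "cc_mvmr") %in%
                    tab$method))
})

test_that("pipeline fails fast on a missing column before any computation", {
  out <- withr::local_tempdir()
  config <- list(
    seed = 1, out_dir = out,
    data = list(simulate = list(design = "two_exposure", n_individuals = 300,
                                n_snps_per_exposure = 4)),
    exposures = c("x1", "nope"), outcome = "y", outcome_type = "continuous"
  )
  expect_error(run_pipeline(config), "stage 'schema'.*nope")
  expect_false(file.exists(file.path(out, "results.tsv")))
})

test_that("truth records serialise to YAML", {
  sim <- simulate_two_exposure_cohort(
    sim_config(n_individuals = 50, n_snps_per_exposure = 3, seed = 3))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_truth_yaml(sim$truth, path)
  y <- yaml::read_yaml(path)
  expect_equal(y$beta_x1, 1)
  expect_equal(unlist(y$gamma1), sim$truth$gamma1, tolerance = 1e-6)
})
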