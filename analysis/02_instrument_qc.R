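#!/usr/bin/env Rscript
# Instrument quality control on the two-exposure cohort: pairwise LD
# pruning against the cohort dosages, first-stage strength (mean, joint and
# conditional F), and a Steiger directionality check of the instruments.

library(mrcollide)

dir.create("results", showWarnings = FALSE)
cfg <- cc_study_config(seed = 101)
sim <- simulate_two_exposure_cohort(cfg)
geno <- sim$genotypes
truth <- sim$truth

# mock discovery p-values from the generating gammas (stronger SNP, smaller p)
inst <- data.frame(id = truth$snps_x1, chrom = geno$info$chrom[
                     match(truth$snps_x1, geno$info$id)],
                   p = pmin(1, exp(-2000 * truth$gamma1^2)),
                   stringsAsFactors = FALSE)
pruned <- ld_prune_pairwise(inst, geno, r2_threshold = 0.05)
message(sprintf("LD pruning: %d of %d exposure-1 instruments retained",
                nrow(pruned), nrow(inst)))

f1 <- mean_f_statistic(geno$dosages[, truth$snps_x1], sim$cohort$x1)
f2 <- mean_f_statistic(geno$dosages[, truth$snps_x2], sim$cohort$x2)
cf <- conditional_f(geno, as.matrix(sim$cohort[c("x1", "x2")]))
strength <- data.frame(
  exposure = c("x1", "x2"),
  mean_f = c(f1$mean_f, f2$mean_f),
  joint_f = c(f1$joint_f, f2$joint_f),
  conditional_f = as.numeric(cf)
)
write.table(strength, "results/instrument_strength.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message("Instrument strength (weak-instrument regime by design):")
print(strength)

# Steiger direction check: instruments should explain more of their own
# exposure than of the outcome
r2_x1 <- snp_trait_r2(geno$dosages[, truth$snps_x1], sim$cohort$x1)
r2_y <- snp_trait_r2(geno$dosages[, truth$snps_x1], sim$cohort$y)
names(r2_x1) <- names(r2_y) <- truth$snps_x1
kept <- steiger_filter(truth$snps_x1, r2_x1, r2_y)
message(sprintf("Steiger filter (target = exposure 1): %d / %d SNPs retained",
                length(kept), length(truth$snps_x1)))
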