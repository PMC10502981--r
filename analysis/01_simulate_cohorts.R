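#!/usr/bin/env Rscript
# Generate the two synthetic study cohorts (two-exposure pleiotropy design
# and mediation design), write them to plain-text interchange files, and
# record the generating truth. All downstream drivers re-generate in memory
# from the same seeds; the files written here document the study conditions.

library(mrcollide)

dir.create("results/cohorts", recursive = TRUE, showWarnings = FALSE)

message("Two-exposure design (weak instruments, 20% directional pleiotropy)")
cfg2 <- cc_study_config(seed = 101)
sim2 <- simulate_two_exposure_cohort(cfg2)
write_dosage_raw(sim2$genotypes, "results/cohorts/two_exposure.raw")
write_phenotypes(sim2$cohort, "results/cohorts/two_exposure_phenotypes.csv")
write_truth_yaml(sim2$truth, "results/cohorts/two_exposure_truth.yaml")
message(sprintf("  n = %d individuals, %d SNPs (%d pleiotropic)",
                nrow(sim2$cohort), ncol(sim2$genotypes$dosages),
                length(sim2$truth$pleiotropic_snps)))
message(sprintf("  exposure variances: %.3f / %.3f (unit by construction)",
                var(sim2$cohort$x1), var(sim2$cohort$x2)))

message("Mediation design (true total 0.4, true mediated proportion 0.5)")
cfgm <- mediation_study_config(seed = 102)
simm <- simulate_mediation_cohort(cfgm)
write_dosage_raw(simm$genotypes, "results/cohorts/mediation.raw")
write_phenotypes(simm$cohort, "results/cohorts/mediation_phenotypes.csv")
write_truth_yaml(simm$truth, "results/cohorts/mediation_truth.yaml")
message(sprintf("  n = %d, truth: total = %.2f, pi_m = %.2f",
                nrow(simm$cohort), simm$truth$total_effect,
                simm$truth$pi_m_true))
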