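#!/usr/bin/env Rscript
# Simulate the study cohort and persist it as plain-text fixtures.
#
# The generator plants every structure the downstream analyses look for:
# clock probes carrying the age + acceleration signal, 19 age-DMPs and 50
# acceleration-DMPs, 20 promoter CpGs negatively coupled to expression,
# subtype centroid shifts, four study batches, purity mixing, CNV segments
# with CDKN2A homozygous deletions, and proportional-hazards survival with
# a treatment-by-MGMT interaction.

source("analysis/common.R")

cfg <- study_config()
cohort <- generate_cohort(cfg)
write_fixtures(cohort, COHORT_DIR)

s <- cohort$truth$sample
message(sprintf("cohort: %d probes x %d samples", nrow(cohort$betas),
                ncol(cohort$betas)))
message(sprintf("true acceleration: mean %.2f years, sd %.2f years",
                mean(s$accel), sd(s$accel)))
message(sprintf("subtypes: %s",
                paste(sprintf("%s=%d", names(table(s$subtype)),
                              table(s$subtype)), collapse = ", ")))
message(sprintf("events: %d of %d", sum(s$event), nrow(s)))
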