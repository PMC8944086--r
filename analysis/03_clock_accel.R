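#!/usr/bin/env Rscript
# DNAm age, age acceleration and the cohort baseline table.
#
# DNAm age is predicted from the clock-probe betas with the generating
# clock coefficients (the analog of supplying published multi-tissue clock
# weights); acceleration is DNAm age minus chronological age. The baseline
# table mirrors a per-dataset cohort description: age, DNAm age,
# acceleration, MGMT status, purity and entropy by study.

source("analysis/common.R")

co <- load_cohort()
sheet <- co$sample_sheet
M_adj <- read_matrix_tsv(file.path(RESULTS_DIR, "m_values_adjusted.tsv"),
                         scale = "M")
betas <- m_to_beta(M_adj)

dnam <- predict_dnam_age(betas, co$truth$clock)
accel <- age_acceleration(unname(dnam[sheet$sample_id]), sheet$age)
acc_tab <- data.frame(sample_id = sheet$sample_id, age = sheet$age,
                      dnam_age = unname(dnam[sheet$sample_id]),
                      acceleration = accel)
save_table(acc_tab, "acceleration.tsv")

message(sprintf("acceleration: mean %.2f years, sd %.2f (t-test vs 0: p = %.2g)",
                mean(accel), sd(accel), t.test(accel)$p.value))
for (b in unique(sheet$batch)) {
  i <- sheet$batch == b
  message(sprintf("  %s: r(age, DNAm age) = %.3f  (n = %d)", b,
                  cor(sheet$age[i], acc_tab$dnam_age[i],
                      method = "spearman"), sum(i)))
}

baseline <- do.call(rbind, lapply(split(seq_len(nrow(sheet)), sheet$batch),
  function(i) data.frame(
    dataset = sheet$batch[i[1]], n = length(i),
    age_mean = mean(sheet$age[i]), age_sd = sd(sheet$age[i]),
    dnam_age_mean = mean(acc_tab$dnam_age[i]),
    accel_mean = mean(accel[i]), accel_sd = sd(accel[i])
  )))
save_table(baseline, "baseline.tsv")

# how much of DNAm age do the CNV-affected clock probes explain?
clock_ids <- intersect(names(co$truth$clock$coefficients), rownames(betas))
cnv_chroms <- unique(co$truth$cnv$breakpoints$chrom)
ann <- co$annotation
affected <- clock_ids[ann$chrom[match(clock_ids, ann$probe_id)] %in%
                        cnv_chroms]
if (length(affected) >= 4) {
  pc <- pca_table(t(betas[affected, , drop = FALSE]))
  fit <- summary(lm(acc_tab$dnam_age ~ pc$scores[, 1:4]))
  message(sprintf(
    "CNV-chromosome clock probes: first 4 PCs explain %.1f%% of DNAm age",
    100 * fit$r.squared))
}
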