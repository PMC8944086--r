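#!/usr/bin/env Rscript
# Outcome statistics: HC3 Wald tests of subtype and study effects on the
# sample-level characteristics, the interaction Cox models, and the
# stratified categorical test.

source("analysis/common.R")

co <- load_cohort()
sheet <- co$sample_sheet
acc <- read.table(file.path(RESULTS_DIR, "acceleration.tsv"), header = TRUE,
                  sep = "\t")
et <- read.table(file.path(RESULTS_DIR, "entropy.tsv"), header = TRUE,
                 sep = "\t")
purity <- read.table(file.path(RESULTS_DIR, "purity.tsv"), header = TRUE,
                     sep = "\t")

# Wald tests with HC3 sandwich covariance: subtype, study, interaction
design <- data.frame(class = factor(sheet$subtype),
                     study = factor(sheet$batch))
characteristics <- list(age = sheet$age, dnam_age = acc$dnam_age,
                        accel = acc$acceleration, purity = purity$purity,
                        global_hme = et$global_hme,
                        hme_prom_island = et$Island.promoter)
# model-comparison convention: main terms are tested in the additive model,
# the interaction in the full two-way model
wald <- do.call(rbind, lapply(names(characteristics), function(ch) {
  y <- characteristics[[ch]]
  do.call(rbind, lapply(c("class", "study", "class:study"), function(tm) {
    fml <- if (tm == "class:study") ~ class * study else ~ class + study
    w <- wald_hc3(y, design, tm, formula = fml)
    data.frame(characteristic = ch, term = tm, f_stat = w$f_stat,
               p_value = w$p_value)
  }))
}))
save_table(wald, "wald.tsv")
message("HC3 Wald tests (class term):")
for (ch in names(characteristics)) {
  row <- wald[wald$characteristic == ch & wald$term == "class", ]
  message(sprintf("  %-16s F = %7.3f  p = %.4g", ch, row$f_stat,
                  row$p_value))
}

# Cox models, one per candidate prognostic covariate, each with the
# treatment / MGMT / covariate / treatment x MGMT term structure
cox_rows <- lapply(list(
  acceleration = acc$acceleration,
  global_hme = et$global_hme,
  hme_prom_island = et$Island.promoter
), function(covar) {
  cox_interaction_fit(sheet$survival_time, sheet$event, sheet$treatment,
                      factor(sheet$mgmt, levels = c("U", "M")), covar)
})
names(cox_rows) <- c("acceleration", "global_hme", "hme_prom_island")
cox_tab <- do.call(rbind, Map(function(nm, fit) {
  cbind(model = nm, fit$table)
}, names(cox_rows), cox_rows))
save_table(cox_tab, "cox.tsv")
message("Cox models (covariate term):")
for (nm in names(cox_rows)) {
  t <- cox_rows[[nm]]$table
  i <- t$term == "covariate"
  message(sprintf("  %-16s HR = %.5f  z = %.3f  p = %.4g", nm, t$hr[i],
                  t$z[i], t$p_value[i]))
  j <- grepl(":", t$term)
  message(sprintf("    TRT x MGMT     HR = %.5f  p = %.4g", t$hr[j],
                  t$p_value[j]))
}

# stratified association between MGMT status and treatment arm (expected
# null: both were assigned independently)
tbl <- with(sheet, table(factor(treatment), factor(mgmt), factor(batch)))
ch <- cmh_test(array(tbl, dim = dim(tbl)))
message(sprintf("CMH (MGMT x treatment | study): chi2 = %.3f, p = %.3f",
                ch$statistic, ch$p_value))
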