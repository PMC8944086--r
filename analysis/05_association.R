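#!/usr/bin/env Rscript
# Methylome-wide scans: age DMPs, acceleration DMPs, subtype DMPs, their
# overlap, functional methylation against expression, and gene-set
# enrichment of the acceleration-associated genes.

source("analysis/common.R")

co <- load_cohort()
sheet <- co$sample_sheet
M_adj <- read_matrix_tsv(file.path(RESULTS_DIR, "m_values_adjusted.tsv"),
                         scale = "M")
betas <- m_to_beta(M_adj)
acc <- read.table(file.path(RESULTS_DIR, "acceleration.tsv"), header = TRUE,
                  sep = "\t")

dmp_age <- dmp_scan(M_adj, sheet$age)
dmp_accel <- dmp_scan(M_adj, acc$acceleration)
dmp_class <- dmp_scan(M_adj, factor(sheet$subtype))

a <- dmp_age$probe_id[dmp_age$is_dmp]
b <- dmp_accel$probe_id[dmp_accel$is_dmp]
cl <- dmp_class$probe_id[dmp_class$is_dmp]
message(sprintf("DMPs at q < 0.1: age %d, acceleration %d, subtype %d",
                length(a), length(b), length(cl)))
message(sprintf("overlaps: age&accel %d, accel&class %d, all three %d",
                length(intersect(a, b)), length(intersect(b, cl)),
                length(Reduce(intersect, list(a, b, cl)))))

truth_age <- co$truth$probe$probe_id[co$truth$probe$is_age_dmp]
truth_accel <- co$truth$probe$probe_id[co$truth$probe$is_accel_dmp]
message(sprintf("planted recovery: age %d/%d, accel %d/%d",
                length(intersect(a, truth_age)), length(truth_age),
                length(intersect(b, truth_accel)), length(truth_accel)))

save_table(dmp_age[dmp_age$is_dmp, ], "dmp_age.tsv")
save_table(dmp_accel[dmp_accel$is_dmp, ], "dmp_accel.tsv")
save_table(data.frame(set = c("age", "accel", "class", "age&accel",
                              "age&class", "accel&class", "all"),
                      count = c(length(a), length(b), length(cl),
                                length(intersect(a, b)),
                                length(intersect(a, cl)),
                                length(intersect(b, cl)),
                                length(Reduce(intersect, list(a, b, cl))))),
           "dmp_venn.tsv")

fun <- functional_scan(betas, co$expression, co$annotation)
message(sprintf("functional CpGs (q < 0.05, rho <= -0.3): %d of %d tested",
                sum(fun$is_functional), nrow(fun)))
save_table(fun[fun$is_functional, ], "functional.tsv")

# enrichment of acceleration-DMP genes against a seeded synthetic gene-set
# collection: one set is spiked with the planted acceleration genes, the
# rest are random draws, so the spiked set should dominate
ann <- co$annotation
accel_genes <- unique(ann$gene[match(b, ann$probe_id)])
accel_genes <- accel_genes[!is.na(accel_genes) & nzchar(accel_genes)]
universe <- unique(ann$gene[nzchar(ann$gene)])
set.seed(MASTER_SEED)
sets <- c(list(SPIKED = unique(c(
  accel_genes, sample(universe, 10)
))), setNames(lapply(1:30, function(k) sample(universe, 40)),
              sprintf("RANDOM_%02d", 1:30)))
if (length(accel_genes) > 0) {
  gsea <- hypergeom_gsea(accel_genes, sets, universe)
  message(sprintf("enriched sets at Bonferroni p <= 0.1: %d (top: %s)",
                  sum(gsea$significant), gsea$set[1]))
  save_table(gsea, "gsea.tsv")
}
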