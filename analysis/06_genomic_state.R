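#!/usr/bin/env Rscript
# Sample-level molecular metrics: MGMT-STP27 classification, purity,
# copy-number segmentation of one sample, CDKN2A homozygous-deletion calls,
# G-CIMP clustering and nearest-centroid subtyping.

source("analysis/common.R")

co <- load_cohort()
sheet <- co$sample_sheet
M_adj <- read_matrix_tsv(file.path(RESULTS_DIR, "m_values_adjusted.tsv"),
                         scale = "M")

mgmt <- mgmt_stp27(M_adj, unlist(co$truth$stp27_coefficients))
agree <- mean((mgmt$status == "M") == (sheet$mgmt == "M"))
message(sprintf("MGMT-STP27 at cutoff 0.358: %d M / %d U (%.0f%% vs truth)",
                sum(mgmt$status == "M"), sum(mgmt$status == "U"),
                100 * agree))
save_table(mgmt, "mgmt.tsv")

purity <- estimate_purity(co$betas, co$truth$tumor_reference,
                          co$truth$normal_profile)
message(sprintf("purity: mean %.2f, r vs truth %.3f", mean(purity),
                cor(purity, co$truth$sample$purity)))
save_table(data.frame(sample_id = names(purity), purity = unname(purity)),
           "purity.tsv")

lr <- copy_number_logratio(co$intensities$meth, co$intensities$unmeth,
                           co$intensities$reference_total)

ck <- which(co$annotation$gene == "CDKN2A")
hd <- cdkn2a_hd_call(colMeans(lr[ck, , drop = FALSE]))
truth_hd <- hd$sample_id %in% unlist(co$truth$cnv$hd_samples)
message(sprintf("CDKN2A HD: %d called (%.0f%% agreement with planted set)",
                sum(hd$hd), 100 * mean(hd$hd == truth_hd)))
save_table(hd, "cdkn2a_hd.tsv")

# segment the first HD sample; planted breakpoints sit on chr7 and chr10
s1 <- hd$sample_id[hd$hd][1]
ord <- order(match(co$annotation$chrom, paste0("chr", 1:22)),
             co$annotation$pos)
segs <- cbs_segment(lr[ord, s1], chrom = co$annotation$chrom[ord],
                    pos = co$annotation$pos[ord], n_perm = 200,
                    seed = MASTER_SEED)
message(sprintf("CBS on %s: %d segments over 22 chromosomes", s1,
                nrow(segs)))
aberrant <- segs[abs(segs$seg_mean) > 0.3, ]
message(sprintf("  aberrant segments (|log2| > 0.3): %s",
                paste(unique(aberrant$chrom), collapse = ", ")))
save_table(segs, "segments.tsv")
write_segments_bed(segs, file.path(RESULTS_DIR, "segments.bed"))

gc <- gcimp_cluster(M_adj)
message(sprintf("G-CIMP clustering: %d / %d samples in the high-methylation cluster",
                sum(gc$gcimp), nrow(gc)))

lab <- nearest_centroid_subtype(co$betas, co$truth$centroids)
message(sprintf("nearest-centroid subtype accuracy vs truth: %.0f%%",
                100 * mean(lab == sheet$subtype)))
save_table(data.frame(sample_id = names(lab), subtype = unname(lab)),
           "subtype_calls.tsv")
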