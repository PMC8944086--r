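#' Methylation Shannon entropy (HME)
#'
#' Marker-level normalized methylation entropy. Each CpG marker has two
#' states, methylated with probability `p` (the beta value) and unmethylated
#' with `1 - p`, so the per-marker entropy is bounded by log(2). The HME of
#' N markers is the summed two-state entropy normalized by `N * log(1/2)`,
#' giving a value in \[0, 1\]: 0 when every marker is fully methylated or
#' fully unmethylated, 1 when every marker sits at 0.5.
#'
#' @name entropy
NULL

#' Normalized methylation entropy of a beta profile
#'
#' `HME = sum_i [p_u log(p_u) + p_m log(p_m)] / (N log(1/2))` with
#' `p_m = p_i`, `p_u = 1 - p_i`, natural logs, and the convention
#' `0 * log(0) = 0` (so betas exactly 0 or 1 contribute zero entropy, with
#' no clipping).
#'
#' @param betas numeric vector of methylated fractions in \[0, 1\].
#' @return normalized entropy in \[0, 1\].
#' @export
hme <- function(betas) {
  if (length(betas) == 0) stop("empty beta vector")
  stopifnot_probability(betas, "betas")
  xlogx <- function(p) ifelse(p == 0, 0, p * log(p))
  # `+ 0` normalizes the signed zero arising from a zero numerator over the
  # negative normalizer
  sum(xlogx(1 - betas) + xlogx(betas)) / (length(betas) * log(0.5)) + 0
}

#' Per-stratum methylation entropy table
#'
#' HME per sample within each of the 12 genomic strata formed by the six
#' island-relation categories crossed with promoter status, plus the global
#' HME over all probes. Empty strata are reported as `NA`, not zero.
#'
#' @param m beta matrix (probes x samples).
#' @param ann probe annotation covering the matrix probes (columns
#'   `probe_id`, `island_relation`, `is_promoter`).
#' @return data.frame, one row per sample: `sample_id`, `global_hme`, one
#'   column per stratum (`<relation>.promoter` / `<relation>.nonpromoter`);
#'   attribute `"stratum_n"` holds probe counts per stratum.
#' @export
hme_by_stratum <- function(m, ann) {
  probes <- rownames(m)
  missing <- setdiff(probes, ann$probe_id)
  if (length(missing) > 0) {
    stop("probes missing annotation: ", paste(utils::head(missing, 5),
                                              collapse = ", "))
  }
  ann <- ann[match(probes, ann$probe_id), , drop = FALSE]
  strata <- paste0(ann$island_relation,
                   ifelse(ann$is_promoter, ".promoter", ".nonpromoter"))
  levels <- as.vector(outer(ISLAND_RELATIONS,
                            c(".promoter", ".nonpromoter"), paste0))
  out <- data.frame(sample_id = colnames(m),
                    global_hme = apply(m, 2, hme),
                    stringsAsFactors = FALSE, row.names = NULL)
  counts <- integer(length(levels))
  names(counts) <- levels
  for (s in levels) {
    idx <- strata == s
    counts[[s]] <- sum(idx)
    out[[s]] <- if (any(idx)) apply(m[idx, , drop = FALSE], 2, hme) else NA_real_
  }
  attr(out, "stratum_n") <- counts
  out
}

#' Read-level methylation haplotype entropy
#'
#' Per-CpG-normalized base-2 Shannon entropy of methylation haplotype
#' (read-pattern) frequencies over a window of `n_cpgs` CpGs:
#' `H = -(1/n_cpgs) * sum_k f_k log2(f_k)` with `0 * log(0) = 0`. A locus
#' covered 50/50 by fully methylated and fully unmethylated 4-CpG alleles
#' gives exactly 0.25; a single pattern gives 0; the uniform distribution
#' over all `2^n_cpgs` patterns gives 1. Included as a reference oracle for
#' the read-level formulation of methylation disorder.
#'
#' @param pattern_frequencies numeric vector of haplotype frequencies,
#'   summing to 1 (tolerance 1e-9).
#' @param n_cpgs number of CpGs in the window (>= 1).
#' @return normalized entropy in \[0, 1\].
#' @export
read_haplotype_entropy <- function(pattern_frequencies, n_cpgs) {
  if (n_cpgs < 1) stop("n_cpgs must be >= 1")
  stopifnot_probability(pattern_frequencies, "pattern_frequencies")
  if (abs(sum(pattern_frequencies) - 1) > 1e-9) {
    stop("pattern frequencies must sum to 1")
  }
  f <- pattern_frequencies[pattern_frequencies > 0]
  -sum(f * log2(f)) / n_cpgs
}
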