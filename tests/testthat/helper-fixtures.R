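# Small cohorts and hand-built fixtures shared across test files.

# A quiet, fully deterministic small cohort: no noise, single batch, full
# purity, no subtype acceleration shifts. The clock identity holds exactly.
quiet_config <- function(n_samples = 40, n_probes = 1200,
                         n_clock_probes = 50, seed = 101, ...) {
  cohort_config(
    n_samples = n_samples, n_probes = n_probes,
    n_clock_probes = n_clock_probes,
    noise_sd = 0, batch_labels = "one", batch_sd = 0,
    purity_range = c(1, 1),
    acceleration_model = list(mean = 36.81, sd = 0,
                              subtype_shift = c(MES = 0, RTK_I = 0,
                                                RTK_II = 0)),
    seed = seed, ...
  )
}

# Default-condition cohort at reduced size (shared across files to avoid
# regenerating).
default_small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_cohort(cohort_config(
        n_samples = 80, n_probes = 1500, n_clock_probes = 50,
        batch_labels = c("A", "B"), seed = 42
      ))
    }
    cache
  }
})

# Minimal hand-built annotation for unit fixtures.
tiny_annotation <- function(probe_ids, chrom = "chr1",
                            island = "OpenSea", promoter = FALSE,
                            snp = FALSE, sex = FALSE, gene = "") {
  n <- length(probe_ids)
  data.frame(
    probe_id = probe_ids,
    chrom = rep_len(chrom, n), pos = seq_len(n) * 1000L,
    island_relation = rep_len(island, n),
    gene = rep_len(gene, n),
    tss_distance = ifelse(rep_len(promoter, n), 500L, 5000L),
    is_promoter = rep_len(promoter, n),
    is_snp_probe = rep_len(snp, n),
    is_sex_chromosome = rep_len(sex, n),
    stringsAsFactors = FALSE
  )
}

meth_matrix_m <- function(x) {
  attr(x, "scale") <- "M"
  x
}

tiny_beta_matrix <- function(n_probes = 6, n_samples = 4, seed = 1,
                             ids = sprintf("cg%03d", seq_len(n_probes))) {
  set.seed(seed)
  m <- matrix(runif(n_probes * n_samples, 0.1, 0.9), nrow = n_probes,
              dimnames = list(ids, sprintf("S%02d", seq_len(n_samples))))
  meth_matrix(m, "beta")
}
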