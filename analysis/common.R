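# Shared paths and study configuration for the analysis drivers.
# Source this at the top of each numbered script.

library(methage)

RESULTS_DIR <- "results"
COHORT_DIR <- file.path(RESULTS_DIR, "cohort")
MASTER_SEED <- 1234

# Study conditions: an adult IDHwt GBM trial population profiled on a
# 450k-style array, scaled to 10,000 probes / 200 patients so the full
# workflow runs on a desktop.
study_config <- function(seed = MASTER_SEED) {
  cohort_config(n_samples = 200, n_probes = 10000, n_clock_probes = 353,
                seed = seed)
}

load_cohort <- function() {
  if (!dir.exists(COHORT_DIR)) {
    stop("run analysis/01_simulate.R first: ", COHORT_DIR, " not found")
  }
  read_fixtures(COHORT_DIR)
}

save_table <- function(df, name) {
  path <- file.path(RESULTS_DIR, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
  invisible(path)
}
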