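#' End-to-end analysis pipeline
#'
#' Orchestrates the full analysis from a single configuration: generate (or
#' load) a cohort, filter probes, convert to M-values, aggregate batches,
#' predict DNAm age and acceleration, compute the stratified entropy table,
#' run the DMP / functional / enrichment scans, derive the sample-level
#' molecular metrics (MGMT, purity, CNV, subtype), and fit the multivariate
#' and outcome models. Every stochastic stage derives its seed from the
#' single master seed, so re-running with the same configuration reproduces
#' all numbers.
#'
#' @name pipeline_cli
NULL

#' Pipeline configuration
#'
#' @param cohort a `meth_cohort` (from [generate_cohort()] or
#'   [read_fixtures()]); if `NULL`, one is generated from `generator`.
#' @param generator a [cohort_config()] used when `cohort` is `NULL`.
#' @param detection_p_thresh probe detection p-value threshold.
#' @param dmp_q DMP threshold on the Bonferroni-adjusted q-value.
#' @param functional_q,functional_rho functional-methylation criteria.
#' @param mgmt_cutoff MGMT-STP27 probability cutoff.
#' @param gsea_p Bonferroni threshold for gene-set enrichment.
#' @param n_perm permutations for ADONIS.
#' @param run_cnv run copy-number segmentation (the slowest stage).
#' @param out_dir directory for report tables, or `NULL` to skip writing.
#' @param seed master seed for all stochastic stages.
#' @return validated `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = NULL, generator = cohort_config(),
                            detection_p_thresh = 0.01, dmp_q = 0.1,
                            functional_q = 0.05, functional_rho = -0.3,
                            mgmt_cutoff = 0.358, gsea_p = 0.1,
                            n_perm = 99, run_cnv = FALSE, out_dir = NULL,
                            seed = 1) {
  stopifnot(detection_p_thresh > 0, detection_p_thresh <= 1,
            dmp_q > 0, dmp_q <= 1, functional_q > 0, functional_q <= 1,
            functional_rho < 0, mgmt_cutoff > 0, mgmt_cutoff < 1,
            gsea_p > 0, gsea_p <= 1, n_perm >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of the YAML file override the [pipeline_config()] defaults;
#' a `generator:` block overrides [cohort_config()] fields.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen_args <- y$generator %||% list()
  y$generator <- NULL
  gen <- do.call(cohort_config, gen_args)
  do.call(pipeline_config, c(list(generator = gen), y))
}

pipeline_stage <- function(log, name, fn) {
  res <- tryCatch(fn(), error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
  log[[length(log) + 1L]] <- list(stage = name, done = TRUE)
  list(log = log, value = res)
}

#' Run the full pipeline
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_report`: `baseline` (per-dataset summary
#'   of age, DNAm age, acceleration, subtype, MGMT, purity, entropy),
#'   `acceleration` (per-sample DNAm age / acceleration), `dmp_age`,
#'   `dmp_accel`, `dmp_counts` + `venn` (scan overlap), `functional`,
#'   `gsea`, `entropy`, `mgmt`, `purity`, `segments` (if `run_cnv`),
#'   `cdkn2a`, `subtype_calls`, `wald` (per-characteristic HC3 F tests),
#'   `cox` (interaction outcome models), `varpart`, `adonis`, `log`,
#'   `thresholds`,
#'   `seed`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  seed <- config$seed

  st <- pipeline_stage(log, "cohort", function() {
    config$cohort %||% generate_cohort(config$generator)
  })
  log <- st$log; cohort <- st$value
  truth <- cohort$truth
  sheet <- cohort$sample_sheet

  st <- pipeline_stage(log, "preprocess", function() {
    betas <- filter_probes(cohort$betas, cohort$annotation,
                           detection_p = cohort$detection_p,
                           p_thresh = config$detection_p_thresh)
    M <- beta_to_m(betas)
    if (length(unique(sheet$batch)) > 1) {
      M <- combat_adjust(M, sheet$batch,
                         covariates = data.frame(age = sheet$age))
      betas <- m_to_beta(M)
      attr(betas, "scale") <- "beta"
    }
    list(betas = betas, M = M)
  })
  log <- st$log; prep <- st$value

  st <- pipeline_stage(log, "clock", function() {
    dnam <- predict_dnam_age(prep$betas, truth$clock)
    data.frame(sample_id = sheet$sample_id, age = sheet$age,
               dnam_age = unname(dnam[sheet$sample_id]),
               acceleration = age_acceleration(unname(dnam[sheet$sample_id]),
                                               sheet$age),
               stringsAsFactors = FALSE)
  })
  log <- st$log; accel_tab <- st$value

  st <- pipeline_stage(log, "entropy", function() {
    hme_by_stratum(prep$betas, cohort$annotation)
  })
  log <- st$log; entropy_tab <- st$value

  st <- pipeline_stage(log, "association", function() {
    dmp_age <- dmp_scan(prep$M, sheet$age, q_thresh = config$dmp_q)
    dmp_accel <- dmp_scan(prep$M, accel_tab$acceleration,
                          q_thresh = config$dmp_q)
    dmp_class <- dmp_scan(prep$M, factor(sheet$subtype),
                          q_thresh = config$dmp_q)
    fun <- functional_scan(prep$betas, cohort$expression, cohort$annotation,
                           q_thresh = config$functional_q,
                           rho_thresh = config$functional_rho)
    sets_age <- unique(cohort$annotation$gene[
      match(dmp_age$probe_id[dmp_age$is_dmp], cohort$annotation$probe_id)])
    sets_age <- sets_age[nzchar(sets_age)]
    universe <- unique(cohort$annotation$gene[nzchar(cohort$annotation$gene)])
    gene_sets <- synthetic_gene_sets(universe, seed = seed)
    gsea <- if (length(sets_age) > 0) {
      hypergeom_gsea(sets_age, gene_sets, universe, p_thresh = config$gsea_p)
    } else NULL
    a <- dmp_age$probe_id[dmp_age$is_dmp]
    b <- dmp_accel$probe_id[dmp_accel$is_dmp]
    cl <- dmp_class$probe_id[dmp_class$is_dmp]
    venn <- c(age = length(a), accel = length(b), class = length(cl),
              `age&accel` = length(intersect(a, b)),
              `age&class` = length(intersect(a, cl)),
              `accel&class` = length(intersect(b, cl)),
              `age&accel&class` = length(Reduce(intersect, list(a, b, cl))))
    list(dmp_age = dmp_age, dmp_accel = dmp_accel, dmp_class = dmp_class,
         functional = fun, gsea = gsea, venn = venn)
  })
  log <- st$log; assoc <- st$value

  st <- pipeline_stage(log, "genomic_state", function() {
    mgmt <- mgmt_stp27(prep$M, truth$stp27_coefficients,
                       cutoff = config$mgmt_cutoff)
    purity <- estimate_purity(cohort$betas, truth$tumor_reference,
                              truth$normal_profile)
    lr <- copy_number_logratio(cohort$intensities$meth,
                               cohort$intensities$unmeth,
                               cohort$intensities$reference_total)
    ck <- cohort$annotation$gene == "CDKN2A"
    cdkn2a <- if (sum(ck) > 0 && ncol(lr) >= 20) {
      cdkn2a_hd_call(colMeans(lr[ck, , drop = FALSE]))
    } else NULL
    segs <- NULL
    if (config$run_cnv) {
      s1 <- colnames(lr)[1]
      ord <- order(match(cohort$annotation$chrom,
                         paste0("chr", 1:22)), cohort$annotation$pos)
      segs <- cbs_segment(lr[ord, s1], chrom = cohort$annotation$chrom[ord],
                          pos = cohort$annotation$pos[ord],
                          n_perm = 200, seed = seed)
    }
    subtype_calls <- nearest_centroid_subtype(cohort$betas, truth$centroids)
    gcimp <- gcimp_cluster(prep$M)
    list(mgmt = mgmt, purity = purity, cdkn2a = cdkn2a, segments = segs,
         subtype_calls = subtype_calls, gcimp = gcimp)
  })
  log <- st$log; gstate <- st$value

  st <- pipeline_stage(log, "stats_outcome", function() {
    strata_cols <- setdiff(names(entropy_tab), c("sample_id", "global_hme"))
    Y <- as.matrix(entropy_tab[, strata_cols, drop = FALSE])
    Y <- Y[, colSums(is.na(Y)) == 0, drop = FALSE]
    vp <- variation_partition(Y, sheet$age, accel_tab$acceleration,
                              factor(sheet$subtype),
                              labels = c("age", "accel", "class"))
    ad <- adonis_euclidean(t(prep$M), sheet$subtype,
                           n_perm = config$n_perm, seed = seed)
    design <- data.frame(class = factor(sheet$subtype),
                         study = factor(sheet$batch))
    wald_rows <- lapply(
      list(age = sheet$age, dnam_age = accel_tab$dnam_age,
           accel = accel_tab$acceleration, purity = gstate$purity,
           global_hme = entropy_tab$global_hme),
      function(y) {
        # main terms in the additive model, interaction in the full model
        out <- lapply(c("class", "study", "class:study"), function(tm) {
          fml <- if (tm == "class:study") ~ class * study else
            ~ class + study
          w <- wald_hc3(y, design, tm, formula = fml)
          data.frame(term = tm, f_stat = w$f_stat, p_value = w$p_value)
        })
        do.call(rbind, out)
      })
    wald <- do.call(rbind, Map(cbind, characteristic = names(wald_rows),
                               wald_rows))
    cox <- cox_interaction_fit(sheet$survival_time, sheet$event,
                               sheet$treatment,
                               factor(sheet$mgmt, levels = c("U", "M")),
                               accel_tab$acceleration,
                               covariate_name = "acceleration")
    list(varpart = vp, adonis = ad, wald = wald, cox = cox)
  })
  log <- st$log; outc <- st$value

  baseline <- do.call(rbind, lapply(split(seq_len(nrow(sheet)),
                                          sheet$batch), function(i) {
    data.frame(
      dataset = sheet$batch[i[1]], n = length(i),
      age_mean = mean(sheet$age[i]), age_sd = stats::sd(sheet$age[i]),
      dnam_age_mean = mean(accel_tab$dnam_age[i]),
      accel_mean = mean(accel_tab$acceleration[i]),
      accel_sd = stats::sd(accel_tab$acceleration[i]),
      mgmt_m = sum(gstate$mgmt$status[i] == "M"),
      purity_mean = mean(gstate$purity[i]),
      global_hme_mean = mean(entropy_tab$global_hme[i]),
      stringsAsFactors = FALSE
    )
  }))

  report <- structure(list(
    baseline = baseline, acceleration = accel_tab,
    dmp_age = assoc$dmp_age, dmp_accel = assoc$dmp_accel,
    dmp_class = assoc$dmp_class,
    dmp_counts = assoc$venn[c("age", "accel", "class")],
    venn = assoc$venn, functional = assoc$functional, gsea = assoc$gsea,
    entropy = entropy_tab, mgmt = gstate$mgmt, purity = gstate$purity,
    cdkn2a = gstate$cdkn2a, segments = gstate$segments,
    subtype_calls = gstate$subtype_calls, gcimp = gstate$gcimp,
    wald = outc$wald, cox = outc$cox, varpart = outc$varpart,
    adonis = outc$adonis, filter_report = attr(prep$betas, "filter_report"),
    log = log,
    thresholds = config[c("detection_p_thresh", "dmp_q", "functional_q",
                          "functional_rho", "mgmt_cutoff", "gsea_p")],
    seed = seed
  ), class = "pipeline_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

# Seeded synthetic gene-set collection over a universe: random sets plus one
# set concentrated on the query-prone genes cannot be known here, so sets are
# purely random; enrichment against them is a null reference.
synthetic_gene_sets <- function(universe, n_sets = 50, seed = 1) {
  with_block_seed(seed, "misc", function() {
    sets <- lapply(seq_len(n_sets), function(k) {
      sample(universe, min(length(universe),
                           max(5, stats::rpois(1, 30))))
    })
    stats::setNames(sets, sprintf("SET_%03d", seq_len(n_sets)))
  })
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report\n")
  cat(sprintf("  DMP counts: age %d, accel %d, class %d\n",
              x$dmp_counts[["age"]], x$dmp_counts[["accel"]],
              x$dmp_counts[["class"]]))
  cat(sprintf("  mean acceleration: %.2f years\n",
              mean(x$acceleration$acceleration)))
  cat(sprintf("  varpart joint R2: %.3f\n", x$varpart$joint_r2))
  invisible(x)
}

#' Write the report tables under a directory
#'
#' One TSV per table plus a JSON run log holding the seed, thresholds and
#' stage log.
#'
#' @param report a `pipeline_report`.
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) {
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(report$baseline, "baseline.tsv")
  wt(report$acceleration, "acceleration.tsv")
  wt(report$dmp_age[report$dmp_age$is_dmp, ], "dmp_age.tsv")
  wt(report$dmp_accel[report$dmp_accel$is_dmp, ], "dmp_accel.tsv")
  wt(report$functional, "functional.tsv")
  wt(report$entropy, "entropy.tsv")
  wt(report$mgmt, "mgmt.tsv")
  wt(report$wald, "wald.tsv")
  wt(report$cox$table, "cox.tsv")
  wt(report$varpart$fractions, "varpart.tsv")
  if (!is.null(report$segments)) wt(report$segments, "segments.tsv")
  jsonlite::write_json(
    list(seed = report$seed, thresholds = report$thresholds,
         venn = as.list(report$venn),
         adonis = report$adonis[c("r_squared", "p_value")],
         filter_report = as.list(report$filter_report),
         stages = report$log),
    file.path(dir, "run_log.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
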