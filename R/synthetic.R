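#' Synthetic 450k-style cohort generator
#'
#' Seeded generator of a methylation cohort with the statistical structure
#' the downstream analysis assumes: probe-class beta baselines (bimodal in
#' promoter CpG islands, intermediate in open sea), an age signal on clock
#' probes plus a tumor "acceleration" term, three methylation subtypes with
#' centroid shifts, planted age- and acceleration-DMPs, promoter CpGs
#' negatively coupled to expression, batch shifts, purity mixing with a
#' fixed synthetic normal-brain profile, planted CNV segments (including
#' CDKN2A homozygous deletions) in the signal intensities, the two MGMT
#' promoter probes driven by a known logistic model, and proportional-
#' hazards survival with an MGMT-by-treatment interaction. A ground-truth
#' record accompanies every cohort so each downstream stage can be tested
#' against what was planted. Each logical block (annotation, subjects,
#' clock, DMPs, expression, noise, CNV, survival, ...) draws from its own
#' seeded stream, so enlarging one block does not perturb another.
#'
#' @name synthetic_data
NULL

#' Cohort generator configuration
#'
#' Defaults describe the cohort the analysis targets: an adult IDH-wild-type
#' glioblastoma trial population (ages 27-85), acceleration averaging 36.81
#' years (sd 23.99) with subtype-dependent shifts (highest in RTK II),
#' subtype mix ~31/20/49% MES/RTK I/RTK II, four study batches, a
#' treatment-by-MGMT interaction of log-HR -1.3 and a protective
#' acceleration effect of log-HR -0.0147 per year.
#'
#' @param n_samples,n_probes,n_clock_probes cohort dimensions.
#' @param subtype_proportions named simplex over MES, RTK_I, RTK_II.
#' @param age_range years, `c(min, max)`.
#' @param acceleration_model list: `mean`, `sd` (years) and named
#'   `subtype_shift` (years added per subtype).
#' @param n_dmp_age,n_dmp_accel,n_functional planted probe counts.
#' @param slope_age,slope_accel planted DMP slopes (beta units per year).
#' @param expression_coupling target Spearman correlation (negative) of
#'   functional probes with their gene's expression.
#' @param batch_labels character vector of batch names (one batch disables
#'   batch effects).
#' @param batch_sd per-probe per-batch location shift sd, logit scale.
#' @param noise_sd beta-scale noise sd (applied on the logit scale via the
#'   delta method so values stay inside (0, 1) without truncation).
#' @param survival_params list: `baseline_rate`, `censoring_rate` (1/years),
#'   `log_hr_treatment`, `log_hr_mgmt`, `log_hr_interaction`,
#'   `log_hr_accel_per_year`.
#' @param cnv_params list: `cdkn2a_hd_fraction`, `hd_log2ratio`,
#'   `intensity_noise_sd` and `segment_spec` (list of
#'   `list(chrom, start, end, log2ratio, fraction)`).
#' @param purity_range tumor-purity interval within \[0, 1\].
#' @param n_subtype_probes probes carrying subtype centroid shifts.
#' @param seed master integer seed.
#' @return validated `cohort_config` list.
#' @export
cohort_config <- function(
    n_samples = 200,
    n_probes = 10000,
    n_clock_probes = 353,
    subtype_proportions = c(MES = 0.31, RTK_I = 0.20, RTK_II = 0.49),
    age_range = c(27, 85),
    acceleration_model = list(
      mean = 36.81, sd = 23.99,
      subtype_shift = c(MES = -7.7, RTK_I = -3.4, RTK_II = 6.5)
    ),
    n_dmp_age = 19,
    n_dmp_accel = 50,
    n_functional = 20,
    slope_age = 0.002,
    slope_accel = 0.004,
    expression_coupling = -0.5,
    batch_labels = c("study1", "study2", "study3", "study4"),
    batch_sd = 0.1,
    noise_sd = 0.03,
    survival_params = list(
      baseline_rate = 0.55, censoring_rate = 0.15,
      log_hr_treatment = -0.3, log_hr_mgmt = -0.2,
      log_hr_interaction = -1.3, log_hr_accel_per_year = -0.0147
    ),
    cnv_params = list(
      cdkn2a_hd_fraction = 0.4, hd_log2ratio = -3.32,
      intensity_noise_sd = 0.1,
      segment_spec = list(
        list(chrom = "chr7", start = 2e7, end = 6e7, log2ratio = 0.58,
             fraction = 0.6),
        list(chrom = "chr10", start = 1e6, end = 9e7, log2ratio = -1,
             fraction = 0.7)
      )
    ),
    purity_range = c(0.45, 0.99),
    n_subtype_probes = max(50, round(0.05 * n_probes)),
    seed = 1) {
  cfg <- as.list(environment())
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    if (n_samples < 0 || n_probes <= 0 || n_clock_probes <= 0) {
      stop("counts must be positive (n_samples may be 0)")
    }
    if (abs(sum(subtype_proportions) - 1) > 1e-8 ||
        any(subtype_proportions < 0)) {
      stop("subtype_proportions must be a simplex over the subtypes")
    }
    if (n_clock_probes > n_probes) stop("n_clock_probes exceeds n_probes")
    if (length(age_range) != 2 || diff(age_range) <= 0 || age_range[1] <= 0) {
      stop("age_range must be an increasing positive interval")
    }
    if (survival_params$baseline_rate <= 0 ||
        survival_params$censoring_rate <= 0) {
      stop("survival rates must be positive")
    }
    if (any(purity_range < 0) || any(purity_range > 1) ||
        purity_range[1] > purity_range[2]) {
      stop("purity_range must be an interval within [0, 1]")
    }
    if (noise_sd < 0 || batch_sd < 0) stop("noise sds must be >= 0")
  })
  invisible(cfg)
}

MGMT_PROBES <- c("cg12434587", "cg12981137")
N_CDKN2A_PROBES <- 10L

#' Simulate proportional-hazards survival for given covariates
#'
#' Event times are exponential with rate
#' `baseline_rate * exp(lp)` where
#' `lp = b_trt*trt + b_mgmt*mgmt + b_int*trt*mgmt + b_accel*(accel - mean(accel))`;
#' censoring times are exponential with `censoring_rate`; observed time is
#' the minimum (reported in months).
#'
#' @param treatment,mgmt 0/1 vectors.
#' @param accel acceleration in years.
#' @param params `survival_params` list (see [cohort_config()]).
#' @param seed integer seed.
#' @return data.frame: `time` (months), `event` (0/1), `log_hazard`.
#' @export
simulate_survival <- function(treatment, mgmt, accel, params, seed = 1) {
  n <- length(treatment)
  with_block_seed(seed, "survival", function() {
    lp <- params$log_hr_treatment * treatment +
      params$log_hr_mgmt * mgmt +
      params$log_hr_interaction * treatment * mgmt +
      params$log_hr_accel_per_year * (accel - mean(accel))
    t_event <- stats::rexp(n, rate = params$baseline_rate * exp(lp))
    t_cens <- stats::rexp(n, rate = params$censoring_rate)
    data.frame(time = pmin(t_event, t_cens) * 12,
               event = as.integer(t_event <= t_cens),
               log_hazard = lp)
  })
}

#' Generate a synthetic cohort with ground truth
#'
#' @param config a [cohort_config()].
#' @return list of class `meth_cohort`: `betas` (probes x samples, beta
#'   scale), `annotation`, `sample_sheet`, `expression` (genes x samples),
#'   `intensities` (list `meth`, `unmeth`, `reference_total`),
#'   `detection_p`, `truth` (ground-truth record), `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  seed <- config$seed
  n <- config$n_samples
  p <- config$n_probes
  subtypes <- names(config$subtype_proportions)

  ## ---- annotation ---------------------------------------------------------
  ann <- with_block_seed(seed, "annotation", function() {
    probe_id <- sprintf("cg%08d", seq_len(p))
    # special probes: MGMT pair + CDKN2A block carry fixed ids/locations
    probe_id[1:2] <- MGMT_PROBES
    chrom_pool <- paste0("chr", 1:22)
    chrom <- chrom_pool[cut(seq_len(p), 22, labels = FALSE)]
    pos <- stats::ave(seq_len(p), chrom, FUN = function(i) {
      sort(sample.int(1e8, length(i)))
    })
    island_relation <- sample(ISLAND_RELATIONS, p, replace = TRUE)
    is_promoter <- stats::runif(p) < 0.3
    tss_distance <- ifelse(is_promoter,
                           round(stats::runif(p, -1500, 1500)),
                           round(sample(c(-1, 1), p, TRUE) *
                                   stats::runif(p, 1501, 50000)))
    gene <- ifelse(is_promoter,
                   sprintf("GENE%05d", sample.int(max(1, p %/% 4), p,
                                                  replace = TRUE)),
                   "")
    df <- data.frame(probe_id, chrom, pos, island_relation, gene,
                     tss_distance, is_promoter,
                     is_snp_probe = stats::runif(p) < 0.01,
                     is_sex_chromosome = stats::runif(p) < 0.01,
                     stringsAsFactors = FALSE)
    # MGMT pair: chr10 promoter probes of MGMT
    mg <- match(MGMT_PROBES, df$probe_id)
    df$chrom[mg] <- "chr10"
    df$gene[mg] <- "MGMT"
    df$is_promoter[mg] <- TRUE
    df$tss_distance[mg] <- c(-200, 150)
    # CDKN2A block: contiguous chr9 probes
    ck <- utils::head(which(df$chrom == "chr9"), N_CDKN2A_PROBES)
    df$gene[ck] <- "CDKN2A"
    df
  })
  cdkn2a_idx <- which(ann$gene == "CDKN2A")
  mgmt_idx <- match(MGMT_PROBES, ann$probe_id)
  budget <- config$n_clock_probes + config$n_dmp_age + config$n_dmp_accel +
    config$n_functional + length(cdkn2a_idx) + 2L
  if (p < budget) {
    stop(sprintf("n_probes = %d too small for the planted structure (%d)",
                 p, budget))
  }

  ## ---- probe roles --------------------------------------------------------
  roles <- with_block_seed(seed, "probes", function() {
    special <- c(mgmt_idx, cdkn2a_idx)
    free <- setdiff(seq_len(p), special)
    clock <- sort(sample(free, config$n_clock_probes))
    free <- setdiff(free, clock)
    dmp_age <- sort(sample(free, config$n_dmp_age))
    free <- setdiff(free, dmp_age)
    dmp_accel <- sort(sample(free, config$n_dmp_accel))
    free <- setdiff(free, dmp_accel)
    # functional probes must be promoter probes with a dedicated gene
    functional <- sort(sample(free, config$n_functional))
    free <- setdiff(free, functional)
    subtype_probes <- sort(sample(free, min(config$n_subtype_probes,
                                            length(free))))
    list(clock = clock, dmp_age = dmp_age, dmp_accel = dmp_accel,
         functional = functional, subtype = subtype_probes,
         special = special)
  })
  ann$is_promoter[roles$functional] <- TRUE
  ann$tss_distance[roles$functional] <-
    round(seq(-1400, 1400, length.out = length(roles$functional)))
  ann$gene[roles$functional] <- sprintf("FGENE%04d",
                                        seq_along(roles$functional))
  # planted structure must survive the preprocessing filters
  keepers <- c(roles$clock, roles$dmp_age, roles$dmp_accel, roles$functional,
               roles$subtype, roles$special)
  ann$is_snp_probe[keepers] <- FALSE
  ann$is_sex_chromosome[keepers] <- FALSE
  ann$is_clock <- seq_len(p) %in% roles$clock

  ## ---- subjects -----------------------------------------------------------
  subj <- with_block_seed(seed, "subjects", function() {
    am <- config$acceleration_model
    subtype <- if (n > 0) {
      sample(subtypes, n, replace = TRUE, prob = config$subtype_proportions)
    } else character(0)
    age <- stats::runif(n, config$age_range[1], config$age_range[2])
    accel <- stats::rnorm(n, am$mean + am$subtype_shift[subtype], am$sd)
    accel <- pmax(accel, 1 - age)  # keep DNAm age above 1 year
    data.frame(
      sample_id = sprintf("S%04d", seq_len(n)),
      age = age,
      sex = sample(c("F", "M"), n, replace = TRUE),
      batch = sample(config$batch_labels, n, replace = TRUE),
      treatment = stats::rbinom(n, 1, 0.5),
      mgmt = stats::rbinom(n, 1, 0.5),
      purity = stats::runif(n, config$purity_range[1],
                            config$purity_range[2]),
      subtype = subtype, accel = accel,
      stringsAsFactors = FALSE
    )
  })

  ## ---- mean beta matrix ---------------------------------------------------
  mk <- with_block_seed(seed, "clock", function() {
    b <- stats::runif(config$n_clock_probes, 0.35, 0.60)
    cc <- sample(c(-1, 1), config$n_clock_probes, TRUE) *
      stats::runif(config$n_clock_probes, 0.015, 0.035)
    w <- cc / sum(cc^2)                  # so that sum(w * cc) = 1
    list(baseline = b, slope = cc, weights = w, intercept = -sum(w * b))
  })
  clock_truth <- clock_model(
    intercept = mk$intercept,
    coefficients = stats::setNames(mk$weights, ann$probe_id[roles$clock])
  )

  base <- with_block_seed(seed, "baseline", function() {
    rel <- ann$island_relation
    prom <- ann$is_promoter
    b <- stats::runif(p, 0.2, 0.8)
    pi_idx <- rel == "Island" & prom            # bimodal, mostly ordered
    b[pi_idx] <- ifelse(stats::runif(sum(pi_idx)) < 0.7,
                        stats::runif(sum(pi_idx), 0.01, 0.10),
                        stats::runif(sum(pi_idx), 0.90, 0.99))
    os_idx <- rel == "OpenSea"                  # intermediate, disordered
    b[os_idx] <- stats::runif(sum(os_idx), 0.35, 0.65)
    b[roles$dmp_age] <- stats::runif(config$n_dmp_age, 0.35, 0.65)
    b[roles$dmp_accel] <- stats::runif(config$n_dmp_accel, 0.35, 0.65)
    b[roles$functional] <- stats::runif(config$n_functional, 0.30, 0.70)
    b
  })

  dmp_truth <- with_block_seed(seed, "dmp", function() {
    list(sign_age = sample(c(-1, 1), config$n_dmp_age, TRUE),
         sign_accel = sample(c(-1, 1), config$n_dmp_accel, TRUE),
         centroid_shift = matrix(
           stats::rnorm(length(roles$subtype) * length(subtypes), 0, 0.12),
           nrow = length(roles$subtype),
           dimnames = list(ann$probe_id[roles$subtype], subtypes)
         ))
  })

  mu <- matrix(if (n > 0) base else numeric(0), nrow = p, ncol = n,
               dimnames = list(ann$probe_id, subj$sample_id))
  if (n > 0) {
    t_age <- age_transform(subj$age + subj$accel)
    mu[roles$clock, ] <- mk$baseline + outer(mk$slope, t_age)
    mid_age <- mean(config$age_range)
    mu[roles$dmp_age, ] <- mu[roles$dmp_age, ] +
      outer(dmp_truth$sign_age * config$slope_age, subj$age - mid_age)
    mu[roles$dmp_accel, ] <- mu[roles$dmp_accel, ] +
      outer(dmp_truth$sign_accel * config$slope_accel,
            subj$accel - config$acceleration_model$mean)
    mu[roles$subtype, ] <-
      mu[roles$subtype, ] + dmp_truth$centroid_shift[, subj$subtype]
    # MGMT promoter pair driven by the true MGMT state
    mu[mgmt_idx, ] <- rep(ifelse(subj$mgmt == 1, 0.80, 0.15),
                          each = length(mgmt_idx))
  }
  mu <- pmin(pmax(mu, 0.005), 0.995)

  # subtype centroids of the noiseless means (before purity/noise)
  centroids <- if (n > 0) {
    vapply(subtypes, function(s) {
      cols <- subj$subtype == s
      if (any(cols)) rowMeans(mu[roles$subtype, cols, drop = FALSE])
      else rep(NA_real_, length(roles$subtype))
    }, numeric(length(roles$subtype)))
  } else {
    matrix(numeric(0), nrow = length(roles$subtype), ncol = length(subtypes),
           dimnames = list(ann$probe_id[roles$subtype], subtypes))
  }
  if (n > 0) rownames(centroids) <- ann$probe_id[roles$subtype]

  ## ---- purity mixing with a fixed normal-brain profile --------------------
  normal_profile <- with_block_seed(seed, "purity", function() {
    nb <- ifelse(stats::runif(p) < 0.5,
                 stats::runif(p, 0.02, 0.20), stats::runif(p, 0.80, 0.98))
    nb[mgmt_idx] <- 0.10   # normal brain: MGMT promoter unmethylated
    # normal brain shows no age acceleration: its clock profile reads as a
    # mid-cohort donor age, so purity mixing dilutes (not randomizes) accel
    nb[roles$clock] <- mk$baseline +
      mk$slope * age_transform(mean(config$age_range))
    stats::setNames(nb, ann$probe_id)
  })
  tumor_ref <- rowMeans(mu)
  if (n > 0 && any(subj$purity < 1)) {
    mu <- sweep(mu, 2, subj$purity, "*") +
      outer(normal_profile, 1 - subj$purity)
  }

  ## ---- noise and batch shifts --------------------------------------------
  betas <- with_block_seed(seed, "noise", function() {
    out <- mu
    if (config$noise_sd > 0 && n > 0) {
      sd_logit <- config$noise_sd / (mu * (1 - mu))
      out <- stats::plogis(stats::qlogis(mu) +
                             stats::rnorm(length(mu)) * sd_logit)
    }
    out
  })
  n_batches <- length(unique(subj$batch))
  if (config$batch_sd > 0 && n > 0 && n_batches > 1) {
    betas <- with_block_seed(seed, "batch", function() {
      shifts <- matrix(stats::rnorm(p * n_batches, 0, config$batch_sd),
                       nrow = p,
                       dimnames = list(ann$probe_id, unique(subj$batch)))
      stats::plogis(stats::qlogis(pmin(pmax(betas, 1e-6), 1 - 1e-6)) +
                      shifts[, subj$batch, drop = FALSE])
    })
  }
  dim(betas) <- c(p, n)
  dimnames(betas) <- list(ann$probe_id, subj$sample_id)
  betas <- meth_matrix(betas, "beta")

  ## ---- detection p-values -------------------------------------------------
  detection_p <- with_block_seed(seed, "misc", function() {
    dp <- matrix(stats::runif(p * n, 0, 0.005), nrow = p,
                 dimnames = list(ann$probe_id, subj$sample_id))
    if (n > 0) {
      failable <- setdiff(seq_len(p), keepers)
      n_fail <- round(0.005 * length(failable))
      if (n_fail > 0) {
        rows <- sample(failable, n_fail)
        cols <- sample.int(n, n_fail, replace = TRUE)
        dp[cbind(rows, cols)] <- stats::runif(n_fail, 0.02, 0.1)
      }
    }
    dp
  })

  ## ---- expression ---------------------------------------------------------
  genes <- unique(ann$gene[nzchar(ann$gene)])
  expression <- with_block_seed(seed, "expression", function() {
    ex <- matrix(stats::rnorm(length(genes) * n, 8, 1),
                 nrow = length(genes),
                 dimnames = list(genes, subj$sample_id))
    rho <- abs(config$expression_coupling)
    noise_scale <- sqrt(1 / rho^2 - 1)
    for (k in seq_along(roles$functional)) {
      i <- roles$functional[k]
      g <- ann$gene[i]
      z <- as.numeric(scale(betas[i, ]))
      ex[g, ] <- 8 + sign(config$expression_coupling) *
        (z + stats::rnorm(n, 0, noise_scale))
    }
    ex
  })

  ## ---- CNV intensities ----------------------------------------------------
  cnv <- with_block_seed(seed, "cnv", function() {
    cp <- config$cnv_params
    base_int <- 2000 * 2^stats::rnorm(p, 0, 0.15)
    lr <- matrix(0, nrow = p, ncol = n)
    seg_samples <- list()
    for (k in seq_along(cp$segment_spec)) {
      sg <- cp$segment_spec[[k]]
      rows <- which(ann$chrom == sg$chrom & ann$pos >= sg$start &
                      ann$pos <= sg$end)
      cols <- which(stats::runif(n) < (sg$fraction %||% 0.5))
      if (length(rows) > 0 && length(cols) > 0) {
        lr[rows, cols] <- lr[rows, cols] + sg$log2ratio
      }
      seg_samples[[k]] <- subj$sample_id[cols]
    }
    hd_samples <- if (n > 0) {
      subj$sample_id[stats::runif(n) < cp$cdkn2a_hd_fraction]
    } else character(0)
    lr[cdkn2a_idx, match(hd_samples, subj$sample_id)] <- cp$hd_log2ratio
    if (cp$intensity_noise_sd > 0 && n > 0) {
      lr <- lr + stats::rnorm(length(lr), 0, cp$intensity_noise_sd)
    }
    total <- base_int * 2^lr
    list(meth = total * betas, unmeth = total * (1 - betas),
         reference_total = stats::setNames(base_int, ann$probe_id),
         seg_samples = seg_samples, hd_samples = hd_samples)
  })
  dimnames(cnv$meth) <- dimnames(cnv$unmeth) <- dimnames(betas)

  ## ---- survival -----------------------------------------------------------
  surv <- simulate_survival(subj$treatment, subj$mgmt, subj$accel,
                            config$survival_params, seed = seed)

  sample_sheet <- data.frame(
    subj[, c("sample_id", "age", "sex", "batch", "treatment")],
    survival_time = surv$time, event = surv$event,
    subtype = subj$subtype, mgmt = ifelse(subj$mgmt == 1, "M", "U"),
    stringsAsFactors = FALSE
  )

  probe_flags <- data.frame(
    probe_id = ann$probe_id,
    is_clock = ann$is_clock,
    is_age_dmp = seq_len(p) %in% roles$dmp_age,
    is_accel_dmp = seq_len(p) %in% roles$dmp_accel,
    is_functional = seq_len(p) %in% roles$functional,
    is_subtype = seq_len(p) %in% roles$subtype,
    stringsAsFactors = FALSE
  )

  cnv_breakpoints <- do.call(rbind, lapply(config$cnv_params$segment_spec,
    function(sg) data.frame(chrom = sg$chrom, start = sg$start,
                            end = sg$end, log2ratio = sg$log2ratio,
                            stringsAsFactors = FALSE)))

  truth <- list(
    sample = data.frame(subj, log_hazard = surv$log_hazard,
                        survival_time = surv$time, event = surv$event,
                        stringsAsFactors = FALSE),
    probe = probe_flags,
    clock = clock_truth,
    slopes = list(
      age = stats::setNames(dmp_truth$sign_age * config$slope_age,
                            ann$probe_id[roles$dmp_age]),
      accel = stats::setNames(dmp_truth$sign_accel * config$slope_accel,
                              ann$probe_id[roles$dmp_accel])
    ),
    stp27_coefficients = c(1.5, 1, 1),
    centroids = centroids,
    cnv = list(breakpoints = cnv_breakpoints,
               segment_samples = cnv$seg_samples,
               hd_samples = cnv$hd_samples,
               hd_log2ratio = config$cnv_params$hd_log2ratio),
    normal_profile = normal_profile,
    tumor_reference = tumor_ref,
    functional_genes = stats::setNames(ann$gene[roles$functional],
                                       ann$probe_id[roles$functional])
  )

  structure(list(
    betas = betas, annotation = ann, sample_sheet = sample_sheet,
    expression = expression,
    intensities = list(meth = cnv$meth, unmeth = cnv$unmeth,
                       reference_total = cnv$reference_total),
    detection_p = detection_p, truth = truth, config = config
  ), class = "meth_cohort")
}

#' @export
print.meth_cohort <- function(x, ...) {
  cat(sprintf("meth_cohort: %d probes x %d samples (seed %d)\n",
              nrow(x$betas), ncol(x$betas), x$config$seed))
  invisible(x)
}

#' Write / read a cohort as plain-text fixtures
#'
#' Beta, expression, intensity and detection-p matrices as TSV; the probe
#' manifest as a 450k-style CSV; the sample sheet as TSV; the truth record
#' (excluding the large per-probe reference vectors, which are written as
#' their own TSV) as JSON. A round trip reproduces the matrices to text
#' precision.
#'
#' @param cohort a `meth_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly / the reconstructed cohort list.
#' @export
write_fixtures <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_matrix_tsv(cohort$betas, fp("betas.tsv"))
  write_matrix_tsv(cohort$expression, fp("expression.tsv"))
  write_matrix_tsv(cohort$intensities$meth, fp("intensity_meth.tsv"))
  write_matrix_tsv(cohort$intensities$unmeth, fp("intensity_unmeth.tsv"))
  write_matrix_tsv(cohort$detection_p, fp("detection_p.tsv"))
  write_manifest_csv(cohort$annotation, fp("manifest.csv"))
  utils::write.table(cohort$sample_sheet, fp("sample_sheet.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  refs <- data.frame(
    probe_id = names(cohort$truth$normal_profile),
    normal_profile = unname(cohort$truth$normal_profile),
    tumor_reference = unname(cohort$truth$tumor_reference),
    reference_total = unname(cohort$intensities$reference_total)
  )
  utils::write.table(refs, fp("reference_profiles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth_small <- cohort$truth
  truth_small$normal_profile <- NULL
  truth_small$tumor_reference <- NULL
  truth_small$clock <- list(
    intercept = cohort$truth$clock$intercept,
    coefficients = as.list(cohort$truth$clock$coefficients),
    adult_age = cohort$truth$clock$adult_age
  )
  truth_small$centroids <- data.frame(
    probe_id = rownames(cohort$truth$centroids),
    as.data.frame(cohort$truth$centroids, row.names = NULL)
  )
  jsonlite::write_json(truth_small, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(dir)
}

#' @rdname write_fixtures
#' @export
read_fixtures <- function(dir) {
  fp <- function(f) file.path(dir, f)
  truth <- jsonlite::read_json(fp("truth.json"), simplifyVector = TRUE)
  refs <- utils::read.table(fp("reference_profiles.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  truth$normal_profile <- stats::setNames(refs$normal_profile, refs$probe_id)
  truth$tumor_reference <- stats::setNames(refs$tumor_reference,
                                           refs$probe_id)
  truth$clock <- clock_model(
    intercept = truth$clock$intercept,
    coefficients = unlist(truth$clock$coefficients),
    adult_age = truth$clock$adult_age
  )
  if (!is.matrix(truth$centroids) && !is.null(truth$centroids$probe_id)) {
    cols <- names(truth$centroids)[vapply(truth$centroids, is.numeric,
                                          logical(1))]
    cm <- vapply(cols, function(cl) unlist(truth$centroids[[cl]]),
                 numeric(length(truth$centroids$probe_id)))
    rownames(cm) <- unlist(truth$centroids$probe_id)
    truth$centroids <- cm
  }
  list(
    betas = read_matrix_tsv(fp("betas.tsv"), "beta"),
    expression = read_matrix_tsv(fp("expression.tsv")),
    intensities = list(
      meth = read_matrix_tsv(fp("intensity_meth.tsv")),
      unmeth = read_matrix_tsv(fp("intensity_unmeth.tsv")),
      reference_total = stats::setNames(refs$reference_total, refs$probe_id)
    ),
    detection_p = read_matrix_tsv(fp("detection_p.tsv")),
    annotation = read_manifest_csv(fp("manifest.csv")),
    sample_sheet = utils::read.table(fp("sample_sheet.tsv"), header = TRUE,
                                     sep = "\t", stringsAsFactors = FALSE),
    truth = truth
  )
}
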