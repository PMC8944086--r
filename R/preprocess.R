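#' Probe filtering, beta/M conversion and batch aggregation
#'
#' The pipeline represents a methylation data set as a plain numeric matrix
#' (probes in rows, samples in columns) carrying a `"scale"` attribute of
#' `"beta"` (methylated fraction in \[0, 1\]) or `"M"` (log2 odds), plus a
#' probe annotation `data.frame` modelled on the Illumina 450k manifest with
#' columns `probe_id`, `chrom`, `pos` (1-based, hg19 labels carried as
#' metadata only), `island_relation` (Island, N_Shore, S_Shore, N_Shelf,
#' S_Shelf, OpenSea), `gene`, `tss_distance`, `is_promoter`
#' (|tss_distance| <= 1500), `is_snp_probe` and `is_sex_chromosome`.
#'
#' @name preprocess
NULL

ISLAND_RELATIONS <- c("Island", "N_Shore", "S_Shore", "N_Shelf", "S_Shelf",
                      "OpenSea")

#' Tag a matrix with its methylation scale
#'
#' @param x numeric matrix, probes x samples, with dimnames.
#' @param scale `"beta"` or `"M"`.
#' @return the matrix with a `"scale"` attribute.
#' @export
meth_matrix <- function(x, scale = c("beta", "M")) {
  scale <- match.arg(scale)
  if (!is.matrix(x) || !is.numeric(x)) stop("'x' must be a numeric matrix")
  if ((nrow(x) > 0 && is.null(rownames(x))) ||
      (ncol(x) > 0 && is.null(colnames(x)))) {
    stop("matrix needs probe rownames and sample colnames")
  }
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x))) {
    stop("duplicate probe or sample identifiers")
  }
  if (scale == "beta" && any(x < 0 | x > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0, 1]")
  }
  attr(x, "scale") <- scale
  x
}

meth_scale <- function(x) attr(x, "scale") %||% "beta"

#' Remove failing, sex-chromosome and SNP-overlapping probes
#'
#' A probe is dropped when (i) its detection p-value exceeds `p_thresh` in
#' more than a fraction `max_fail_frac` of samples (default 0: failure in any
#' sample removes the probe, the strictest reading), (ii) it lies on a sex
#' chromosome, or (iii) it overlaps a SNP. Probe order is preserved; counts
#' removed per rule are attached as attribute `"filter_report"`.
#'
#' @param m methylation matrix (probes x samples).
#' @param ann probe annotation covering all probes of `m`.
#' @param detection_p optional probes x samples matrix of detection p-values
#'   (rownames must cover `m`'s probes); omit to skip the detection rule.
#' @param p_thresh detection p-value threshold (default 0.01).
#' @param max_fail_frac maximum tolerated fraction of samples failing the
#'   detection threshold before the probe is removed.
#' @param drop_sex,drop_snp logical switches for the two annotation rules.
#' @return the filtered matrix, same scale tag, with a `filter_report`
#'   attribute (named counts removed per rule, evaluated independently).
#' @export
filter_probes <- function(m, ann, detection_p = NULL, p_thresh = 0.01,
                          max_fail_frac = 0, drop_sex = TRUE,
                          drop_snp = TRUE) {
  probes <- rownames(m)
  missing <- setdiff(probes, ann$probe_id)
  if (length(missing) > 0) {
    stop("probes missing annotation: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5))
  }
  ann <- ann[match(probes, ann$probe_id), , drop = FALSE]

  fail_detect <- rep(FALSE, length(probes))
  if (!is.null(detection_p)) {
    dp <- detection_p[probes, colnames(m), drop = FALSE]
    frac_fail <- rowMeans(dp > p_thresh)
    fail_detect <- frac_fail > max_fail_frac
  }
  fail_sex <- if (drop_sex) ann$is_sex_chromosome else rep(FALSE, length(probes))
  fail_snp <- if (drop_snp) ann$is_snp_probe else rep(FALSE, length(probes))

  keep <- !(fail_detect | fail_sex | fail_snp)
  out <- meth_matrix(m[keep, , drop = FALSE], meth_scale(m))
  attr(out, "filter_report") <- c(
    detection = sum(fail_detect), sex_chromosome = sum(fail_sex),
    snp = sum(fail_snp), removed = sum(!keep), retained = sum(keep)
  )
  out
}

#' Beta to M-value conversion (log2 odds)
#'
#' M = log2(beta / (1 - beta)); betas are clipped to \[eps, 1 - eps\] so the
#' M-values of degenerate betas stay finite. The inverse is exact inside the
#' clip range.
#'
#' @param beta numeric vector or matrix of methylated fractions in \[0, 1\].
#' @param eps clipping bound (default 1e-6).
#' @return M-values, same shape; matrices keep dimnames and get an `"M"`
#'   scale tag.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) stop("beta values outside [0, 1]")
  b <- pmin(pmax(beta, eps), 1 - eps)
  m <- log2(b / (1 - b))
  if (is.matrix(beta)) {
    dim(m) <- dim(beta)
    dimnames(m) <- dimnames(beta)
    attr(m, "scale") <- "M"
  }
  m
}

#' @rdname beta_to_m
#' @param M numeric vector or matrix of M-values.
#' @export
m_to_beta <- function(M) {
  b <- 2^M / (1 + 2^M)
  b[is.infinite(M) & M > 0] <- 1
  if (is.matrix(M)) {
    dim(b) <- dim(M)
    dimnames(b) <- dimnames(M)
    attr(b, "scale") <- "beta"
  }
  b
}

#' Aggregate batches with parametric empirical-Bayes adjustment
#'
#' Location/scale batch adjustment (ComBat) of an M-value matrix across study
#' or chip batches, retaining the effects of protected covariates. With a
#' single batch the input is returned unchanged.
#'
#' @param M M-value matrix (probes x samples).
#' @param batch factor or character vector of batch labels, one per sample.
#' @param covariates optional data.frame of biological covariates to protect
#'   (one row per sample).
#' @return adjusted matrix, same dimensions and scale tag.
#' @export
combat_adjust <- function(M, batch, covariates = NULL) {
  batch <- as.factor(batch)
  if (length(batch) != ncol(M)) stop("one batch label per sample required")
  if (any(table(batch) < 2)) stop("every batch needs at least 2 samples")
  if (nlevels(droplevels(batch)) < 2) {
    return(M)
  }
  mod <- NULL
  if (!is.null(covariates)) {
    mod <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  }
  quiet_log <- utils::capture.output(
    out <- suppressMessages(sva::ComBat(dat = M, batch = batch, mod = mod,
                                        par.prior = TRUE,
                                        prior.plots = FALSE))
  )
  attr(out, "combat_log") <- quiet_log
  dimnames(out) <- dimnames(M)
  attr(out, "scale") <- meth_scale(M)
  out
}

#' Read / write methylation matrices and manifests as plain text
#'
#' Matrices are written as TSV with probe IDs in the first column; manifests
#' as CSV using the standard 450k column names (IlmnID, CHR, MAPINFO,
#' Relation_to_UCSC_CpG_Island, UCSC_RefGene_Name, UCSC_RefGene_Group).
#'
#' @param m matrix to write.
#' @param path file path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(probe_id = rownames(m),
                   format(m, digits = 17, scientific = TRUE, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @param scale scale tag to attach on read.
#' @export
read_matrix_tsv <- function(path, scale = "beta") {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  attr(m, "scale") <- scale
  m
}

# Manifest column mapping: internal name -> 450k manifest name
MANIFEST_COLS <- c(
  probe_id = "IlmnID", chrom = "CHR", pos = "MAPINFO",
  island_relation = "Relation_to_UCSC_CpG_Island",
  gene = "UCSC_RefGene_Name", gene_region = "UCSC_RefGene_Group",
  tss_distance = "TSS_Distance", is_promoter = "Is_Promoter",
  is_snp_probe = "Is_SNP_Probe", is_sex_chromosome = "Is_Sex_Chromosome",
  is_clock = "Is_Clock_Probe"
)

#' @rdname write_matrix_tsv
#' @param ann probe annotation data.frame.
#' @export
write_manifest_csv <- function(ann, path) {
  out <- ann
  idx <- match(names(MANIFEST_COLS), names(out))
  names(out)[idx[!is.na(idx)]] <- MANIFEST_COLS[!is.na(idx)]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_manifest_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  rev_map <- stats::setNames(names(MANIFEST_COLS), MANIFEST_COLS)
  idx <- match(names(rev_map), names(df))
  names(df)[idx[!is.na(idx)]] <- rev_map[!is.na(idx)]
  for (col in c("is_promoter", "is_snp_probe", "is_sex_chromosome",
                "is_clock")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  df
}
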