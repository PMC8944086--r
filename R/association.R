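#' Methylome-wide association scans and gene-set enrichment
#'
#' Differentially methylated positions (DMPs) are detected probe-by-probe by
#' comparing a linear model containing the variable of interest (e.g.
#' `CpG ~ age` or `CpG ~ Accel`) against the intercept-only null with an
#' F-test, Bonferroni-adjusted across probes; a probe is a DMP when the
#' adjusted q-value falls below 0.1. Functional methylation is a promoter
#' CpG (within 1500 bp of the TSS) whose methylation is negatively
#' rank-correlated with its gene's expression (q < 0.05 and Spearman rho
#' <= -0.3). Gene-set enrichment uses upper-tail hypergeometric tests with
#' Bonferroni adjustment.
#'
#' @name association
NULL

#' Probe-wise linear-model F-test scan
#'
#' For every probe row, the full model `value ~ covariate` (covariates may be
#' numeric or factor; several columns allowed via a data.frame) is compared
#' to the intercept-only model:
#' `F = ((RSS0 - RSS1)/df_diff) / (RSS1/df_res)`. Adjustment is Bonferroni
#' (`q = min(1, p * n_probes)`), and the adjusted value is reported as the
#' q-value. Constant probes get `F = 0, p = 1`.
#'
#' @param M methylation matrix (probes x samples), typically M-values.
#' @param covariate numeric vector, factor, or data.frame (one row per
#'   sample) with the variable(s) of interest.
#' @param q_thresh DMP threshold on the adjusted q-value (default 0.1).
#' @return data.frame: `probe_id`, `f_stat`, `p_value`, `q_value`,
#'   `effect_dir` (sign of the first non-intercept coefficient), `is_dmp`.
#' @export
dmp_scan <- function(M, covariate, q_thresh = 0.1) {
  if (!is.data.frame(covariate)) covariate <- data.frame(x = covariate)
  if (nrow(covariate) != ncol(M)) {
    stop("covariate length must equal the number of samples")
  }
  for (j in seq_along(covariate)) {
    v <- covariate[[j]]
    if ((is.numeric(v) && stats::sd(v) == 0) ||
        (!is.numeric(v) && length(unique(v)) < 2)) {
      stop("constant covariate: the full and null models coincide")
    }
  }
  X <- stats::model.matrix(~ ., data = covariate)
  n <- nrow(X)
  p_full <- qr(X)$rank
  if (n <= p_full + 1) stop("too few samples for the model")

  Y <- t(M)                               # samples x probes
  qrX <- qr(X)
  fitted <- qr.fitted(qrX, Y)
  rss1 <- colSums((Y - fitted)^2)
  center <- colMeans(Y)
  rss0 <- colSums(sweep(Y, 2, center)^2)

  df_diff <- p_full - 1
  df_res <- n - p_full
  f_stat <- ((rss0 - rss1) / df_diff) / (rss1 / df_res)
  constant <- rss0 < 1e-24
  f_stat[constant] <- 0
  p <- stats::pf(f_stat, df_diff, df_res, lower.tail = FALSE)
  p[constant] <- 1
  q <- pmin(1, p * nrow(M))

  beta1 <- qr.coef(qrX, Y)
  eff <- if (nrow(beta1) >= 2) sign(beta1[2, ]) else rep(0, ncol(Y))

  data.frame(probe_id = rownames(M), f_stat = f_stat, p_value = p,
             q_value = q, effect_dir = unname(eff), is_dmp = q < q_thresh,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Functional-methylation scan against expression
#'
#' Spearman correlation test of each promoter CpG (|TSS distance| within
#' `tss_window`) against the expression of its annotated gene, over the
#' samples shared by the two matrices. P-values use the t approximation for
#' n >= 10 and the exact permutation distribution below. Adjustment is
#' Benjamini-Hochberg by default (`adjust = "bonferroni"` to switch). A CpG
#' is functional when `q < q_thresh` and `rho <= rho_thresh`. Probes
#' annotated to several genes (comma/semicolon-separated) are tested once
#' per gene; genes absent from the expression matrix are skipped and
#' counted in attribute `"n_skipped"`.
#'
#' @param betas beta (or M) matrix, probes x samples.
#' @param expression genes x samples expression matrix.
#' @param ann probe annotation (`probe_id`, `gene`, `tss_distance`).
#' @param tss_window promoter window around the TSS in bp (default 1500).
#' @param q_thresh,rho_thresh functional criteria (defaults 0.05, -0.3).
#' @param adjust multiple-testing procedure, `"BH"` or `"bonferroni"`.
#' @return data.frame: `probe_id`, `gene`, `rho`, `p_value`, `q_value`,
#'   `is_functional`.
#' @export
functional_scan <- function(betas, expression, ann, tss_window = 1500,
                            q_thresh = 0.05, rho_thresh = -0.3,
                            adjust = c("BH", "bonferroni")) {
  adjust <- match.arg(adjust)
  samples <- intersect(colnames(betas), colnames(expression))
  if (length(samples) < 10) stop("need >= 10 shared samples")
  ann <- ann[match(rownames(betas), ann$probe_id), , drop = FALSE]
  promoter <- !is.na(ann$tss_distance) & abs(ann$tss_distance) <= tss_window &
    !is.na(ann$gene) & nzchar(ann$gene)

  rows <- list()
  n_skipped <- 0L
  for (i in which(promoter)) {
    genes <- unique(strsplit(ann$gene[i], "[;,]")[[1]])
    for (g in genes) {
      if (!(g %in% rownames(expression))) {
        n_skipped <- n_skipped + 1L
        next
      }
      b <- betas[i, samples]
      e <- expression[g, samples]
      ct <- suppressWarnings(stats::cor.test(
        b, e, method = "spearman",
        exact = length(samples) < 10
      ))
      rows[[length(rows) + 1L]] <- data.frame(
        probe_id = ann$probe_id[i], gene = g,
        rho = unname(ct$estimate), p_value = ct$p.value,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else {
    data.frame(probe_id = character(), gene = character(), rho = numeric(),
               p_value = numeric())
  }
  out$q_value <- stats::p.adjust(out$p_value, method = adjust)
  out$is_functional <- out$q_value < q_thresh & out$rho <= rho_thresh
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Hypergeometric gene-set over-representation
#'
#' Upper-tail hypergeometric p-value for the overlap between a query gene
#' list and each gene set, within a fixed universe; Bonferroni adjustment
#' across sets; significance at adjusted p <= `p_thresh`.
#'
#' @param query character vector of query genes (must lie in `universe`).
#' @param gene_sets named list of character vectors (subsets of `universe`).
#' @param universe character vector of all testable genes.
#' @param p_thresh significance threshold on the Bonferroni-adjusted p
#'   (default 0.1).
#' @return data.frame: `set`, `set_size`, `overlap`, `p_value`,
#'   `p_adjusted`, `significant`, ordered by p.
#' @export
hypergeom_gsea <- function(query, gene_sets, universe, p_thresh = 0.1) {
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  if (!all(query %in% universe)) stop("query genes outside the universe")
  query <- unique(query)
  n_u <- length(universe)
  n_q <- length(query)

  res <- lapply(names(gene_sets), function(nm) {
    s <- unique(intersect(gene_sets[[nm]], universe))
    k <- length(intersect(query, s))
    # P(overlap >= k) drawing n_q genes from a universe with |s| marked
    p <- if (n_q == 0) 1 else
      stats::phyper(k - 1, length(s), n_u - length(s), n_q,
                    lower.tail = FALSE)
    data.frame(set = nm, set_size = length(s), overlap = k, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- pmin(1, out$p_value * nrow(out))
  out$significant <- out$p_adjusted <= p_thresh & out$overlap > 0
  out[order(out$p_value), , drop = FALSE]
}
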