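#' Sample-level molecular metrics
#'
#' Copy-number log-ratios from combined methylated + unmethylated signal
#' intensities, CDKN2A homozygous-deletion calling by a two-component
#' mixture, methylation-based tumor purity, the two-probe MGMT-STP27
#' logistic classifier, G-CIMP clustering and a nearest-centroid subtype
#' surrogate.
#'
#' @name genomic_state
NULL

#' Per-probe copy-number log2 ratios
#'
#' `log2((meth + unmeth) / reference_total)`, median-centered per sample.
#' Probes with a non-positive total in either the sample or the reference
#' are masked (`NA`).
#'
#' @param meth,unmeth probes x samples intensity matrices (arbitrary
#'   units >= 0).
#' @param reference_total named per-probe reference total intensity.
#' @return probes x samples matrix of centered log2 ratios.
#' @export
copy_number_logratio <- function(meth, unmeth, reference_total) {
  if (any(meth < 0, na.rm = TRUE) || any(unmeth < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative")
  }
  total <- meth + unmeth
  ref <- reference_total[rownames(total)]
  if (any(is.na(ref))) stop("reference does not cover all probes")
  lr <- log2(sweep(total, 1, ref, "/"))
  lr[total <= 0 | ref <= 0] <- NA
  med <- apply(lr, 2, stats::median, na.rm = TRUE)
  sweep(lr, 2, med)
}

#' CDKN2A homozygous-deletion call from copy-number probe means
#'
#' A Gaussian mixture with a common component variance is fit to per-sample
#' mean log2 ratios of the probes in the CDKN2A locus, letting BIC choose
#' between one and two components (the equal-variance model avoids
#' degenerate spike components at cohort-scale n). Samples assigned to the
#' lower-mean component with posterior > 0.5 are called HD. The mixture
#' degenerates to "no HD" when a single component is preferred or when the
#' two component means are separated by less than one component standard
#' deviation.
#'
#' @param cn_means numeric vector of per-sample CDKN2A copy-number means
#'   (>= 20 samples).
#' @return data.frame: `sample_id` (names of `cn_means` or index), `hd`
#'   (logical), `posterior_hd`.
#' @importFrom mclust Mclust mclustBIC
#' @export
cdkn2a_hd_call <- function(cn_means) {
  if (length(cn_means) < 20) stop("need at least 20 samples")
  ids <- names(cn_means) %||% as.character(seq_along(cn_means))
  if (stats::sd(cn_means) < 1e-12) {
    warning("all CDKN2A means identical; calling no HD")
    return(data.frame(sample_id = ids, hd = FALSE, posterior_hd = 0,
                      stringsAsFactors = FALSE))
  }
  fit <- Mclust(cn_means, G = 1:2, modelNames = "E", verbose = FALSE)
  if (is.null(fit) || fit$G == 1) {
    return(data.frame(sample_id = ids, hd = FALSE, posterior_hd = 0,
                      stringsAsFactors = FALSE))
  }
  mu <- fit$parameters$mean
  sd_pool <- sqrt(fit$parameters$variance$sigmasq[1])
  lower <- which.min(mu)
  post <- fit$z[, lower]
  if (abs(diff(mu)) < sd_pool) {
    # components merged: unimodal input, no deletion cluster
    return(data.frame(sample_id = ids, hd = FALSE, posterior_hd = post,
                      stringsAsFactors = FALSE))
  }
  data.frame(sample_id = ids, hd = post > 0.5, posterior_hd = post,
             stringsAsFactors = FALSE)
}

#' Methylation-based tumor purity
#'
#' Least-squares mixing weight `w` of `beta_obs = w * beta_tumor +
#' (1 - w) * beta_normal` over informative probes (reference profiles
#' differing by more than `min_diff`), clipped to \[0, 1\].
#'
#' @param betas beta matrix (probes x samples) or a single profile vector
#'   named by probe.
#' @param tumor_ref,normal_ref per-probe reference beta profiles, named.
#' @param min_diff informativeness threshold on |tumor - normal|
#'   (default 0.3); at least `min_probes` informative probes are required.
#' @param min_probes minimum informative probes (default 50).
#' @return named numeric vector of purities in \[0, 1\].
#' @export
estimate_purity <- function(betas, tumor_ref, normal_ref, min_diff = 0.3,
                            min_probes = 50) {
  if (!is.matrix(betas)) betas <- cbind(sample1 = betas)
  probes <- intersect(rownames(betas),
                      intersect(names(tumor_ref), names(normal_ref)))
  d <- tumor_ref[probes] - normal_ref[probes]
  info <- probes[abs(d) > min_diff]
  if (length(info) < min_probes) {
    stop(sprintf("only %d informative probes (need >= %d)",
                 length(info), min_probes))
  }
  dd <- tumor_ref[info] - normal_ref[info]
  num <- crossprod(betas[info, , drop = FALSE] - normal_ref[info], dd)
  w <- drop(num) / sum(dd^2)
  stats::setNames(pmin(pmax(w, 0), 1), colnames(betas))
}

#' MGMT-STP27 promoter-methylation classification
#'
#' Logistic model on the M-values of the two MGMT promoter probes
#' cg12434587 and cg12981137:
#' `probability = plogis(b0 + b1 * M1 + b2 * M2)`; the reported score is
#' `logit(probability)` (the linear predictor) and the promoter is called
#' methylated (`M`) when probability >= `cutoff` (default 0.358; the
#' boundary value classifies as `M`). The model coefficients are a required
#' input; they are not re-estimated here.
#'
#' @param M M-value matrix containing rows `cg12434587` and `cg12981137`
#'   (probes x samples), or a named length-2 vector for a single sample.
#' @param coefficients numeric length 3: intercept, slope for cg12434587,
#'   slope for cg12981137.
#' @param cutoff classification threshold on the probability (default 0.358).
#' @return data.frame: `sample_id`, `score`, `probability`, `status`
#'   (`"M"`/`"U"`).
#' @export
mgmt_stp27 <- function(M, coefficients, cutoff = 0.358) {
  probes <- c("cg12434587", "cg12981137")
  if (!is.matrix(M)) M <- cbind(sample1 = M[probes])
  missing <- setdiff(probes, rownames(M))
  if (length(missing) > 0) {
    stop("missing MGMT probe(s): ", paste(missing, collapse = ", "))
  }
  if (length(coefficients) != 3) {
    stop("coefficients must be (intercept, slope1, slope2)")
  }
  lp <- coefficients[1] + coefficients[2] * M[probes[1], ] +
    coefficients[3] * M[probes[2], ]
  prob <- stats::plogis(lp)
  data.frame(sample_id = colnames(M), score = unname(lp),
             probability = unname(prob),
             status = ifelse(prob >= cutoff, "M", "U"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' G-CIMP clustering by Ward's algorithm
#'
#' Unsupervised hierarchical clustering (Ward's criterion on Euclidean
#' distances) of samples, cut at `k` clusters. The cluster with the highest
#' mean methylation over the `n_var` most variable probes is flagged
#' G-CIMP-positive.
#'
#' @param M methylation matrix (probes x samples).
#' @param k number of clusters (default 2).
#' @param n_var number of most-variable probes used for the high-methylation
#'   rule (default 1000, capped at the probe count).
#' @return data.frame: `sample_id`, `cluster`, `gcimp` (logical).
#' @export
gcimp_cluster <- function(M, k = 2, n_var = 1000) {
  if (ncol(M) < 4) stop("need at least 4 samples")
  hc <- stats::hclust(stats::dist(t(M)), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  v <- apply(M, 1, stats::var)
  top <- order(v, decreasing = TRUE)[seq_len(min(n_var, nrow(M)))]
  mean_meth <- tapply(colMeans(M[top, , drop = FALSE])[names(cl)], cl, mean)
  gcimp_cl <- as.integer(names(which.max(mean_meth)))
  data.frame(sample_id = colnames(M), cluster = unname(cl),
             gcimp = unname(cl) == gcimp_cl,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Nearest-centroid methylation subtype surrogate
#'
#' Assigns each sample to the centroid (MES, RTK_I, RTK_II by default)
#' with the smallest Euclidean distance; ties resolve to the earliest label
#' in centroid column order. A surrogate for external random-forest
#' methylation classifiers, intended for synthetic cohorts with known
#' subtype structure.
#'
#' @param M methylation matrix (probes x samples).
#' @param centroids probes x subtypes matrix of centroid profiles on the
#'   same probes (rownames must cover `M`'s probes used).
#' @return named character vector of subtype labels, one per sample.
#' @export
nearest_centroid_subtype <- function(M, centroids) {
  probes <- intersect(rownames(M), rownames(centroids))
  if (length(probes) == 0) stop("no shared probes with the centroids")
  X <- M[probes, , drop = FALSE]
  C <- centroids[probes, , drop = FALSE]
  # squared distances: ||x||^2 - 2 x.c + ||c||^2
  d2 <- outer(colSums(X^2), colSums(C^2), "+") - 2 * crossprod(X, C)
  # ties (within numerical tolerance) resolve to the earliest centroid column
  pick <- apply(d2, 1, function(d) {
    which(d <= min(d) + 1e-9 * (1 + abs(min(d))))[1]
  })
  lab <- colnames(C)[pick]
  stats::setNames(lab, colnames(M))
}
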