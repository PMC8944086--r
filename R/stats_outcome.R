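#' Multivariate and outcome statistics
#'
#' PCA of methylation tables, permutation MANOVA (ADONIS) on Euclidean
#' distances, three-block variation partitioning with Venn fractions, Wald
#' F-tests with HC3 sandwich covariance, interaction Cox models and the
#' Cochran-Mantel-Haenszel test.
#'
#' @name stats_outcome
NULL

#' PCA of a samples x features table
#'
#' Eigen-decomposition of the covariance of column-centered data; the sum of
#' eigenvalues equals the total per-feature variance.
#'
#' @param X samples x features numeric matrix (transpose a probes x samples
#'   methylation matrix before calling).
#' @param center,scale passed to [stats::prcomp()].
#' @return list: `eigenvalues` (non-increasing), `scores` (samples x PCs),
#'   `loadings`, `var_explained`.
#' @export
pca_table <- function(X, center = TRUE, scale = FALSE) {
  if (nrow(X) < 2) stop("need at least 2 samples")
  pc <- stats::prcomp(X, center = center, scale. = scale)
  ev <- pc$sdev^2
  list(eigenvalues = ev, scores = pc$x, loadings = pc$rotation,
       var_explained = ev / sum(ev))
}

#' Permutation MANOVA (ADONIS) on Euclidean distances
#'
#' Partitions the total sum of squares of the Euclidean distance matrix by a
#' grouping factor; the p-value is permutational,
#' `(1 + #{F* >= F}) / (n_perm + 1)`, with free permutation of sample labels.
#'
#' @param X samples x features matrix, or a `dist` object.
#' @param grouping factor (or coercible) of group labels, one per sample.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return list: `r_squared`, `f_stat`, `p_value`, `n_perm`.
#' @export
adonis_euclidean <- function(X, grouping, n_perm = 999, seed = 1) {
  grouping <- droplevels(as.factor(grouping))
  if (nlevels(grouping) < 2) stop("need at least 2 groups")
  if (any(table(grouping) == 0)) stop("empty group")
  d <- if (inherits(X, "dist")) X else stats::dist(X, method = "euclidean")
  df <- data.frame(g = grouping)
  fit <- with_block_seed(seed, "permutation", function() {
    vegan::adonis2(d ~ g, data = df, permutations = n_perm)
  })
  list(r_squared = fit$R2[1], f_stat = fit$F[1], p_value = fit$`Pr(>F)`[1],
       n_perm = n_perm)
}

block_r2 <- function(Y, blocks, adjusted = FALSE) {
  n <- nrow(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  ss_tot <- sum(Yc^2)
  r2_of <- function(members) {
    X <- do.call(cbind, lapply(members, function(b) {
      stats::model.matrix(~ ., data = as.data.frame(b))[, -1, drop = FALSE]
    }))
    fit <- stats::lm.fit(cbind(1, X), Yc)
    r2 <- 1 - sum(fit$residuals^2) / ss_tot
    if (adjusted) {
      p <- fit$rank - 1
      r2 <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
    }
    r2
  }
  r2_of
}

#' Three-block variation partitioning
#'
#' Decomposes the variance of a multivariate response explained by three
#' explanatory blocks (e.g. age, age acceleration, tumor classification)
#' into the 7 Venn fractions (3 unique, 3 pairwise-shared, 1 common) plus
#' the residual, by fitting the 7 redundancy models A, B, C, AB, AC, BC,
#' ABC and applying inclusion-exclusion. Raw R-squared fractions sum exactly
#' to the joint-model R-squared; Ezekiel-adjusted fractions are reported
#' alongside (primary for interpretation, since raw R-squared inflates with
#' block rank). Shared fractions can be negative under suppression or
#' collinearity; they are reported, not clipped.
#'
#' @param Y samples x variables response matrix (e.g. the HME table).
#' @param A,B,C explanatory blocks: vector, factor or data.frame, one row
#'   per sample.
#' @param labels length-3 character labels for the blocks.
#' @return object of class `varpart3`: data.frame `fractions` with columns
#'   `fraction`, `r2`, `adj_r2`; plus `joint_r2`, `residual`.
#' @export
variation_partition <- function(Y, A, B, C,
                                labels = c("A", "B", "C")) {
  Y <- as.matrix(Y)
  blocks <- list(A = A, B = B, C = C)
  lens <- vapply(blocks, function(b) {
    if (is.data.frame(b)) nrow(b) else length(b)
  }, numeric(1))
  if (any(lens != nrow(Y))) stop("blocks and response must share samples")

  r2 <- block_r2(Y, blocks, adjusted = FALSE)
  r2a <- block_r2(Y, blocks, adjusted = TRUE)
  models <- list(A = list(A), B = list(B), C = list(C),
                 AB = list(A, B), AC = list(A, C), BC = list(B, C),
                 ABC = list(A, B, C))
  R <- vapply(models, r2, numeric(1))
  Ra <- vapply(models, r2a, numeric(1))

  venn <- function(R) {
    a <- R[["ABC"]] - R[["BC"]]
    b <- R[["ABC"]] - R[["AC"]]
    c <- R[["ABC"]] - R[["AB"]]
    d <- R[["AC"]] + R[["BC"]] - R[["C"]] - R[["ABC"]]   # A&B only
    e <- R[["AB"]] + R[["BC"]] - R[["B"]] - R[["ABC"]]   # A&C only
    f <- R[["AB"]] + R[["AC"]] - R[["A"]] - R[["ABC"]]   # B&C only
    g <- R[["ABC"]] - (a + b + c + d + e + f)            # A&B&C
    c(a, b, c, d, e, f, g)
  }
  fr <- venn(R)
  fra <- venn(Ra)
  nm <- c(labels,
          paste(labels[1], labels[2], sep = "&"),
          paste(labels[1], labels[3], sep = "&"),
          paste(labels[2], labels[3], sep = "&"),
          paste(labels, collapse = "&"))
  structure(list(
    fractions = data.frame(fraction = nm, r2 = fr, adj_r2 = fra,
                           stringsAsFactors = FALSE),
    joint_r2 = R[["ABC"]], joint_adj_r2 = Ra[["ABC"]],
    residual = 1 - R[["ABC"]],
    single_r2 = R[c("A", "B", "C")],
    labels = labels
  ), class = "varpart3")
}

#' @export
print.varpart3 <- function(x, ...) {
  cat("Variation partitioning (3 blocks:",
      paste(x$labels, collapse = ", "), ")\n")
  print(x$fractions, row.names = FALSE)
  cat(sprintf("joint R2 = %.4f, residual = %.4f\n", x$joint_r2, x$residual))
  invisible(x)
}

#' Wald F-test with HC3 sandwich covariance
#'
#' Fits `response ~ .` on the design data.frame by OLS, estimates the
#' coefficient covariance with the HC3 heteroscedasticity-consistent
#' sandwich (`(X'X)^-1 X' diag(e_i^2 / (1-h_ii)^2) X (X'X)^-1`), and tests
#' the joint null that all coefficients belonging to the requested model
#' terms are zero with a Wald F statistic
#' (`F = (Rb)' (R V R')^-1 (Rb) / q` on `(q, n - p)` df).
#'
#' @param response numeric response vector.
#' @param design data.frame of covariates (one row per sample); the model is
#'   `response ~ .` including all columns (use `formula` to override, e.g.
#'   `~ class * study`).
#' @param terms character vector of term labels to test jointly (as they
#'   appear in `attr(terms(fit), "term.labels")`, e.g. `"class"` or
#'   `"class:study"`).
#' @param formula optional right-hand-side formula over `design` columns.
#' @return list per tested term set: `f_stat`, `df1`, `df2`, `p_value`,
#'   plus the fitted `lm` and the HC3 `vcov`.
#' @export
wald_hc3 <- function(response, design, terms, formula = NULL) {
  design <- as.data.frame(design)
  dat <- cbind(.y = response, design)
  fml <- if (is.null(formula)) stats::as.formula(".y ~ .") else
    stats::update(formula, .y ~ .)
  fit <- stats::lm(fml, data = dat)
  h <- stats::hatvalues(fit)
  if (any(h >= 1 - 1e-12)) stop("saturated design point (leverage = 1)")
  V <- sandwich::vcovHC(fit, type = "HC3")
  asgn <- attr(stats::model.matrix(fit), "assign")
  term_labels <- attr(stats::terms(fit), "term.labels")
  idx <- which(asgn %in% match(terms, term_labels))
  if (length(idx) == 0) stop("no coefficients match the requested terms")
  b <- stats::coef(fit)[idx]
  Vb <- V[idx, idx, drop = FALSE]
  q <- length(idx)
  f_stat <- drop(t(b) %*% solve(Vb, b)) / q
  df2 <- fit$df.residual
  list(f_stat = f_stat, df1 = q, df2 = df2,
       p_value = stats::pf(f_stat, q, df2, lower.tail = FALSE),
       fit = fit, vcov = V)
}

#' Interaction Cox model: treatment, MGMT, covariate, treatment x MGMT
#'
#' Multivariable proportional-hazards fit by maximum partial likelihood with
#' Efron tie handling, with exactly the terms of the outcome model:
#' treatment arm, MGMT status, one continuous or categorical covariate
#' (e.g. age acceleration), and the treatment-by-MGMT interaction (the
#' predictive-factor term).
#'
#' @param time survival times (any unit).
#' @param event 0/1 event indicator (>= 10 events required).
#' @param treatment,mgmt factors (or coercible, incl. 0/1) per sample.
#' @param covariate numeric vector or factor per sample.
#' @param covariate_name label for the covariate row in the output.
#' @return object of class `cox_interaction`: data.frame `table` with
#'   `term`, `hr`, `z`, `p_value`; `loglik` (log partial likelihood at the
#'   solution); `converged`; and the underlying `coxph` fit.
#' @export
cox_interaction_fit <- function(time, event, treatment, mgmt, covariate,
                                covariate_name = "covariate") {
  if (sum(event) < 10) stop("need at least 10 events")
  if (any(!is.finite(time)) || any(time <= 0)) stop("times must be positive")
  dat <- data.frame(time = time, event = event,
                    trt = as.factor(treatment), mgmt = as.factor(mgmt),
                    cov = covariate)
  fit <- survival::coxph(
    survival::Surv(time, event) ~ trt + mgmt + cov + trt:mgmt,
    data = dat, ties = "efron"
  )
  s <- summary(fit)
  co <- s$coefficients
  term <- rownames(co)
  term[grepl("^cov", term)] <- covariate_name
  tab <- data.frame(term = term, hr = co[, "exp(coef)"],
                    z = co[, "z"], p_value = co[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  warn_sep <- any(abs(co[, "coef"]) > 10)
  if (warn_sep) warning("very large coefficient: possible separation")
  structure(list(table = tab, loglik = fit$loglik[2],
                 converged = !warn_sep, fit = fit),
            class = "cox_interaction")
}

#' @export
print.cox_interaction <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("log partial likelihood: %.3f\n", x$loglik))
  invisible(x)
}

#' Cochran-Mantel-Haenszel test for a 2x2xK table
#'
#' Mantel-Haenszel chi-squared on one df, continuity correction off by
#' default. Strata with a zero row or column margin carry no information
#' and are dropped with a warning.
#'
#' @param tbl 2x2xK array of non-negative counts.
#' @param correct apply continuity correction (default FALSE).
#' @return list: `statistic`, `p_value`, `k_used`.
#' @export
cmh_test <- function(tbl, correct = FALSE) {
  if (length(dim(tbl)) == 2) tbl <- array(tbl, dim = c(dim(tbl), 1))
  if (!all(dim(tbl)[1:2] == c(2, 2))) stop("need a 2x2xK array")
  if (any(tbl < 0)) stop("negative counts")
  ok <- apply(tbl, 3, function(s) {
    all(rowSums(s) > 0) && all(colSums(s) > 0)
  })
  if (!any(ok)) stop("no informative strata (all have a zero margin)")
  if (!all(ok)) {
    warning(sprintf("%d stratum(s) with a zero margin skipped", sum(!ok)))
  }
  use <- tbl[, , ok, drop = FALSE]
  if (dim(use)[3] == 1) {
    # single stratum: closed-form Mantel-Haenszel chi-squared
    s <- use[, , 1]
    a <- s[1, 1]; r1 <- sum(s[1, ]); c1 <- sum(s[, 1]); N <- sum(s)
    ea <- r1 * c1 / N
    va <- r1 * (N - r1) * c1 * (N - c1) / (N^2 * (N - 1))
    dev <- abs(a - ea) - if (correct) 0.5 else 0
    stat <- max(dev, 0)^2 / va
    return(list(statistic = stat,
                p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
                k_used = 1L))
  }
  ht <- stats::mantelhaen.test(use, correct = correct)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       k_used = sum(ok))
}
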