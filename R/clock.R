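#' Epigenetic clock: DNAm age and age acceleration
#'
#' DNAm age is a penalized linear predictor over clock CpG betas, fit and
#' evaluated on a transformed age scale that is logarithmic in childhood and
#' linear in adulthood. Age acceleration is DNAm age minus chronological age,
#' in years.
#'
#' @name clock
NULL

#' Piecewise age transform used by multi-tissue epigenetic clocks
#'
#' `F(a) = log(a + 1) - log(adult_age + 1)` for `a <= adult_age`, and
#' `(a - adult_age) / (adult_age + 1)` above; continuous at `adult_age`
#' where both branches equal 0. `age_untransform()` is the exact inverse.
#'
#' @param age chronological age in years (> -1).
#' @param adult_age knot of the transform in years (default 20).
#' @return transformed age (dimensionless) / years for the inverse.
#' @export
age_transform <- function(age, adult_age = 20) {
  if (any(age <= -1)) stop("age must be > -1")
  ifelse(age <= adult_age,
         log(age + 1) - log(adult_age + 1),
         (age - adult_age) / (adult_age + 1))
}

#' @rdname age_transform
#' @param x transformed age value.
#' @export
age_untransform <- function(x, adult_age = 20) {
  ifelse(x <= 0,
         exp(x + log(adult_age + 1)) - 1,
         x * (adult_age + 1) + adult_age)
}

#' Construct a clock model
#'
#' @param intercept intercept on the transformed-age scale.
#' @param coefficients named numeric vector of per-probe weights (beta scale);
#'   names are probe IDs.
#' @param adult_age transform knot in years.
#' @return an object of class `clock_model`.
#' @export
clock_model <- function(intercept, coefficients, adult_age = 20) {
  if (anyDuplicated(names(coefficients))) stop("duplicate clock probe ids")
  if (is.null(names(coefficients))) stop("coefficients must be named by probe")
  if (adult_age <= 0) stop("adult_age must be positive")
  structure(list(intercept = intercept, coefficients = coefficients,
                 adult_age = adult_age),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("clock_model: %d probes, intercept %.4f, adult_age %g\n",
              length(x$coefficients), x$intercept, x$adult_age))
  invisible(x)
}

#' Predict DNAm age from clock-probe betas
#'
#' The linear predictor `intercept + sum(coef * beta)` over the clock probes
#' present in the matrix is inverse-transformed to years. Clock probes absent
#' from the matrix (e.g. removed by filtering) are dropped from the predictor
#' without re-normalization, with a warning giving the count; pass
#' `impute_missing = TRUE` to substitute each missing probe's coefficient
#' times 0.5 instead.
#'
#' @param m beta-scale methylation matrix (probes x samples).
#' @param clock a `clock_model`.
#' @param impute_missing substitute beta = 0.5 for missing clock probes.
#' @return named numeric vector of DNAm ages (years), one per sample.
#' @export
predict_dnam_age <- function(m, clock, impute_missing = FALSE) {
  stopifnot(inherits(clock, "clock_model"))
  probes <- names(clock$coefficients)
  present <- probes[probes %in% rownames(m)]
  if (length(present) == 0) stop("no clock probes present in the matrix")
  n_missing <- length(probes) - length(present)
  if (n_missing > 0) {
    warning(sprintf("%d of %d clock probes missing from the matrix; %s",
                    n_missing, length(probes),
                    if (impute_missing) "imputing beta = 0.5"
                    else "dropped from the predictor"))
  }
  lp <- clock$intercept +
    drop(crossprod(m[present, , drop = FALSE], clock$coefficients[present]))
  if (impute_missing && n_missing > 0) {
    lp <- lp + sum(clock$coefficients[setdiff(probes, present)]) * 0.5
  }
  stats::setNames(age_untransform(lp, clock$adult_age), colnames(m))
}

#' Age acceleration in years
#'
#' @param dnam_age DNAm age (years).
#' @param age chronological age (years).
#' @return `dnam_age - age`.
#' @export
age_acceleration <- function(dnam_age, age) {
  if (any(!is.finite(dnam_age)) || any(!is.finite(age))) {
    stop("ages must be finite")
  }
  dnam_age - age
}

#' Quantile-matching calibration of clock-probe betas
#'
#' Per-probe linear rescaling that maps each probe's observed (min, max)
#' across samples onto the reference profile's, so sample quantiles of
#' clock-probe betas match the reference; a monotone map that preserves
#' within-probe sample ranking. Probes with (near-)constant observed values
#' are left unchanged with a warning. This is a generic stand-in for
#' array-specific calibration procedures, and is off by default in the
#' pipeline because the synthetic generator emits data already on the model
#' scale.
#'
#' @param m beta matrix.
#' @param reference list with per-probe numeric `lo`/`hi` vectors (named by
#'   probe), or a probes x samples reference matrix from which they are taken.
#' @return calibrated matrix, clipped to \[0, 1\].
#' @export
calibrate_betas <- function(m, reference) {
  if (is.matrix(reference)) {
    shared <- intersect(rownames(m), rownames(reference))
    reference <- list(
      lo = apply(reference[shared, , drop = FALSE], 1, min),
      hi = apply(reference[shared, , drop = FALSE], 1, max)
    )
  }
  out <- m
  shared <- intersect(rownames(m), names(reference$lo))
  skipped <- 0L
  for (p in shared) {
    rng <- range(m[p, ])
    if (diff(rng) < 1e-12) {
      skipped <- skipped + 1L
      next
    }
    out[p, ] <- reference$lo[[p]] +
      (m[p, ] - rng[1]) / diff(rng) * (reference$hi[[p]] - reference$lo[[p]])
  }
  if (skipped > 0) {
    warning(sprintf("%d constant probes skipped during calibration", skipped))
  }
  out[] <- pmin(pmax(out, 0), 1)
  attr(out, "scale") <- "beta"
  out
}

#' Train a clock by cross-validated elastic net
#'
#' Ages are transformed with [age_transform()] before fitting; the penalty is
#' selected by k-fold cross-validation with a fold assignment derived from
#' `seed`, making the fit deterministic.
#'
#' @param betas beta matrix (probes x samples).
#' @param ages chronological ages (years), one per sample.
#' @param alpha elastic-net mixing (1 = lasso, 0 = ridge; default 0.5).
#' @param nfolds cross-validation folds.
#' @param adult_age transform knot.
#' @param seed integer seed for the fold assignment.
#' @return a `clock_model` with nonzero coefficients only; attribute
#'   `"cv_r2"` holds the cross-validated R-squared at the selected penalty.
#' @export
train_clock <- function(betas, ages, alpha = 0.5, nfolds = 5, adult_age = 20,
                        seed = 1) {
  if (ncol(betas) < 20) stop("need at least 20 training samples")
  if (stats::sd(ages) == 0) stop("constant ages: nothing to fit")
  y <- age_transform(ages, adult_age)
  x <- t(betas)
  foldid <- with_block_seed(seed, "misc", function() {
    sample(rep_len(seq_len(nfolds), ncol(betas)))
  })
  cv <- glmnet::cv.glmnet(x, y, alpha = alpha, foldid = foldid,
                          standardize = TRUE)
  co <- as.matrix(stats::coef(cv, s = "lambda.min"))
  keep <- which(co[-1, 1] != 0)
  model <- clock_model(intercept = co[1, 1],
                       coefficients = stats::setNames(co[-1, 1][keep],
                                                      rownames(co)[-1][keep]),
                       adult_age = adult_age)
  cv_mse <- cv$cvm[cv$lambda == cv$lambda.min]
  attr(model, "cv_r2") <- 1 - cv_mse / stats::var(y)
  model
}

#' Read / write clock coefficients as CSV
#'
#' One row per probe (`probe_id`, `coefficient`) plus an `(Intercept)` row.
#'
#' @param clock a `clock_model`.
#' @param path file path.
#' @export
write_clock_csv <- function(clock, path) {
  df <- data.frame(
    probe_id = c("(Intercept)", names(clock$coefficients)),
    coefficient = c(clock$intercept, unname(clock$coefficients))
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_clock_csv
#' @param adult_age transform knot for the loaded model.
#' @export
read_clock_csv <- function(path, adult_age = 20) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  i <- df$probe_id == "(Intercept)"
  clock_model(intercept = df$coefficient[i],
              coefficients = stats::setNames(df$coefficient[!i],
                                             df$probe_id[!i]),
              adult_age = adult_age)
}
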