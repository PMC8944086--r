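test_that("PCA conserves total variance and detects rank structure", {
  set.seed(61)
  X <- matrix(rnorm(40 * 8), 40, 8)
  pc <- pca_table(X)
  expect_equal(sum(pc$eigenvalues), sum(apply(X, 2, var)), tolerance = 1e-8)
  expect_true(all(diff(pc$eigenvalues) <= 1e-12))
  # rank-1 data -> one nonzero eigenvalue
  u <- rnorm(30); v <- rnorm(5)
  R1 <- outer(u, v)
  pc1 <- pca_table(R1)
  expect_gt(pc1$eigenvalues[1], 1e-8)
  expect_lt(max(pc1$eigenvalues[-1]), 1e-12)
})

test_that("first PC separates planted clusters", {
  set.seed(62)
  X <- rbind(matrix(rnorm(20 * 10, 0), 20), matrix(rnorm(20 * 10, 3), 20))
  pc <- pca_table(X)
  s <- pc$scores[, 1]
  grp <- rep(c(0, 1), each = 20)
  auc_pairs <- outer(s[grp == 1], s[grp == 0], ">")
  auc <- max(mean(auc_pairs), 1 - mean(auc_pairs))
  expect_gt(auc, 0.95)
})

test_that("ADONIS on univariate Euclidean data equals one-way ANOVA R2", {
  set.seed(63)
  y <- rnorm(30)
  g <- factor(rep(c("a", "b", "c"), each = 10))
  ad <- adonis_euclidean(matrix(y, ncol = 1), g, n_perm = 199, seed = 5)
  a <- anova(lm(y ~ g))
  r2_aov <- a$`Sum Sq`[1] / sum(a$`Sum Sq`)
  expect_equal(ad$r_squared, r2_aov, tolerance = 1e-10)
})

test_that("ADONIS R2 is scale-invariant, zero for identical groups, seeded", {
  set.seed(64)
  X <- matrix(rnorm(24 * 3), 24, 3)
  g <- rep(c("u", "v"), each = 12)
  a1 <- adonis_euclidean(X, g, n_perm = 99, seed = 9)
  a2 <- adonis_euclidean(X * 100, g, n_perm = 99, seed = 9)
  expect_equal(a1$r_squared, a2$r_squared, tolerance = 1e-10)
  expect_identical(a1$p_value, a2$p_value)
  # identical data across groups
  Xs <- rbind(X[1:12, ], X[1:12, ])
  a3 <- adonis_euclidean(Xs, g, n_perm = 99, seed = 9)
  expect_lt(a3$r_squared, 1e-10)
  expect_error(adonis_euclidean(X, rep("one", 24)), "2 groups")
})

test_that("variation partitioning: orthogonal blocks have no shared fractions", {
  n <- 64
  # orthogonal design: balanced +-1 contrasts
  A <- rep(c(-1, 1), each = 32)
  B <- rep(rep(c(-1, 1), each = 16), 2)
  C <- rep(rep(c(-1, 1), each = 8), 4)
  set.seed(65)
  Y <- cbind(0.5 * A + 0.3 * B + 0.2 * C + rnorm(n, 0, 0.5),
             -0.2 * A + 0.4 * C + rnorm(n, 0, 0.5))
  vp <- variation_partition(Y, A, B, C)
  fr <- setNames(vp$fractions$r2, vp$fractions$fraction)
  shared <- fr[grepl("&", names(fr))]
  expect_lt(max(abs(shared)), 1e-8)
  r2_single <- vp$single_r2
  expect_equal(unname(fr["A"]), unname(r2_single["A"]), tolerance = 1e-8)
  expect_equal(unname(fr["B"]), unname(r2_single["B"]), tolerance = 1e-8)
  expect_equal(sum(vp$fractions$r2), vp$joint_r2, tolerance = 1e-10)
  expect_equal(vp$residual, 1 - vp$joint_r2, tolerance = 1e-12)
})

test_that("duplicating a block moves its variance into the shared fraction", {
  set.seed(66)
  n <- 50
  Cb <- rnorm(n)
  Y <- cbind(Cb + rnorm(n, 0, 0.3), 2 * Cb + rnorm(n, 0, 0.3))
  B <- rnorm(n)
  vp <- variation_partition(Y, Cb, B, Cb, labels = c("A", "B", "C"))
  fr <- setNames(vp$fractions$r2, vp$fractions$fraction)
  expect_lt(abs(fr[["A"]]), 1e-10)
  expect_lt(abs(fr[["C"]]), 1e-10)
  expect_gt(fr[["A&C"]], 0.5)
})

test_that("variation partitioning is invariant to block order", {
  set.seed(67)
  n <- 40
  A <- rnorm(n); B <- factor(rep(letters[1:2], each = 20)); C <- rnorm(n)
  Y <- cbind(rnorm(n), rnorm(n))
  v1 <- variation_partition(Y, A, B, C, labels = c("A", "B", "C"))
  v2 <- variation_partition(Y, C, B, A, labels = c("C", "B", "A"))
  f1 <- setNames(v1$fractions$r2, v1$fractions$fraction)
  f2 <- setNames(v2$fractions$r2, v2$fractions$fraction)
  expect_equal(unname(f1["A"]), unname(f2["A"]), tolerance = 1e-10)
  expect_equal(unname(f1["A&B"]), unname(f2["B&A"]), tolerance = 1e-10)
  expect_equal(v1$joint_r2, v2$joint_r2, tolerance = 1e-12)
})

test_that("raw fractions agree with vegan::varpart on the same data", {
  set.seed(68)
  n <- 45
  A <- rnorm(n); B <- rnorm(n); C <- rnorm(n)
  Y <- cbind(A + 0.5 * B + rnorm(n, 0, 0.6), B - C + rnorm(n, 0, 0.6))
  vp <- variation_partition(Y, A, B, C)
  vg <- vegan::varpart(Y, ~ A, ~ B, ~ C,
                       data = data.frame(A = A, B = B, C = C))
  ind <- vg$part$indfract
  fr <- setNames(vp$fractions$adj_r2, vp$fractions$fraction)
  # vegan rows [a]..[g]: unique A, unique B, unique C are rows 1..3
  expect_equal(unname(fr["A"]), ind$Adj.R.square[1], tolerance = 1e-6)
  expect_equal(unname(fr["B"]), ind$Adj.R.square[2], tolerance = 1e-6)
  expect_equal(unname(fr["C"]), ind$Adj.R.square[3], tolerance = 1e-6)
})

test_that("HC3 covariance matches a hand-computed elementwise oracle at n = 6", {
  X <- cbind(1, c(0.2, 1.1, 2.3, 3.0, 4.2, 5.1))
  y <- c(1.1, 0.4, 2.8, 2.1, 4.9, 4.3)
  # oracle, assembled element by element from the definition
  XtXinv <- solve(t(X) %*% X)
  e <- y - X %*% XtXinv %*% t(X) %*% y
  h <- diag(X %*% XtXinv %*% t(X))
  meat <- matrix(0, 2, 2)
  for (i in 1:6) {
    xi <- X[i, , drop = FALSE]
    meat <- meat + as.numeric(e[i]^2 / (1 - h[i])^2) * t(xi) %*% xi
  }
  V_oracle <- XtXinv %*% meat %*% XtXinv
  w <- wald_hc3(y, data.frame(x = X[, 2]), terms = "x")
  expect_equal(unname(w$vcov), unname(V_oracle), tolerance = 1e-10)
  # Wald F for the single slope = b^2 / V[2,2]
  b <- (XtXinv %*% t(X) %*% y)[2]
  expect_equal(w$f_stat, b^2 / V_oracle[2, 2], tolerance = 1e-10)
})

test_that("HC3 F agrees with the classical F under homoscedasticity at n = 2000", {
  set.seed(69)
  n <- 2000
  x <- rnorm(n)
  g <- factor(sample(c("p", "q"), n, TRUE))
  y <- 0.5 * x + 0.3 * (g == "q") + rnorm(n)
  w <- wald_hc3(y, data.frame(x = x, g = g), terms = "x")
  cls <- summary(lm(y ~ x + g))$coefficients["x", "t value"]^2
  expect_lt(abs(w$f_stat - cls) / cls, 0.1)
})

test_that("HC3 Wald p-values are calibrated under the null", {
  set.seed(70)
  reps <- 500
  pvals <- vapply(seq_len(reps), function(r) {
    n <- 50
    x <- rnorm(n)
    y <- rnorm(n) * (1 + 0.5 * abs(x))   # heteroscedastic null
    wald_hc3(y, data.frame(x = x), terms = "x")$p_value
  }, numeric(1))
  frac <- mean(pvals < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.08)
})

test_that("wald_hc3 errors on saturated designs and unknown terms", {
  y <- rnorm(4)
  g <- factor(c("a", "b", "c", "d"))   # one observation per cell
  expect_error(wald_hc3(y, data.frame(g = g), terms = "g"), "leverage")
  expect_error(wald_hc3(rnorm(10), data.frame(x = rnorm(10)), terms = "zz"),
               "no coefficients")
})

test_that("Cox interaction model reports the four-term outcome structure", {
  co <- default_small_cohort()
  s <- co$truth$sample
  fit <- cox_interaction_fit(s$survival_time, s$event, s$treatment,
                             s$mgmt, s$accel, covariate_name = "accel")
  expect_equal(nrow(fit$table), 4)
  expect_true("accel" %in% fit$table$term)
  expect_equal(fit$table$hr, exp(coef(fit$fit)), ignore_attr = TRUE)
  expect_true(is.finite(fit$loglik))
  expect_error(cox_interaction_fit(s$survival_time, rep(0, nrow(s)),
                                   s$treatment, s$mgmt, s$accel),
               "10 events")
})

test_that("null covariate HR is near 1 with nominal CI coverage", {
  params <- list(baseline_rate = 0.55, censoring_rate = 0.15,
                 log_hr_treatment = -0.3, log_hr_mgmt = -0.2,
                 log_hr_interaction = -1.0, log_hr_accel_per_year = 0)
  set.seed(71)
  n <- 500
  trt <- rbinom(n, 1, 0.5); mg <- rbinom(n, 1, 0.5)
  accel <- rnorm(n, 36.8, 24)
  hrs <- numeric(200); covered <- logical(200)
  for (r in 1:200) {
    sv <- simulate_survival(trt, mg, accel, params, seed = 3000 + r)
    fit <- cox_interaction_fit(sv$time, sv$event, trt, mg, accel)
    i <- which(fit$table$term == "covariate")
    b <- log(fit$table$hr[i])
    se <- abs(b / fit$table$z[i])
    if (!is.finite(se)) se <- sqrt(diag(vcov(fit$fit)))[3]
    hrs[r] <- fit$table$hr[i]
    covered[r] <- (b - 1.96 * se) <= 0 && 0 <= (b + 1.96 * se)
  }
  expect_lt(abs(mean(hrs) - 1), 0.1)
  expect_gte(mean(covered), 0.93)
})

test_that("CMH reduces to the closed-form Mantel-Haenszel statistic for K = 1", {
  tbl <- array(c(12, 5, 7, 14), dim = c(2, 2, 1))
  got <- cmh_test(tbl)
  a <- 12; r1 <- 19; c1 <- 17; N <- 38
  expected_a <- r1 * c1 / N
  var_a <- r1 * (N - r1) * c1 * (N - c1) / (N^2 * (N - 1))
  stat <- (a - expected_a)^2 / var_a
  expect_equal(got$statistic, stat, tolerance = 1e-12)
  expect_equal(got$p_value, pchisq(stat, 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("CMH is calibrated under per-stratum odds ratio 1", {
  set.seed(72)
  pvals <- vapply(1:300, function(r) {
    tbl <- array(0, dim = c(2, 2, 3))
    for (k in 1:3) {
      p_row <- runif(1, 0.3, 0.7); p_col <- runif(1, 0.3, 0.7)
      n_k <- 60
      row_i <- rbinom(n_k, 1, p_row); col_i <- rbinom(n_k, 1, p_col)
      tbl[, , k] <- table(factor(row_i, 0:1), factor(col_i, 0:1))
    }
    out <- tryCatch(cmh_test(tbl), error = function(e) NULL)
    if (is.null(out)) NA_real_ else out$p_value
  }, numeric(1))
  frac <- mean(pvals < 0.05, na.rm = TRUE)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.08)
})

test_that("CMH skips zero-margin strata and errors when none remain", {
  tbl <- array(c(10, 5, 8, 9,  0, 0, 3, 4), dim = c(2, 2, 2))
  expect_warning(out <- cmh_test(tbl), "skipped")
  expect_equal(out$k_used, 1)
  degenerate <- array(c(5, 0, 0, 0), dim = c(2, 2, 1))
  expect_error(cmh_test(degenerate), "no informative")
})
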