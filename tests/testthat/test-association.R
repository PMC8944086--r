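make_probe_matrix <- function(values, samples) {
  m <- matrix(values, ncol = samples,
              dimnames = list(sprintf("cg%04d", seq_len(length(values) / samples)),
                              sprintf("s%03d", seq_len(samples))))
  m
}

test_that("single-covariate F equals the squared t of the slope", {
  set.seed(21)
  n <- 40
  x <- rnorm(n)
  Y <- make_probe_matrix(rnorm(30 * n), n)
  res <- dmp_scan(Y, x)
  for (i in c(1, 15, 30)) {
    fit <- summary(lm(Y[i, ] ~ x))
    expect_equal(res$f_stat[i], fit$coefficients["x", "t value"]^2,
                 tolerance = 1e-10)
    expect_equal(res$p_value[i], fit$coefficients["x", "Pr(>|t|)"],
                 tolerance = 1e-10)
  }
})

test_that("dmp_scan matches anova() for a factor covariate", {
  set.seed(22)
  n <- 36
  g <- factor(rep(c("a", "b", "c"), each = 12))
  Y <- make_probe_matrix(rnorm(10 * n), n)
  res <- dmp_scan(Y, g)
  for (i in c(2, 9)) {
    a <- anova(lm(Y[i, ] ~ g))
    expect_equal(res$f_stat[i], a$`F value`[1], tolerance = 1e-10)
    expect_equal(res$p_value[i], a$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("dmp_scan handles degenerate inputs per contract", {
  Y <- rbind(cg0001 = rep(0.5, 8), cg0002 = rnorm(8))
  colnames(Y) <- sprintf("s%03d", 1:8)
  x <- rnorm(8)
  res <- dmp_scan(Y, x)
  expect_equal(res$f_stat[1], 0)      # constant probe
  expect_equal(res$p_value[1], 1)
  expect_error(dmp_scan(Y, rep(3, 8)), "constant covariate")
  expect_error(dmp_scan(Y, rnorm(5)), "length")
})

test_that("dmp_scan is invariant to affine rescaling of the covariate", {
  set.seed(23)
  Y <- make_probe_matrix(rnorm(20 * 30), 30)
  x <- rnorm(30)
  a <- dmp_scan(Y, x)
  b <- dmp_scan(Y, 3.7 * x - 11)
  expect_equal(a$f_stat, b$f_stat, tolerance = 1e-9)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-9)
})

test_that("Bonferroni q is monotone in p and never smaller than p", {
  set.seed(24)
  Y <- make_probe_matrix(rnorm(50 * 25), 25)
  res <- dmp_scan(Y, rnorm(25))
  expect_true(all(res$q_value >= res$p_value))
  o <- order(res$p_value)
  expect_true(all(diff(res$q_value[o]) >= 0))
  expect_true(all(res$q_value <= 1))
  expect_identical(res$is_dmp, res$q_value < 0.1)
})

test_that("null probes give uniform p-values and planted slopes are recovered", {
  # planted-truth cohort: exact slopes (no purity attenuation, no shifts)
  cfg <- quiet_config(n_samples = 150, n_probes = 1200, seed = 303)
  cfg$noise_sd <- 0.03
  cfg$acceleration_model$sd <- 23.99
  co <- generate_cohort(cfg)
  M <- beta_to_m(co$betas)
  accel <- co$truth$sample$accel
  res <- dmp_scan(M, accel)
  fl <- co$truth$probe
  # null set: probes with zero generating slope and no accel-linked mechanism
  null_set <- !(fl$is_accel_dmp | fl$is_clock | fl$is_subtype)
  frac05 <- mean(res$p_value[null_set] < 0.05)
  expect_gt(frac05, 0.02)
  expect_lt(frac05, 0.09)
  expect_gt(mean(res$is_dmp[fl$is_accel_dmp]), 0.8)
  expect_lte(sum(res$is_dmp[null_set]), 2)
})

test_that("functional_scan flags perfect negative and never positive correlation", {
  set.seed(25)
  n <- 20
  b <- matrix(runif(2 * n), nrow = 2,
              dimnames = list(c("cgN", "cgP"), sprintf("s%02d", 1:n)))
  ann <- tiny_annotation(rownames(b), promoter = TRUE)
  ann$gene <- c("GNEG", "GPOS")
  expr <- rbind(GNEG = -rank(b["cgN", ]), GPOS = rank(b["cgP", ]))
  colnames(expr) <- colnames(b)
  res <- functional_scan(b, expr, ann)
  expect_equal(res$rho[res$probe_id == "cgN"], -1)
  expect_true(res$is_functional[res$probe_id == "cgN"])
  expect_equal(res$rho[res$probe_id == "cgP"], 1)
  expect_false(res$is_functional[res$probe_id == "cgP"])
})

test_that("functional_scan recovers planted couplings with few false flags", {
  cfg <- quiet_config(n_samples = 150, n_probes = 1200, seed = 404)
  cfg$noise_sd <- 0.03
  co <- generate_cohort(cfg)
  res <- functional_scan(co$betas, co$expression, co$annotation)
  truth_ids <- co$truth$probe$probe_id[co$truth$probe$is_functional]
  hits <- res$probe_id[res$is_functional]
  expect_gte(length(intersect(hits, truth_ids)), 16)
  expect_lte(length(setdiff(hits, truth_ids)), 2)
})

test_that("functional_scan skips genes absent from expression and counts them", {
  b <- tiny_beta_matrix(3, 12)
  ann <- tiny_annotation(rownames(b), promoter = TRUE)
  ann$gene <- c("IN1", "MISSING", "IN2")
  expr <- matrix(rnorm(24), 2, 12,
                 dimnames = list(c("IN1", "IN2"), colnames(b)))
  res <- functional_scan(b, expr, ann)
  expect_equal(attr(res, "n_skipped"), 1)
  expect_setequal(res$probe_id, c("cg001", "cg003"))
})

test_that("hypergeometric enrichment matches combinatorial oracles", {
  universe <- sprintf("g%02d", 1:20)
  res <- hypergeom_gsea(universe[1:5], list(hit = universe[1:5]), universe)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  # tail p equals direct summation of point masses j >= k
  set.seed(26)
  for (r in 1:20) {
    N <- sample(20:60, 1); K <- sample(3:10, 1); nq <- sample(3:15, 1)
    uni <- sprintf("u%03d", seq_len(N))
    gs <- list(s = sample(uni, K))
    q <- sample(uni, nq)
    k <- length(intersect(q, gs$s))
    direct <- sum(dhyper(k:min(K, nq), K, N - K, nq))
    got <- hypergeom_gsea(q, gs, uni)$p_value
    expect_equal(got, direct, tolerance = 1e-12)
  }
})

test_that("empty query enriches nothing and empty universe errors", {
  uni <- letters[1:10]
  res <- hypergeom_gsea(character(0), list(s = uni[1:3]), uni)
  expect_false(any(res$significant))
  expect_error(hypergeom_gsea("a", list(s = "a"), character(0)), "universe")
  expect_error(hypergeom_gsea("zzz", list(s = uni[1:3]), uni), "outside")
})

test_that("scan overlap counts obey inclusion-exclusion bounds", {
  co <- default_small_cohort()
  M <- beta_to_m(co$betas)
  s <- co$truth$sample
  a <- dmp_scan(M, s$age); b <- dmp_scan(M, s$accel)
  A <- a$probe_id[a$is_dmp]; B <- b$probe_id[b$is_dmp]
  expect_lte(length(intersect(A, B)), min(length(A), length(B)))
  expect_equal(length(union(A, B)),
               length(A) + length(B) - length(intersect(A, B)))
})
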