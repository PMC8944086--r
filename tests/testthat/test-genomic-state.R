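test_that("copy-number log-ratios recover planted intensity changes", {
  set.seed(41)
  p <- 200
  ids <- sprintf("cg%04d", 1:p)
  ref <- setNames(rep(2000, p), ids)
  beta <- runif(p, 0.2, 0.8)
  total <- rep(2000, p)
  total[51:70] <- 4000          # doubled region
  total[101:120] <- 200         # planted HD (x0.1)
  meth <- matrix(total * beta, ncol = 1, dimnames = list(ids, "s1"))
  unmeth <- matrix(total * (1 - beta), ncol = 1, dimnames = list(ids, "s1"))
  lr <- copy_number_logratio(meth, unmeth, ref)
  expect_equal(median(lr[1:50, 1]), 0, tolerance = 1e-10)
  expect_equal(mean(lr[51:70, 1]), 1, tolerance = 1e-10)
  expect_equal(mean(lr[101:120, 1]), log2(0.1), tolerance = 1e-10)
  # identical to reference -> all zero after centering
  meth0 <- matrix(2000 * beta, ncol = 1, dimnames = list(ids, "s1"))
  unm0 <- matrix(2000 * (1 - beta), ncol = 1, dimnames = list(ids, "s1"))
  expect_lt(max(abs(copy_number_logratio(meth0, unm0, ref))), 1e-12)
  # zero totals masked
  methz <- meth; methz[1, 1] <- 0; unmz <- unmeth; unmz[1, 1] <- 0
  expect_true(is.na(copy_number_logratio(methz, unmz, ref)[1, 1]))
  expect_error(copy_number_logratio(-meth, unmeth, ref), "non-negative")
})

test_that("CBS finds a planted single step within 3 probes", {
  set.seed(42)
  x <- c(rnorm(100, 0, 0.2), rnorm(100, 1, 0.2))
  segs <- cbs_segment(x, n_perm = 500, seed = 7)
  expect_equal(nrow(segs), 2)
  expect_lte(abs(segs$end_index[1] - 100), 3)
  expect_lt(abs(segs$seg_mean[1] - 0), 0.1)
  expect_lt(abs(segs$seg_mean[2] - 1), 0.1)
})

test_that("CBS recovers two nested steps and tiles the probes exactly", {
  set.seed(43)
  x <- c(rnorm(80, 0, 0.2), rnorm(60, 1.2, 0.2), rnorm(80, -0.2, 0.2))
  segs <- cbs_segment(x, n_perm = 500, seed = 8)
  expect_gte(nrow(segs), 3)
  bks <- segs$end_index[-nrow(segs)]
  expect_true(any(abs(bks - 80) <= 3))
  expect_true(any(abs(bks - 140) <= 3))
  # tiling: consecutive, covering all probes
  expect_equal(segs$start_index[1], 1)
  expect_equal(segs$end_index[nrow(segs)], 220)
  expect_true(all(segs$start_index[-1] == segs$end_index[-nrow(segs)] + 1))
  expect_equal(sum(segs$n_probes), 220)
  # means near truth
  truth_means <- c(0, 1.2, -0.2)
  got <- segs$seg_mean[order(segs$start_index)][1:3]
  expect_lt(max(abs(got - truth_means)), 0.12)
})

test_that("CBS leaves flat noise unsegmented in most seeded runs", {
  set.seed(44)
  one_seg <- vapply(1:40, function(r) {
    x <- rnorm(100, 0, 0.2)
    nrow(cbs_segment(x, n_perm = 200, seed = r)) == 1
  }, logical(1))
  expect_gte(mean(one_seg), 0.95)
})

test_that("CBS never crosses chromosome boundaries", {
  set.seed(45)
  x <- c(rnorm(60, 0, 0.2), rnorm(60, 2, 0.2))
  chrom <- rep(c("chr1", "chr2"), each = 60)
  segs <- cbs_segment(x, chrom = chrom, n_perm = 200, seed = 2)
  expect_setequal(unique(segs$chrom), c("chr1", "chr2"))
  for (ch in c("chr1", "chr2")) {
    s <- segs[segs$chrom == ch, ]
    expect_equal(sum(s$n_probes), 60)
  }
})

test_that("segments export to BED with 0-based half-open coordinates", {
  segs <- data.frame(chrom = "chr1", start = 1, end = 100,
                     start_index = 1, end_index = 100, n_probes = 100,
                     seg_mean = 0.5, p_value = NA)
  path <- withr::local_tempfile(fileext = ".bed")
  write_segments_bed(segs, path)
  bed <- read.table(path, sep = "\t")
  expect_equal(bed$V2, 0)
  expect_equal(bed$V3, 100)
})

test_that("CDKN2A mixture separates a planted bimodal cohort", {
  set.seed(46)
  truth <- rep(c(FALSE, TRUE), c(60, 60))
  cn <- setNames(ifelse(truth, rnorm(120, -3, 0.3), rnorm(120, 0, 0.3)),
                 sprintf("s%03d", 1:120))
  call <- cdkn2a_hd_call(cn)
  expect_gte(mean(call$hd == truth), 0.98)
  # posteriors are probabilities of the lower component
  expect_true(all(call$posterior_hd >= 0 & call$posterior_hd <= 1))
})

test_that("CDKN2A call degenerates to no-HD on unimodal or constant input", {
  set.seed(47)
  expect_equal(sum(cdkn2a_hd_call(rnorm(60, 0, 0.3))$hd), 0)
  expect_warning(out <- cdkn2a_hd_call(rep(0.1, 25)), "identical")
  expect_false(any(out$hd))
  expect_error(cdkn2a_hd_call(rnorm(10)), "at least 20")
})

test_that("purity estimation recovers constructed mixtures", {
  set.seed(48)
  p <- 300
  ids <- sprintf("cg%04d", 1:p)
  tum <- setNames(ifelse(runif(p) < 0.5, runif(p, 0, 0.2),
                         runif(p, 0.8, 1)), ids)
  nor <- setNames(1 - tum + rnorm(p, 0, 0.02), ids)
  nor <- pmin(pmax(nor, 0), 1)
  mk <- function(w) {
    m <- matrix(w * tum + (1 - w) * nor, ncol = 1,
                dimnames = list(ids, "s"))
    m
  }
  expect_lt(estimate_purity(mk(0), tum, nor), 0.02)
  expect_gt(estimate_purity(mk(1), tum, nor), 0.98)
  expect_equal(unname(estimate_purity(mk(0.5), tum, nor)), 0.5,
               tolerance = 0.02)
  # monotone in the constructed weight
  ws <- seq(0.1, 0.9, by = 0.2)
  est <- vapply(ws, function(w) unname(estimate_purity(mk(w), tum, nor)),
                numeric(1))
  expect_true(all(diff(est) > 0))
  # no informative probes -> error
  flat <- setNames(rep(0.5, p), ids)
  expect_error(estimate_purity(mk(0.5), flat, flat), "informative")
})

test_that("MGMT-STP27 contract: inverse-logit, boundary rule, monotonicity", {
  m <- matrix(c(0, 0), 2, 1,
              dimnames = list(c("cg12434587", "cg12981137"), "s1"))
  call <- mgmt_stp27(m, c(0, 1, 1))
  expect_equal(call$probability, 0.5)
  expect_identical(call$status, "M")          # 0.5 >= 0.358
  expect_equal(call$score, 0)
  # probability exactly at the cutoff classifies M
  lp_cut <- qlogis(0.358)
  m2 <- matrix(c(lp_cut, 0), 2, 1,
               dimnames = list(c("cg12434587", "cg12981137"), "s1"))
  expect_identical(mgmt_stp27(m2, c(0, 1, 1))$status, "M")
  # monotone in each M-value for positive slopes
  grid <- seq(-6, 6, by = 0.5)
  probs1 <- vapply(grid, function(v) {
    mm <- matrix(c(v, 1), 2, 1,
                 dimnames = list(c("cg12434587", "cg12981137"), "s1"))
    mgmt_stp27(mm, c(0.5, 1.2, 0.8))$probability
  }, numeric(1))
  expect_true(all(diff(probs1) > 0))
  # missing probe errors with its name
  m3 <- matrix(0, 1, 1, dimnames = list("cg12434587", "s1"))
  expect_error(mgmt_stp27(m3, c(0, 1, 1)), "cg12981137")
  expect_error(mgmt_stp27(m, c(0, 1)), "intercept")
})

test_that("Ward clustering recovers well-separated blobs; labels are stable", {
  set.seed(49)
  p <- 60
  a <- matrix(rnorm(p * 10, 0), nrow = p)
  b <- matrix(rnorm(p * 10, 4), nrow = p)
  M <- cbind(a, b)
  dimnames(M) <- list(sprintf("cg%03d", 1:p), sprintf("s%02d", 1:20))
  res <- gcimp_cluster(M)
  expect_equal(length(unique(res$cluster[1:10])), 1)
  expect_equal(length(unique(res$cluster[11:20])), 1)
  expect_true(res$cluster[1] != res$cluster[11])
  # high-methylation cluster carries the G-CIMP flag
  expect_true(all(res$gcimp[11:20]))
  # duplicated sample gets the same label
  M2 <- cbind(M, dup = M[, 1])
  colnames(M2)[21] <- "dup"
  res2 <- gcimp_cluster(M2)
  expect_equal(res2$cluster[21], res2$cluster[1])
  # permutation invariance up to relabeling
  perm <- sample(20)
  res3 <- gcimp_cluster(M[, perm])
  expect_equal(res3$gcimp[match(res$sample_id, res3$sample_id)], res$gcimp)
})

test_that("nearest-centroid subtyping is exact on centroids and breaks ties first-label", {
  p <- 30
  cent <- matrix(c(rep(0.2, p), rep(0.5, p), rep(0.8, p)), ncol = 3,
                 dimnames = list(sprintf("cg%03d", 1:p),
                                 c("MES", "RTK_I", "RTK_II")))
  m <- meth_matrix(cbind(s1 = cent[, "RTK_I"]), "beta")
  expect_identical(unname(nearest_centroid_subtype(m, cent)), "RTK_I")
  # equidistant between MES and RTK_I -> MES by column order
  mid <- cbind(s2 = rep(0.35, p))
  rownames(mid) <- rownames(cent)
  expect_identical(unname(nearest_centroid_subtype(meth_matrix(mid, "beta"),
                                                   cent)), "MES")
})

test_that("planted subtypes are recovered at >= 95% accuracy", {
  cfg <- quiet_config(n_samples = 100, seed = 505)
  cfg$noise_sd <- 0.03
  co <- generate_cohort(cfg)
  lab <- nearest_centroid_subtype(co$betas, co$truth$centroids)
  expect_gte(mean(lab == co$truth$sample$subtype), 0.95)
})
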