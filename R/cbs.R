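#' Circular binary segmentation of copy-number log-ratios
#'
#' Recursive circular binary segmentation: within a segment of m ordered
#' probes, the candidate change is the arc (i, j] maximizing the normalized
#' mean difference between the arc and its complement,
#' `T = |mean_arc - mean_rest| / (s * sqrt(1/k + 1/(m-k)))`. The split is
#' accepted when the permutation p-value of max |T| (probes shuffled within
#' the segment) falls below `alpha`, using the `(1 + b) / (1 + B)` estimator;
#' accepted boundaries inside the segment become breakpoints and the
#' subsegments are revisited. Arcs narrower than `min_width` on either side
#' are not considered.
#'
#' @param logratio numeric vector of per-probe log2 ratios, ordered by
#'   genomic position.
#' @param chrom optional chromosome label per probe; segmentation never
#'   crosses a chromosome boundary.
#' @param pos optional 1-based probe positions (defaults to the probe index).
#' @param alpha acceptance level for the permutation test (default 0.01).
#' @param n_perm permutations per tested segment (default 1000).
#' @param min_width minimum probes per segment side (default 3).
#' @param seed integer seed for the permutation stream.
#' @return data.frame of segments: `chrom`, `start`, `end` (1-based
#'   inclusive probe positions), `start_index`, `end_index`, `n_probes`,
#'   `seg_mean`, `p_value` (permutation p of the split that created the
#'   segment's outer boundary; NA for never-split segments). Segments tile
#'   the probes of each chromosome exactly.
#' @export
cbs_segment <- function(logratio, chrom = NULL, pos = NULL, alpha = 0.01,
                        n_perm = 1000, min_width = 3, seed = 1) {
  n <- length(logratio)
  if (is.null(chrom)) chrom <- rep("chr1", n)
  if (is.null(pos)) pos <- seq_len(n)
  stopifnot(length(chrom) == n, length(pos) == n)

  segs <- list()
  with_block_seed(seed, "permutation", function() {
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      x <- logratio[idx]
      pieces <- cbs_recurse(x, alpha = alpha, n_perm = n_perm,
                            min_width = min_width)
      for (pc in pieces) {
        i0 <- idx[pc$from]
        i1 <- idx[pc$to]
        segs[[length(segs) + 1L]] <<- data.frame(
          chrom = ch, start = pos[i0], end = pos[i1],
          start_index = i0, end_index = i1,
          n_probes = pc$to - pc$from + 1L,
          seg_mean = mean(x[pc$from:pc$to]),
          p_value = pc$p, stringsAsFactors = FALSE
        )
      }
    }
  })
  do.call(rbind, segs)
}

# Candidate arcs (i, j] for a segment of m probes: i in 0..m-1, j in
# i+1..m; i = 0 or j = m yield a single internal boundary. Precomputed once
# per segment and reused across permutations.
arc_index <- function(m, min_width) {
  ij <- which(upper.tri(matrix(FALSE, m + 1, m + 1)), arr.ind = TRUE)
  i <- ij[, 1] - 1L
  j <- ij[, 2] - 1L
  k <- j - i
  ok <- k >= min_width & (m - k) >= min_width
  list(i = i[ok], j = j[ok], k = k[ok],
       w = sqrt(1 / k[ok] + 1 / (m - k[ok])))
}

# Max circular-arc statistic given precomputed arc indices.
max_arc_stat <- function(x, idx) {
  m <- length(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0 || length(idx$i) == 0) {
    return(list(stat = 0, i = 0L, j = 0L))
  }
  cs <- c(0, cumsum(x))
  total <- cs[m + 1]
  arc_sum <- cs[idx$j + 1] - cs[idx$i + 1]
  t_stat <- abs(arc_sum / idx$k - (total - arc_sum) / (m - idx$k)) /
    (s * idx$w)
  best <- which.max(t_stat)
  list(stat = t_stat[best], i = idx$i[best], j = idx$j[best])
}

# Permutation max-arc statistics; vectorized over arcs per permutation.
perm_arc_stats <- function(x, n_perm, idx) {
  vapply(seq_len(n_perm), function(b) {
    max_arc_stat(sample(x), idx)$stat
  }, numeric(1))
}

cbs_recurse <- function(x, alpha, n_perm, min_width, p_in = NA_real_) {
  m <- length(x)
  if (m < 2 * min_width) {
    return(list(list(from = 1L, to = m, p = p_in)))
  }
  idx <- arc_index(m, min_width)
  obs <- max_arc_stat(x, idx)
  if (obs$stat == 0) return(list(list(from = 1L, to = m, p = p_in)))
  null_stats <- perm_arc_stats(x, n_perm, idx)
  p <- (1 + sum(null_stats >= obs$stat)) / (1 + n_perm)
  if (p >= alpha) {
    return(list(list(from = 1L, to = m, p = p_in)))
  }
  cuts <- sort(unique(c(obs$i, obs$j)))
  cuts <- cuts[cuts > 0 & cuts < m]
  bounds <- c(0L, cuts, m)
  out <- list()
  for (b in seq_len(length(bounds) - 1L)) {
    lo <- bounds[b] + 1L
    hi <- bounds[b + 1L]
    sub <- cbs_recurse(x[lo:hi], alpha, n_perm, min_width, p_in = p)
    for (pc in sub) {
      out[[length(out) + 1L]] <- list(from = pc$from + lo - 1L,
                                      to = pc$to + lo - 1L, p = pc$p)
    }
  }
  out
}

#' Write segments as BED
#'
#' Converts the internal 1-based inclusive coordinates to BED's 0-based
#' half-open convention.
#'
#' @param segments data.frame from [cbs_segment()].
#' @param path output path.
#' @export
write_segments_bed <- function(segments, path) {
  bed <- data.frame(chrom = segments$chrom,
                    start = segments$start - 1L,
                    end = segments$end,
                    name = sprintf("seg%03d", seq_len(nrow(segments))),
                    score = segments$seg_mean)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
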