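# Internal helpers shared across modules.

# Child seed for a named pseudo-random block. Each logical block of a
# simulation draws from its own stream derived from the master seed, so
# enlarging one block (e.g. adding probes) does not perturb the draws of
# another (e.g. survival times). Kept below 2^31 - 1.
child_seed <- function(seed, block) {
  offsets <- c(
    probes = 11L, annotation = 23L, subjects = 37L, clock = 41L,
    dmp = 53L, functional = 67L, expression = 71L, batch = 83L,
    noise = 97L, survival = 101L, cnv = 113L, purity = 127L,
    mgmt = 131L, permutation = 139L, misc = 149L, baseline = 151L
  )
  off <- offsets[[block]]
  (as.integer(seed) %% 1000000L) * 1000L + off
}

# Evaluate fn under a local RNG state seeded from (seed, block); the caller's
# RNG state is untouched.
with_block_seed <- function(seed, block, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(child_seed(seed, block))
  fn()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_probability <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
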