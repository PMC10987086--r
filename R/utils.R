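# Internal helpers shared across the package.

# Derive independent sub-seeds from one user-facing seed. Keeps every derived
# seed a valid 32-bit integer so results are portable across platforms.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

# Sample-SD (n - 1) of the columns of a matrix, without apply() overhead.
col_sds <- function(x) {
  n <- nrow(x)
  m <- colMeans(x)
  sqrt(pmax(colSums(x^2) - n * m^2, 0) / (n - 1))
}

# Draw from Normal(mean, sd) truncated to (0, Inf) by redrawing; `mean` may be
# a vector. Falls back to a tiny positive floor if a cell cannot converge
# (pathological sd >> mean), which keeps downstream Weber fractions finite.
rnorm_pos <- function(n, mean, sd) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= 0)
  tries <- 0L
  while (length(bad) > 0 && tries < 100L) {
    x[bad] <- rnorm(length(bad), if (length(mean) > 1) mean[bad] else mean,
                    if (length(sd) > 1) sd[bad] else sd)
    bad <- bad[x[bad] <= 0]
    tries <- tries + 1L
  }
  if (length(bad) > 0) x[bad] <- .Machine$double.eps
  x
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}
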