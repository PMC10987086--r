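#' Numerical distance between two targets
#'
#' The base-10 logarithm of the ratio between two target levels, in absolute
#' value: `|log10(a / b)|`. Symmetric; zero iff `a == b`. Vectorised.
#'
#' @param a,b Positive target levels.
#' @return Non-negative numeric distance(s) in log10-ratio units.
#' @export
#' @examples
#' numerical_distance(8, 32)   # log10(4)
#' numerical_distance(14, 16)
numerical_distance <- function(a, b) {
  if (any(a <= 0) || any(b <= 0)) abort("Targets must be positive.")
  abs(log10(a / b))
}

#' Inter-participant correlation matrix of Weber fractions
#'
#' Pearson correlation, across participants, between the Weber-fraction
#' vectors of every pair of targets. High correlations between nearby targets
#' are the signature of a shared channel.
#'
#' @param wfm A [wf_matrix] with >= 3 participants and >= 2 targets.
#' @return A `corr_matrix`: a symmetric targets x targets correlation matrix
#'   with unit diagonal, carrying its target levels as dimnames.
#' @export
wf_correlation_matrix <- function(wfm) {
  v <- wf_values(wfm)
  if (nrow(v) < 3) abort("Need >= 3 participants to correlate across participants.")
  if (ncol(v) < 2) abort("Need >= 2 targets.")
  sds <- col_sds(v)
  if (any(sds == 0)) {
    bad <- wf_targets(wfm)[sds == 0]
    abort(sprintf("Target(s) with zero between-participant variance: %s (correlation undefined).",
                  paste(bad, collapse = ", ")))
  }
  new_corr_matrix(cor(v), wf_targets(wfm))
}

#' @rdname wf_correlation_matrix
#' @param values Symmetric correlation matrix.
#' @param targets Target levels labelling rows/columns.
#' @export
new_corr_matrix <- function(values, targets) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == ncol(values), length(targets) == nrow(values))
  dimnames(values) <- list(as.character(targets), as.character(targets))
  structure(values, targets = as.numeric(targets), class = c("corr_matrix", "matrix", "array"))
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat(sprintf("<corr_matrix: %d targets>\n", nrow(x)))
  print(round(unclass(x), 3))
  invisible(x)
}

corr_targets <- function(corr) attr(corr, "targets") %||% as.numeric(rownames(corr))

#' Tidy a correlation matrix into target pairs
#'
#' One row per unordered off-diagonal target pair, with the pair's numerical
#' distance attached.
#'
#' @param x A `corr_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `target_a`, `target_b`, `distance`, `r`.
#' @method tidy corr_matrix
#' @export
tidy.corr_matrix <- function(x, ...) {
  targets <- corr_targets(x)
  ut <- which(upper.tri(x), arr.ind = TRUE)
  tibble::tibble(
    target_a = targets[ut[, 1]],
    target_b = targets[ut[, 2]],
    distance = numerical_distance(targets[ut[, 1]], targets[ut[, 2]]),
    r = unclass(x)[ut]
  )
}

#' Default numerical-distance bins
#'
#' The six log10-ratio bins used to summarise correlation as a function of
#' numerical distance: <0.08, 0.08–0.14, 0.14–0.21, 0.21–0.29, 0.29–0.39,
#' >0.39. Bins are half-open `[lo, hi)`; together they partition (0, Inf).
#'
#' @return Numeric vector of interior bin edges.
#' @export
default_distance_bins <- function() {
  c(0.08, 0.14, 0.21, 0.29, 0.39)
}

bin_labels <- function(edges) {
  c(sprintf("<%g", edges[1]),
    sprintf("%g-%g", head(edges, -1), tail(edges, -1)),
    sprintf(">%g", tail(edges, 1)))
}

assign_bins <- function(distance, edges) {
  findInterval(distance, edges, left.open = FALSE) + 1L
}

#' Correlation as a function of numerical distance, binned
#'
#' Averages the off-diagonal correlation coefficients (each unordered pair
#' once; 55 pairs for 11 targets) within numerical-distance bins.
#'
#' @param corr A `corr_matrix` from [wf_correlation_matrix()].
#' @param edges Interior bin edges in log10-ratio units
#'   (default [default_distance_bins()]).
#' @return A tibble with one row per bin: `bin` (label), `lo`, `hi`,
#'   `mean_r`, `n_pairs`. Empty bins keep `n_pairs = 0` and `mean_r = NA`.
#' @export
binned_correlation_curve <- function(corr, edges = default_distance_bins()) {
  if (is.unsorted(edges, strictly = TRUE) || any(edges <= 0)) {
    abort("`edges` must be strictly increasing and positive.")
  }
  pairs <- tidy.corr_matrix(corr)
  idx <- assign_bins(pairs$distance, edges)
  k <- length(edges) + 1L
  mean_r <- vapply(seq_len(k), function(i) {
    if (any(idx == i)) mean(pairs$r[idx == i]) else NA_real_
  }, numeric(1))
  tibble::tibble(
    bin = bin_labels(edges),
    lo = c(0, edges),
    hi = c(edges, Inf),
    mean_r = mean_r,
    n_pairs = vapply(seq_len(k), function(i) sum(idx == i), integer(1))
  )
}

#' Linear dependence of correlation on numerical distance
#'
#' Ordinary least-squares fit of the off-diagonal correlation coefficients
#' (unbinned, each unordered pair once) against numerical distance. A
#' negative slope indicates channel-like tuning; a flat slope indicates a
#' single untuned mechanism.
#'
#' @param corr A `corr_matrix`.
#' @return A list with `slope`, `stderr`, `p_value`, `intercept`, `n_pairs`.
#' @export
distance_slope <- function(corr) {
  pairs <- tidy.corr_matrix(corr)
  if (length(unique(pairs$distance)) < 3) {
    abort("Need >= 3 distinct numerical distances for the slope fit.")
  }
  fit <- lm(r ~ distance, data = pairs)
  s <- summary(fit)$coefficients
  list(slope = unname(s["distance", "Estimate"]),
       stderr = unname(s["distance", "Std. Error"]),
       p_value = unname(s["distance", "Pr(>|t|)"]),
       intercept = unname(s["(Intercept)", "Estimate"]),
       n_pairs = nrow(pairs))
}

# Fast slope of r against precomputed distances (no lm overhead).
slope_only <- function(r, d) {
  dc <- d - mean(d)
  sum(dc * r) / sum(dc^2)
}

#' Permutation null for the distance-correlation structure
#'
#' On each iteration, each participant's Weber fractions are shuffled across
#' targets (preserving every participant's multiset of values), the
#' correlation matrix recomputed, and the binned curve and unbinned slope
#' recorded. Under this null any dependence of correlation on numerical
#' distance is destroyed while the marginal pairing structure is preserved.
#'
#' @param wfm A [wf_matrix].
#' @param n_iter Number of permutation iterations (default 10000).
#' @param seed Integer seed.
#' @param edges Distance-bin edges (default [default_distance_bins()]).
#' @return An object of class `shuffle_null`: a list with `null_curve`
#'   (per-bin mean correlation across iterations), `slopes` (null slope
#'   distribution), `observed_slope`, `p_value` (two-sided empirical p for
#'   the observed slope), `n_iter`, `seed`.
#' @export
shuffle_null <- function(wfm, n_iter = 10000, seed = 1,
                         edges = default_distance_bins()) {
  if (n_iter < 1) abort("`n_iter` must be >= 1.")
  v <- wf_values(wfm)
  targets <- wf_targets(wfm)
  n_t <- length(targets)
  dm <- numerical_distance(rep(targets, n_t), rep(targets, each = n_t))
  ut <- upper.tri(matrix(0, n_t, n_t))
  d <- matrix(dm, n_t, n_t)[ut]
  idx <- assign_bins(d, edges)
  k <- length(edges) + 1L
  obs <- distance_slope(wf_correlation_matrix(wfm))$slope
  res <- withr::with_seed(as.integer(seed), {
    slopes <- numeric(n_iter)
    bin_sums <- matrix(0, n_iter, k)
    perm <- v
    for (it in seq_len(n_iter)) {
      for (i in seq_len(nrow(v))) perm[i, ] <- v[i, sample.int(n_t)]
      r <- cor(perm)[ut]
      slopes[it] <- slope_only(r, d)
      bin_sums[it, ] <- vapply(seq_len(k), function(b) {
        if (any(idx == b)) mean(r[idx == b]) else NA_real_
      }, numeric(1))
    }
    list(slopes = slopes, bins = bin_sums)
  })
  null_curve <- tibble::tibble(
    bin = bin_labels(edges),
    lo = c(0, edges),
    hi = c(edges, Inf),
    mean_r = colMeans(res$bins),
    n_pairs = vapply(seq_len(k), function(b) sum(idx == b), integer(1))
  )
  p <- (1 + sum(abs(res$slopes) >= abs(obs))) / (n_iter + 1)
  structure(
    list(null_curve = null_curve, slopes = res$slopes,
         observed_slope = obs, p_value = p, n_iter = n_iter, seed = seed),
    class = "shuffle_null"
  )
}

#' @export
print.shuffle_null <- function(x, ...) {
  cat(sprintf("<shuffle_null: %d iterations>\n", x$n_iter))
  cat(sprintf("  observed slope: %.3f (two-sided empirical p = %.4g)\n",
              x$observed_slope, x$p_value))
  cat(sprintf("  null slope mean %.4f, sd %.4f\n", mean(x$slopes), sd(x$slopes)))
  invisible(x)
}

#' Read/write a correlation matrix as CSV
#'
#' Targets label both the header row and a leading `target` column.
#'
#' @param corr A `corr_matrix`.
#' @param path File path.
#' @return `write_corr_matrix()` returns `path` invisibly;
#'   `read_corr_matrix()` a `corr_matrix`.
#' @export
write_corr_matrix <- function(corr, path) {
  df <- tibble::as_tibble(as.data.frame(unclass(corr)), .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble::tibble(target = corr_targets(corr)), df)
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_corr_matrix
#' @export
read_corr_matrix <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(names(x)[1] == "target")
  new_corr_matrix(as.matrix(x[, -1]), x$target)
}
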