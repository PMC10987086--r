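test_that("numerical distance is the absolute log10 ratio", {
  expect_equal(numerical_distance(8, 32), log10(4))
  expect_equal(numerical_distance(32, 8), log10(4))
  expect_equal(numerical_distance(14, 16), abs(log10(14 / 16)))
  expect_equal(numerical_distance(17, 17), 0)
  expect_error(numerical_distance(-1, 8))
  expect_error(numerical_distance(8, 0))
})

test_that("the correlation matrix matches an independent Pearson computation", {
  # perfect correlation / anticorrelation
  w1 <- wfm_from_matrix(cbind(c(1, 2, 3), c(1, 2, 3), c(3, 2, 1)), c(8, 16, 32))
  cm <- wf_correlation_matrix(w1)
  expect_equal(unclass(cm)["8", "16"], 1)
  expect_equal(unclass(cm)["8", "32"], -1)
  expect_equal(unclass(cm), t(unclass(cm)))
  expect_equal(diag(unclass(cm)), setNames(rep(1, 3), c("8", "16", "32")))
  # brute-force oracle on random 5x4 matrices
  set.seed(99)
  for (rep in 1:5) {
    v <- matrix(runif(20, 0.1, 0.3), 5, 4)
    w <- wfm_from_matrix(v, c(8, 11, 16, 24))
    cm <- unclass(wf_correlation_matrix(w))
    for (i in 1:3) for (j in (i + 1):4) {
      expect_equal(cm[i, j], pearson_oracle(v[, i], v[, j]), tolerance = 1e-12)
    }
  }
  # degenerate target named in the error
  v <- cbind(c(1, 2, 3), rep(0.2, 3))
  expect_error(wf_correlation_matrix(wfm_from_matrix(v, c(8, 16))), "16")
  expect_error(wf_correlation_matrix(wfm_from_matrix(v[1:2, ], c(8, 16))), "participants")
})

test_that("distance binning uses each unordered pair once with the printed edges", {
  cfg <- two_channel_config()
  w <- simulate_cohort(cfg, 10, seed = 1)
  curve <- binned_correlation_curve(wf_correlation_matrix(w))
  expect_equal(sum(curve$n_pairs), choose(11, 2))
  expect_equal(curve$lo, c(0, 0.08, 0.14, 0.21, 0.29, 0.39))
  # hand assignment of a boundary-near pair: d(8,10) = 0.0969 -> second bin
  d <- numerical_distance(8, 10)
  expect_true(d >= 0.08 && d < 0.14)
  pairs <- tidy(wf_correlation_matrix(w))
  manual <- pairs |>
    dplyr::mutate(bin = cut(distance, c(0, 0.08, 0.14, 0.21, 0.29, 0.39, Inf),
                            right = FALSE)) |>
    dplyr::group_by(bin) |>
    dplyr::summarise(mean_r = mean(r), n = dplyr::n())
  expect_equal(curve$n_pairs[curve$n_pairs > 0], manual$n)
  expect_equal(curve$mean_r[curve$n_pairs > 0], manual$mean_r, tolerance = 1e-12)
  # constant off-diagonal correlations give the constant in every bin
  m <- matrix(0.4, 4, 4); diag(m) <- 1
  const <- binned_correlation_curve(new_corr_matrix(m, c(8, 10, 16, 32)))
  expect_true(all(abs(const$mean_r[const$n_pairs > 0] - 0.4) < 1e-12))
})

test_that("the distance slope recovers constructed linear structure", {
  targets <- numchan_targets()
  n_t <- length(targets)
  d <- outer(targets, targets, function(a, b) numerical_distance(a, b))
  # r = 1 - d by construction: slope exactly -1
  m <- 1 - d; diag(m) <- 1
  s <- suppressWarnings(distance_slope(new_corr_matrix(m, targets)))
  expect_equal(s$slope, -1, tolerance = 1e-10)
  expect_lt(s$stderr, 1e-10)
  # constant off-diagonal: slope 0
  m0 <- matrix(0.3, n_t, n_t); diag(m0) <- 1
  s0 <- suppressWarnings(distance_slope(new_corr_matrix(m0, targets)))
  expect_equal(s0$slope, 0, tolerance = 1e-12)
  expect_equal(s$n_pairs, choose(n_t, 2))
})

test_that("the shuffle null is seeded, unbiased in slope, and mean-preserving", {
  cfg <- two_channel_config()
  w <- simulate_cohort(cfg, 20, seed = 21, mode = "trials")
  n1 <- shuffle_null(w, n_iter = 400, seed = 5)
  n2 <- shuffle_null(w, n_iter = 400, seed = 5)
  expect_identical(n1$slopes, n2$slopes)
  expect_identical(n1$null_curve, n2$null_curve)
  # expected null slope ~ 0
  se <- sd(n1$slopes) / sqrt(length(n1$slopes))
  expect_lt(abs(mean(n1$slopes)), 3 * se)
  # permutation preserves the marginal pairing structure: the grand mean of
  # off-diagonal correlations matches the observed grand mean in expectation
  obs <- tidy(wf_correlation_matrix(w))
  obs_grand <- mean(obs$r)
  null_grand <- sum(n1$null_curve$mean_r * n1$null_curve$n_pairs) /
    sum(n1$null_curve$n_pairs)
  expect_lt(abs(null_grand - obs_grand), 0.05)
  # observed two-channel slope is extreme under its own null
  expect_lt(n1$p_value, 0.05)
})

test_that("correlation matrices round-trip through CSV", {
  cfg <- two_channel_config()
  cm <- wf_correlation_matrix(simulate_cohort(cfg, 8, seed = 2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_corr_matrix(cm, path)
  back <- read_corr_matrix(path)
  expect_equal(unclass(back), unclass(cm), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(as.numeric(rownames(back)), numchan_targets())
})
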