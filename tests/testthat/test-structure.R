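test_that("z-scoring standardises each target and is idempotent", {
  v <- cbind(c(1, 2, 3), c(10, 30, 20), c(5, 5.5, 6.5))
  w <- wfm_from_matrix(v, c(8, 16, 32))
  z <- zscore_targets(w)
  zv <- wf_values(z)
  expect_equal(unname(zv[, 1]), c(-1, 0, 1))
  expect_true(all(abs(colMeans(zv)) < 1e-12))
  expect_true(all(abs(apply(zv, 2, sd) - 1) < 1e-12))
  expect_equal(wf_values(zscore_targets(z)), zv, tolerance = 1e-12)
  bad <- wfm_from_matrix(cbind(c(1, 2, 3), rep(1, 3)), c(8, 16))
  expect_error(zscore_targets(bad), "16")
})

test_that("inconsistency coefficients match an independent implementation", {
  set.seed(7)
  x <- matrix(rnorm(40), 8, 5)
  hc <- hclust(dist(x), method = "ward.D2")
  for (depth in 2:3) {
    inc <- inconsistency_coefficients(hc, depth = depth)
    # oracle: iterative breadth-first gather of merge heights
    oracle <- sapply(seq_len(nrow(hc$merge)), function(k) {
      frontier <- k
      heights <- c()
      for (lev in seq_len(depth)) {
        heights <- c(heights, hc$height[frontier])
        frontier <- as.vector(hc$merge[frontier, ])
        frontier <- frontier[frontier > 0]
        if (length(frontier) == 0) break
      }
      if (length(heights) < 2 || sd(heights) == 0) 0
      else (hc$height[k] - mean(heights)) / sd(heights)
    })
    expect_equal(inc, oracle, tolerance = 1e-12)
  }
})

test_that("identical target profiles merge first, at height zero", {
  set.seed(3)
  base <- rnorm(6)
  v <- unname(cbind(base, base, rnorm(6) + 5, rnorm(6) - 5))
  w <- wfm_from_matrix(v, c(8, 10, 16, 32))
  cl <- hierarchical_clusters(w)
  expect_equal(cl$hclust$height[1], 0)
  expect_equal(sort(cl$hclust$merge[1, ]), c(-2, -1))  # targets 8 and 10
  expect_error(hierarchical_clusters(wfm_from_matrix(v[, 1:2], c(8, 16))), "3 targets")
})

test_that("contiguity detection treats clusters as intervals of the target order", {
  t4 <- c(8, 10, 16, 32)
  expect_true(is_contiguous(c(1, 1, 2, 2), t4))
  expect_true(is_contiguous(rep(1, 4), t4))
  expect_true(is_contiguous(1:4, t4))
  expect_false(is_contiguous(c(1, 2, 2, 1), t4))
  tt <- numchan_targets()
  expect_true(is_contiguous(c(rep(1, 4), rep(2, 7)), tt))
  expect_false(is_contiguous(c(1, rep(2, 9), 1), tt))
  expect_error(is_contiguous(c(1, 2), t4))
})

test_that("two-channel cohorts recover a contiguous low/high split", {
  cfg <- two_channel_config(noise_sd = 0.02)
  hits <- 0
  for (i in 1:5) {
    w <- simulate_cohort(cfg, 30, seed = 400 + i, mode = "trials")
    cl <- hierarchical_clusters(w)
    if (cl$n_clusters == 2 && cl$contiguous) hits <- hits + 1
  }
  expect_gte(hits, 4)
  # clustering depends only on the Wf vectors, not participant order
  w <- simulate_cohort(cfg, 20, seed = 451, mode = "trials")
  shuffled <- new_wf_matrix(wf_values(w)[20:1, ], w$participant_id[20:1],
                            wf_targets(w), "fast")
  expect_equal(hierarchical_clusters(shuffled)$assignments,
               hierarchical_clusters(w)$assignments)
})

test_that("the contiguity null is seeded and rarely contiguous on structureless data", {
  flat <- channel_config(1, noise_sd = 0.066)
  w <- simulate_cohort(flat, 30, seed = 17, mode = "trials")
  n1 <- contiguity_null(w, n_iter = 500, seed = 2)
  n2 <- contiguity_null(w, n_iter = 500, seed = 2)
  expect_identical(n1$proportion_contiguous, n2$proportion_contiguous)
  expect_lt(n1$proportion_contiguous, 0.05)
  # the union of clusters is always the full target set
  expect_true(all(n1$n_clusters >= 1))
})

test_that("factor extraction retains eigenvalue > 1 components and recovers flanks", {
  cfg <- two_channel_config(noise_sd = 0.02)
  w <- simulate_cohort(cfg, 30, seed = 71, mode = "trials")
  fs <- factor_solution(w)
  expect_equal(fs$n_components, sum(fs$eigenvalues > 1))
  expect_equal(fs$n_components, 2L)
  expect_equal(fs$total_variance, sum(fs$eigenvalues[1:2]) / 11, tolerance = 1e-12)
  # each flank's targets load dominantly on one component
  dom <- apply(fs$loadings, 1, which.max)
  targets <- wf_targets(w)
  expect_equal(length(unique(dom[targets <= 11])), 1L)
  expect_equal(length(unique(dom[targets >= 24])), 1L)
  expect_false(dom[1] == dom[11])
  # promax and varimax agree on the dominant component of every flank target
  # (mid-range targets sit between the channels and are genuinely ambiguous)
  fv <- factor_solution(w, rotation = "varimax")
  dom_v <- apply(fv$loadings, 1, which.max)
  flank <- targets <= 13 | targets >= 21
  agree <- (dom == dom[1]) == (dom_v == dom_v[1])
  expect_true(all(agree[flank]))
})

test_that("an untuned cohort yields a single dominant component", {
  # equicorrelated structure: only the first eigenvalue exceeds 1
  flat <- channel_config(1, observer_sd = 0.08, noise_sd = 0.03)
  w <- simulate_cohort(flat, 40, seed = 91, mode = "analytic")
  fs <- factor_solution(w)
  expect_equal(fs$n_components, 1L)
  # closed-form check: for an equicorrelation matrix with mean off-diagonal r,
  # the second eigenvalue is about 1 - r < 1
  rbar <- mean(tidy(wf_correlation_matrix(w))$r)
  expect_lt(1 - rbar, 1)
  expect_lt(fs$eigenvalues[2], 1)
})

test_that("log-Gaussian fits are exact on log-Gaussian data and robust to degeneracy", {
  targets <- numchan_targets()
  for (pars in list(c(11, 0.25, 1), c(29, 0.4, 0.8))) {
    y <- pars[3] * exp(-(log10(targets / pars[1]))^2 / (2 * pars[2]^2))
    f <- loggaussian_fit(y, targets)
    expect_equal(f$peak, pars[1], tolerance = 1e-6)
    expect_equal(f$width, pars[2], tolerance = 1e-6)
    expect_gt(f$r2, 1 - 1e-9)
  }
  # constant loadings: degenerate but must not crash
  fc <- loggaussian_fit(rep(0.5, 11), targets)
  expect_true(is.finite(fc$peak) && is.finite(fc$width))
  expect_equal(fc$r2, 0)
  expect_error(loggaussian_fit(c(1, 2, 3), c(8, 16, 32)), "4 targets")
})

test_that("component tuning peaks straddle the geometric channel mean", {
  cfg <- two_channel_config(noise_sd = 0.02)
  gm <- sqrt(8 * 32)
  for (i in 1:4) {
    w <- simulate_cohort(cfg, 30, seed = 600 + i, mode = "trials")
    fs <- factor_solution(w)
    pks <- sort(sapply(seq_len(fs$n_components), function(j) {
      loggaussian_fit(fs$loadings[, j], wf_targets(w))$peak
    }))
    expect_lt(pks[1], gm)
    expect_gt(pks[length(pks)], gm)
  }
})

test_that("dendrograms export to Newick and JSON", {
  cfg <- two_channel_config()
  w <- simulate_cohort(cfg, 12, seed = 13)
  cl <- hierarchical_clusters(w)
  nwk <- cluster_newick(cl)
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, as.character(numchan_targets()))
  path <- withr::local_tempfile(fileext = ".json")
  write_cluster_result(cl, path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(j$n_clusters, cl$n_clusters)
  expect_equal(length(j$heights), 10)
})
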