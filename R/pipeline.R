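#' Run the full covariance-channel analysis end to end
#'
#' Executes preprocess -> correlation/distance analysis -> permutation nulls
#' -> clustering and factor structure (-> channel-model fits if requested) on
#' a trial table, or on a cohort simulated from a generative channel
#' configuration, and writes every artifact plus a JSON manifest to
#' `out_dir`. Identical configuration and seed reproduce identical outputs.
#'
#' @param out_dir Output directory (created if missing).
#' @param trials `"simulate"`, a path to a trial CSV, or a trial tibble.
#' @param config [channel_config()] used when `trials = "simulate"`.
#' @param n_observers Cohort size for simulation.
#' @param condition Condition label.
#' @param seed Integer master seed; all stage seeds derive from it.
#' @param n_iter_null Iterations for the shuffle and contiguity nulls.
#' @param fit_channels Integer vector of channel counts to fit (e.g.
#'   `c(1, 2)`), or `NULL` to skip model fitting.
#' @param fit_grid Parameter grid for the fits (default [coarse_fit_grid()]).
#' @param n_experiments_fit Simulated experiments per grid point.
#' @param edges Distance-bin edges.
#' @return Invisibly, a list with every computed object and the manifest.
#' @export
run_pipeline <- function(out_dir,
                         trials = "simulate",
                         config = channel_config(2),
                         n_observers = 30,
                         condition = "fast",
                         seed = 1,
                         n_iter_null = 1000,
                         fit_channels = NULL,
                         fit_grid = NULL,
                         n_experiments_fit = 100,
                         edges = default_distance_bins()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(seed, 5L)
  simulated <- identical(trials, "simulate")
  if (simulated) {
    trials <- simulate_cohort_trials(config, n_observers, seed = seeds[1],
                                     condition = condition)
    write_trials(trials, file.path(out_dir, "trials.csv"))
  } else if (is.character(trials)) {
    trials <- read_trials(trials)
  }

  cleaned <- remove_outliers(trials)
  write_trials(cleaned, file.path(out_dir, "cleaned_trials.csv"))
  write_cleaning_report(cleaned, file.path(out_dir, "cleaning_report.json"))

  stats <- reproduction_stats(cleaned)
  wfm <- build_wf_matrix(stats, condition = condition)
  write_wf_matrix(wfm, file.path(out_dir, "wf_matrix.csv"))

  corr <- wf_correlation_matrix(wfm)
  write_corr_matrix(corr, file.path(out_dir, "corr_matrix.csv"))
  curve <- binned_correlation_curve(corr, edges)
  readr::write_csv(curve, file.path(out_dir, "binned_curve.csv"))
  slope <- distance_slope(corr)

  null <- shuffle_null(wfm, n_iter = n_iter_null, seed = seeds[2], edges = edges)
  null_band <- quantile(null$slopes, c(0.025, 0.975), names = FALSE)
  distance_dependent <- slope$slope < null_band[1] || slope$slope > null_band[2]
  jsonlite::write_json(
    list(slope = slope,
         null_slope_mean = mean(null$slopes),
         null_slope_band_95 = null_band,
         empirical_p = null$p_value,
         distance_dependent = distance_dependent,
         null_curve = as.data.frame(null$null_curve)),
    file.path(out_dir, "distance_analysis.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )

  clusters <- hierarchical_clusters(wfm)
  write_cluster_result(clusters, file.path(out_dir, "clusters.json"))
  writeLines(cluster_newick(clusters), file.path(out_dir, "dendrogram.nwk"))
  contig_null <- contiguity_null(wfm, n_iter = n_iter_null, seed = seeds[3])

  solution <- factor_solution(wfm)
  readr::write_csv(tibble::as_tibble(solution$loadings, rownames = "target"),
                   file.path(out_dir, "loadings.csv"))
  tuning <- purrr::map(colnames(solution$loadings), function(cn) {
    glance(loggaussian_fit(solution$loadings[, cn], wf_targets(wfm)))
  })
  names(tuning) <- colnames(solution$loadings)
  jsonlite::write_json(
    list(n_components = solution$n_components,
         total_variance = solution$total_variance,
         rotation = solution$rotation,
         contiguity_null_proportion = contig_null$proportion_contiguous,
         tuning_fits = purrr::map(tuning, as.list)),
    file.path(out_dir, "structure_summary.json"),
    auto_unbox = TRUE, digits = NA
  )

  fits <- NULL
  if (!is.null(fit_channels)) {
    mean_wf <- mean(wf_values(wfm))
    fits <- purrr::map(fit_channels, function(k) {
      fit_channel_model(
        corr, n_channels = k, mean_wf = mean_wf,
        grid = fit_grid %||% coarse_fit_grid(k),
        n_observers = nrow(wfm), n_experiments = n_experiments_fit,
        n_reps = config$n_reps, seed = seeds[4]
      )
    })
    names(fits) <- paste0("channels_", fit_channels)
    jsonlite::write_json(purrr::map(fits, function(f) as.list(glance(f))),
                         file.path(out_dir, "model_fits.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("numchan")),
    seed = seed,
    stage_seeds = seeds,
    simulated = simulated,
    condition = condition,
    n_observers = nrow(wfm),
    targets = wf_targets(wfm),
    n_iter_null = n_iter_null,
    edges = edges,
    fit_channels = fit_channels,
    n_experiments_fit = if (is.null(fit_channels)) NULL else n_experiments_fit,
    config = if (simulated) {
      x <- unclass(config)
      x$fwhm_octaves <- if (is.finite(x$fwhm_octaves)) x$fwhm_octaves else "flat"
      x
    } else NULL,
    distance_dependent = distance_dependent
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(
    trials = trials, cleaned = cleaned, wf_matrix = wfm, corr = corr,
    curve = curve, slope = slope, shuffle_null = null,
    clusters = clusters, contiguity_null = contig_null,
    factor_solution = solution, tuning_fits = tuning,
    model_fits = fits, manifest = manifest
  ))
}
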