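#' Predicted inter-participant correlation matrix of a channel model
#'
#' Simulates `n_experiments` cohorts from a generative channel configuration
#' and returns the elementwise mean of their inter-participant correlation
#' matrices. With no measurement noise, targets handled by the same channel
#' correlate near 1; measurement noise scales all correlations down without
#' creating a distance trend, while channel tuning does create one.
#'
#' @param config A [channel_config()].
#' @param n_observers Observers per simulated cohort.
#' @param n_experiments Number of simulated experiments averaged.
#' @param seed Integer seed.
#' @param mode `"trials"` (default: full trial simulation with `config$n_reps`
#'   repetitions, as in the study design) or `"analytic"`.
#' @return A `corr_matrix` (mean predicted correlations; unit diagonal).
#' @export
#' @examples
#' cfg <- channel_config(2, fwhm_octaves = 1.45, n_reps = 25)
#' predict_corr_matrix(cfg, n_observers = 10, n_experiments = 20, seed = 1)
predict_corr_matrix <- function(config, n_observers = 30, n_experiments = 1000,
                                seed = 1, mode = c("trials", "analytic")) {
  stopifnot(inherits(config, "channel_config"))
  mode <- match.arg(mode)
  if (n_observers < 3) abort("`n_observers` must be >= 3 for correlations.")
  if (n_experiments < 1) abort("`n_experiments` must be >= 1.")
  targets <- config$target_set
  n_t <- length(targets)
  # Chunk experiments so the trial array stays modest in memory.
  per_exp <- n_observers * n_t * (if (mode == "trials") config$n_reps else 1L)
  block_size <- max(1L, min(n_experiments, floor(2e6 / per_exp)))
  acc <- matrix(0, n_t, n_t)
  withr::with_seed(as.integer(seed), {
    done <- 0L
    while (done < n_experiments) {
      b <- min(block_size, n_experiments - done)
      v <- simulate_wf_block(config, n_observers, b, mode)
      for (e in seq_len(b)) {
        rows <- seq.int((e - 1L) * n_observers + 1L, e * n_observers)
        acc <- acc + cor(v[rows, , drop = FALSE])
      }
      done <- done + b
    }
  })
  new_corr_matrix(acc / n_experiments, targets)
}

#' Variance explained of an empirical correlation matrix by a prediction
#'
#' `R^2 = 1 - SS_res / SS_tot` over the off-diagonal upper triangle, with
#' `SS_tot` taken about the empirical off-diagonal mean. Can be negative when
#' the prediction does worse than the empirical mean.
#'
#' @param predicted,empirical `corr_matrix` objects over the same targets.
#' @return A single numeric R-squared (<= 1).
#' @export
matrix_r2 <- function(predicted, empirical) {
  tp <- corr_targets(predicted)
  te <- corr_targets(empirical)
  if (length(tp) != length(te) || any(tp != te)) {
    abort("`predicted` and `empirical` must share the same target set.")
  }
  ut <- upper.tri(unclass(empirical))
  rp <- unclass(predicted)[ut]
  re <- unclass(empirical)[ut]
  ss_tot <- sum((re - mean(re))^2)
  if (ss_tot == 0) abort("Empirical off-diagonal correlations are constant; R^2 undefined.")
  1 - sum((re - rp)^2) / ss_tot
}

#' Parameter grids for simulation-based channel-model fitting
#'
#' `channel_fit_grid()` is the full default search grid: tuning bandwidth
#' 0.5–2.0 octaves in steps of 0.1 (dropped for the flat model), observer
#' channel variability 0.01–0.15 in steps of 0.005, and measurement noise
#' 0–0.15 in steps of 0.005. `coarse_fit_grid()` is a small grid for
#' recovery experiments and quick runs.
#'
#' @param n_channels Number of channels the grid is for (1 drops `fwhm_octaves`).
#' @param fwhm_octaves,observer_sd,noise_sd Candidate values.
#' @return A tibble with one row per parameter combination.
#' @export
channel_fit_grid <- function(n_channels = 2,
                             fwhm_octaves = seq(0.5, 2, by = 0.1),
                             observer_sd = seq(0.01, 0.15, by = 0.005),
                             noise_sd = seq(0, 0.15, by = 0.005)) {
  if (any(fwhm_octaves < 0.5 | fwhm_octaves > 2)) {
    abort("`fwhm_octaves` candidates must lie in [0.5, 2].")
  }
  if (n_channels == 1) {
    tidyr::expand_grid(fwhm_octaves = NA_real_,
                       observer_sd = observer_sd, noise_sd = noise_sd)
  } else {
    tidyr::expand_grid(fwhm_octaves = fwhm_octaves,
                       observer_sd = observer_sd, noise_sd = noise_sd)
  }
}

#' @rdname channel_fit_grid
#' @export
coarse_fit_grid <- function(n_channels = 2,
                            fwhm_octaves = c(0.5, 1, 1.45, 2),
                            observer_sd = c(0.05, 0.08, 0.11),
                            noise_sd = c(0.05, 0.075, 0.1)) {
  channel_fit_grid(n_channels, fwhm_octaves, observer_sd, noise_sd)
}

#' Fit a channel model to an empirical correlation matrix by simulation
#'
#' Grid search over tuning bandwidth, observer channel variability and
#' measurement noise. Each grid point predicts a correlation matrix by
#' simulation ([predict_corr_matrix()]) and is scored by [matrix_r2()]
#' against the empirical matrix; the population mean Weber fraction is fixed
#' from the data, not fitted. Common random numbers (the same seed at every
#' grid point) stabilise comparisons across the grid.
#'
#' @param empirical A `corr_matrix` to fit.
#' @param n_channels 1 (flat), 2, 4, or another positive integer; channel
#'   peaks are log-spaced over `peak_range`.
#' @param mean_wf Population mean Weber fraction, fixed from the data.
#' @param grid Parameter grid (a tibble as from [channel_fit_grid()]);
#'   defaults to the full grid.
#' @param n_observers Cohort size per simulated experiment.
#' @param n_experiments Simulated experiments per grid point (1000 for final
#'   fits; smaller values give a faster, approximate search).
#' @param n_reps Simulated repetitions per target and observer.
#' @param seed Integer seed (shared across grid points).
#' @param peak_range Lowest and highest channel peak.
#' @param mode Simulation mode passed to [predict_corr_matrix()].
#' @return An object of class `channel_fit` with the best parameters, its
#'   `r2`, and the full grid trace; see [tidy.channel_fit()] and
#'   [glance.channel_fit()].
#' @export
fit_channel_model <- function(empirical, n_channels, mean_wf = 0.176,
                              grid = NULL, n_observers = 30,
                              n_experiments = 1000, n_reps = 25, seed = 1,
                              peak_range = c(8, 32),
                              mode = c("trials", "analytic")) {
  mode <- match.arg(mode)
  if (is.null(grid)) grid <- channel_fit_grid(n_channels)
  if (nrow(grid) == 0) abort("The search grid is empty.")
  need <- c("fwhm_octaves", "observer_sd", "noise_sd")
  if (!all(need %in% names(grid))) {
    abort("`grid` must have columns fwhm_octaves, observer_sd, noise_sd.")
  }
  targets <- corr_targets(empirical)
  seeds <- derive_seeds(seed, 1L)
  r2 <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- channel_config(
      n_channels = n_channels,
      fwhm_octaves = if (n_channels > 1) grid$fwhm_octaves[i] else 1.45,
      mean_wf = mean_wf,
      observer_sd = grid$observer_sd[i],
      noise_sd = grid$noise_sd[i],
      n_reps = n_reps,
      target_set = targets
    )
    matrix_r2(
      predict_corr_matrix(cfg, n_observers = n_observers,
                          n_experiments = n_experiments,
                          seed = seeds[1], mode = mode),
      empirical
    )
  }, numeric(1))
  trace <- dplyr::mutate(grid, r2 = r2)
  best <- which.max(r2)
  structure(
    list(
      n_channels = n_channels,
      fwhm_octaves = if (n_channels > 1) grid$fwhm_octaves[best] else Inf,
      observer_sd = grid$observer_sd[best],
      noise_sd = grid$noise_sd[best],
      mean_wf = mean_wf,
      r2 = r2[best],
      grid_trace = trace,
      n_experiments = n_experiments,
      n_observers = n_observers,
      n_reps = n_reps,
      mode = mode,
      seed = seed
    ),
    class = "channel_fit"
  )
}

#' @export
print.channel_fit <- function(x, ...) {
  cat(sprintf("<channel_fit: %d-channel model, R^2 = %.3f>\n", x$n_channels, x$r2))
  if (x$n_channels > 1) cat(sprintf("  fwhm_octaves: %.3g\n", x$fwhm_octaves))
  cat(sprintf("  observer_sd:  %.3g\n  noise_sd:     %.3g\n  mean_wf:      %.3g (fixed)\n",
              x$observer_sd, x$noise_sd, x$mean_wf))
  cat(sprintf("  %d grid points, %d experiments x %d observers each\n",
              nrow(x$grid_trace), x$n_experiments, x$n_observers))
  invisible(x)
}

#' Tidy / summarise a channel-model fit
#'
#' `tidy()` returns the full grid trace (one row per evaluated parameter
#' combination with its R-squared); `glance()` returns a one-row summary of
#' the best fit.
#'
#' @param x A `channel_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy channel_fit
#' @export
tidy.channel_fit <- function(x, ...) {
  x$grid_trace
}

#' @rdname tidy.channel_fit
#' @method glance channel_fit
#' @export
glance.channel_fit <- function(x, ...) {
  tibble::tibble(
    n_channels = x$n_channels,
    fwhm_octaves = x$fwhm_octaves,
    observer_sd = x$observer_sd,
    noise_sd = x$noise_sd,
    mean_wf = x$mean_wf,
    r2 = x$r2,
    n_experiments = x$n_experiments,
    n_observers = x$n_observers,
    seed = x$seed
  )
}

#' Serialise a channel-model fit (including its grid trace) to JSON
#'
#' @param fit A `channel_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_channel_fit <- function(fit, path) {
  stopifnot(inherits(fit, "channel_fit"))
  out <- fit
  out$grid_trace <- as.data.frame(fit$grid_trace)
  class(out) <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
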