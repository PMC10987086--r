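#' Simulate reproduction trials for one observer cell
#'
#' Draws `n_reps` reproductions of a single target by an observer whose
#' precision is the Weber fraction `wf`. Responses follow Weber's law:
#' counts are drawn from Normal(target, wf * target), rounded to the nearest
#' integer and floored at 1; response durations are counts divided by the
#' tapping rate.
#'
#' @param wf Weber fraction of the observer at this target (>= 0).
#' @param target Target numerosity (> 0).
#' @param n_reps Number of repetitions (>= 2).
#' @param seed Integer seed.
#' @param rate_hz Tapping rate in Hz (defaults to a fast-tapping rate).
#' @param response `"normal"` (default) or `"lognormal"` response generation;
#'   the lognormal variant matches mean `target` and coefficient of variation
#'   `wf`.
#' @param participant_id,condition Labels copied into the output.
#' @return A tibble with columns `participant_id`, `condition`, `target`,
#'   `response_count`, `response_duration`.
#' @export
#' @examples
#' simulate_trials(0.17, 16, n_reps = 5, seed = 1)
simulate_trials <- function(wf, target, n_reps, seed,
                            rate_hz = 6.8,
                            response = c("normal", "lognormal"),
                            participant_id = "S01", condition = "fast") {
  if (wf < 0) abort("`wf` must be >= 0.")
  check_positive_scalar(target, "target")
  if (n_reps < 2) abort("`n_reps` must be >= 2: the Weber fraction is undefined on fewer trials.")
  response <- match.arg(response)
  counts <- withr::with_seed(as.integer(seed), {
    draw_counts(rep(target, n_reps), rep(wf, n_reps), response)
  })
  tibble::tibble(
    participant_id = participant_id,
    condition = condition,
    target = target,
    response_count = as.integer(counts),
    response_duration = counts / rate_hz
  )
}

# Weber-noise response counts; vectorised over cells.
draw_counts <- function(targets, wfs, response = "normal") {
  x <- if (response == "lognormal") {
    sdlog <- sqrt(log(1 + wfs^2))
    exp(rnorm(length(targets), log(targets) - sdlog^2 / 2, sdlog))
  } else {
    rnorm(length(targets), targets, wfs * targets)
  }
  pmax(round(x), 1)
}

# Per-observer, per-channel Weber fractions for `n_total` observers.
draw_channel_wfs <- function(config, n_total) {
  k <- config$n_channels
  if (config$shared_observer_deviate) {
    matrix(rnorm_pos(n_total, config$mean_wf, config$observer_sd),
           nrow = n_total, ncol = k)
  } else {
    matrix(rnorm_pos(n_total * k, config$mean_wf, config$observer_sd),
           nrow = n_total, ncol = k)
  }
}

# Core generative engine: realised Weber-fraction matrix for
# n_observers * n_experiments observers at the config's targets.
# mode "analytic": effective wf + additive measurement noise.
# mode "trials":   n_reps simulated responses -> sd/mean estimator, then
#                  additive measurement noise (the paper-level observable).
simulate_wf_block <- function(config, n_observers, n_experiments, mode) {
  targets <- config$target_set
  n_t <- length(targets)
  total <- n_observers * n_experiments
  cw <- draw_channel_wfs(config, total)                    # total x k
  wmat <- channel_weight_matrix(config)                    # k x n_t
  eff <- cw %*% wmat                                       # total x n_t
  if (mode == "analytic") {
    wf <- if (config$noise_sd > 0) {
      matrix(rnorm_pos(length(eff), as.vector(eff), config$noise_sd),
             nrow = total)
    } else eff
    return(wf)
  }
  n_reps <- config$n_reps
  cells <- total * n_t
  tv <- rep(targets, each = total)
  sdv <- as.vector(eff) * tv
  x <- matrix(
    draw_counts(rep(tv, each = n_reps), rep(as.vector(eff), each = n_reps),
                config$response),
    nrow = n_reps
  )
  m <- colMeans(x)
  wf_est <- col_sds(x) / m
  if (config$noise_sd > 0) {
    wf_est <- rnorm_pos(cells, wf_est, config$noise_sd)
  }
  matrix(wf_est, nrow = total)
}

#' Simulate a cohort of observers as a Weber-fraction matrix
#'
#' Draws per-observer channel Weber fractions from
#' Normal(`mean_wf`, `observer_sd`) (truncated positive), computes the
#' effective Weber fraction at every target, and realises the measured value
#' either analytically (`mode = "analytic"`: additive Normal(0, `noise_sd`)
#' measurement noise) or through full trial simulation (`mode = "trials"`:
#' `n_reps` responses per cell, the SD/mean estimator, then measurement
#' noise).
#'
#' @param config A [channel_config()].
#' @param n_observers Number of simulated observers (>= 2).
#' @param seed Integer seed; the same seed reproduces the same cohort.
#' @param mode `"analytic"` or `"trials"`.
#' @param condition Condition label stored in the result.
#' @return A [wf_matrix] (participants x targets tibble of Weber fractions).
#' @export
#' @examples
#' cfg <- channel_config(2, observer_sd = 0.08, noise_sd = 0.075)
#' simulate_cohort(cfg, n_observers = 5, seed = 1)
simulate_cohort <- function(config, n_observers, seed,
                            mode = c("analytic", "trials"),
                            condition = "simulated") {
  stopifnot(inherits(config, "channel_config"))
  if (n_observers < 2) abort("`n_observers` must be >= 2.")
  mode <- match.arg(mode)
  values <- withr::with_seed(as.integer(seed), {
    simulate_wf_block(config, n_observers, 1L, mode)
  })
  new_wf_matrix(values,
                participants = sprintf("S%02d", seq_len(n_observers)),
                targets = config$target_set,
                condition = condition)
}

#' Simulate a full trial table for a cohort
#'
#' Generates the raw long-format trial records the preprocessing pipeline
#' expects: every observer reproduces every target `n_reps` times, with a
#' per-observer tapping rate drawn once from Normal(`rate_hz`, `rate_sd`)
#' (truncated positive).
#'
#' @inheritParams simulate_cohort
#' @param condition `"fast"` or `"slow"`; sets the default tapping rate
#'   (6.8 Hz fast, 3.3 Hz slow) unless `rate_hz` is given.
#' @param rate_hz,rate_sd Mean and SD of the per-observer tapping rate (Hz).
#' @return A tibble of trial records (`participant_id`, `condition`,
#'   `target`, `response_count`, `response_duration`).
#' @export
#' @examples
#' cfg <- channel_config(2, n_reps = 5)
#' trials <- simulate_cohort_trials(cfg, n_observers = 3, seed = 1)
simulate_cohort_trials <- function(config, n_observers, seed,
                                   condition = c("fast", "slow"),
                                   rate_hz = NULL, rate_sd = NULL) {
  stopifnot(inherits(config, "channel_config"))
  if (n_observers < 2) abort("`n_observers` must be >= 2.")
  condition <- match.arg(condition)
  if (is.null(rate_hz)) rate_hz <- if (condition == "fast") 6.8 else 3.3
  if (is.null(rate_sd)) rate_sd <- if (condition == "fast") 1.0 else 1.6
  targets <- config$target_set
  n_t <- length(targets)
  n_reps <- config$n_reps
  withr::with_seed(as.integer(seed), {
    cw <- draw_channel_wfs(config, n_observers)
    eff <- cw %*% channel_weight_matrix(config)    # n_obs x n_t
    rates <- rnorm_pos(n_observers, rate_hz, rate_sd)
    cell_target <- rep(targets, each = n_observers)
    counts <- draw_counts(rep(cell_target, each = n_reps),
                          rep(as.vector(eff), each = n_reps),
                          config$response)
    obs_idx <- rep(rep(seq_len(n_observers), times = n_t), each = n_reps)
    tibble::tibble(
      participant_id = sprintf("S%02d", obs_idx),
      condition = condition,
      target = rep(cell_target, each = n_reps),
      response_count = as.integer(counts),
      response_duration = counts / rates[obs_idx]
    ) |>
      dplyr::arrange(.data$participant_id, .data$target)
  })
}
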