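#' The eleven default target numerosities
#'
#' Target numbers used throughout the package's default study design:
#' 8, 10, 11, 13, 14, 16, 19, 21, 24, 28, 32.
#'
#' @return An integer vector of length 11.
#' @export
#' @examples
#' numchan_targets()
numchan_targets <- function() {
  c(8L, 10L, 11L, 13L, 14L, 16L, 19L, 21L, 24L, 28L, 32L)
}

#' Gaussian channel sensitivity in log coordinates
#'
#' Sensitivity of a numerosity-tuned channel with Gaussian tuning on the
#' log2 (octave) axis. The tuning is parameterised by its full width at half
#' maximum in octaves, so `channel_sensitivity(p, w, p * 2^(w / 2)) == 0.5`.
#'
#' @param peak Preferred numerosity of the channel (> 0).
#' @param fwhm_octaves Full bandwidth (FWHM) of the tuning curve, in octaves.
#' @param n Probed numerosity (> 0); vectorised.
#' @return Sensitivity in (0, 1], equal to 1 at `n == peak`.
#' @export
#' @examples
#' channel_sensitivity(8, 1.45, 8)
#' channel_sensitivity(8, 1.45, c(10, 16, 32))
channel_sensitivity <- function(peak, fwhm_octaves, n) {
  check_positive_scalar(peak, "peak")
  check_positive_scalar(fwhm_octaves, "fwhm_octaves")
  if (any(!is.finite(n) | n <= 0)) {
    abort("`n` must contain positive finite numerosities.")
  }
  sigma <- fwhm_octaves / (2 * sqrt(2 * log(2)))
  exp(-(log2(n / peak))^2 / (2 * sigma^2))
}

#' Log-spaced channel peaks
#'
#' Peaks of an `n_channels`-channel layout, equally spaced in log coordinates
#' from `lo` to `hi` inclusive (a geometric sequence). The one-channel model is
#' flat (untuned) and has no peak: request it via [channel_config()] with
#' `n_channels = 1`.
#'
#' @param n_channels Number of channels (>= 2).
#' @param lo,hi Lowest and highest peak numerosities, `0 < lo < hi`.
#' @return A numeric vector of length `n_channels`.
#' @export
#' @examples
#' channel_peaks(2, 8, 32)
#' channel_peaks(4, 8, 32)
channel_peaks <- function(n_channels, lo = 8, hi = 32) {
  if (!is.numeric(n_channels) || length(n_channels) != 1 || n_channels < 2) {
    abort("`n_channels` must be >= 2; the 1-channel model is flat and has no peak (use channel_config(n_channels = 1)).")
  }
  check_positive_scalar(lo, "lo")
  check_positive_scalar(hi, "hi")
  if (lo >= hi) abort("`lo` must be smaller than `hi`.")
  2^seq(log2(lo), log2(hi), length.out = as.integer(n_channels))
}

#' Generative channel-model configuration
#'
#' Bundles the parameters of the generative observer model: a bank of
#' numerosity channels with Gaussian tuning in log2 coordinates, per-observer
#' channel sensitivity (Weber fraction) drawn around a population mean, and
#' additive measurement noise on the realised Weber fraction.
#'
#' @param n_channels 1 (flat/untuned), 2, 4, or any positive integer.
#' @param peaks Channel peak numerosities; defaults to [channel_peaks()] over
#'   8–32 for `n_channels >= 2`, and is `NULL` for the flat model.
#' @param fwhm_octaves Tuning full bandwidth (FWHM) in octaves; ignored by the
#'   flat model. Model fitting constrains it to `[0.5, 2]`.
#' @param mean_wf Population mean Weber fraction of a channel.
#' @param observer_sd SD of the per-observer, per-channel Weber fraction
#'   around `mean_wf`.
#' @param noise_sd SD of the additive measurement noise applied to each
#'   realised Weber-fraction estimate.
#' @param n_reps Repetitions per target per observer when simulating trials.
#' @param target_set Ordered target numerosities; default [numchan_targets()].
#' @param shared_observer_deviate If `TRUE`, one Gaussian deviate per observer
#'   is shared across channels; if `FALSE` (default) channels vary
#'   independently within an observer.
#' @param response Trial response model: `"normal"` (rounded Normal with
#'   SD = wf * target, floored at 1) or `"lognormal"`.
#' @param rate_hz Tapping rate used to turn counts into response durations.
#' @return An object of class `channel_config`.
#' @export
#' @examples
#' channel_config(2, fwhm_octaves = 1.45)
#' channel_config(1, noise_sd = 0.075)
channel_config <- function(n_channels,
                           peaks = NULL,
                           fwhm_octaves = 1.45,
                           mean_wf = 0.176,
                           observer_sd = 0.08,
                           noise_sd = 0.075,
                           n_reps = 25,
                           target_set = numchan_targets(),
                           shared_observer_deviate = FALSE,
                           response = c("normal", "lognormal"),
                           rate_hz = 6.8) {
  if (!is.numeric(n_channels) || length(n_channels) != 1 || n_channels < 1 ||
      n_channels != round(n_channels)) {
    abort("`n_channels` must be a positive integer.")
  }
  n_channels <- as.integer(n_channels)
  if (n_channels == 1L) {
    if (!is.null(peaks)) abort("The 1-channel model is flat: `peaks` must be NULL.")
  } else {
    if (is.null(peaks)) peaks <- channel_peaks(n_channels, 8, 32)
    if (length(peaks) != n_channels) abort("`peaks` must have one entry per channel.")
    if (any(peaks <= 0) || is.unsorted(peaks, strictly = TRUE)) {
      abort("`peaks` must be strictly increasing and positive.")
    }
    check_positive_scalar(fwhm_octaves, "fwhm_octaves")
  }
  check_positive_scalar(mean_wf, "mean_wf")
  if (observer_sd < 0) abort("`observer_sd` must be >= 0.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (n_reps < 2) abort("`n_reps` must be >= 2 (the Weber fraction needs at least two trials).")
  if (any(target_set <= 0) || is.unsorted(target_set, strictly = TRUE)) {
    abort("`target_set` must be strictly increasing and positive.")
  }
  response <- match.arg(response)
  structure(
    list(
      n_channels = n_channels,
      peaks = if (n_channels > 1L) as.numeric(peaks) else NULL,
      fwhm_octaves = if (n_channels > 1L) as.numeric(fwhm_octaves) else Inf,
      mean_wf = as.numeric(mean_wf),
      observer_sd = as.numeric(observer_sd),
      noise_sd = as.numeric(noise_sd),
      n_reps = as.integer(n_reps),
      target_set = as.numeric(target_set),
      shared_observer_deviate = isTRUE(shared_observer_deviate),
      response = response,
      rate_hz = as.numeric(rate_hz)
    ),
    class = "channel_config"
  )
}

#' @export
print.channel_config <- function(x, ...) {
  cat(sprintf("<channel_config: %d channel%s>\n", x$n_channels,
              if (x$n_channels > 1) "s" else " (flat)"))
  if (x$n_channels > 1) {
    cat("  peaks:        ", paste(signif(x$peaks, 4), collapse = ", "), "\n")
    cat("  fwhm_octaves: ", x$fwhm_octaves, "\n")
  }
  cat("  mean_wf:      ", x$mean_wf, "\n")
  cat("  observer_sd:  ", x$observer_sd, "\n")
  cat("  noise_sd:     ", x$noise_sd, "\n")
  cat("  n_reps:       ", x$n_reps, "\n")
  cat("  targets:      ", paste(x$target_set, collapse = ", "), "\n")
  invisible(x)
}

# Channel weight matrix (n_channels x n_targets), columns normalised to sum 1.
channel_weight_matrix <- function(config, targets = config$target_set) {
  if (config$n_channels == 1L) {
    return(matrix(1, nrow = 1, ncol = length(targets)))
  }
  w <- vapply(
    targets,
    function(n) vapply(config$peaks,
                       function(p) channel_sensitivity(p, config$fwhm_octaves, n),
                       numeric(1)),
    numeric(config$n_channels)
  )
  w <- matrix(w, nrow = config$n_channels)
  tot <- colSums(w)
  if (any(tot < .Machine$double.xmin)) {
    abort("All channel weights are numerically zero for some target: it lies too far outside the channel range.")
  }
  sweep(w, 2, tot, "/")
}

#' Effective Weber fraction of an observer at a numerosity
#'
#' The behaviour at numerosities covered by more than one channel is a
#' sensitivity-weighted average of the observer's per-channel Weber fractions.
#' The flat 1-channel model returns the single channel's value everywhere.
#'
#' @param channel_wfs One Weber fraction per channel (all > 0).
#' @param n Probed numerosity (vectorised).
#' @param config A [channel_config()].
#' @return Effective Weber fraction(s) at `n`.
#' @export
#' @examples
#' cfg <- channel_config(2, fwhm_octaves = 1.45)
#' effective_wf(c(0.15, 0.20), 16, cfg)
effective_wf <- function(channel_wfs, n, config) {
  if (length(channel_wfs) != config$n_channels) {
    abort("`channel_wfs` must hold one Weber fraction per channel.")
  }
  if (any(channel_wfs <= 0)) abort("`channel_wfs` must all be positive.")
  w <- channel_weight_matrix(config, targets = n)
  as.numeric(crossprod(w, channel_wfs))
}

#' Read/write a channel-model configuration
#'
#' Serialises a [channel_config()] to a YAML file (key names identical to the
#' constructor arguments) and back.
#'
#' @param config A `channel_config`.
#' @param path File path.
#' @return `write_channel_config()` returns `path` invisibly;
#'   `read_channel_config()` returns a `channel_config`.
#' @export
write_channel_config <- function(config, path) {
  stopifnot(inherits(config, "channel_config"))
  x <- unclass(config)
  x$fwhm_octaves <- if (is.finite(x$fwhm_octaves)) x$fwhm_octaves else NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_channel_config
#' @export
read_channel_config <- function(path) {
  x <- yaml::read_yaml(path)
  channel_config(
    n_channels = x$n_channels,
    peaks = if (!is.null(x$peaks)) as.numeric(x$peaks) else NULL,
    fwhm_octaves = if (!is.null(x$fwhm_octaves)) x$fwhm_octaves else 1.45,
    mean_wf = x$mean_wf,
    observer_sd = x$observer_sd,
    noise_sd = x$noise_sd,
    n_reps = x$n_reps,
    target_set = as.numeric(x$target_set),
    shared_observer_deviate = isTRUE(x$shared_observer_deviate),
    response = x$response,
    rate_hz = x$rate_hz
  )
}
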