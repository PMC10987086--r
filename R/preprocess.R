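#' Remove outlier trials by per-cell z-score
#'
#' Within each (participant, condition, target) cell, responses are converted
#' once to z-scores (sample SD) and trials with |z| > `z_threshold` are
#' eliminated. The pass is single-shot: cell statistics are computed once and
#' not re-estimated after removal. Cells with zero variance are left
#' untouched (z is undefined there).
#'
#' @param trials Long trial table with columns `participant_id`, `condition`,
#'   `target` and the response column named by `value`.
#' @param value Response column to screen (unquoted); `response_count` for
#'   number tasks, `response_duration` for the duration task.
#' @param z_threshold Exclusion threshold in SD units (default 3).
#' @return The cleaned trial tibble, with a cleaning report attached as the
#'   `"cleaning_report"` attribute (see [cleaning_report()]).
#' @export
#' @examples
#' cfg <- channel_config(2, n_reps = 10)
#' trials <- simulate_cohort_trials(cfg, 3, seed = 1)
#' cleaned <- remove_outliers(trials)
#' cleaning_report(cleaned)$fraction_removed
remove_outliers <- function(trials, value = response_count, z_threshold = 3) {
  value <- enquo(value)
  vname <- as_name(value)
  if (!vname %in% names(trials)) abort(sprintf("Column `%s` not found in `trials`.", vname))
  flagged <- trials |>
    dplyr::group_by(.data$participant_id, .data$condition, .data$target) |>
    dplyr::mutate(
      .cell_n = dplyr::n(),
      .cell_sd = sd(!!value),
      .z = dplyr::if_else(.data$.cell_sd > 0,
                          (!!value - mean(!!value)) / .data$.cell_sd, 0),
      .drop_trial = abs(.data$.z) > z_threshold
    ) |>
    dplyr::ungroup()
  if (any(flagged$.cell_n < 2)) {
    abort("Every (participant, condition, target) cell needs >= 2 trials to screen outliers.")
  }
  removed <- dplyr::filter(flagged, .data$.drop_trial)
  per_cell <- removed |>
    dplyr::count(.data$participant_id, .data$condition, .data$target,
                 name = "n_removed")
  cleaned <- flagged |>
    dplyr::filter(!.data$.drop_trial) |>
    dplyr::select(-dplyr::all_of(c(".cell_n", ".cell_sd", ".z", ".drop_trial")))
  report <- list(
    n_input_trials = nrow(trials),
    n_removed = nrow(removed),
    fraction_removed = nrow(removed) / nrow(trials),
    z_threshold = z_threshold,
    per_cell_removed = per_cell
  )
  attr(cleaned, "cleaning_report") <- report
  cleaned
}

#' Cleaning report of an outlier-screened trial table
#'
#' @param trials A tibble returned by [remove_outliers()].
#' @return A list: `n_input_trials`, `n_removed`, `fraction_removed`,
#'   `z_threshold`, and `per_cell_removed` (a tibble of removal counts per
#'   participant/condition/target cell).
#' @export
cleaning_report <- function(trials) {
  rep <- attr(trials, "cleaning_report")
  if (is.null(rep)) abort("`trials` carries no cleaning report; run remove_outliers() first.")
  rep
}

#' Serialise a cleaning report to JSON
#'
#' @param trials A tibble returned by [remove_outliers()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cleaning_report <- function(trials, path) {
  jsonlite::write_json(cleaning_report(trials), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}

#' Per-cell reproduction accuracy and precision
#'
#' For each (participant, condition, target) cell of a cleaned trial table,
#' computes accuracy (mean reproduction) and precision as the Weber fraction:
#' sample SD of responses divided by their mean. Statistics are computed on
#' the raw (non-standardised) responses.
#'
#' @inheritParams remove_outliers
#' @return A tibble with columns `participant_id`, `condition`, `target`,
#'   `n_trials`, `mean_response`, `sd_response`, `wf`. Cells with fewer than
#'   two trials get `NA` statistics and a warning.
#' @export
reproduction_stats <- function(trials, value = response_count) {
  value <- enquo(value)
  out <- trials |>
    dplyr::group_by(.data$participant_id, .data$condition, .data$target) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      mean_response = mean(!!value),
      sd_response = sd(!!value),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mean_response = dplyr::if_else(.data$n_trials < 2, NA_real_, .data$mean_response),
      sd_response = dplyr::if_else(.data$n_trials < 2, NA_real_, .data$sd_response),
      wf = .data$sd_response / .data$mean_response
    ) |>
    dplyr::arrange(.data$participant_id, .data$condition, .data$target)
  if (anyNA(out$wf)) {
    n_bad <- sum(is.na(out$wf))
    warn(sprintf("%d cell(s) had fewer than 2 trials; their statistics are NA.", n_bad))
  }
  out
}

#' Assemble a Weber-fraction matrix from per-cell statistics
#'
#' Pivots the output of [reproduction_stats()] into a participants x targets
#' [wf_matrix]. Participants missing any target cell are dropped (with a
#' warning): the correlation analyses require complete vectors. Ordering is
#' deterministic: participants by identifier, targets ascending.
#'
#' @param stats Output of [reproduction_stats()] for one condition.
#' @param condition Condition label; defaults to the (single) condition in
#'   `stats`.
#' @return A [wf_matrix].
#' @export
build_wf_matrix <- function(stats, condition = NULL) {
  if (nrow(stats) == 0) abort("`stats` is empty.")
  conds <- unique(stats$condition)
  if (is.null(condition)) {
    if (length(conds) > 1) abort("`stats` mixes conditions; pass `condition` explicitly.")
    condition <- conds
  } else {
    stats <- dplyr::filter(stats, .data$condition == !!condition)
    if (nrow(stats) == 0) abort(sprintf("No rows for condition \"%s\".", condition))
  }
  targets <- sort(unique(stats$target))
  wide <- stats |>
    dplyr::select("participant_id", "target", "wf") |>
    tidyr::pivot_wider(names_from = "target", values_from = "wf",
                       names_sort = TRUE) |>
    dplyr::arrange(.data$participant_id)
  complete <- stats::complete.cases(wide)
  if (any(!complete)) {
    warn(sprintf("Dropping %d participant(s) with missing target cells: %s",
                 sum(!complete),
                 paste(wide$participant_id[!complete], collapse = ", ")))
    wide <- wide[complete, , drop = FALSE]
  }
  if (nrow(wide) == 0) abort("No participant has a Weber fraction at every target.")
  vals <- as.matrix(wide[, -1])
  if (any(vals == 0)) {
    warn("Some cells have a Weber fraction of exactly 0 (zero response variance).")
  }
  new_wf_matrix(vals, wide$participant_id, targets, condition)
}

#' Read/write a long trial table as CSV
#'
#' Columns: `participant_id`, `condition`, `target`, `response_count`,
#' `response_duration` (header required, UTF-8, '.' decimal separator).
#'
#' @param trials Trial tibble.
#' @param path File path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()` a tibble.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         participant_id = readr::col_character(),
                         condition = readr::col_character(),
                         target = readr::col_double(),
                         response_count = readr::col_integer(),
                         response_duration = readr::col_double()
                       ))
  need <- c("participant_id", "condition", "target", "response_count", "response_duration")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort(sprintf("Trial CSV is missing column(s): %s", paste(missing, collapse = ", ")))
  }
  x
}
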