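#' Derive per-participant duration targets from the number task
#'
#' For each participant and each number target, extracts the mean response
#' duration across (cleaned) trials. These per-participant durations are the
#' stimulus set of the duration-matching control task: each participant
#' reproduces the durations they themselves produced in the number task.
#'
#' @param number_trials Cleaned long trial table from the number task, with
#'   `response_duration` present.
#' @return A tibble with columns `participant_id`, `target` (the source
#'   number target), `rank` (1 = smallest target), `duration` (seconds).
#'   Participants missing any target are dropped with a warning.
#' @export
derive_duration_targets <- function(number_trials) {
  if (!"response_duration" %in% names(number_trials)) {
    abort("`number_trials` must contain `response_duration`.")
  }
  tab <- number_trials |>
    dplyr::group_by(.data$participant_id, .data$target) |>
    dplyr::summarise(duration = mean(.data$response_duration), .groups = "drop")
  n_targets <- length(unique(tab$target))
  counts <- dplyr::count(tab, .data$participant_id)
  incomplete <- counts$participant_id[counts$n < n_targets]
  if (length(incomplete) > 0) {
    warn(sprintf("Dropping participant(s) without durations at every target: %s",
                 paste(incomplete, collapse = ", ")))
    tab <- dplyr::filter(tab, !.data$participant_id %in% incomplete)
  }
  if (nrow(tab) == 0) abort("No participant has durations at every target.")
  tab |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::arrange(.data$target, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("participant_id", "target", "rank", "duration") |>
    dplyr::arrange(.data$participant_id, .data$rank)
}

#' Read/write a duration-target table
#'
#' The CSV layout has one row per rank (1 = shortest source target) and one
#' column per participant.
#'
#' @param duration_targets Tibble from [derive_duration_targets()] (columns
#'   `participant_id`, `rank`, `duration`).
#' @param path File path.
#' @return `write_duration_targets()` returns `path` invisibly;
#'   `read_duration_targets()` a tibble with columns `participant_id`,
#'   `rank`, `duration`.
#' @export
write_duration_targets <- function(duration_targets, path) {
  wide <- duration_targets |>
    dplyr::select("participant_id", "rank", "duration") |>
    tidyr::pivot_wider(names_from = "participant_id", values_from = "duration") |>
    dplyr::arrange(.data$rank) |>
    dplyr::select(-"rank")
  readr::write_csv(wide, path)
  invisible(path)
}

#' @rdname write_duration_targets
#' @export
read_duration_targets <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  x |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    tidyr::pivot_longer(-"rank", names_to = "participant_id",
                        values_to = "duration") |>
    dplyr::arrange(.data$participant_id, .data$rank) |>
    dplyr::select("participant_id", "rank", "duration")
}

#' The packaged duration-target table of the reference study design
#'
#' Eleven target durations (seconds) for each of nine participants (S1–S9)
#' of the duration-matching control task, as produced by those participants
#' in the number task.
#'
#' @return A tibble with columns `participant_id`, `rank`, `duration`.
#' @export
duration_targets_table <- function() {
  read_duration_targets(
    system.file("extdata", "duration_targets.csv", package = "numchan",
                mustWork = TRUE)
  )
}

#' Compare reproduction precision between the number and duration tasks
#'
#' Averages each participant's Weber fractions across stimulus levels in
#' both tasks and reports the paired differences. Duration levels are
#' matched to number targets by rank (the duration targets are
#' participant-specific). If number reproduction were driven by elapsed
#' duration, duration precision would have to be at least as good as number
#' precision; a clearly higher duration Weber fraction rules that strategy
#' out.
#'
#' @param number_wfm,duration_wfm [wf_matrix] objects over the same
#'   participants (duration targets ranked).
#' @return An object of class `task_comparison`: `by_participant` (tibble
#'   with `wf_number`, `wf_duration`, `difference`), `mean_wf_number`,
#'   `mean_wf_duration`, `sd_wf_number`, `sd_wf_duration`,
#'   `mean_difference`.
#' @export
compare_task_precision <- function(number_wfm, duration_wfm) {
  pn <- number_wfm$participant_id
  pd <- duration_wfm$participant_id
  if (!setequal(pn, pd)) {
    abort("The two matrices must cover the same participants.")
  }
  vn <- wf_values(number_wfm)
  vd <- wf_values(duration_wfm)[match(pn, pd), , drop = FALSE]
  by_participant <- tibble::tibble(
    participant_id = pn,
    wf_number = rowMeans(vn),
    wf_duration = rowMeans(vd),
    difference = rowMeans(vd) - rowMeans(vn)
  )
  structure(
    list(
      by_participant = by_participant,
      mean_wf_number = mean(by_participant$wf_number),
      mean_wf_duration = mean(by_participant$wf_duration),
      sd_wf_number = sd(by_participant$wf_number),
      sd_wf_duration = sd(by_participant$wf_duration),
      mean_difference = mean(by_participant$difference)
    ),
    class = "task_comparison"
  )
}

#' @export
print.task_comparison <- function(x, ...) {
  cat("<task_comparison>\n")
  cat(sprintf("  number:   mean Wf %.3f (SD %.3f)\n", x$mean_wf_number, x$sd_wf_number))
  cat(sprintf("  duration: mean Wf %.3f (SD %.3f)\n", x$mean_wf_duration, x$sd_wf_duration))
  cat(sprintf("  mean paired difference (duration - number): %.3f over %d participants\n",
              x$mean_difference, nrow(x$by_participant)))
  invisible(x)
}

#' Tidy / summarise a number-vs-duration precision comparison
#'
#' @param x A `task_comparison`.
#' @param ... Unused.
#' @return `tidy()`: per-participant tibble; `glance()`: one-row summary.
#' @method tidy task_comparison
#' @export
tidy.task_comparison <- function(x, ...) {
  x$by_participant
}

#' @rdname tidy.task_comparison
#' @method glance task_comparison
#' @export
glance.task_comparison <- function(x, ...) {
  tibble::tibble(
    mean_wf_number = x$mean_wf_number,
    sd_wf_number = x$sd_wf_number,
    mean_wf_duration = x$mean_wf_duration,
    sd_wf_duration = x$sd_wf_duration,
    mean_difference = x$mean_difference,
    n_participants = nrow(x$by_participant)
  )
}
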