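#' Weber-fraction matrix
#'
#' The pipeline's central object: one row per participant, one column per
#' target (plus a leading `participant_id` column), each cell the Weber
#' fraction (SD of reproductions / mean reproduction) of that participant at
#' that target. Stored as a tibble subclass so it pipes through dplyr; use
#' [wf_values()] for the bare numeric matrix and [wf_targets()] for the
#' ordered target levels.
#'
#' @param values Numeric matrix, participants x targets.
#' @param participants Character vector of participant identifiers.
#' @param targets Strictly increasing positive target levels (numerosities,
#'   or ranked duration levels).
#' @param condition Condition label (e.g. `"fast"`, `"slow"`, `"duration"`).
#' @return A `wf_matrix` tibble.
#' @export
new_wf_matrix <- function(values, participants, targets, condition = "unknown") {
  values <- as.matrix(values)
  dimnames(values) <- NULL
  if (nrow(values) != length(participants) || ncol(values) != length(targets)) {
    abort("`values` must be participants x targets.")
  }
  if (is.unsorted(targets, strictly = TRUE) || any(targets <= 0)) {
    abort("`targets` must be strictly increasing and positive.")
  }
  out <- tibble::as_tibble(as.data.frame(values))
  names(out) <- as.character(targets)
  out <- dplyr::bind_cols(tibble::tibble(participant_id = as.character(participants)), out)
  structure(out,
            targets = as.numeric(targets),
            condition = condition,
            class = c("wf_matrix", class(tibble::tibble())))
}

#' @rdname new_wf_matrix
#' @param wfm A `wf_matrix`.
#' @export
wf_values <- function(wfm) {
  stopifnot(inherits(wfm, "wf_matrix"))
  m <- as.matrix(as.data.frame(wfm)[, -1, drop = FALSE])
  rownames(m) <- wfm$participant_id
  storage.mode(m) <- "double"
  m
}

#' @rdname new_wf_matrix
#' @export
wf_targets <- function(wfm) {
  stopifnot(inherits(wfm, "wf_matrix"))
  attr(wfm, "targets")
}

#' @rdname new_wf_matrix
#' @export
wf_condition <- function(wfm) {
  stopifnot(inherits(wfm, "wf_matrix"))
  attr(wfm, "condition") %||% "unknown"
}

#' @export
print.wf_matrix <- function(x, ...) {
  cat(sprintf("<wf_matrix: %d participants x %d targets, condition \"%s\">\n",
              nrow(x), length(wf_targets(x)), wf_condition(x)))
  NextMethod()
}

#' Tidy a Weber-fraction matrix to long format
#'
#' @param x A [wf_matrix].
#' @param ... Unused.
#' @return A tibble with columns `participant_id`, `target`, `wf`.
#' @method tidy wf_matrix
#' @export
tidy.wf_matrix <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"participant_id",
                      names_to = "target", values_to = "wf") |>
    dplyr::mutate(target = as.numeric(.data$target)) |>
    dplyr::arrange(.data$participant_id, .data$target)
}

#' Read/write a Weber-fraction matrix as CSV
#'
#' The CSV layout is one row per participant: first column `participant_id`,
#' remaining columns one per target, labelled with the target level.
#'
#' @param wfm A [wf_matrix].
#' @param path File path.
#' @param condition Condition label to attach on read.
#' @return `write_wf_matrix()` returns `path` invisibly; `read_wf_matrix()`
#'   returns a `wf_matrix`.
#' @export
write_wf_matrix <- function(wfm, path) {
  stopifnot(inherits(wfm, "wf_matrix"))
  readr::write_csv(tibble::as_tibble(wfm), path)
  invisible(path)
}

#' @rdname write_wf_matrix
#' @export
read_wf_matrix <- function(path, condition = "unknown") {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (names(x)[1] != "participant_id") {
    abort("Expected first CSV column `participant_id`.")
  }
  targets <- as.numeric(names(x)[-1])
  if (anyNA(targets)) abort("All non-leading columns must be labelled with numeric target levels.")
  new_wf_matrix(as.matrix(x[, -1]), x$participant_id, targets, condition)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
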