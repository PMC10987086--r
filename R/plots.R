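# ggplot2 convenience plots for the main result types.

#' Plot Weber fractions against target level
#'
#' Thin lines show individual participants, the heavy line the cohort mean.
#'
#' @param object A [wf_matrix].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot wf_matrix
#' @export
autoplot.wf_matrix <- function(object, ...) {
  long <- tidy.wf_matrix(object)
  means <- long |>
    dplyr::group_by(.data$target) |>
    dplyr::summarise(wf = mean(.data$wf), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$target, y = .data$wf)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$participant_id),
                       alpha = 0.25, linewidth = 0.3) +
    ggplot2::geom_line(data = means, linewidth = 1.1, colour = "firebrick") +
    ggplot2::geom_point(data = means, size = 2, colour = "firebrick") +
    ggplot2::scale_x_log10(breaks = unique(long$target)) +
    ggplot2::labs(x = "Target", y = "Weber fraction",
                  title = sprintf("Reproduction precision (%s)", wf_condition(object))) +
    ggplot2::theme_minimal()
}

#' Heatmap of an inter-participant correlation matrix
#'
#' @param object A `corr_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot corr_matrix
#' @export
autoplot.corr_matrix <- function(object, ...) {
  targets <- corr_targets(object)
  df <- tidyr::expand_grid(a = seq_along(targets), b = seq_along(targets)) |>
    dplyr::mutate(
      target_a = factor(targets[.data$a], levels = targets),
      target_b = factor(targets[.data$b], levels = targets),
      r = as.vector(unclass(object))
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target_a, y = .data$target_b,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = "Target", y = "Target", fill = "r") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Correlation strength as a function of numerical distance
#'
#' Plots the binned correlation curve of an observed matrix; optionally
#' overlays the permutation-null curve.
#'
#' @param corr A `corr_matrix`.
#' @param null Optional `shuffle_null` object.
#' @param edges Distance-bin edges.
#' @return A ggplot.
#' @export
plot_correlation_curve <- function(corr, null = NULL,
                                   edges = default_distance_bins()) {
  curve <- binned_correlation_curve(corr, edges) |>
    dplyr::mutate(mid = ifelse(is.finite(.data$hi), (.data$lo + .data$hi) / 2,
                               .data$lo * 1.2),
                  which = "observed")
  if (!is.null(null)) {
    nc <- null$null_curve |>
      dplyr::mutate(mid = ifelse(is.finite(.data$hi), (.data$lo + .data$hi) / 2,
                                 .data$lo * 1.2),
                    which = "random")
    curve <- dplyr::bind_rows(curve, nc)
  }
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$mid, y = .data$mean_r,
                                      colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Numerical distance (log10 ratio, bin midpoint)",
                  y = "Mean correlation", colour = NULL) +
    ggplot2::theme_minimal()
}

# Segment coordinates of an hclust dendrogram (leaves at their order positions).
dendrogram_segments <- function(hc) {
  m <- hc$merge
  h <- hc$height
  pos <- numeric(nrow(m))
  leaf_x <- match(seq_len(nrow(m) + 1L), hc$order)
  segs <- vector("list", nrow(m))
  node_x <- function(i) if (i < 0) leaf_x[-i] else pos[i]
  node_y <- function(i) if (i < 0) 0 else h[i]
  for (i in seq_len(nrow(m))) {
    x1 <- node_x(m[i, 1]); x2 <- node_x(m[i, 2])
    y1 <- node_y(m[i, 1]); y2 <- node_y(m[i, 2])
    pos[i] <- (x1 + x2) / 2
    segs[[i]] <- tibble::tibble(
      x = c(x1, x1, x2), xend = c(x1, x2, x2),
      y = c(y1, h[i], h[i]), yend = c(h[i], h[i], y2)
    )
  }
  dplyr::bind_rows(segs)
}

#' Dendrogram of a target clustering
#'
#' @param object A `channel_clusters` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot channel_clusters
#' @export
autoplot.channel_clusters <- function(object, ...) {
  hc <- object$hclust
  segs <- dendrogram_segments(hc)
  leaves <- tibble::tibble(
    x = seq_along(hc$order),
    label = hc$labels[hc$order],
    cluster = factor(object$assignments[hc$labels[hc$order]])
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::geom_text(data = leaves,
                       ggplot2::aes(x = .data$x, y = -0.02 * max(hc$height),
                                    label = .data$label, colour = .data$cluster),
                       vjust = 1, fontface = "bold") +
    ggplot2::labs(x = NULL, y = "Merge height (Ward)", colour = "Cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Component loadings with log-Gaussian tuning curves
#'
#' Plots each retained component's loading profile over targets and overlays
#' the fitted log-Gaussian tuning curves.
#'
#' @param object A `component_solution`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot component_solution
#' @export
autoplot.component_solution <- function(object, ...) {
  long <- tidy.component_solution(object)
  targets <- object$targets
  grid_n <- exp(seq(log(min(targets)), log(max(targets)), length.out = 120))
  curves <- purrr::map_dfr(colnames(object$loadings), function(cn) {
    f <- loggaussian_fit(object$loadings[, cn], targets)
    tibble::tibble(
      target = grid_n,
      loading = f$amplitude * exp(-(log10(grid_n / f$peak))^2 / (2 * f$width^2)),
      component = cn
    )
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$target, y = .data$loading,
                                     colour = .data$component)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(data = curves, linewidth = 0.8) +
    ggplot2::scale_x_log10(breaks = targets) +
    ggplot2::labs(x = "Target", y = "Component loading", colour = NULL) +
    ggplot2::theme_minimal()
}
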