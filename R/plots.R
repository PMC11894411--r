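# ggplot2 displays for the main result types.

#' Plot a screen-coverage displacement map
#'
#' Diverging tile map: white at zero displacement (uniform coverage), red
#' above, blue below (-1 = no gaze data in the cell).
#'
#' @param object A `coverage_map` from [coverage_displacement()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coverage_map <- function(object, ...) {
  ggplot(object, aes(x = .data$cell_x, y = .data$cell_y,
                     fill = .data$displacement)) +
    geom_tile() +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                         limits = c(-1, 1)) +
    scale_y_reverse() +
    coord_fixed() +
    labs(x = "grid cell (x)", y = "grid cell (y)",
         fill = "displacement\nfrom uniform") +
    theme_minimal()
}

#' Plot a fixation heatmap
#'
#' @param object A `fixation_heatmap` from [fixation_heatmap()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fixation_heatmap <- function(object, ...) {
  ggplot(object, aes(x = .data$cell_x, y = .data$cell_y,
                     fill = .data$value)) +
    geom_tile() +
    scale_fill_gradient(low = "white", high = "#b2182b", limits = c(0, 1)) +
    scale_y_reverse() +
    coord_fixed() +
    labs(x = "grid cell (x)", y = "grid cell (y)", fill = "normalized\ncount") +
    theme_minimal()
}

#' Bland-Altman plot
#'
#' Differences against pair means with the bias (solid) and limits of
#' agreement (dashed).
#'
#' @param object A `bland_altman` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot(object$points, aes(x = .data$mean, y = .data$diff)) +
    geom_point(alpha = 0.6) +
    geom_hline(yintercept = object$bias, linewidth = 0.8) +
    geom_hline(yintercept = c(object$loa_low, object$loa_high),
               linetype = "dashed") +
    labs(x = "mean of pair", y = "difference (query - reference)") +
    theme_minimal()
}

#' Plot a DTW warp path within its Sakoe-Chiba band
#'
#' @param object A `dtw_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dtw_result <- function(object, ...) {
  ggplot(object$path, aes(x = .data$i, y = .data$j)) +
    geom_abline(slope = 1, intercept = c(-object$band_halfwidth,
                                         object$band_halfwidth),
                color = "grey70") +
    geom_path(color = "#b2182b", linewidth = 0.8) +
    coord_fixed() +
    labs(x = "query index", y = "reference index") +
    theme_minimal()
}

#' Plot a success-vs-size curve fit
#'
#' @param object A `success_curve_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.success_curve_fit <- function(object, ...) {
  grid <- tibble::tibble(
    size_dva = seq(min(object$data$size_dva), max(object$data$size_dva),
                   length.out = 100))
  grid$fit <- success_curve(object, grid$size_dva)
  ggplot(object$data, aes(x = .data$size_dva, y = .data$median_success)) +
    geom_point(size = 2) +
    geom_line(data = grid, aes(y = .data$fit), color = "#2166ac") +
    geom_vline(xintercept = object$plateau_onset_dva, linetype = "dashed") +
    labs(x = "target diameter (DVA)", y = "median successful targets") +
    theme_minimal()
}

#' Plot rolling workload metric series
#'
#' @param object A `metric_series` tibble (rows from one or more metrics
#'   can be bound together).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metric_series <- function(object, ...) {
  ggplot(object, aes(x = .data$t_center, y = .data$value,
                     color = .data$metric)) +
    geom_line() +
    geom_point(size = 1) +
    labs(x = "window centre (s)", y = "metric value", color = NULL) +
    theme_minimal()
}

#' Plot detected events over the gaze trace
#'
#' Horizontal velocity-coded event ribbon: one colored segment per
#' detected event along time.
#'
#' @param object An `event_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.event_table <- function(object, ...) {
  ggplot(object, aes(xmin = .data$t_on_s, xmax = .data$t_off_s,
                     ymin = 0, ymax = 1, fill = .data$label)) +
    geom_rect() +
    scale_fill_manual(values = c(fixation = "#4daf4a", saccade = "#e41a1c",
                                 pursuit = "#377eb8", gap = "grey70")) +
    labs(x = "time (s)", y = NULL, fill = "event") +
    theme_minimal() +
    theme(axis.text.y = element_blank())
}
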