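# Task-level analyses: painting coverage, focus dwell scoring and
# success-vs-size curve, cross-task pursuit comparison.

#' Screen-coverage displacement from uniform
#'
#' Bins valid gaze samples into `grid_cell_px` x `grid_cell_px` cells
#' (remainder cells at the right/bottom edges count as cells) and computes
#' per-cell displacement from uniform coverage. With `c` the uniform unit
#' (total samples / number of cells), displacement is
#' `clip(count / c - 1, -1, +1)`: zero for uniform coverage, -1 for a cell
#' with no gaze data, saturating at +1 for a cell with at least twice the
#' uniform count. Before clipping, displacements sum to zero over the
#' grid.
#'
#' @param stream A [gaze_stream()].
#' @param grid_cell_px Cell edge in pixels (default 100).
#' @return A `coverage_map` tibble with one row per cell: `cell_x`,
#'   `cell_y` (1-based indices), `n`, `displacement`; attributes
#'   `uniform_unit_c`, `n_cells_x`, `n_cells_y`, `grid_cell_px`.
#' @export
coverage_displacement <- function(stream, grid_cell_px = 100) {
  check_number(grid_cell_px, "grid_cell_px", positive = TRUE)
  geometry <- stream_geometry(stream)
  ok <- stream$valid & is.finite(stream$x_px) & is.finite(stream$y_px)
  x <- stream$x_px[ok]; y <- stream$y_px[ok]
  on <- x >= 0 & x <= geometry$width_px & y >= 0 & y <= geometry$height_px
  x <- x[on]; y <- y[on]
  if (length(x) == 0) {
    gc_abort("No valid on-screen samples to bin.", "gc_empty_input")
  }
  ncx <- ceiling(geometry$width_px / grid_cell_px)
  ncy <- ceiling(geometry$height_px / grid_cell_px)
  ix <- pmin(floor(x / grid_cell_px) + 1, ncx)
  iy <- pmin(floor(y / grid_cell_px) + 1, ncy)
  counts <- table(factor(ix, levels = 1:ncx), factor(iy, levels = 1:ncy))
  cc <- length(x) / (ncx * ncy)
  grid <- tidyr::expand_grid(cell_y = 1:ncy, cell_x = 1:ncx)
  grid$n <- as.numeric(counts[cbind(grid$cell_x, grid$cell_y)])
  grid$displacement <- pmin(pmax(grid$n / cc - 1, -1), 1)
  structure(grid[, c("cell_x", "cell_y", "n", "displacement")],
            uniform_unit_c = cc, n_cells_x = ncx, n_cells_y = ncy,
            grid_cell_px = grid_cell_px,
            class = c("coverage_map", class(tibble::tibble())))
}

#' Normalized fixation heatmap
#'
#' Bins fixation events by their centroid (midpoint of on/off positions)
#' into the coverage grid and normalizes by the count of the most
#' frequently fixated cell, so the maximum cell value is exactly 1.
#'
#' @param events An `event_table` containing at least one fixation.
#' @param geometry A [screen_geometry()].
#' @param grid_cell_px Cell edge in pixels (default 100).
#' @return A `fixation_heatmap` tibble: `cell_x`, `cell_y`, `n`, `value`.
#' @export
fixation_heatmap <- function(events, geometry = screen_geometry(),
                             grid_cell_px = 100) {
  check_geometry(geometry)
  fix <- events[!is.na(events$label) & events$label == "fixation", ,
                drop = FALSE]
  fix <- fix[is.finite(fix$x_on_px) & is.finite(fix$x_off_px), ,
             drop = FALSE]
  if (nrow(fix) == 0) {
    gc_abort("No fixation events to bin.", "gc_empty_input")
  }
  cx <- (fix$x_on_px + fix$x_off_px) / 2
  cy <- (fix$y_on_px + fix$y_off_px) / 2
  ncx <- ceiling(geometry$width_px / grid_cell_px)
  ncy <- ceiling(geometry$height_px / grid_cell_px)
  ix <- pmin(pmax(floor(cx / grid_cell_px) + 1, 1), ncx)
  iy <- pmin(pmax(floor(cy / grid_cell_px) + 1, 1), ncy)
  counts <- table(factor(ix, levels = 1:ncx), factor(iy, levels = 1:ncy))
  grid <- tidyr::expand_grid(cell_y = 1:ncy, cell_x = 1:ncx)
  grid$n <- as.numeric(counts[cbind(grid$cell_x, grid$cell_y)])
  grid$value <- grid$n / max(grid$n)
  structure(grid[, c("cell_x", "cell_y", "n", "value")],
            grid_cell_px = grid_cell_px,
            class = c("fixation_heatmap", class(tibble::tibble())))
}

#' Score a Focus-task run
#'
#' Replays the dwell/timeout logic over a recorded gaze stream. Per
#' target, a dwell clock starts when gaze first enters the target disc and
#' resets whenever gaze stays outside the disc (or is invalid) for longer
#' than `grace_s`. A target succeeds when the clock reaches
#' `dwell_required_s` before `timeout_s` has elapsed; the next target
#' appears at the moment of selection or timeout.
#'
#' @param stream A [gaze_stream()] covering the schedule's time span.
#' @param schedule A [focus_schedule()].
#' @param grace_s Dropout/excursion tolerance before a dwell reset
#'   (default 0.1 s).
#' @param dwell_reset_policy `"full"` (the clock restarts from zero after
#'   a reset; default) or `"pause"` (out-of-disc time beyond the grace is
#'   not counted but accrued dwell is kept).
#' @return A `focus_result` tibble, one row per target: `target`,
#'   `size_dva`, `t_on_s`, `success`, `completion_s` (onset-to-selection
#'   time, `NA` on timeout), `elapsed_s` (`completion_s` or the timeout),
#'   `dwell_resets`.
#' @export
score_focus <- function(stream, schedule, grace_s = 0.1,
                        dwell_reset_policy = c("full", "pause")) {
  dwell_reset_policy <- match.arg(dwell_reset_policy)
  geometry <- stream_geometry(stream)
  tg <- schedule$targets
  radius_px <- dva_to_px(tg$diameter_dva / 2, geometry)
  t <- stream$t_s
  n <- length(t)
  inside_target <- function(k) {
    stream$valid &
      sqrt((stream$x_px - tg$x_px[k])^2 + (stream$y_px - tg$y_px[k])^2) <=
        radius_px[k]
  }
  res <- vector("list", nrow(tg))
  t_on <- t[1]
  i <- 1L
  for (k in seq_len(nrow(tg))) {
    inside <- inside_target(k)
    inside[is.na(inside)] <- FALSE
    dwell_start <- NA_real_; out_since <- NA_real_
    accrued <- 0                        # used by the "pause" policy
    resets <- 0L
    resolved <- NA_real_; success <- NA
    while (i <= n) {
      ti <- t[i]
      if (inside[i]) {
        if (is.na(dwell_start)) dwell_start <- ti
        out_since <- NA_real_
      } else if (!is.na(dwell_start)) {
        if (is.na(out_since)) out_since <- ti
        if (ti - out_since > grace_s) {
          if (dwell_reset_policy == "pause") {
            accrued <- accrued + (out_since - dwell_start)
          } else {
            accrued <- 0
          }
          resets <- resets + 1L
          dwell_start <- NA_real_
          out_since <- NA_real_
        }
      }
      done_at <- if (!is.na(dwell_start)) {
        dwell_start + (schedule$dwell_required_s - accrued)
      } else NA_real_
      if (!is.na(done_at) && ti >= done_at && done_at <= t_on +
            schedule$timeout_s) {
        resolved <- done_at; success <- TRUE
        break
      }
      if (ti - t_on >= schedule$timeout_s) {
        resolved <- t_on + schedule$timeout_s; success <- FALSE
        break
      }
      i <- i + 1L
    }
    if (i > n) {
      gc_abort("Gaze stream ends before the schedule is complete.",
               "gc_insufficient_data")
    }
    res[[k]] <- tibble::tibble(
      target = k, size_dva = tg$diameter_dva[k], t_on_s = t_on,
      success = success,
      completion_s = if (success) resolved - t_on else NA_real_,
      elapsed_s = resolved - t_on,
      dwell_resets = resets
    )
    t_on <- resolved
  }
  structure(dplyr::bind_rows(res),
            class = c("focus_result", class(tibble::tibble())))
}

#' Aggregate Focus results by target size
#'
#' @param result A `focus_result` from [score_focus()].
#' @return A tibble per size: `size_dva`, `n_targets`, `n_success`,
#'   `median_success` (0/1 per-target median), `mean_completion_s` among
#'   successes.
#' @export
focus_by_size <- function(result) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(result), .data$size_dva),
    n_targets = dplyr::n(),
    n_success = sum(.data$success),
    median_success = median(as.numeric(.data$success)),
    mean_completion_s = mean(.data$completion_s[.data$success]),
    .groups = "drop"
  )
}

#' Fit the success-vs-size asymptotic exponential
#'
#' Least-squares fit of `y(s) = a - b * exp(-c * s)` (with `c >= 0`) to
#' the per-size median success counts, via Levenberg-Marquardt with up to
#' 20 jittered restarts. The first derivative `b * c * exp(-c * s)` and
#' second derivative `-b * c^2 * exp(-c * s)` characterize the plateau:
#' the plateau onset is reported where the first derivative drops below
#' `slope_threshold` (default 1.0 per DVA).
#'
#' @param data A data frame with columns `size_dva` and `median_success`
#'   (at least 3 distinct sizes).
#' @param slope_threshold First-derivative level defining plateau onset.
#' @return A `success_curve_fit` object with elements `a`, `b`, `c`,
#'   `residual_norm`, `plateau_onset_dva`, `data`.
#' @export
fit_success_curve <- function(data, slope_threshold = 1.0) {
  check_columns(data, c("size_dva", "median_success"), "`data`")
  s <- data$size_dva; y <- data$median_success
  if (length(unique(s)) < 3) {
    gc_abort("Need at least 3 distinct sizes.", "gc_insufficient_data")
  }
  if (var(y) == 0) {
    fit <- list(a = mean(y), b = 0, c = 0, residual_norm = 0)
  } else {
    df <- data.frame(s = s, y = y)
    starts <- list(c(a = max(y), b = max(y) - min(y), c = 1))
    set.seed(1203)
    for (j in 1:19) {
      starts[[j + 1]] <- c(a = max(y) * runif(1, 0.8, 1.5),
                           b = (max(y) - min(y)) * runif(1, 0.3, 3) + 0.1,
                           c = exp(runif(1, log(0.05), log(3))))
    }
    best <- NULL
    for (st in starts) {
      f <- tryCatch(
        minpack.lm::nlsLM(y ~ a - b * exp(-c * s), data = df, start = st,
                          lower = c(a = -Inf, b = -Inf, c = 0),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(f)) {
        rn <- sqrt(sum(stats::residuals(f)^2))
        if (is.null(best) || rn < best$rn) best <- list(fit = f, rn = rn)
      }
    }
    if (is.null(best)) {
      gc_abort("Curve fit failed to converge from all restarts.",
               "gc_fit_failure")
    }
    cf <- stats::coef(best$fit)
    fit <- list(a = unname(cf["a"]), b = unname(cf["b"]),
                c = unname(cf["c"]), residual_norm = best$rn)
  }
  fit$data <- tibble::tibble(size_dva = s, median_success = y)
  fit$plateau_onset_dva <- if (fit$b * fit$c > slope_threshold && fit$c > 0) {
    log(fit$b * fit$c / slope_threshold) / fit$c
  } else {
    min(s)  # slope already below threshold at the smallest size
  }
  structure(fit, class = "success_curve_fit")
}

#' Evaluate a fitted success curve and its derivatives
#'
#' @param fit A `success_curve_fit`.
#' @param size_dva Sizes at which to evaluate.
#' @return Numeric vector.
#' @export
success_curve <- function(fit, size_dva) {
  fit$a - fit$b * exp(-fit$c * size_dva)
}

#' @rdname success_curve
#' @export
success_curve_deriv1 <- function(fit, size_dva) {
  fit$b * fit$c * exp(-fit$c * size_dva)
}

#' @rdname success_curve
#' @export
success_curve_deriv2 <- function(fit, size_dva) {
  -fit$b * fit$c^2 * exp(-fit$c * size_dva)
}

#' @export
print.success_curve_fit <- function(x, ...) {
  cat(sprintf("<success_curve_fit> y(s) = %.4g - %.4g * exp(-%.4g * s)\n",
              x$a, x$b, x$c))
  cat(sprintf("  residual norm %.4g, plateau onset %.2f DVA\n",
              x$residual_norm, x$plateau_onset_dva))
  invisible(x)
}

#' Compare smooth-pursuit segments between two conditions
#'
#' Extracts pursuit durations and amplitudes from two event tables (e.g.
#' the tracking and painting tasks) and applies the Mann-Whitney U test
#' separately to each measure.
#'
#' @param events_a,events_b Event tables; each must contain at least one
#'   pursuit event.
#' @param names Condition names used in the output (default "a", "b").
#' @return A tibble with one row per measure (`duration_s`,
#'   `magnitude_dva`): `u`, `p_value`, `median_a`, `median_b`, `n_a`,
#'   `n_b`.
#' @export
compare_pursuits <- function(events_a, events_b, names = c("a", "b")) {
  pull_pursuits <- function(ev, who) {
    p <- ev[!is.na(ev$label) & ev$label == "pursuit", , drop = FALSE]
    if (nrow(p) == 0) {
      gc_abort(sprintf("Condition %s has no pursuit events.", who),
               "gc_insufficient_data")
    }
    tibble::tibble(duration_s = p$t_off_s - p$t_on_s,
                   magnitude_dva = p$amplitude_dva)
  }
  a <- pull_pursuits(events_a, names[1])
  b <- pull_pursuits(events_b, names[2])
  purrr::map_dfr(c("duration_s", "magnitude_dva"), function(m) {
    mw <- mann_whitney_u(a[[m]], b[[m]])
    tibble::tibble(measure = m, u = mw$u, p_value = mw$p_value,
                   median_a = median(a[[m]], na.rm = TRUE),
                   median_b = median(b[[m]], na.rm = TRUE),
                   n_a = nrow(a), n_b = nrow(b))
  })
}
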