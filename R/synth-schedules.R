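# Task stimulus schedules: what appears on the screen and when. The three
# tasks isolate fixations+saccades (focus), smooth pursuit (tracking) and
# free exploration (painting).

#' Focus-task stimulus schedule
#'
#' An ordered list of circular dwell targets. Each target appears
#' immediately when the previous one is resolved (selected or timed out),
#' must be fixated continuously for `dwell_required_s` seconds, and times
#' out after `timeout_s` seconds.
#'
#' @param targets Tibble with columns `x_px`, `y_px`, `diameter_dva`.
#' @param dwell_required_s Continuous dwell needed for success (default 2 s).
#' @param timeout_s Per-target timeout (default 10 s).
#' @return A `focus_schedule` object.
#' @export
focus_schedule <- function(targets, dwell_required_s = 2, timeout_s = 10) {
  check_columns(targets, c("x_px", "y_px", "diameter_dva"), "focus targets")
  check_number(dwell_required_s, "dwell_required_s", positive = TRUE)
  check_number(timeout_s, "timeout_s", positive = TRUE)
  structure(list(targets = tibble::as_tibble(targets),
                 dwell_required_s = dwell_required_s, timeout_s = timeout_s),
            class = "focus_schedule")
}

#' Generate a randomized Focus-task schedule
#'
#' Draws `n_targets` circular targets with diameters cycled (balanced)
#' across `size_set_dva` and centres uniform over the region where the
#' whole target fits on screen. Reproducible for a fixed seed.
#'
#' @param n_targets Number of targets (default 60, the task's full length).
#' @param size_set_dva Target diameters in DVA. The default
#'   `c(2, 3, 4, 5, 6, 7)` spans the range where dwell success transitions
#'   from hard to easy.
#' @param geometry A [screen_geometry()].
#' @param dwell_required_s,timeout_s Passed to [focus_schedule()].
#' @param seed Integer seed.
#' @return A `focus_schedule`.
#' @export
make_focus_schedule <- function(n_targets = 60,
                                size_set_dva = c(2, 3, 4, 5, 6, 7),
                                geometry = screen_geometry(),
                                dwell_required_s = 2, timeout_s = 10,
                                seed = 1) {
  check_number(n_targets, "n_targets", positive = TRUE)
  check_geometry(geometry)
  if (any(size_set_dva <= 0)) {
    gc_abort("Target sizes must be positive.", "gc_invalid_size")
  }
  radii_px <- dva_to_px(size_set_dva / 2, geometry)
  if (any(2 * radii_px >= geometry$width_px) ||
      any(2 * radii_px >= geometry$height_px)) {
    gc_abort("A target size does not fit on the screen.", "gc_invalid_size")
  }
  set.seed(seed)
  sizes <- rep_len(size_set_dva, n_targets)
  sizes <- sample(sizes)  # balanced counts, randomized order
  r <- dva_to_px(sizes / 2, geometry)
  targets <- tibble::tibble(
    x_px = runif(n_targets, r, geometry$width_px - r),
    y_px = runif(n_targets, r, geometry$height_px - r),
    diameter_dva = sizes
  )
  focus_schedule(targets, dwell_required_s, timeout_s)
}

#' Tracking-task target path
#'
#' Piecewise-linear waypoint trajectories traversed at constant angular
#' speed. `waypoints` is a long tibble with one row per waypoint:
#' `target` (trajectory id), `x_px`, `y_px`, and `t_s` (traversal time
#' since trajectory onset, with `t_s = 0` at the first waypoint).
#'
#' @param waypoints Waypoint tibble as described above.
#' @param speed_dva_s Angular traversal speed (default 15 DVA/s).
#' @return A `tracking_path` object.
#' @export
tracking_path <- function(waypoints, speed_dva_s = 15) {
  check_columns(waypoints, c("target", "x_px", "y_px", "t_s"),
                "tracking waypoints")
  check_number(speed_dva_s, "speed_dva_s", positive = TRUE)
  structure(list(waypoints = tibble::as_tibble(waypoints),
                 speed_dva_s = speed_dva_s),
            class = "tracking_path")
}

#' Generate randomized Tracking-task trajectories
#'
#' Each of `n_targets` trajectories is a random piecewise-linear path of
#' `n_segments` segments, each at least `min_segment_dva` long, traversed
#' at constant angular speed `speed_dva_s` (segment traversal times are
#' derived from the segment's angular length).
#'
#' @param n_targets Number of moving targets (default 24, the task's full
#'   length).
#' @param speed_dva_s Angular speed in DVA/s (default 15).
#' @param geometry A [screen_geometry()].
#' @param n_segments Segments per trajectory (default 3).
#' @param min_segment_dva Minimum segment length in DVA (default 5).
#' @param seed Integer seed.
#' @return A `tracking_path`.
#' @export
make_tracking_path <- function(n_targets = 24, speed_dva_s = 15,
                               geometry = screen_geometry(),
                               n_segments = 3, min_segment_dva = 5,
                               seed = 1) {
  check_number(n_targets, "n_targets", positive = TRUE)
  check_number(speed_dva_s, "speed_dva_s", positive = TRUE)
  check_geometry(geometry)
  set.seed(seed)
  margin <- 20
  draw_point <- function() {
    c(runif(1, margin, geometry$width_px - margin),
      runif(1, margin, geometry$height_px - margin))
  }
  wp <- purrr::map_dfr(seq_len(n_targets), function(k) {
    pts <- matrix(NA_real_, n_segments + 1, 2)
    pts[1, ] <- draw_point()
    for (i in seq_len(n_segments)) {
      repeat {
        p <- draw_point()
        seg <- angular_distance(pts[i, 1], pts[i, 2], p[1], p[2], geometry)
        if (seg >= min_segment_dva) break
      }
      pts[i + 1, ] <- p
    }
    # traversed angular length: integral of infinitesimal steps, i.e. the
    # pixel length at the local angular resolution
    seg_dva <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2) *
      dva_per_px(geometry)
    tibble::tibble(target = k, x_px = pts[, 1], y_px = pts[, 2],
                   t_s = c(0, cumsum(seg_dva / speed_dva_s)))
  })
  tracking_path(wp, speed_dva_s)
}

#' Painting-task specification
#'
#' Free "painting" of the screen with the gaze cursor for a fixed
#' duration, starting at the screen centre.
#'
#' @param duration_s Task duration in seconds (default 300, i.e. 5 min).
#' @param start Starting position `c(x_px, y_px)`; defaults to the screen
#'   centre of `geometry`.
#' @param geometry A [screen_geometry()].
#' @return A `painting_spec` object.
#' @export
painting_spec <- function(duration_s = 300, start = NULL,
                          geometry = screen_geometry()) {
  check_number(duration_s, "duration_s", positive = TRUE)
  if (is.null(start)) {
    start <- c(geometry$width_px / 2, geometry$height_px / 2)
  }
  structure(list(duration_s = duration_s,
                 start = as.numeric(start)),
            class = "painting_spec")
}

#' Sample a tracking path at a fixed rate
#'
#' Linear interpolation of each trajectory's waypoint traversal on a
#' uniform time grid; trajectories are concatenated back to back.
#'
#' @param path A [tracking_path()].
#' @param rate_hz Sampling rate (default 100).
#' @return Tibble with columns `target`, `t_s` (global time), `x_px`,
#'   `y_px`, `corner` (TRUE for samples adjacent to a waypoint corner or a
#'   trajectory boundary).
#' @export
sample_tracking_path <- function(path, rate_hz = 100) {
  dt <- 1 / rate_hz
  offset <- 0
  wps <- path$waypoints
  by_target <- split(wps, factor(wps$target, levels = unique(wps$target)))
  purrr::map_dfr(by_target, function(w) {
    total <- max(w$t_s)
    tt <- seq(0, total, by = dt)
    x <- approx(w$t_s, w$x_px, xout = tt)$y
    y <- approx(w$t_s, w$y_px, xout = tt)$y
    # flag samples whose finite-difference step straddles a waypoint time
    corner_t <- w$t_s[c(-1, -nrow(w))]
    corner <- vapply(tt, function(ti) {
      any(abs(ti - corner_t) <= dt)
    }, logical(1))
    out <- tibble::tibble(target = w$target[1], t_s = offset + tt,
                          x_px = x, y_px = y, corner = corner)
    offset <<- offset + total + dt
    out
  })
}
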