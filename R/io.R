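# File I/O: CSV streams, JSON schedules/intervals, YAML config, and the
# per-session bundle. Column schemas:
#   gaze  CSV: t_s,x_px,y_px,valid   (valid in {0,1})
#   pupil CSV: t_s,diameter_mm
#   rr    CSV: beat_t_s,rr_ms

#' Read / write a gaze CSV
#'
#' @param path File path.
#' @param geometry A [screen_geometry()] attached to the returned stream.
#' @param rate_hz Nominal sampling rate attached to the returned stream.
#' @return `read_gaze_csv()` returns a [gaze_stream()];
#'   `write_gaze_csv()` invisibly returns `path`.
#' @export
read_gaze_csv <- function(path, geometry = screen_geometry(), rate_hz = 100) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("t_s", "x_px", "y_px", "valid"), basename(path))
  check_monotone_time(df$t_s, basename(path))
  df$valid <- df$valid != 0
  gaze_stream(df, geometry = geometry, rate_hz = rate_hz)
}

#' @rdname read_gaze_csv
#' @param stream A [gaze_stream()].
#' @export
write_gaze_csv <- function(stream, path) {
  df <- tibble::as_tibble(stream)
  df$valid <- as.integer(df$valid)
  readr::write_csv(df, path)
  invisible(path)
}

#' Read / write a pupil-diameter CSV
#'
#' @inheritParams read_gaze_csv
#' @return `read_pupil_csv()` returns a `pupil_stream` tibble with columns
#'   `t_s`, `diameter_mm`, `valid`.
#' @export
read_pupil_csv <- function(path, rate_hz = 100) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("t_s", "diameter_mm"), basename(path))
  check_monotone_time(df$t_s, basename(path))
  pupil_stream(df, rate_hz = rate_hz)
}

#' @rdname read_pupil_csv
#' @param stream A `pupil_stream`.
#' @export
write_pupil_csv <- function(stream, path) {
  readr::write_csv(tibble::as_tibble(stream)[, c("t_s", "diameter_mm")], path)
  invisible(path)
}

#' Construct a pupil stream
#'
#' @param samples Data frame with columns `t_s`, `diameter_mm` (and
#'   optionally `valid`). Rows are tracker samples; blink dropouts appear
#'   as holes in the time base, not as rows.
#' @param rate_hz Nominal sampling rate.
#' @return A `pupil_stream` tibble with columns `t_s`, `diameter_mm`,
#'   `valid`.
#' @export
pupil_stream <- function(samples, rate_hz = 100) {
  check_columns(samples, c("t_s", "diameter_mm"), "pupil samples")
  check_monotone_time(samples$t_s, "pupil stream")
  out <- tibble::as_tibble(samples)
  if (!"valid" %in% names(out)) out$valid <- is.finite(out$diameter_mm)
  out <- out[, c("t_s", "diameter_mm", "valid")]
  structure(out, rate_hz = rate_hz,
            class = c("pupil_stream", class(tibble::tibble())))
}

#' Construct an RR-interval series
#'
#' @param beats Data frame with columns `beat_t_s` (beat time, seconds)
#'   and `rr_ms` (interval ending at that beat, milliseconds), optionally
#'   `artifact` (logical flag, default all `FALSE`).
#' @return An `rr_series` tibble.
#' @export
rr_series <- function(beats) {
  check_columns(beats, c("beat_t_s", "rr_ms"), "RR series")
  check_monotone_time(beats$beat_t_s, "RR series")
  if (any(beats$rr_ms <= 0)) {
    gc_abort("RR intervals must be strictly positive.", "gc_invalid_interval")
  }
  out <- tibble::as_tibble(beats)
  if (!"artifact" %in% names(out)) out$artifact <- FALSE
  out <- out[, c("beat_t_s", "rr_ms", "artifact")]
  structure(out, class = c("rr_series", class(tibble::tibble())))
}

#' Read / write an RR-interval CSV
#'
#' @inheritParams read_gaze_csv
#' @return `read_rr_csv()` returns an [rr_series()].
#' @export
read_rr_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("beat_t_s", "rr_ms"), basename(path))
  check_monotone_time(df$beat_t_s, basename(path))
  rr_series(df)
}

#' @rdname read_rr_csv
#' @param series An [rr_series()].
#' @export
write_rr_csv <- function(series, path) {
  readr::write_csv(tibble::as_tibble(series)[, c("beat_t_s", "rr_ms")], path)
  invisible(path)
}

#' Read / write task schedules as JSON
#'
#' Serializes [focus_schedule()], [tracking_path()] and [painting_spec()]
#' objects.
#'
#' @param schedule A schedule object.
#' @param path File path.
#' @export
write_schedule_json <- function(schedule, path) {
  obj <- if (inherits(schedule, "focus_schedule")) {
    list(type = "focus",
         dwell_required_s = schedule$dwell_required_s,
         timeout_s = schedule$timeout_s,
         targets = schedule$targets)
  } else if (inherits(schedule, "tracking_path")) {
    list(type = "tracking",
         speed_dva_s = schedule$speed_dva_s,
         waypoints = schedule$waypoints)
  } else if (inherits(schedule, "painting_spec")) {
    list(type = "painting",
         duration_s = schedule$duration_s,
         start = schedule$start)
  } else {
    gc_abort("Unknown schedule type.", "gc_invalid_parameter")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schedule_json
#' @export
read_schedule_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  switch(obj$type,
    focus = focus_schedule(targets = tibble::as_tibble(obj$targets),
                           dwell_required_s = obj$dwell_required_s,
                           timeout_s = obj$timeout_s),
    tracking = tracking_path(waypoints = tibble::as_tibble(obj$waypoints),
                             speed_dva_s = obj$speed_dva_s),
    painting = painting_spec(duration_s = obj$duration_s,
                             start = unlist(obj$start)),
    gc_abort(sprintf("Unknown schedule type \"%s\" in %s.", obj$type, path),
             "gc_schema_error")
  )
}

#' Bundle the signals of one recorded (or simulated) session
#'
#' Plumbing container holding the gaze, pupil and RR streams, the per-task
#' stimulus schedules, the labeled task intervals and optional per-task
#' subjective workload scores.
#'
#' @param gaze A [gaze_stream()].
#' @param pupil A [pupil_stream()].
#' @param rr An [rr_series()].
#' @param schedules Named list of schedule objects, one per task.
#' @param task_intervals Tibble with columns `task`, `t_on_s`, `t_off_s`;
#'   intervals must be ordered and non-overlapping.
#' @param tlx_scores Optional named numeric vector of per-task scores.
#' @return A `session_bundle` list.
#' @export
session_bundle <- function(gaze, pupil, rr, schedules = list(),
                           task_intervals = NULL, tlx_scores = NULL) {
  if (!is.null(task_intervals)) {
    check_columns(task_intervals, c("task", "t_on_s", "t_off_s"),
                  "task intervals")
    o <- order(task_intervals$t_on_s)
    ti <- task_intervals[o, ]
    if (any(ti$t_off_s <= ti$t_on_s) ||
        (nrow(ti) > 1 && any(utils::head(ti$t_off_s, -1) >
                             utils::tail(ti$t_on_s, -1) + 1e-9))) {
      gc_abort("Task intervals must be positive-length and non-overlapping.",
               "gc_schema_error")
    }
    bad <- setdiff(names(schedules), ti$task)
    if (length(bad) > 0) {
      gc_abort(sprintf("Schedule(s) %s reference no task interval.",
                       paste(bad, collapse = ", ")), "gc_schema_error")
    }
    task_intervals <- tibble::as_tibble(ti)
  }
  structure(list(gaze = gaze, pupil = pupil, rr = rr, schedules = schedules,
                 task_intervals = task_intervals, tlx_scores = tlx_scores),
            class = "session_bundle")
}

#' Read / write a session bundle as a directory of plain-text files
#'
#' Writes `gaze.csv`, `pupil.csv`, `rr.csv`, one `schedule_<task>.json`
#' per task, `task_intervals.json` and `tlx.json` under `dir`. Numeric
#' round trips are exact to well beyond 9 significant digits.
#'
#' @param bundle A [session_bundle()].
#' @param dir Directory path (created if needed).
#' @param geometry,rate_hz Used when re-reading the gaze stream.
#' @export
write_session <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gaze_csv(bundle$gaze, file.path(dir, "gaze.csv"))
  write_pupil_csv(bundle$pupil, file.path(dir, "pupil.csv"))
  write_rr_csv(bundle$rr, file.path(dir, "rr.csv"))
  for (task in names(bundle$schedules)) {
    write_schedule_json(bundle$schedules[[task]],
                        file.path(dir, paste0("schedule_", task, ".json")))
  }
  if (!is.null(bundle$task_intervals)) {
    jsonlite::write_json(bundle$task_intervals,
                         file.path(dir, "task_intervals.json"), digits = NA)
  }
  if (!is.null(bundle$tlx_scores)) {
    jsonlite::write_json(as.list(bundle$tlx_scores),
                         file.path(dir, "tlx.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir, geometry = screen_geometry(), rate_hz = 100) {
  gaze <- read_gaze_csv(file.path(dir, "gaze.csv"), geometry, rate_hz)
  pupil <- read_pupil_csv(file.path(dir, "pupil.csv"))
  rr <- read_rr_csv(file.path(dir, "rr.csv"))
  sched_files <- list.files(dir, pattern = "^schedule_.*\\.json$",
                            full.names = TRUE)
  schedules <- lapply(sched_files, read_schedule_json)
  names(schedules) <- sub("^schedule_(.*)\\.json$", "\\1",
                          basename(sched_files))
  ti_path <- file.path(dir, "task_intervals.json")
  task_intervals <- if (file.exists(ti_path)) {
    tibble::as_tibble(jsonlite::read_json(ti_path, simplifyVector = TRUE))
  }
  tlx_path <- file.path(dir, "tlx.json")
  tlx <- if (file.exists(tlx_path)) {
    unlist(jsonlite::read_json(tlx_path, simplifyVector = TRUE))
  }
  session_bundle(gaze, pupil, rr, schedules, task_intervals, tlx)
}

#' Read a YAML configuration file
#'
#' Configuration keys mirror the function arguments: `geometry`
#' (width_px, height_px, diagonal_cm, distance_cm), `detector` (passed to
#' [detector_params()]), `workload` (win_s, step_s, cpd_mode), `smoothing`
#' (window) and `seed`. Missing keys fall back to package defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A named list with entries `geometry`, `detector`, `workload`,
#'   `smoothing`, `seed`.
#' @export
read_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  geometry <- do.call(screen_geometry, cfg$geometry %||% list())
  detector <- do.call(detector_params, cfg$detector %||% list())
  workload <- utils::modifyList(
    list(win_s = 10, step_s = 5, cpd_mode = "relative"),
    cfg$workload %||% list())
  smoothing <- utils::modifyList(list(window = 5), cfg$smoothing %||% list())
  list(geometry = geometry, detector = detector, workload = workload,
       smoothing = smoothing, seed = cfg$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
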