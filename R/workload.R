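# Physiological workload metrics: pupil preprocessing and change in pupil
# diameter (CPD), RR-interval artifact flagging, heart rate, and
# ultra-short-term RMSSD, per task and in rolling windows.

#' Clean a pupil-diameter stream
#'
#' Applies three rules, in order, to flag invalid samples (samples are
#' never deleted from the timeline):
#' 1. size outliers: diameters outside the feasible `[min_mm, max_mm]`
#'    range;
#' 2. dilation-speed outliers: per-sample speed (the larger absolute
#'    diameter change per unit time versus the preceding and following
#'    surviving samples) above `median + speed_mad_mult * MAD`;
#' 3. gap margins: samples within `gap_pad_ms` of either edge of a gap in
#'    the surviving time series longer than `gap_min_ms`.
#'
#' @param stream A [pupil_stream()].
#' @param min_mm,max_mm Feasible diameter range (defaults 1.5 and 9 mm).
#' @param speed_mad_mult MAD multiplier for rule 2 (default 16).
#' @param gap_pad_ms Margin removed around gaps (default 50 ms).
#' @param gap_min_ms Minimum spacing counting as a gap (default 75 ms).
#' @return The stream with updated `valid`; the attribute
#'   `clean_report` (see [clean_report()]) records per-rule removals.
#' @export
clean_pupil <- function(stream, min_mm = 1.5, max_mm = 9,
                        speed_mad_mult = 16, gap_pad_ms = 50,
                        gap_min_ms = 75) {
  if (nrow(stream) == 0) {
    gc_abort("Empty pupil stream.", "gc_empty_input")
  }
  t <- stream$t_s; d <- stream$diameter_mm
  valid <- stream$valid & is.finite(d)

  size_mask <- valid & (d < min_mm | d > max_mm)
  valid <- valid & !size_mask

  speed_mask <- rep(FALSE, length(t))
  idx <- which(valid)
  if (length(idx) >= 3) {
    ti <- t[idx]; di <- d[idx]
    fwd <- c(abs(diff(di)) / diff(ti), NA)
    bwd <- c(NA, abs(diff(di)) / diff(ti))
    sp <- pmax(fwd, bwd, na.rm = TRUE)
    thr <- median(sp, na.rm = TRUE) +
      speed_mad_mult * mad(sp, constant = 1, na.rm = TRUE)
    speed_mask[idx[which(sp > thr)]] <- TRUE
    valid <- valid & !speed_mask
  }

  gap_mask <- rep(FALSE, length(t))
  idx <- which(valid)
  if (length(idx) >= 2) {
    ti <- t[idx]
    gaps <- which(diff(ti) > gap_min_ms / 1000)
    pad <- gap_pad_ms / 1000
    for (g in gaps) {
      ta <- ti[g]; tb <- ti[g + 1]
      gap_mask[idx[(ti >= ta - pad & ti <= ta) |
                     (ti >= tb & ti <= tb + pad)]] <- TRUE
    }
    valid <- valid & !gap_mask
  }

  if (!any(valid)) {
    gc_abort("All pupil samples were removed by cleaning.",
             "gc_degenerate_stream")
  }
  out <- stream
  out$valid <- valid
  report <- list(
    n_removed_size = sum(size_mask),
    n_removed_speed = sum(speed_mask),
    n_removed_gap = sum(gap_mask),
    masks = tibble::tibble(t_s = t, size = size_mask, speed = speed_mask,
                           gap = gap_mask)
  )
  attr(out, "clean_report") <- report
  out
}

#' @rdname clean_pupil
#' @param cleaned A stream returned by `clean_pupil()`.
#' @export
clean_report <- function(cleaned) {
  attr(cleaned, "clean_report")
}

#' Baseline pupil diameter
#'
#' Mean valid diameter over the `baseline_len_s` seconds immediately
#' before `task_start_s` (the resting window preceding the first task).
#' At least half of the window's expected samples must be valid.
#'
#' @param stream A (cleaned) [pupil_stream()].
#' @param task_start_s Start time of the first task (s).
#' @param baseline_len_s Baseline window length (default 2 s).
#' @return Baseline diameter in mm.
#' @export
baseline_pupil <- function(stream, task_start_s, baseline_len_s = 2) {
  rate <- attr(stream, "rate_hz") %||% 100
  win <- stream$t_s >= task_start_s - baseline_len_s &
    stream$t_s < task_start_s
  ok <- win & stream$valid
  if (sum(ok) < 0.5 * baseline_len_s * rate) {
    gc_abort("Fewer than half of the baseline-window samples are valid.",
             "gc_baseline_failure")
  }
  mean(stream$diameter_mm[ok])
}

#' Change in pupil diameter (CPD)
#'
#' CPD over a span is the deviation of the mean valid diameter from the
#' baseline, by default as a fractional (relative) change
#' `(mean - baseline) / baseline`; `cpd_mode = "absolute"` reports the
#' difference in mm instead. `mode = "task"` computes one value over
#' `span`; `mode = "rolling"` emits one value per `win_s`-second window
#' stepped by `step_s` inside `span`, with windows containing under 50%
#' valid samples set to `NA`.
#'
#' @param stream A cleaned [pupil_stream()].
#' @param baseline_mm Baseline diameter from [baseline_pupil()].
#' @param mode `"task"` or `"rolling"`.
#' @param span `c(t0, t1)` span in seconds; defaults to the stream range.
#' @param win_s,step_s Rolling window length and step (defaults 10 and 5).
#' @param cpd_mode `"relative"` (default) or `"absolute"`.
#' @return A scalar for `mode = "task"`; otherwise a `metric_series`
#'   tibble (`metric`, `t_start`, `t_center`, `value`).
#' @export
cpd <- function(stream, baseline_mm, mode = c("task", "rolling"),
                span = NULL, win_s = 10, step_s = 5,
                cpd_mode = c("relative", "absolute")) {
  mode <- match.arg(mode)
  cpd_mode <- match.arg(cpd_mode)
  check_number(baseline_mm, "baseline_mm", positive = TRUE)
  if (is.null(span)) span <- range(stream$t_s)
  rate <- attr(stream, "rate_hz") %||% 100
  span_cpd <- function(t0, t1) {
    win <- stream$t_s >= t0 & stream$t_s < t1
    ok <- win & stream$valid
    if (sum(ok) < 0.5 * (t1 - t0) * rate) return(NA_real_)
    m <- mean(stream$diameter_mm[ok])
    if (cpd_mode == "relative") (m - baseline_mm) / baseline_mm
    else m - baseline_mm
  }
  if (mode == "task") {
    return(span_cpd(span[1], span[2]))
  }
  w <- rolling_windows(span[1], span[2], win_s, step_s)
  metric_series("CPD", w, vapply(seq_len(nrow(w)), function(j) {
    span_cpd(w$t_start[j], w$t_end[j])
  }, numeric(1)), win_s, step_s)
}

metric_series <- function(name, windows, values, win_s, step_s) {
  structure(tibble::tibble(metric = name, t_start = windows$t_start,
                           t_center = windows$t_center, value = values),
            win_s = win_s, step_s = step_s,
            class = c("metric_series", class(tibble::tibble())))
}

#' Heart rate from RR intervals
#'
#' Per-beat heart rate via the hyperbolic identity
#' `HR x RR = 60000` (bpm x ms). `mode = "beats"` returns the per-beat
#' series; `mode = "rolling"` averages per-beat HR of unflagged beats in
#' rolling windows; `mode = "task"` returns a single mean over `span`.
#'
#' @param series An [rr_series()].
#' @param mode `"beats"`, `"task"` or `"rolling"`.
#' @param span `c(t0, t1)` in seconds; defaults to the beat-time range.
#' @param win_s,step_s Rolling window length and step.
#' @return A tibble (`beat_t_s`, `hr_bpm`) for `"beats"`; a scalar for
#'   `"task"`; a `metric_series` for `"rolling"`.
#' @export
rr_to_hr <- function(series, mode = c("beats", "task", "rolling"),
                     span = NULL, win_s = 10, step_s = 5) {
  mode <- match.arg(mode)
  if (any(series$rr_ms <= 0)) {
    gc_abort("RR intervals must be strictly positive.", "gc_invalid_interval")
  }
  hr <- 60000 / series$rr_ms
  if (mode == "beats") {
    return(tibble::tibble(beat_t_s = series$beat_t_s, hr_bpm = hr))
  }
  keep <- !series$artifact
  if (is.null(span)) span <- range(series$beat_t_s)
  if (mode == "task") {
    ok <- keep & series$beat_t_s >= span[1] & series$beat_t_s <= span[2]
    if (!any(ok)) gc_abort("No beats in span.", "gc_insufficient_data")
    return(mean(hr[ok]))
  }
  w <- rolling_windows(span[1], span[2], win_s, step_s)
  vals <- vapply(seq_len(nrow(w)), function(j) {
    ok <- keep & series$beat_t_s >= w$t_start[j] &
      series$beat_t_s < w$t_end[j]
    if (sum(ok) < 2) NA_real_ else mean(hr[ok])
  }, numeric(1))
  metric_series("HR", w, vals, win_s, step_s)
}

#' Flag RR-interval artifacts
#'
#' Automated stand-in for manual beat editing: flags intervals deviating
#' from the running local median (window `local_win` beats) by more than
#' `dev_frac`. Flagged intervals are excluded from downstream HR and
#' RMSSD computations.
#'
#' @param series An [rr_series()] with at least `local_win` beats.
#' @param dev_frac Fractional deviation threshold (default 0.3).
#' @param local_win Local median window in beats (odd, default 11).
#' @return The series with its `artifact` column updated; the attribute
#'   `edits` lists the newly flagged indices.
#' @export
filter_rr_artifacts <- function(series, dev_frac = 0.3, local_win = 11) {
  if (nrow(series) < local_win) {
    gc_abort("Fewer beats than the local median window.",
             "gc_insufficient_data")
  }
  med <- runmed(series$rr_ms, local_win, endrule = "median")
  flag <- abs(series$rr_ms - med) / med > dev_frac
  out <- series
  out$artifact <- series$artifact | flag
  attr(out, "edits") <- which(flag)
  out
}

#' Ultra-short-term RMSSD
#'
#' Root mean square of successive differences of unflagged RR intervals.
#' A difference contributes only when the two intervals are consecutive
#' beats and neither is flagged, so differences never span an edited
#' beat. Task durations here are under 5 minutes, i.e. the ultra-short
#' recording regime.
#'
#' @param series An [rr_series()].
#' @param mode `"task"` (one value over `span`) or `"rolling"`.
#' @param span `c(t0, t1)` in seconds; defaults to the beat-time range.
#' @param win_s,step_s Rolling window length and step.
#' @param min_beats Minimum unflagged beats per span (default 3).
#' @return A scalar (ms) for `"task"`; a `metric_series` for
#'   `"rolling"` (windows with too few beats give `NA`).
#' @export
rmssd <- function(series, mode = c("task", "rolling"), span = NULL,
                  win_s = 10, step_s = 5, min_beats = 3) {
  mode <- match.arg(mode)
  if (is.null(span)) span <- range(series$beat_t_s)
  span_rmssd <- function(t0, t1, strict) {
    inwin <- series$beat_t_s >= t0 & series$beat_t_s < t1
    keep <- inwin & !series$artifact
    if (sum(keep) < min_beats) {
      if (strict) gc_abort("Too few unflagged beats in span.",
                           "gc_insufficient_data")
      return(NA_real_)
    }
    idx <- which(inwin)
    ok <- !series$artifact[idx]
    d <- diff(series$rr_ms[idx])
    use <- ok[-length(ok)] & ok[-1]
    if (!any(use)) {
      if (strict) gc_abort("No unflagged successive differences in span.",
                           "gc_insufficient_data")
      return(NA_real_)
    }
    sqrt(mean(d[use]^2))
  }
  if (mode == "task") {
    return(span_rmssd(span[1], span[2] + 1e-9, strict = TRUE))
  }
  w <- rolling_windows(span[1], span[2], win_s, step_s)
  metric_series("RMSSD", w, vapply(seq_len(nrow(w)), function(j) {
    span_rmssd(w$t_start[j], w$t_end[j], strict = FALSE)
  }, numeric(1)), win_s, step_s)
}

#' Min-max normalize workload metrics within participant
#'
#' RMSSD is negated before normalization (it is negatively correlated
#' with workload, so the sign flip makes all metrics point the same way);
#' each metric is then mapped onto `[0, 1]` by `(x - min) / (max - min)`
#' within each participant (and any other grouping columns present).
#' Row order is preserved.
#'
#' @param df A tidy data frame with columns `metric`, `value`, and
#'   optionally `participant` (plus any columns to keep).
#' @param negate_metrics Metrics negated before scaling (default
#'   `"RMSSD"`).
#' @return The input with an added `value_norm` column; negated metrics
#'   are renamed with a `neg` prefix in a `metric_norm` column.
#' @export
normalize_metrics <- function(df, negate_metrics = "RMSSD") {
  check_columns(df, c("metric", "value"), "`df`")
  group_cols <- intersect(c("participant", "task_group", "metric"),
                          names(df))
  out <- tibble::as_tibble(df)
  out$.row <- seq_len(nrow(out))
  out <- dplyr::group_by(out, dplyr::across(dplyr::all_of(group_cols)))
  out <- dplyr::mutate(
    out,
    .signed = ifelse(.data$metric %in% negate_metrics, -.data$value,
                     .data$value),
    .min = min(.data$.signed, na.rm = TRUE),
    .max = max(.data$.signed, na.rm = TRUE)
  )
  out <- dplyr::ungroup(out)
  if (any(out$.max - out$.min == 0)) {
    gc_abort("A metric is constant within a participant; min-max normalization is degenerate.",
             "gc_degenerate_normalization")
  }
  out$value_norm <- (out$.signed - out$.min) / (out$.max - out$.min)
  out$metric_norm <- ifelse(out$metric %in% negate_metrics,
                            paste0("neg", out$metric), out$metric)
  out <- out[order(out$.row), ]
  out$.row <- NULL; out$.signed <- NULL; out$.min <- NULL; out$.max <- NULL
  out
}
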