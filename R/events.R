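# Velocity-threshold eye-movement event detection (adaptive-threshold
# family of Nystrom & Holmqvist): Savitzky-Golay angular velocity, a
# data-driven saccade threshold, and pursuit/fixation splitting of the
# low-pass-filtered intersaccadic signal.

#' Detector parameters
#'
#' @param sg_window Savitzky-Golay window length in samples (odd).
#' @param sg_order Savitzky-Golay polynomial order (< `sg_window`).
#' @param init_threshold_dva_s Initial saccade velocity threshold for the
#'   adaptive iteration (DVA/s).
#' @param threshold_sd_mult Multiplier on the below-threshold SD in the
#'   adaptive update (default 6).
#' @param min_fixation_s,min_saccade_s,min_pursuit_s Minimum event
#'   durations (s).
#' @param pursuit_vel_dva_s Pursuit velocity threshold applied to the
#'   low-pass-filtered intersaccadic signal (DVA/s).
#' @param lowpass_cutoff_hz Butterworth cutoff for intersaccadic
#'   filtering (Hz).
#' @param max_gap_interp_s Invalid gaps up to this duration are linearly
#'   interpolated before differentiation; longer gaps become `gap` events.
#' @return A `detector_params` list.
#' @export
detector_params <- function(sg_window = 7, sg_order = 2,
                            init_threshold_dva_s = 300,
                            threshold_sd_mult = 6,
                            min_fixation_s = 0.04, min_saccade_s = 0.01,
                            min_pursuit_s = 0.04, pursuit_vel_dva_s = 6,
                            lowpass_cutoff_hz = 4, max_gap_interp_s = 0.075) {
  if (sg_window %% 2 == 0 || sg_window < 3) {
    gc_abort("`sg_window` must be an odd integer >= 3.",
             "gc_invalid_parameter")
  }
  if (sg_order >= sg_window) {
    gc_abort("`sg_order` must be smaller than `sg_window`.",
             "gc_invalid_parameter")
  }
  for (d in c(min_fixation_s, min_saccade_s, min_pursuit_s)) {
    check_number(d, "minimum event duration", positive = TRUE)
  }
  check_number(init_threshold_dva_s, "init_threshold_dva_s", positive = TRUE)
  check_number(pursuit_vel_dva_s, "pursuit_vel_dva_s", positive = TRUE)
  check_number(lowpass_cutoff_hz, "lowpass_cutoff_hz", positive = TRUE)
  list(sg_window = sg_window, sg_order = sg_order,
       init_threshold_dva_s = init_threshold_dva_s,
       threshold_sd_mult = threshold_sd_mult,
       min_fixation_s = min_fixation_s, min_saccade_s = min_saccade_s,
       min_pursuit_s = min_pursuit_s,
       pursuit_vel_dva_s = pursuit_vel_dva_s,
       lowpass_cutoff_hz = lowpass_cutoff_hz,
       max_gap_interp_s = max_gap_interp_s)
}

# Angular screen coordinates (deg, signed, origin at screen centre), with
# short invalid gaps linearly interpolated. Returns list(xa, ya, valid)
# where valid marks samples usable for velocity estimation.
angular_coords <- function(stream, params) {
  geometry <- stream_geometry(stream)
  rate <- stream_rate(stream)
  v <- stream$valid & is.finite(stream$x_px) & is.finite(stream$y_px)
  xa <- px_to_dva_signed(stream$x_px, geometry$width_px / 2, geometry)
  ya <- px_to_dva_signed(stream$y_px, geometry$height_px / 2, geometry)
  xa[!v] <- NA_real_; ya[!v] <- NA_real_
  usable <- v
  if (any(!v)) {
    runs <- true_runs(!v)
    max_len <- params$max_gap_interp_s * rate
    t <- stream$t_s
    for (j in seq_len(nrow(runs))) {
      s <- runs$start[j]; e <- runs$end[j]
      interior <- s > 1 && e < length(v)
      if (interior && (e - s + 1) <= max_len) {
        idx <- s:e
        xa[idx] <- approx(t[c(s - 1, e + 1)], xa[c(s - 1, e + 1)], t[idx])$y
        ya[idx] <- approx(t[c(s - 1, e + 1)], ya[c(s - 1, e + 1)], t[idx])$y
        usable[idx] <- TRUE
      }
    }
  }
  # fill residual gaps with nearest valid value so the FIR filter cannot
  # spread NAs; the filled samples stay flagged unusable
  if (any(!usable)) {
    xa <- fill_nearest(xa)
    ya <- fill_nearest(ya)
  }
  list(xa = xa, ya = ya, valid = usable)
}

fill_nearest <- function(x) {
  n <- length(x)
  ok <- which(is.finite(x))
  if (length(ok) == 0) return(rep(0, n))
  idx <- findInterval(seq_len(n), ok)
  lo <- ok[pmax(idx, 1L)]
  hi <- ok[pmin(idx + 1L, length(ok))]
  nearest <- ifelse(idx == 0, hi,
                    ifelse(seq_len(n) - lo <= hi - seq_len(n), lo, hi))
  x[seq_len(n)] <- x[nearest]
  x
}

#' Estimate angular gaze velocity
#'
#' Converts gaze positions to angular screen coordinates, differentiates
#' each axis with a Savitzky-Golay smoothing-polynomial filter and returns
#' the Euclidean norm of the two angular derivatives. Invalid gaps up to
#' `max_gap_interp_s` are linearly interpolated first; samples inside
#' longer gaps are marked invalid.
#'
#' @param stream A [gaze_stream()].
#' @param params A [detector_params()].
#' @return A tibble with columns `t_s`, `v_dva_s`, `valid`, aligned 1:1
#'   with the input samples.
#' @export
estimate_velocity <- function(stream, params = detector_params()) {
  n <- nrow(stream)
  if (n < params$sg_window) {
    gc_abort("Stream shorter than the Savitzky-Golay window.",
             "gc_insufficient_data")
  }
  rate <- stream_rate(stream)
  ac <- angular_coords(stream, params)
  vx <- signal::sgolayfilt(ac$xa, p = params$sg_order, n = params$sg_window,
                           m = 1, ts = 1 / rate)
  vy <- signal::sgolayfilt(ac$ya, p = params$sg_order, n = params$sg_window,
                           m = 1, ts = 1 / rate)
  v <- sqrt(vx^2 + vy^2)
  v[!ac$valid] <- NA_real_
  tibble::tibble(t_s = stream$t_s, v_dva_s = v, valid = ac$valid)
}

#' Adaptive saccade velocity threshold
#'
#' Iterates `PT <- mean(v[v <= PT]) + k * sd(v[v <= PT])` from
#' `init_threshold_dva_s` until the update changes by less than 1 DVA/s
#' (or 100 iterations). The comparison is inclusive; a zero-variance
#' below-threshold sample converges to its mean.
#'
#' @param vel A velocity tibble from [estimate_velocity()].
#' @param params A [detector_params()].
#' @return A list with `pt` (threshold, DVA/s), `mean_below`, `sd_below`
#'   and `n_iter`.
#' @export
adaptive_saccade_threshold <- function(vel, params = detector_params()) {
  v <- vel$v_dva_s[vel$valid & is.finite(vel$v_dva_s)]
  if (length(v) < 100) {
    gc_abort("Need at least 100 valid velocity samples.",
             "gc_insufficient_data")
  }
  if (!any(v <= params$init_threshold_dva_s)) {
    gc_abort("No velocity samples at or below the initial threshold.",
             "gc_threshold_failure")
  }
  pt <- params$init_threshold_dva_s
  m <- s <- NA_real_
  for (iter in seq_len(100)) {
    below <- v[v <= pt]
    m <- mean(below)
    s <- if (length(below) > 1) sd(below) else 0
    new_pt <- m + params$threshold_sd_mult * s
    if (abs(new_pt - pt) < 1) {
      pt <- new_pt
      break
    }
    pt <- new_pt
  }
  list(pt = pt, mean_below = m, sd_below = s, n_iter = iter)
}

# Low-pass filter an intersaccadic segment's angular position and return
# the finite-difference speed. Falls back to the unfiltered velocity for
# segments too short to filter stably.
segment_slow_speed <- function(xa, ya, v_raw, rate, cutoff) {
  m <- length(xa)
  if (m < 12) return(v_raw)
  bf <- signal::butter(2, min(0.99, cutoff / (rate / 2)), type = "low")
  # detrend + mirror-pad before filtfilt: the zero-phase filter assumes
  # zero initial conditions and would otherwise ring at segment edges
  lowpass <- function(z) {
    tt <- seq_len(m)
    co <- stats::coef(stats::lm.fit(cbind(1, tt), z))
    trend <- co[1] + co[2] * tt
    res <- z - trend
    pad <- min(m - 1, ceiling(rate / cutoff) * 3)
    padded <- c(rev(res[2:(pad + 1)]), res, rev(res[(m - pad):(m - 1)]))
    filt <- signal::filtfilt(bf, padded)[(pad + 1):(pad + m)]
    filt + trend
  }
  xf <- lowpass(xa)
  yf <- lowpass(ya)
  dxy <- sqrt(diff(xf)^2 + diff(yf)^2) * rate
  c(dxy[1], (dxy[-1] + dxy[-length(dxy)]) / 2, dxy[length(dxy)])
}

#' Detect eye-movement events
#'
#' Classifies every sample of a gaze stream as saccade, pursuit, fixation
#' or gap and returns the event segments. Saccades are runs with velocity
#' at or above the adaptive threshold lasting at least `min_saccade_s`.
#' Each intersaccadic segment is low-pass filtered (Butterworth,
#' `lowpass_cutoff_hz`) in position; runs of filtered speed at or above
#' `pursuit_vel_dva_s` lasting at least `min_pursuit_s` become pursuits
#' and the remaining runs of at least `min_fixation_s` become fixations.
#' Sub-minimum fragments are merged into the neighbouring event with the
#' closer median velocity (ties prefer the preceding neighbour). Invalid
#' stretches are gaps. Events are ordered, non-overlapping and cover the
#' full timeline.
#'
#' @param stream A [gaze_stream()].
#' @param params A [detector_params()].
#' @return An `event_table` tibble with columns `label`, `t_on_s`,
#'   `t_off_s`, `x_on_px`, `y_on_px`, `x_off_px`, `y_off_px`,
#'   `amplitude_dva`, `peak_vel_dva_s`, `median_vel_dva_s`.
#' @export
detect_events <- function(stream, params = detector_params()) {
  rate <- stream_rate(stream)
  geometry <- stream_geometry(stream)
  n <- nrow(stream)
  vel <- estimate_velocity(stream, params)
  thr <- adaptive_saccade_threshold(vel, params)
  ac <- angular_coords(stream, params)
  v <- vel$v_dva_s

  lab <- rep(NA_character_, n)
  lab[!vel$valid] <- "gap"

  # stage 1: saccades. The adaptive threshold can collapse toward zero on
  # noise-free data, so it is floored at the pursuit threshold (a saccade
  # slower than a pursuit is a contradiction).
  pt_eff <- max(thr$pt, params$pursuit_vel_dva_s)
  sacc_cand <- vel$valid & v >= pt_eff
  runs <- true_runs(sacc_cand)
  min_sacc_n <- params$min_saccade_s * rate
  for (j in seq_len(nrow(runs))) {
    idx <- runs$start[j]:runs$end[j]
    # refine onset/offset at the half-peak crossing: the symmetric
    # derivative kernel smears a velocity step symmetrically, so the
    # half-amplitude crossing localizes the true saccade edge
    pk <- which.max(v[idx])
    half <- v[idx][pk] / 2
    s <- pk
    while (s > 1 && v[idx][s - 1] >= half) s <- s - 1
    e <- pk
    while (e < length(idx) && v[idx][e + 1] >= half) e <- e + 1
    core <- idx[s:e]
    if (length(core) >= min_sacc_n) {
      lab[core] <- "saccade"
    }
  }

  # stage 2+3: intersaccadic pursuit / fixation
  inter <- vel$valid & is.na(lab)
  min_purs_n <- params$min_pursuit_s * rate
  min_fix_n <- params$min_fixation_s * rate
  for (j in seq_len(nrow(runs <- true_runs(inter)))) {
    idx <- runs$start[j]:runs$end[j]
    vf <- segment_slow_speed(ac$xa[idx], ac$ya[idx], v[idx], rate,
                             params$lowpass_cutoff_hz)
    purs <- vf >= params$pursuit_vel_dva_s
    prun <- true_runs(purs)
    seg_lab <- rep(NA_character_, length(idx))
    ext_thr <- params$pursuit_vel_dva_s / 2
    for (q in seq_len(nrow(prun))) {
      if (prun$end[q] - prun$start[q] + 1 >= min_purs_n) {
        # hysteresis: grow the run outward down to half the threshold to
        # recover the low-pass filter's onset/offset ramps
        s <- prun$start[q]
        while (s > 1 && is.na(seg_lab[s - 1]) && vf[s - 1] >= ext_thr) {
          s <- s - 1
        }
        e <- prun$end[q]
        while (e < length(idx) && is.na(seg_lab[e + 1]) &&
                 vf[e + 1] >= ext_thr) {
          e <- e + 1
        }
        seg_lab[s:e] <- "pursuit"
      }
    }
    frun <- true_runs(is.na(seg_lab))
    for (q in seq_len(nrow(frun))) {
      if (frun$end[q] - frun$start[q] + 1 >= min_fix_n) {
        seg_lab[frun$start[q]:frun$end[q]] <- "fixation"
      }
    }
    lab[idx] <- seg_lab
  }

  lab <- merge_fragments(lab, v)
  events_from_labels(lab, stream, v, geometry, rate)
}

# Assign every unlabeled fragment to the adjacent labeled run whose median
# velocity is closer to the fragment's; exact ties keep the preceding one.
merge_fragments <- function(lab, v) {
  frag <- true_runs(is.na(lab))
  for (j in seq_len(nrow(frag))) {
    s <- frag$start[j]; e <- frag$end[j]
    left <- if (s > 1) lab[s - 1] else NA_character_
    right <- if (e < length(lab)) lab[e + 1] else NA_character_
    cand <- c(left = left, right = right)
    cand <- cand[!is.na(cand) & cand != "gap"]
    if (length(cand) == 0) {
      lab[s:e] <- "fixation"
      next
    }
    if (length(cand) == 1) {
      lab[s:e] <- cand[[1]]
      next
    }
    fm <- median(v[s:e], na.rm = TRUE)
    lrun <- run_of(lab, s - 1)
    rrun <- run_of(lab, e + 1)
    lmed <- median(v[lrun], na.rm = TRUE)
    rmed <- median(v[rrun], na.rm = TRUE)
    lab[s:e] <- if (!is.finite(fm) || abs(fm - lmed) <= abs(fm - rmed)) {
      cand[["left"]]
    } else {
      cand[["right"]]
    }
  }
  lab
}

run_of <- function(lab, i) {
  val <- lab[i]
  s <- i
  while (s > 1 && identical(lab[s - 1], val)) s <- s - 1
  e <- i
  while (e < length(lab) && identical(lab[e + 1], val)) e <- e + 1
  s:e
}

events_from_labels <- function(lab, stream, v, geometry, rate) {
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dt <- 1 / rate
  ev <- purrr::map_dfr(seq_along(r$values), function(j) {
    idx <- starts[j]:ends[j]
    xi <- stream$x_px[idx]; yi <- stream$y_px[idx]
    ok <- which(is.finite(xi))
    a <- if (length(ok) > 0) ok[1] else NA_integer_
    b <- if (length(ok) > 0) ok[length(ok)] else NA_integer_
    amp <- if (!is.na(a)) {
      angular_distance(xi[a], yi[a], xi[b], yi[b], geometry)
    } else NA_real_
    tibble::tibble(
      label = r$values[j],
      t_on_s = stream$t_s[starts[j]],
      t_off_s = stream$t_s[ends[j]] + dt,
      x_on_px = if (is.na(a)) NA_real_ else xi[a],
      y_on_px = if (is.na(a)) NA_real_ else yi[a],
      x_off_px = if (is.na(b)) NA_real_ else xi[b],
      y_off_px = if (is.na(b)) NA_real_ else yi[b],
      amplitude_dva = amp,
      peak_vel_dva_s = suppressWarnings(max(v[idx], na.rm = TRUE)),
      median_vel_dva_s = median(v[idx], na.rm = TRUE)
    )
  })
  ev$peak_vel_dva_s[!is.finite(ev$peak_vel_dva_s)] <- NA_real_
  structure(ev, class = c("event_table", class(tibble::tibble())))
}

#' Per-sample labels implied by an event table
#'
#' @param events An `event_table` from [detect_events()].
#' @param t_s Sample times to label.
#' @return Character vector of labels, one per element of `t_s`.
#' @export
events_to_labels <- function(events, t_s) {
  idx <- findInterval(t_s, events$t_on_s)
  out <- events$label[pmax(idx, 1L)]
  out[t_s >= max(events$t_off_s)] <- events$label[nrow(events)]
  out
}

#' Read / write an event table CSV
#'
#' @param events An `event_table`.
#' @param path File path.
#' @export
write_events_csv <- function(events, path) {
  readr::write_csv(tibble::as_tibble(events), path)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_columns(df, c("label", "t_on_s", "t_off_s"), basename(path))
  structure(tibble::as_tibble(df),
            class = c("event_table", class(tibble::tibble())))
}

#' Summarize detected events per label
#'
#' @param events An `event_table` (possibly empty).
#' @return A tibble with one row per label: `label`, `n`,
#'   `total_duration_s`, `median_duration_s`, `median_amplitude_dva`, and
#'   list-columns `durations_s`, `amplitudes_dva` holding the empirical
#'   distributions. All four labels are present (zero rows contribute
#'   `n = 0`).
#' @export
summarize_events <- function(events) {
  labels <- c("fixation", "saccade", "pursuit", "gap")
  purrr::map_dfr(labels, function(lb) {
    sub <- events[!is.na(events$label) & events$label == lb, , drop = FALSE]
    dur <- sub$t_off_s - sub$t_on_s
    tibble::tibble(
      label = lb,
      n = nrow(sub),
      total_duration_s = sum(dur),
      median_duration_s = if (nrow(sub) > 0) median(dur) else NA_real_,
      median_amplitude_dva = if (nrow(sub) > 0) {
        median(sub$amplitude_dva, na.rm = TRUE)
      } else NA_real_,
      durations_s = list(dur),
      amplitudes_dva = list(sub$amplitude_dva)
    )
  })
}
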