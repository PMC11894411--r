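# Synthetic physiological signals. The generator encodes the standard
# monotone workload relations: higher workload -> larger pupil diameter,
# higher heart rate, lower heart-rate variability.

#' Piecewise-constant workload profile
#'
#' Defines a latent workload level `w(t)` in `[0, 1]` together with the
#' gains that map it into the physiological signals: pupil dilation (mm
#' per unit workload), mean RR shortening (ms per unit workload) and RMSSD
#' reduction (ms per unit workload).
#'
#' Defaults model a moderate effect in a resting adult: 0.5 mm pupil gain,
#' an 800 ms resting RR (75 bpm) shortened by 100 ms at full workload
#' (~85 bpm), and a resting RMSSD of 40 ms falling to 15 ms at full
#' workload.
#'
#' @param t_breaks Non-decreasing vector of segment start times (s); the
#'   first element is the profile origin.
#' @param w_levels Workload level per segment, in `[0, 1]`.
#' @param pupil_gain_mm Pupil dilation per unit workload (mm).
#' @param rr_baseline_ms Resting mean RR interval (ms).
#' @param rr_slope_ms RR shortening per unit workload (ms).
#' @param rmssd_baseline_ms Resting RMSSD (ms).
#' @param rmssd_slope_ms RMSSD reduction per unit workload (ms).
#' @return A `workload_profile` object.
#' @export
workload_profile <- function(t_breaks = 0, w_levels = 0,
                             pupil_gain_mm = 0.5,
                             rr_baseline_ms = 800, rr_slope_ms = 100,
                             rmssd_baseline_ms = 40, rmssd_slope_ms = 25) {
  if (length(t_breaks) != length(w_levels) || length(t_breaks) < 1) {
    gc_abort("`t_breaks` and `w_levels` must have equal positive length.",
             "gc_invalid_parameter")
  }
  if (is.unsorted(t_breaks)) {
    gc_abort("`t_breaks` must be non-decreasing.", "gc_invalid_parameter")
  }
  if (any(w_levels < 0 | w_levels > 1)) {
    gc_abort("Workload levels must lie in [0, 1].", "gc_invalid_parameter")
  }
  if (rr_baseline_ms - rr_slope_ms <= 0 ||
      rmssd_baseline_ms - rmssd_slope_ms < 0) {
    gc_abort("Profile slopes would yield non-positive RR or negative RMSSD.",
             "gc_invalid_parameter")
  }
  structure(list(t_breaks = as.numeric(t_breaks),
                 w_levels = as.numeric(w_levels),
                 pupil_gain_mm = pupil_gain_mm,
                 rr_baseline_ms = rr_baseline_ms, rr_slope_ms = rr_slope_ms,
                 rmssd_baseline_ms = rmssd_baseline_ms,
                 rmssd_slope_ms = rmssd_slope_ms),
            class = "workload_profile")
}

#' Evaluate a workload profile
#'
#' @param profile A [workload_profile()].
#' @param t Time(s) in seconds.
#' @return Workload level(s) `w(t)`; times before the first break take the
#'   first level.
#' @export
profile_w <- function(profile, t) {
  idx <- findInterval(t, profile$t_breaks)
  profile$w_levels[pmax(idx, 1L)]
}

#' Simulate a pupil-diameter stream
#'
#' Clean diameter is `baseline + gain * w(t)` plus slow AR(1) noise.
#' Blinks are inserted as holes in the time base longer than 75 ms;
#' injected outliers either leave the feasible 1.5-9 mm range (size
#' outliers) or jump by ~2 mm for a single sample (dilation-speed
#' outliers). Everything injected is recorded for use as a cleaning
#' oracle.
#'
#' @param profile A [workload_profile()].
#' @param duration_s Stream duration (s).
#' @param baseline_mm Resting diameter; must lie in the feasible
#'   1.5-9 mm range.
#' @param blink_rate Blinks per second (default 0.2).
#' @param outlier_rate Per-sample probability of an injected outlier
#'   (default 0.001).
#' @param noise_sd_mm Standard deviation of the slow noise (default 0.03).
#' @param rate_hz Sampling rate (default 100).
#' @param seed Integer seed.
#' @return A list with elements `stream` (a [pupil_stream()]) and
#'   `injected` (list with `blinks` and `outliers` tibbles).
#' @export
simulate_pupil <- function(profile, duration_s = 120, baseline_mm = 4,
                           blink_rate = 0.2, outlier_rate = 0.001,
                           noise_sd_mm = 0.03, rate_hz = 100, seed = 1) {
  if (baseline_mm < 1.5 || baseline_mm > 9) {
    gc_abort("`baseline_mm` must lie in the feasible range 1.5-9 mm.",
             "gc_invalid_parameter")
  }
  check_number(duration_s, "duration_s", positive = TRUE)
  set.seed(seed)
  n <- floor(duration_s * rate_hz)
  t <- (seq_len(n) - 1) / rate_hz
  d <- baseline_mm + profile$pupil_gain_mm * profile_w(profile, t)
  if (noise_sd_mm > 0) {
    # AR(1) with lag-1 correlation .995: slow hippus-like wander
    rho <- 0.995
    e <- rnorm(n, 0, noise_sd_mm * sqrt(1 - rho^2))
    d <- d + as.numeric(stats::filter(e, rho, method = "recursive"))
  }

  outlier_idx <- which(runif(n) < outlier_rate)
  outliers <- tibble::tibble(t_s = t[outlier_idx],
                             type = rep(c("size", "speed"),
                                        length.out = length(outlier_idx)))
  for (j in seq_along(outlier_idx)) {
    i <- outlier_idx[j]
    d[i] <- if (outliers$type[j] == "size") 9.6 else d[i] + 2
  }

  n_blinks <- rpois(1, blink_rate * duration_s)
  blink_on <- sort(runif(n_blinks, 0, duration_s - 0.4))
  blink_len <- runif(n_blinks, 0.1, 0.3)  # all > 75 ms
  blinks <- tibble::tibble(t_on_s = blink_on, t_off_s = blink_on + blink_len)
  drop <- rep(FALSE, n)
  for (j in seq_len(n_blinks)) {
    drop <- drop | (t >= blinks$t_on_s[j] & t < blinks$t_off_s[j])
  }

  stream <- pupil_stream(tibble::tibble(t_s = t[!drop],
                                        diameter_mm = d[!drop]),
                         rate_hz = rate_hz)
  list(stream = stream, injected = list(blinks = blinks, outliers = outliers))
}

#' Simulate an RR-interval series
#'
#' `RR_i = rr_baseline - rr_slope * w(t_i) + jitter`, with the Gaussian
#' jitter scaled so that the generating RMSSD equals
#' `rmssd_baseline - rmssd_slope * w` (for iid jitter of sd `s`, RMSSD is
#' `s * sqrt(2)`). Ectopic beats are injected as an interval shortened by
#' 45% followed by a compensatory lengthening; injected indices are
#' recorded.
#'
#' @param profile A [workload_profile()].
#' @param n_beats Number of beats (>= 2).
#' @param ectopic_rate Per-beat probability of an ectopic insertion
#'   (default 0).
#' @param seed Integer seed.
#' @return A list with elements `rr` (an [rr_series()]) and
#'   `injected_idx` (indices of the perturbed intervals).
#' @export
simulate_rr <- function(profile, n_beats = 300, ectopic_rate = 0, seed = 1) {
  if (n_beats < 2) {
    gc_abort("`n_beats` must be at least 2.", "gc_invalid_parameter")
  }
  set.seed(seed)
  rr <- numeric(n_beats)
  t <- 0
  tt <- numeric(n_beats)
  for (i in seq_len(n_beats)) {
    w <- profile_w(profile, t)
    sdev <- (profile$rmssd_baseline_ms - profile$rmssd_slope_ms * w) / sqrt(2)
    rr[i] <- profile$rr_baseline_ms - profile$rr_slope_ms * w +
      rnorm(1, 0, sdev)
    t <- t + rr[i] / 1000
    tt[i] <- t
  }
  if (any(rr <= 0)) {
    gc_abort("Profile parameters yielded non-positive RR intervals.",
             "gc_invalid_parameter")
  }
  injected <- integer(0)
  if (ectopic_rate > 0 && n_beats > 3) {
    cand <- which(runif(n_beats - 2) < ectopic_rate) + 1  # avoid first/last
    cand <- cand[c(TRUE, diff(cand) > 1)]                 # no overlapping pairs
    for (i in cand) {
      cut <- 0.45 * rr[i]
      rr[i] <- rr[i] - cut
      rr[i + 1] <- rr[i + 1] + cut
      injected <- c(injected, i, i + 1)
    }
    tt <- cumsum(rr) / 1000
  }
  list(rr = rr_series(tibble::tibble(beat_t_s = tt, rr_ms = rr)),
       injected_idx = injected)
}
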