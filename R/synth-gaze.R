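# Stimulus-locked gaze simulation with per-sample ground-truth labels.
# Fixational jitter is a mean-reverting AR(1) ("drift") process rather
# than white noise: real tracker noise and ocular drift are temporally
# correlated, and this is what makes sub-threshold fixation velocities
# physically plausible at 100 Hz.

#' Behaviour parameters for the gaze simulator
#'
#' @param fixation_noise_sd_dva Stationary SD of fixational jitter (DVA).
#' @param ar_coef Lag-1 autocorrelation of the jitter process at the
#'   sampling rate (default 0.97, a ~0.3 s drift time constant at 100 Hz).
#' @param saccade_peak_vel_dva_s Saccade velocity (DVA/s); saccades are
#'   simulated as constant-velocity jumps.
#' @param pursuit_gain Gaze velocity as a fraction of target velocity
#'   during pursuit.
#' @param dropout_rate Per-sample probability of an invalid (tracking
#'   loss) sample.
#' @param latency_s Saccade latency after a stimulus event (s).
#' @return A named list of behaviour parameters.
#' @export
gaze_behavior <- function(fixation_noise_sd_dva = 0.3, ar_coef = 0.97,
                          saccade_peak_vel_dva_s = 300, pursuit_gain = 1,
                          dropout_rate = 0.02, latency_s = 0.15) {
  check_number(fixation_noise_sd_dva, "fixation_noise_sd_dva", nonneg = TRUE)
  check_number(saccade_peak_vel_dva_s, "saccade_peak_vel_dva_s",
               positive = TRUE)
  check_number(dropout_rate, "dropout_rate", nonneg = TRUE)
  if (ar_coef < 0 || ar_coef >= 1) {
    gc_abort("`ar_coef` must lie in [0, 1).", "gc_invalid_parameter")
  }
  list(fixation_noise_sd_dva = fixation_noise_sd_dva, ar_coef = ar_coef,
       saccade_peak_vel_dva_s = saccade_peak_vel_dva_s,
       pursuit_gain = pursuit_gain, dropout_rate = dropout_rate,
       latency_s = latency_s)
}

# OU/AR(1) jitter series in pixels, stationary sd sd_px.
ou_noise <- function(n, sd_px, rho) {
  if (sd_px == 0 || n == 0) return(numeric(n))
  e <- rnorm(n, 0, sd_px * sqrt(1 - rho^2))
  as.numeric(stats::filter(e, rho, method = "recursive"))
}

#' Simulate a gaze stream for a task schedule
#'
#' Generates a stimulus-locked gaze recording together with per-sample
#' ground-truth event labels (`fixation`, `saccade`, `pursuit`, `gap`).
#' Stationary targets are acquired by a constant-velocity saccade and held
#' with jittered fixation; moving targets are followed at
#' `pursuit_gain` times the target velocity; the painting task interleaves
#' fixations, saccades and slow steering pursuits over the screen.
#' Tracking dropouts appear as invalid samples labeled `gap`.
#'
#' For the focus task the dwell/timeout logic runs online: the next target
#' appears the moment the current one is selected or times out, so target
#' success genuinely depends on the jitter relative to target size.
#'
#' @param schedule A [focus_schedule()], [tracking_path()] or
#'   [painting_spec()].
#' @param behavior A [gaze_behavior()] parameter list.
#' @param geometry A [screen_geometry()].
#' @param rate_hz Sampling rate (default 100).
#' @param seed Integer seed.
#' @param grace_s Dwell grace gap for the online focus logic (s).
#' @return A list with elements `gaze` (a [gaze_stream()]) and `truth`
#'   (list of `samples`, a tibble `t_s`/`label`, and `intervals`, a tibble
#'   `label`/`t_on_s`/`t_off_s` partitioning the timeline).
#' @export
simulate_gaze <- function(schedule, behavior = gaze_behavior(),
                          geometry = screen_geometry(), rate_hz = 100,
                          seed = 1, grace_s = 0.1) {
  check_geometry(geometry)
  check_number(rate_hz, "rate_hz", positive = TRUE)
  set.seed(seed)
  UseMethod("simulate_gaze")
}

finish_sim <- function(x, y, label, behavior, geometry, rate_hz,
                       valid = NULL) {
  n <- length(x)
  t <- (seq_len(n) - 1) / rate_hz
  if (is.null(valid)) {
    valid <- rep(TRUE, n)
    if (behavior$dropout_rate > 0) {
      valid <- runif(n) >= behavior$dropout_rate
    }
  }
  x[!valid] <- NA_real_
  y[!valid] <- NA_real_
  # ground truth records the latent oculomotor state; only signal losses
  # too long to recover (> 75 ms, the blink-gap scale) are labeled gap
  runs <- true_runs(!valid)
  long <- runs[(runs$end - runs$start + 1) / rate_hz > 0.075, ]
  for (j in seq_len(nrow(long))) {
    label[long$start[j]:long$end[j]] <- "gap"
  }
  gaze <- gaze_stream(tibble::tibble(t_s = t, x_px = x, y_px = y,
                                     valid = valid),
                      geometry = geometry, rate_hz = rate_hz)
  list(gaze = gaze, truth = make_truth(t, label, rate_hz))
}

make_truth <- function(t, label, rate_hz) {
  r <- rle(label)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  intervals <- tibble::tibble(label = r$values,
                              t_on_s = t[starts],
                              t_off_s = t[ends] + 1 / rate_hz)
  list(samples = tibble::tibble(t_s = t, label = label),
       intervals = intervals)
}

#' @export
simulate_gaze.focus_schedule <- function(schedule,
                                         behavior = gaze_behavior(),
                                         geometry = screen_geometry(),
                                         rate_hz = 100, seed = 1,
                                         grace_s = 0.1) {
  dt <- 1 / rate_hz
  tg <- schedule$targets
  n_targets <- nrow(tg)
  radius_px <- dva_to_px(tg$diameter_dva / 2, geometry)
  sd_px <- dva_to_px(behavior$fixation_noise_sd_dva, geometry)
  rho <- behavior$ar_coef
  innov <- if (sd_px > 0) sd_px * sqrt(1 - rho^2) else 0
  vel_px_s <- behavior$saccade_peak_vel_dva_s / dva_per_px(geometry)

  n_max <- ceiling(rate_hz * (n_targets * schedule$timeout_s + 5))
  x <- numeric(n_max); y <- numeric(n_max); lab <- character(n_max)
  ok <- logical(n_max)

  pos <- c(geometry$width_px / 2, geometry$height_px / 2)  # fixate centre first
  nx <- 0; ny <- 0                                         # jitter state
  k <- 1L
  t_on <- 0
  state <- "latent"           # latent -> saccade -> fixate
  move_t0 <- 0                # saccade start time
  move_from <- pos
  move_dur <- 0
  dwell_start <- NA_real_; out_since <- NA_real_
  i <- 0L; t <- 0

  while (k <= n_targets) {
    i <- i + 1L
    t <- (i - 1L) * dt
    centre <- c(tg$x_px[k], tg$y_px[k])

    if (state == "latent" && t >= t_on + behavior$latency_s) {
      amp_px <- sqrt(sum((pos - centre)^2))
      move_dur <- amp_px / vel_px_s
      move_from <- pos
      move_t0 <- t
      state <- if (move_dur > 0) "saccade" else "fixate"
    }
    if (state == "saccade") {
      frac <- (t - move_t0) / move_dur
      if (frac >= 1) {
        pos <- centre
        state <- "fixate"
      } else {
        pos <- move_from + frac * (centre - move_from)
      }
    } else if (state == "fixate") {
      pos <- centre
    }

    nx <- rho * nx + rnorm(1, 0, innov)
    ny <- rho * ny + rnorm(1, 0, innov)
    xi <- pos[1] + nx; yi <- pos[2] + ny
    x[i] <- xi; y[i] <- yi
    lab[i] <- if (state == "saccade") "saccade" else "fixation"
    # dropouts are drawn inline so the online dwell logic sees exactly
    # the stream that offline scoring will see
    ok[i] <- behavior$dropout_rate == 0 ||
      runif(1) >= behavior$dropout_rate

    # online dwell logic on the measured (jittered) gaze
    inside <- ok[i] &&
      sqrt((xi - centre[1])^2 + (yi - centre[2])^2) <= radius_px[k]
    if (inside) {
      if (is.na(dwell_start)) dwell_start <- t
      out_since <- NA_real_
    } else if (!is.na(dwell_start)) {
      if (is.na(out_since)) out_since <- t
      if (t - out_since > grace_s) {
        dwell_start <- NA_real_
        out_since <- NA_real_
      }
    }

    resolved <- NA_real_
    done_at <- if (!is.na(dwell_start)) {
      dwell_start + schedule$dwell_required_s
    } else NA_real_
    if (!is.na(done_at) && t >= done_at &&
          done_at <= t_on + schedule$timeout_s) {
      resolved <- done_at
    } else if (t - t_on >= schedule$timeout_s) {
      resolved <- t_on + schedule$timeout_s
    }
    if (!is.na(resolved)) {
      k <- k + 1L
      t_on <- resolved
      state <- "latent"
      dwell_start <- NA_real_; out_since <- NA_real_
      pos <- c(xi - nx, yi - ny)
    }
  }
  finish_sim(x[1:i], y[1:i], lab[1:i], behavior, geometry, rate_hz,
             valid = ok[1:i])
}

#' @export
simulate_gaze.tracking_path <- function(schedule,
                                        behavior = gaze_behavior(),
                                        geometry = screen_geometry(),
                                        rate_hz = 100, seed = 1,
                                        grace_s = 0.1) {
  dt <- 1 / rate_hz
  samp <- sample_tracking_path(schedule, rate_hz)
  vel_px_s <- behavior$saccade_peak_vel_dva_s / dva_per_px(geometry)
  gain <- behavior$pursuit_gain

  n <- nrow(samp)
  x <- numeric(n); y <- numeric(n); lab <- character(n)
  prev_end <- c(geometry$width_px / 2, geometry$height_px / 2)
  for (w in split(seq_len(n),
                  factor(samp$target, levels = unique(samp$target)))) {
    tx <- samp$x_px[w]; ty <- samp$y_px[w]
    m <- length(w)
    amp_px <- sqrt(sum((prev_end - c(tx[1], ty[1]))^2))
    n_sacc <- min(m - 1, ceiling((amp_px / vel_px_s) / dt))
    catch <- n_sacc + 1
    # pursuit from the catch point onward: gaze tracks target increments
    gx <- numeric(m); gy <- numeric(m)
    gx[catch:m] <- tx[catch] + gain * (tx[catch:m] - tx[catch])
    gy[catch:m] <- ty[catch] + gain * (ty[catch:m] - ty[catch])
    if (n_sacc > 0) {
      frac <- seq_len(n_sacc) / catch
      gx[1:n_sacc] <- prev_end[1] + frac * (gx[catch] - prev_end[1])
      gy[1:n_sacc] <- prev_end[2] + frac * (gy[catch] - prev_end[2])
    }
    x[w] <- gx; y[w] <- gy
    lab[w] <- c(rep("saccade", n_sacc), rep("pursuit", m - n_sacc))
    prev_end <- c(gx[m], gy[m])
  }
  sd_px <- dva_to_px(behavior$fixation_noise_sd_dva, geometry)
  x <- x + ou_noise(n, sd_px, behavior$ar_coef)
  y <- y + ou_noise(n, sd_px, behavior$ar_coef)
  finish_sim(x, y, lab, behavior, geometry, rate_hz)
}

#' @export
simulate_gaze.painting_spec <- function(schedule,
                                        behavior = gaze_behavior(),
                                        geometry = screen_geometry(),
                                        rate_hz = 100, seed = 1,
                                        grace_s = 0.1) {
  dt <- 1 / rate_hz
  n <- floor(schedule$duration_s * rate_hz)
  vel_px_s <- behavior$saccade_peak_vel_dva_s / dva_per_px(geometry)
  margin <- 20
  x <- numeric(n); y <- numeric(n); lab <- character(n)
  pos <- schedule$start
  i <- 0L
  mode <- "fixation"
  while (i < n) {
    if (mode == "fixation") {
      m <- min(n - i, max(1L, round(runif(1, 0.3, 1.0) / dt)))
      x[i + seq_len(m)] <- pos[1]
      y[i + seq_len(m)] <- pos[2]
      lab[i + seq_len(m)] <- "fixation"
      i <- i + m
      mode <- if (runif(1) < 0.4) "saccade" else "pursuit"
    } else {
      dest <- c(runif(1, margin, geometry$width_px - margin),
                runif(1, margin, geometry$height_px - margin))
      speed <- if (mode == "saccade") vel_px_s else
        runif(1, 6, 12) / dva_per_px(geometry)
      dist <- sqrt(sum((dest - pos)^2))
      m <- min(n - i, max(1L, ceiling((dist / speed) / dt)))
      frac <- seq_len(m) / max(1L, ceiling((dist / speed) / dt))
      frac <- pmin(frac, 1)
      x[i + seq_len(m)] <- pos[1] + frac * (dest[1] - pos[1])
      y[i + seq_len(m)] <- pos[2] + frac * (dest[2] - pos[2])
      lab[i + seq_len(m)] <- mode
      pos <- c(x[i + m], y[i + m])
      i <- i + m
      mode <- "fixation"
    }
  }
  sd_px <- dva_to_px(behavior$fixation_noise_sd_dva, geometry)
  x <- x + ou_noise(n, sd_px, behavior$ar_coef)
  y <- y + ou_noise(n, sd_px, behavior$ar_coef)
  finish_sim(x, y, lab, behavior, geometry, rate_hz)
}
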