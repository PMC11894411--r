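# Generators: schedules, gaze sessions, pupil and RR series.

test_that("focus schedules are balanced, on-screen, and seed-deterministic", {
  sch <- make_focus_schedule(n_targets = 60, seed = 3)
  expect_equal(nrow(sch$targets), 60)
  expect_equal(as.vector(table(sch$targets$diameter_dva)), rep(10, 6))
  r <- dva_to_px(sch$targets$diameter_dva / 2, study_geom)
  expect_true(all(sch$targets$x_px >= r &
                    sch$targets$x_px <= 1600 - r))
  expect_true(all(sch$targets$y_px >= r &
                    sch$targets$y_px <= 900 - r))
  expect_identical(make_focus_schedule(n_targets = 60, seed = 3), sch)
  # a target as tall as the screen cannot fit
  big <- px_to_dva(900, study_geom) + 1
  expect_error(make_focus_schedule(n_targets = 1, size_set_dva = big),
               class = "gc_invalid_size")
})

test_that("tracking paths traverse at the requested angular speed", {
  tp <- make_tracking_path(n_targets = 24, speed_dva_s = 15, seed = 4)
  expect_equal(length(unique(tp$waypoints$target)), 24)
  s <- sample_tracking_path(tp, 100)
  step_dva <- px_to_dva(sqrt(diff(s$x_px)^2 + diff(s$y_px)^2), study_geom)
  v <- step_dva * 100
  keep <- diff(s$target) == 0 & !(s$corner[-1] | s$corner[-nrow(s)])
  # finite-difference oracle: within 2% of requested, per trajectory too
  expect_lt(abs(mean(v[keep]) / 15 - 1), 0.02)
  per_traj <- tapply(v[keep], s$target[-1][keep], mean)
  expect_true(all(abs(per_traj / 15 - 1) < 0.02))
  expect_identical(make_tracking_path(n_targets = 24, seed = 4)$waypoints,
                   tp$waypoints)
  expect_error(make_tracking_path(speed_dva_s = 0),
               class = "gc_invalid_parameter")
})

test_that("noise-free focus simulation is exactly stimulus-determined", {
  sch <- make_focus_schedule(n_targets = 5, seed = 9)
  beh <- gaze_behavior(fixation_noise_sd_dva = 0, dropout_rate = 0)
  sim <- simulate_gaze(sch, beh, seed = 10)
  labs <- rle(sim$truth$samples$label)$values
  expect_true(all(labs %in% c("fixation", "saccade")))
  expect_true(any(labs == "saccade"))
  # fixation positions sit on target centres
  fx <- sim$truth$samples$label == "fixation"
  on_centres <- vapply(which(fx), function(i) {
    min(sqrt((sim$gaze$x_px[i] - sch$targets$x_px)^2 +
               (sim$gaze$y_px[i] - sch$targets$y_px)^2))
  }, numeric(1))
  # initial centre-of-screen fixation precedes the first saccade
  first_sacc <- which(sim$truth$samples$label == "saccade")[1]
  expect_true(all(on_centres[which(fx) > first_sacc] < 1e-9))
  expect_identical(simulate_gaze(sch, beh, seed = 10)$gaze, sim$gaze)
})

test_that("tracking pursuit with unit gain reproduces target velocity", {
  tp <- make_tracking_path(n_targets = 3, seed = 5)
  beh <- gaze_behavior(fixation_noise_sd_dva = 0, dropout_rate = 0,
                       pursuit_gain = 1)
  sim <- simulate_gaze(tp, beh, seed = 6)
  purs <- sim$truth$samples$label == "pursuit"
  v <- px_to_dva(sqrt(diff(sim$gaze$x_px)^2 + diff(sim$gaze$y_px)^2),
                 study_geom) * 100
  core <- purs[-1] & purs[-length(purs)]
  # away from saccade boundaries / corners, speed is the target's 15 DVA/s
  expect_lt(abs(median(v[core]) - 15), 0.5)
})

test_that("dropout fraction matches its binomial expectation", {
  sim <- simulate_gaze(painting_spec(duration_s = 300),
                       gaze_behavior(dropout_rate = 0.05), seed = 11)
  n <- nrow(sim$gaze)
  expect_gte(n, 29000)
  expect_lt(abs(mean(!sim$gaze$valid) - 0.05), 0.01)
})

test_that("ground-truth intervals partition every session timeline", {
  for (sched in list(make_focus_schedule(n_targets = 4, seed = 1),
                     make_tracking_path(n_targets = 3, seed = 2),
                     painting_spec(duration_s = 20))) {
    sim <- simulate_gaze(sched, gaze_behavior(dropout_rate = 0.03),
                         seed = 12)
    iv <- sim$truth$intervals
    expect_equal(iv$t_on_s[1], sim$gaze$t_s[1])
    expect_equal(iv$t_on_s[-1], utils::head(iv$t_off_s, -1))
    expect_equal(max(iv$t_off_s), max(sim$gaze$t_s) + 0.01)
    expect_equal(nrow(sim$truth$samples), nrow(sim$gaze))
  }
})

test_that("pupil generator reproduces the workload step and rejects bad baselines", {
  prof <- workload_profile(c(0, 60), c(0, 1), pupil_gain_mm = 1)
  sim <- simulate_pupil(prof, duration_s = 120, baseline_mm = 4,
                        blink_rate = 0, outlier_rate = 0, seed = 13)
  lo <- sim$stream$diameter_mm[sim$stream$t_s < 60]
  hi <- sim$stream$diameter_mm[sim$stream$t_s >= 60]
  expect_lt(abs((mean(hi) - mean(lo)) - 1), 0.05)

  flat <- simulate_pupil(workload_profile(), duration_s = 5, baseline_mm = 4,
                         blink_rate = 0, outlier_rate = 0, noise_sd_mm = 0,
                         seed = 14)
  expect_equal(flat$stream$diameter_mm, rep(4, nrow(flat$stream)))
  expect_error(simulate_pupil(prof, baseline_mm = 1.0),
               class = "gc_invalid_parameter")
})

test_that("pupil artifacts are injected as advertised", {
  prof <- workload_profile()
  sim <- simulate_pupil(prof, duration_s = 120, blink_rate = 0.3,
                        outlier_rate = 0.003, seed = 15)
  inj <- sim$injected
  expect_gt(nrow(inj$blinks), 0)
  expect_true(all(inj$blinks$t_off_s - inj$blinks$t_on_s > 0.075))
  # blink samples are absent from the time base
  for (j in seq_len(nrow(inj$blinks))) {
    expect_false(any(sim$stream$t_s >= inj$blinks$t_on_s[j] &
                       sim$stream$t_s < inj$blinks$t_off_s[j]))
  }
  sz <- inj$outliers$t_s[inj$outliers$type == "size"]
  kept <- sz[sz %in% sim$stream$t_s]
  expect_true(all(sim$stream$diameter_mm[match(kept, sim$stream$t_s)] > 9))
})

test_that("rr generator matches closed-form RMSSD and counts ectopics", {
  # degenerate: no jitter, no workload
  prof0 <- workload_profile(rmssd_baseline_ms = 0, rmssd_slope_ms = 0)
  out0 <- simulate_rr(prof0, n_beats = 50, seed = 16)
  expect_equal(stats::sd(out0$rr$rr_ms), 0)
  expect_equal(rmssd(out0$rr), 0)

  # alternating-sign construction: rr alternates +/- d around the mean,
  # successive differences are all 2d, RMSSD = 2d exactly
  d <- 5
  rr_alt <- rr_series(tibble::tibble(
    beat_t_s = cumsum(rep(0.8, 100)),
    rr_ms = 800 + d * c(1, -1)[rep(1:2, 50)]))
  expect_equal(rmssd(rr_alt), 2 * d, tolerance = 1e-12)

  # generating-level check: iid jitter sd s gives RMSSD ~ s * sqrt(2)
  prof <- workload_profile(rmssd_baseline_ms = 40, rmssd_slope_ms = 0)
  out <- simulate_rr(prof, n_beats = 4000, seed = 17)
  expect_lt(abs(rmssd(out$rr) / 40 - 1), 0.05)

  # ectopic insertions: ~binomial(n-2, rate) pairs flagged
  oute <- simulate_rr(prof, n_beats = 1000, ectopic_rate = 0.02, seed = 18)
  n_pairs <- length(oute$injected_idx) / 2
  expect_gt(n_pairs, 10)   # 95% binomial interval around 20
  expect_lt(n_pairs, 30)
  expect_error(simulate_rr(prof, n_beats = 1),
               class = "gc_invalid_parameter")
})

test_that("generators are pure functions of parameters and seed", {
  prof <- workload_profile(c(0, 10), c(0, 1))
  expect_identical(simulate_pupil(prof, duration_s = 5, seed = 19),
                   simulate_pupil(prof, duration_s = 5, seed = 19))
  expect_identical(simulate_rr(prof, n_beats = 30, seed = 20),
                   simulate_rr(prof, n_beats = 30, seed = 20))
})
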