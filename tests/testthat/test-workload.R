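# Pupil cleaning, baseline, CPD, HR, RR artifact flagging, RMSSD,
# normalization.

mk_pupil <- function(d, t = NULL, rate = 100) {
  if (is.null(t)) t <- (seq_along(d) - 1) / rate
  pupil_stream(tibble::tibble(t_s = t, diameter_mm = d), rate_hz = rate)
}

test_that("pupil cleaning applies the three rules in order", {
  # rule 1: out-of-range sample removed
  d <- rep(4, 200); d[50] <- 10
  cl <- clean_pupil(mk_pupil(d))
  expect_false(cl$valid[50])
  expect_equal(clean_report(cl)$n_removed_size, 1)

  # clean constant series: nothing removed
  cl0 <- clean_pupil(mk_pupil(rep(4, 200)))
  expect_true(all(cl0$valid))
  expect_equal(clean_report(cl0)$n_removed_speed, 0)

  # rule 2: a one-sample jump is a dilation-speed outlier
  d2 <- 4 + 0.001 * sin(seq_len(400) / 10)
  d2[200] <- d2[200] + 2
  cl2 <- clean_pupil(mk_pupil(d2))
  expect_false(cl2$valid[200])
  expect_gte(clean_report(cl2)$n_removed_speed, 1)

  # rule 3: 100 ms gap removes samples within 50 ms of both edges
  t <- c(seq(0, 1, by = 0.01), seq(1.11, 2, by = 0.01))
  cl3 <- clean_pupil(mk_pupil(rep(4, length(t)), t = t))
  expect_true(all(!cl3$valid[t >= 0.95 & t <= 1]))
  expect_true(all(!cl3$valid[t >= 1.11 & t <= 1.16]))
  expect_true(cl3$valid[10])
  expect_equal(clean_report(cl3)$n_removed_gap, 12)

  expect_error(clean_pupil(mk_pupil(rep(20, 50))),
               class = "gc_degenerate_stream")
})

test_that("tightening any cleaning threshold never removes fewer samples", {
  set.seed(5)
  sim <- simulate_pupil(workload_profile(c(0, 30), c(0, 1)),
                        duration_s = 60, blink_rate = 0.3,
                        outlier_rate = 0.005, seed = 6)
  n_removed <- function(...) {
    rep <- clean_report(clean_pupil(sim$stream, ...))
    rep$n_removed_size + rep$n_removed_speed + rep$n_removed_gap
  }
  base <- n_removed()
  expect_gte(n_removed(min_mm = 3), base)
  expect_gte(n_removed(speed_mad_mult = 4), base)
  expect_gte(n_removed(gap_pad_ms = 100), base)
  expect_gte(n_removed(gap_min_ms = 40), base)
})

test_that("baseline is the mean over the 2 s preceding the task", {
  cl <- mk_pupil(rep(4, 500))
  expect_equal(baseline_pupil(cl, task_start_s = 3), 4)
  # linear ramp 3 -> 5 over the window averages to 4
  d <- c(rep(3, 100), seq(3, 5, length.out = 200), rep(5, 200))
  expect_equal(baseline_pupil(mk_pupil(d), task_start_s = 3), 4,
               tolerance = 0.01)
  # fully invalid window
  bad <- mk_pupil(rep(4, 500))
  bad$valid[101:300] <- FALSE
  expect_error(baseline_pupil(bad, task_start_s = 3),
               class = "gc_baseline_failure")
})

test_that("cpd computes relative change and rolling window counts", {
  cl <- mk_pupil(rep(4, 1000))
  expect_equal(cpd(cl, baseline_mm = 4), 0)
  cl5 <- mk_pupil(rep(5, 1000))
  expect_equal(cpd(cl5, baseline_mm = 4), 0.25)
  expect_equal(cpd(cl5, baseline_mm = 4, cpd_mode = "absolute"), 1)
  # 60 s task, 10 s windows stepped by 5 s -> 11 windows
  cl60 <- mk_pupil(rep(4, 6000))
  roll <- cpd(cl60, baseline_mm = 4, mode = "rolling", span = c(0, 60))
  expect_equal(nrow(roll), 11)
  expect_true(all(roll$value == 0))
  expect_error(cpd(cl, baseline_mm = 0), class = "gc_invalid_parameter")
})

test_that("HR follows the hyperbolic identity exactly", {
  rr <- rr_series(tibble::tibble(beat_t_s = cumsum(c(1, 0.6, 0.8)),
                                 rr_ms = c(1000, 600, 800)))
  hr <- rr_to_hr(rr)
  expect_equal(hr$hr_bpm, c(60, 100, 75))
  expect_true(all(hr$hr_bpm * rr$rr_ms == 60000))
  expect_error(rr_series(tibble::tibble(beat_t_s = 1, rr_ms = 0)),
               class = "gc_invalid_interval")
})

test_that("rr artifact flagging finds injected ectopics with few false alarms", {
  # clean series: no flags
  prof <- workload_profile()
  clean <- simulate_rr(prof, n_beats = 200, seed = 7)$rr
  expect_equal(length(attr(filter_rr_artifacts(clean), "edits")), 0)

  # single halved interval flagged exactly
  rrv <- rep(800, 50); rrv[25] <- 400
  one <- rr_series(tibble::tibble(beat_t_s = cumsum(rrv) / 1000, rr_ms = rrv))
  expect_identical(attr(filter_rr_artifacts(one), "edits"), 25L)

  # injection oracle
  out <- simulate_rr(prof, n_beats = 1000, ectopic_rate = 0.02, seed = 8)
  flagged <- attr(filter_rr_artifacts(out$rr), "edits")
  hit <- mean(out$injected_idx %in% flagged)
  false_alarm <- mean(!(flagged %in% out$injected_idx))
  expect_gte(hit, 0.9)
  expect_lte(sum(!(flagged %in% out$injected_idx)) / 1000, 0.02)
  expect_error(filter_rr_artifacts(clean[1:5, ]),
               class = "gc_insufficient_data")
})

test_that("rmssd honours flags, spans, and its invariances", {
  rrv <- c(800, 850, 800)
  rr <- rr_series(tibble::tibble(beat_t_s = cumsum(rrv) / 1000, rr_ms = rrv))
  expect_equal(rmssd(rr), 50)

  # invariant to adding a constant; scales with the intervals
  rr2 <- rr_series(tibble::tibble(beat_t_s = rr$beat_t_s,
                                  rr_ms = rrv + 100))
  expect_equal(rmssd(rr2), rmssd(rr))
  rr3 <- rr_series(tibble::tibble(beat_t_s = rr$beat_t_s, rr_ms = rrv * 3))
  expect_equal(rmssd(rr3), 3 * rmssd(rr))

  # differences never span a flagged beat
  rrv4 <- c(800, 810, 400, 810, 800, 810, 800)
  rr4 <- rr_series(tibble::tibble(beat_t_s = cumsum(rrv4) / 1000,
                                  rr_ms = rrv4,
                                  artifact = rrv4 == 400))
  expect_equal(rmssd(rr4), 10)

  expect_error(rmssd(rr[1:2, ]), class = "gc_insufficient_data")
})

test_that("metric normalization negates RMSSD and maps onto [0, 1]", {
  df <- tibble::tibble(metric = c(rep("CPD", 3), rep("RMSSD", 2)),
                       value = c(2, 4, 6, 10, 30))
  out <- normalize_metrics(df)
  expect_equal(out$value_norm[1:3], c(0, 0.5, 1))
  # higher RMSSD = lower workload after the sign flip
  expect_equal(out$value_norm[4:5], c(1, 0))
  expect_equal(out$metric_norm[4], "negRMSSD")
  expect_error(normalize_metrics(tibble::tibble(metric = "HR",
                                                value = c(70, 70))),
               class = "gc_degenerate_normalization")
})
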