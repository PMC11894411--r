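# Coverage displacement, heatmaps, focus scoring, curve fit, pursuit
# comparison.

test_that("coverage displacement follows the clipped proportional formula", {
  ncells <- 16 * 9
  set.seed(1)
  # uniform: 5 samples in every cell -> all zero
  cm <- coverage_displacement(grid_stream(rep(5, ncells)))
  expect_true(all(abs(cm$displacement) < 1e-12))
  expect_equal(attr(cm, "uniform_unit_c"), 5)

  # all mass in one cell -> +1 there, -1 everywhere else
  one <- c(720, rep(0, ncells - 1))
  cm1 <- coverage_displacement(grid_stream(one))
  expect_equal(cm1$displacement[cm1$cell_x == 1 & cm1$cell_y == 1], 1)
  expect_true(all(cm1$displacement[-1] == -1))

  # a cell at 1.5c -> displacement 0.5
  per <- rep(4, ncells); per[1] <- 6
  cm2 <- coverage_displacement(grid_stream(per))
  cc <- attr(cm2, "uniform_unit_c")
  expect_equal(cm2$displacement[1], 6 / cc - 1)
  expect_equal(cm2$displacement[1], 0.5, tolerance = 0.02)

  expect_error(coverage_displacement(make_stream(1, 1, valid = FALSE)),
               class = "gc_empty_input")
})

test_that("pre-clipping displacement sums to zero for arbitrary streams", {
  for (seed in 1:3) {
    sim <- simulate_gaze(painting_spec(duration_s = 20),
                         gaze_behavior(dropout_rate = 0.05), seed = seed)
    cm <- coverage_displacement(sim$gaze)
    cc <- attr(cm, "uniform_unit_c")
    expect_equal(sum(cm$n / cc - 1), 0, tolerance = 1e-9)
    expect_true(all(cm$displacement >= -1 & cm$displacement <= 1))
    expect_equal(sum(cm$n),
                 sum(sim$gaze$valid & sim$gaze$x_px <= 1600 &
                       sim$gaze$x_px >= 0))
  }
})

test_that("fixation heatmap normalizes to a unit maximum", {
  ev <- function(x, y, n) {
    tibble::tibble(label = rep("fixation", n), t_on_s = seq_len(n),
                   t_off_s = seq_len(n) + 0.5,
                   x_on_px = x, y_on_px = y, x_off_px = x, y_off_px = y,
                   amplitude_dva = 0, peak_vel_dva_s = 1,
                   median_vel_dva_s = 1)
  }
  single <- fixation_heatmap(ev(150, 150, 1))
  expect_equal(max(single$value), 1)
  expect_equal(sum(single$value), 1)

  two <- fixation_heatmap(dplyr::bind_rows(ev(150, 150, 4), ev(450, 450, 2)))
  expect_equal(two$value[two$cell_x == 2 & two$cell_y == 2], 1)
  expect_equal(two$value[two$cell_x == 5 & two$cell_y == 5], 0.5)

  no_fix <- ev(1, 1, 1)
  no_fix$label <- "saccade"
  expect_error(fixation_heatmap(no_fix), class = "gc_empty_input")
})

test_that("focus dwell semantics: lock-on, never-on, and grace walkthrough", {
  sch <- focus_schedule(tibble::tibble(x_px = 800, y_px = 450,
                                       diameter_dva = 4))
  # locked on target centre: success at exactly 2 s
  lock <- make_stream(rep(800, 1200), rep(450, 1200))
  r1 <- score_focus(lock, sch)
  expect_true(r1$success)
  expect_identical(r1$completion_s, 2)
  expect_equal(r1$dwell_resets, 0L)

  # never inside: timeout at exactly 10 s
  away <- make_stream(rep(100, 1200), rep(100, 1200))
  r2 <- score_focus(away, sch)
  expect_false(r2$success)
  expect_true(is.na(r2$completion_s))
  expect_identical(r2$elapsed_s, 10)

  # inside 1.5 s, outside 0.5 s (> grace: reset), inside 2.0 s -> 4.0 s
  xs <- c(rep(800, 150), rep(100, 50), rep(800, 1000))
  r3 <- score_focus(make_stream(xs, 450), sch)
  expect_true(r3$success)
  expect_equal(r3$completion_s, 4.0)
  expect_equal(r3$dwell_resets, 1L)

  # an excursion shorter than the grace gap does not reset the clock
  xs4 <- c(rep(800, 100), rep(100, 5), rep(800, 1000))
  r4 <- score_focus(make_stream(xs4, 450), sch)
  expect_equal(r4$completion_s, 2.0)
  expect_equal(r4$dwell_resets, 0L)

  # stream too short for the schedule
  expect_error(score_focus(make_stream(rep(100, 100), 100), sch),
               class = "gc_insufficient_data")
})

test_that("success counts fall monotonically as required dwell grows", {
  sch0 <- make_focus_schedule(n_targets = 12,
                              size_set_dva = c(1, 2, 3, 4), seed = 21)
  sim <- simulate_gaze(sch0, gaze_behavior(fixation_noise_sd_dva = 0.4),
                       seed = 22)
  # pad the recording so longer dwell requirements still fit the stream
  g <- tibble::as_tibble(sim$gaze)
  last_ok <- max(which(g$valid))
  extra <- tibble::tibble(
    t_s = max(g$t_s) + seq_len(12 * 10 * 100) / 100,
    x_px = g$x_px[last_ok], y_px = g$y_px[last_ok], valid = TRUE)
  padded <- gaze_stream(dplyr::bind_rows(g, extra))
  succ <- vapply(c(1, 2, 4, 8), function(d) {
    sch <- focus_schedule(sch0$targets, dwell_required_s = d,
                          timeout_s = 10)
    sum(score_focus(padded, sch)$success)
  }, numeric(1))
  expect_true(all(diff(succ) <= 0))
})

test_that("size-success relationship has the expected direction", {
  # big targets succeed; targets much smaller than the jitter mostly fail
  sch <- make_focus_schedule(n_targets = 20,
                             size_set_dva = c(0.5, 6), seed = 23)
  sim <- simulate_gaze(sch, gaze_behavior(fixation_noise_sd_dva = 0.3,
                                          dropout_rate = 0),
                       seed = 24)
  res <- focus_by_size(score_focus(sim$gaze, sch))
  big <- res[res$size_dva == 6, ]
  small <- res[res$size_dva == 0.5, ]   # radius 0.25 < 2 * noise sd
  expect_equal(big$n_success, big$n_targets)
  expect_lt(small$n_success / small$n_targets, 0.5)
})

test_that("success curve fit recovers exact parameters and derivatives", {
  s <- 2:7
  y <- 10 - 8 * exp(-0.5 * s)
  fit <- fit_success_curve(tibble::tibble(size_dva = s, median_success = y))
  expect_equal(fit$a, 10, tolerance = 1e-6)
  expect_equal(fit$b, 8, tolerance = 1e-6)
  expect_equal(fit$c, 0.5, tolerance = 1e-6)

  # analytic vs numeric first derivative
  h <- 1e-6
  num <- (success_curve(fit, 4 + h) - success_curve(fit, 4 - h)) / (2 * h)
  expect_equal(success_curve_deriv1(fit, 4), num, tolerance = 1e-6)
  expect_equal(success_curve_deriv2(fit, 4),
               -fit$b * fit$c^2 * exp(-fit$c * 4), tolerance = 1e-12)

  # plateau onset: where the slope crosses 1.0
  expect_equal(success_curve_deriv1(fit, fit$plateau_onset_dva), 1,
               tolerance = 1e-9)

  # flat data degenerates to b ~ 0
  flat <- fit_success_curve(tibble::tibble(size_dva = s,
                                           median_success = rep(7, 6)))
  expect_equal(flat$b, 0)
  expect_true(all(abs(success_curve_deriv1(flat, s)) < 1e-9))

  expect_error(fit_success_curve(tibble::tibble(size_dva = c(1, 2),
                                                median_success = c(1, 2))),
               class = "gc_insufficient_data")
})

test_that("pursuit comparison is calibrated under the null and detects shifts", {
  mk_events <- function(durs, amps) {
    structure(tibble::tibble(
      label = "pursuit", t_on_s = seq_along(durs),
      t_off_s = seq_along(durs) + durs,
      x_on_px = 0, y_on_px = 0, x_off_px = 0, y_off_px = 0,
      amplitude_dva = amps, peak_vel_dva_s = 1, median_vel_dva_s = 1),
      class = c("event_table", class(tibble::tibble())))
  }
  # location shift: +1 s duration, clearly significant, medians 1 s apart
  set.seed(77)
  base <- rexp(50, 2)
  cmp <- compare_pursuits(mk_events(base, base), mk_events(base + 1, base))
  dur <- cmp[cmp$measure == "duration_s", ]
  expect_lt(dur$p_value, 0.01)
  expect_equal(dur$median_b - dur$median_a, 1, tolerance = 1e-9)

  # null calibration across replicate seeds
  set.seed(88)
  p_null <- replicate(100, {
    a <- rexp(100, 2); b <- rexp(100, 2)
    min(compare_pursuits(mk_events(a, a), mk_events(b, b))$p_value)
  })
  expect_gte(mean(p_null > 0.05), 0.80)
  pd <- replicate(100, {
    a <- rexp(100, 2); b <- rexp(100, 2)
    compare_pursuits(mk_events(a, a), mk_events(b, b))$p_value[1]
  })
  expect_gte(mean(pd > 0.05), 0.90)

  # no pursuits in a condition
  empty <- mk_events(1, 1)
  empty$label <- "fixation"
  expect_error(compare_pursuits(empty, mk_events(1, 1)),
               class = "gc_insufficient_data")
})
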