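p <- default_parameters()

# analytic minimum-jerk displacement profile for synthetic saccades
min_jerk <- function(amplitude, duration, dt, t0 = 0.1, total = 0.5) {
  t <- seq(0, total, by = dt)
  s <- pmin(pmax((t - t0) / duration, 0), 1)
  amplitude * (10 * s^3 - 15 * s^4 + 6 * s^5)
}

test_that("a constant trace and a too-short trace yield no events", {
  expect_equal(nrow(detect_saccades(rep(0.3, 1000), dt = 0.001)), 0)
  expect_equal(nrow(detect_saccades(c(0, 1), dt = 0.001)), 0)
})

test_that("synthetic minimum-jerk saccades are recovered with their amplitude", {
  pos <- min_jerk(1, 0.02, 0.001)
  ev <- detect_saccades(pos, dt = 0.001)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$amplitude, 1, tolerance = 0.01)
  expect_equal(ev$direction, "right")
  expect_gt(ev$peak_velocity, 50)

  # two opposite 0.5 degree movements 200 ms apart
  pos2 <- min_jerk(0.5, 0.02, 0.001, t0 = 0.1) +
    min_jerk(-0.5, 0.02, 0.001, t0 = 0.3)
  ev2 <- detect_saccades(pos2, dt = 0.001)
  expect_equal(nrow(ev2), 2)
  expect_equal(ev2$direction, c("right", "left"))
  expect_lt(max(abs(ev2$amplitude - c(0.5, -0.5))), 0.02)
})

test_that("detection is invariant to a constant position offset", {
  pos <- min_jerk(0.8, 0.02, 0.001)
  ev <- detect_saccades(pos, dt = 0.001)
  ev_off <- detect_saccades(pos + 17.3, dt = 0.001)
  expect_equal(ev, ev_off)
})

test_that("fixation statistics aggregate events and positions correctly", {
  ev0 <- detect_saccades(rep(0, 1000), dt = 0.001)
  st0 <- summarize_fixation(ev0, rep(0.2, 1000), duration = 1)
  expect_equal(st0$rate, 0)
  expect_true(all(is.na(st0$magnitude_quantiles)))
  expect_true(is.na(st0$main_sequence_slope))
  expect_equal(st0$mean_eye_position, 0.2)

  # 100 events in 100 s, exact main-sequence relationship
  ev <- data.frame(
    onset = seq(0.5, 99.5, length.out = 100),
    offset = seq(0.5, 99.5, length.out = 100) + 0.02,
    amplitude = rep(c(0.5, -1), 50),
    magnitude = rep(c(0.5, 1), 50),
    peak_velocity = 60 * rep(c(0.5, 1), 50),
    direction = rep(c("right", "left"), 50)
  )
  st <- summarize_fixation(ev, rep(0, 10), duration = 100)
  expect_equal(st$rate, 1.0)
  expect_equal(st$main_sequence_slope, 60)
  expect_equal(st$magnitude_quantiles[["q50"]], 0.75)
  expect_error(summarize_fixation(ev, rep(0, 10), duration = 0), "positive")
})

test_that("square-wave jerks require opposition, proximity and matched size", {
  mk <- function(dirs, onsets, mags = rep(1, length(dirs))) {
    data.frame(onset = onsets, offset = onsets + 0.02, amplitude =
                 ifelse(dirs == "right", mags, -mags), magnitude = mags,
               peak_velocity = 60 * mags, direction = dirs)
  }
  expect_equal(detect_swj(mk("right", 0))$count, 0)
  expect_equal(detect_swj(mk(c("right", "left"), c(0, 0.2)))$count, 1)
  expect_equal(detect_swj(mk(c("right", "right"), c(0, 0.2)))$count, 0)
  expect_equal(detect_swj(mk(c("right", "left"), c(0, 0.8)))$count, 0)
  expect_equal(detect_swj(mk(c("right", "left"), c(0, 0.2),
                             c(1, 3)))$count, 0)
})

test_that("oscillation runs are counted once however long they extend", {
  mk <- function(dirs, gap = 0.2) {
    onsets <- seq(0, by = gap, length.out = length(dirs))
    data.frame(onset = onsets, offset = onsets + 0.02,
               amplitude = ifelse(dirs == "right", 1, -1),
               magnitude = 1, peak_velocity = 60, direction = dirs)
  }
  expect_equal(detect_oscillations(mk(c("right", "left", "right"))), 1)
  expect_equal(detect_oscillations(mk(c("right", "left"))), 0)
  expect_equal(detect_oscillations(
    mk(c("right", "left", "right", "left", "right"))), 1)
  expect_equal(detect_oscillations(
    mk(c("right", "left", "right", "right", "left", "right"))), 2)
  expect_equal(detect_oscillations(mk(c("right", "left", "right"),
                                      gap = 0.8)), 0)
})

test_that("the simulated main sequence rises across magnitude bins", {
  ev <- detect_saccades(fixation_run())
  expect_gt(nrow(ev), 10)
  bins <- cut(ev$magnitude, quantile(ev$magnitude, c(0, 1 / 3, 2 / 3, 1)),
              include.lowest = TRUE)
  mean_pv <- tapply(ev$peak_velocity, bins, mean)
  expect_true(all(diff(mean_pv) > 0))
})
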