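p <- default_parameters()

test_that("plant holds position without (or with symmetric) burst input", {
  st <- plant_init(p)
  for (i in 1:100) st <- plant_step(st, 0, 0, p$dt, p)
  expect_equal(st$eye_pos, 0)
  for (i in 1:100) st <- plant_step(st, 300, 300, p$dt, p)
  expect_equal(st$eye_pos, 0)
})

test_that("a rectangular burst displaces the eye by its closed-form integral", {
  R <- 400
  st <- plant_init(p)
  for (i in 1:50) st <- plant_step(st, 0, R, p$dt, p)    # 50-ms pulse
  for (i in 1:300) st <- plant_step(st, 0, 0, p$dt, p)   # settle
  expect_equal(st$eye_pos, p$velocity_gain * R * 0.05, tolerance = 0.01)
  # matched pulse-step: no post-saccadic drift
  drift_probe <- st$eye_pos
  for (i in 1:200) st <- plant_step(st, 0, 0, p$dt, p)
  expect_equal(st$eye_pos, drift_probe, tolerance = 1e-9)
})

test_that("noise-free fixation produces no saccades", {
  p0 <- modify_parameters(p, list(noise_gain = 0))
  res <- run_simulation(p0, experiment(0, "quiet"), 1, seed = 1)
  expect_equal(nrow(detect_saccades(res)), 0)
  expect_lt(max(abs(res$traces$eye_pos)), 1e-6)
})

test_that("a 2 degree target step elicits exactly one accurate rightward saccade", {
  res <- step2_run()
  ev <- detect_saccades(res)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, "right")
  expect_equal(ev$amplitude, 2, tolerance = 0.1)
  expect_gt(ev$onset, 0.2)
})

test_that("simulations are bit-reproducible from their seed", {
  r1 <- run_simulation(p, experiment(0, "fix"), 1.5, seed = 123)
  r2 <- run_simulation(p, experiment(0, "fix"), 1.5, seed = 123)
  expect_identical(r1$traces, r2$traces)
  r3 <- run_simulation(p, experiment(0, "fix"), 1.5, seed = 124)
  expect_false(identical(r1$traces$eye_pos, r3$traces$eye_pos))
})

test_that("the engine agrees with the composed module steps", {
  # Euler scheme on both routes: the engine inlines the module equations,
  # this pins the two implementations together.
  p0 <- modify_parameters(p, list(noise_gain = 0))
  n_steps <- 120L
  delay <- round(p0$visual_delay / p0$dt)
  target_fn <- function(t) ifelse(t < 0.02, 0, 2)
  res <- run_simulation(p0, experiment(target_fn, "cmp"),
                        n_steps * p0$dt, seed = 1, scheme = "euler")

  g <- sc_geometry(p0)
  sc <- sc_init(p0, g)
  bs <- brainstem_init()
  cb <- cerebellum_init()
  pl <- plant_init(p0)
  zero <- rep(0, p0$n_neurons)
  t_axis <- seq(0, by = p0$dt, length.out = n_steps + 1)
  target <- target_fn(t_axis)
  eye_hist <- numeric(n_steps + 1)
  eye <- numeric(n_steps)
  opn <- numeric(n_steps)
  mlr <- numeric(n_steps)
  for (i in seq_len(n_steps)) {
    eye_hist[i] <- pl$eye_pos
    eye[i] <- pl$eye_pos
    j <- max(1L, i - delay)
    err <- target[j] - eye_hist[j]
    cd <- cortical_drive(err, g, p0)
    outs <- sc_outputs(sc, p0)
    rates <- brainstem_rates(bs, p0)
    opn[i] <- rates[["opn"]]
    mlr[i] <- rates[["mlebn_r"]]
    cbtmp <- cb
    cbtmp$bursts <- cerebellum_bursts(cb, outs$drive_bn_left,
                                      outs$drive_bn_right, p0)
    ch <- choke_signal(cbtmp, p0)
    rost <- rostral_reset_drive(cbtmp, p0)
    sc_new <- sc_step(sc, cd$fef + cd$bg, zero, rost, p0$dt, p0,
                      scheme = "euler")
    bs_new <- brainstem_step(bs, outs$drive_bn_left, outs$drive_bn_right,
                             outs$drive_opn, ch$choke_left, ch$choke_right,
                             p0$dt, p0, scheme = "euler")
    cb_new <- cerebellum_step(cb, rates[["mlebn_l"]], rates[["mlebn_r"]],
                              outs$drive_bn_left, outs$drive_bn_right,
                              p0$dt, p0, scheme = "euler")
    pl_new <- plant_step(pl, rates[["mlebn_l"]], rates[["mlebn_r"]],
                         p0$dt, p0, scheme = "euler")
    sc <- sc_new; bs <- bs_new; cb <- cb_new; pl <- pl_new
  }
  idx <- seq_len(n_steps)
  expect_equal(res$traces$eye_pos[idx], eye, tolerance = 1e-9)
  expect_equal(res$traces$r_opn[idx], opn, tolerance = 1e-8)
  expect_equal(res$traces$r_mlebn_r[idx], mlr, tolerance = 1e-8)
})

test_that("result objects carry complete, consistent metadata and traces", {
  res <- run_simulation(p, experiment(0, "meta"), 0.5, seed = 5,
                        record_map = TRUE)
  expect_s3_class(res, "saccsim_result")
  n <- length(res$time)
  expect_equal(nrow(res$traces), n)
  expect_equal(dim(res$sc_map), c(n, p$n_neurons))
  expect_equal(dim(res$burst_map), c(n, p$n_neurons))
  expect_true(all(res$burst_map %in% c(0, res$burst_map[res$burst_map >=
                                                          p$burst_threshold])))
  expect_identical(res$seed, 5L)
  expect_identical(res$condition, "meta")
  expect_output(print(res), "saccades detected")
})

test_that("invalid experiment descriptions are rejected", {
  expect_error(run_simulation(p, list(target = 0), 1, 1), "experiment")
  expect_error(run_simulation(p, experiment(0), 0.005, 1), "10 time steps")
  expect_error(experiment(target = "up"), "number or a function")
  bad <- experiment(function(t) 0)   # not vectorized over time
  expect_error(run_simulation(p, bad, 0.5, 1), "vectorized")
})
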