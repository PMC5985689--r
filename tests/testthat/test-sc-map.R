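p <- default_parameters()
g <- sc_geometry(p)

test_that("lateral connectivity has the Mexican-hat profile", {
  mid <- g$midline
  expect_equal(lateral_weight(mid, mid, g, p), p$A_w)           # dist 0
  expect_equal(lateral_weight(1, p$n_neurons, g, p), -p$C,      # far field
               tolerance = 1e-12)
  # dist = sigma_SC (5 neurons away): (A_w + C) e^{-1/2} - C
  expect_equal(lateral_weight(mid, mid + 5L, g, p), 2 * exp(-0.5) - 1,
               tolerance = 1e-12)
  expect_equal(lateral_weight(mid, mid + 5L, g, p), 0.2130613,
               tolerance = 1e-6)
  W <- lateral_weights(g, p)
  expect_true(isSymmetric(W))
  expect_equal(unname(diag(W)), rep(p$A_w, p$n_neurons))
  expect_true(min(W) >= -p$C)
})

test_that("activation function is the bounded logistic of the state", {
  expect_equal(sc_activation(0, p), 250)                 # midpoint F/2
  expect_equal(sc_activation(1e6, p), 500)               # saturation F
  expect_equal(sc_activation(10, p), 500 / (1 + exp(-1)),
               tolerance = 1e-12)
  u <- seq(-100, 100, length.out = 201)
  a <- sc_activation(u, p)
  expect_true(all(diff(a) > 0))
  expect_true(all(a > 0 & a < p$F))
})

test_that("burst layer thresholds the buildup layer with inclusive boundary", {
  thr <- p$burst_threshold
  expect_equal(burst_layer(rep(thr - 1, 5), p), rep(0, 5))
  expect_equal(burst_layer(thr, p), thr)                 # boundary included
  expect_equal(burst_layer(rep(p$F, 5), p), rep(p$F, 5))
})

test_that("zero input leaves a translation-symmetric interior pattern", {
  st1 <- sc_step(sc_init(p), rep(0, p$n_neurons), rep(0, p$n_neurons), 0,
                 p$dt, p)
  interior <- st1$a[10:92]
  expect_lt(diff(range(interior)), 1e-9)      # all-equal up to edge effects
  st <- settle_sc(rep(0, p$n_neurons), p, n_steps = 600)
  expect_true(all(is.finite(st$u)))
})

test_that("a constant Gaussian input at the pole forms a stable central hill", {
  input <- 300 * exp(-g$positions^2 / (2 * 0.5^2))
  st <- settle_sc(input, p, n_steps = 500)
  # the settled hill is symmetric about the pole and maximal there (the
  # saturated crown is flat, so compare against the midline activation)
  expect_equal(st$a, rev(st$a), tolerance = 1e-9)
  expect_gte(st$a[g$midline], max(st$a) * (1 - 1e-9))
  # hill stability: sup-norm change per step < 1e-6 F within 1 s
  st2 <- sc_step(st, input, rep(0, p$n_neurons), 0, p$dt, p)
  st3 <- settle_sc(input, p, n_steps = 500, state = st2)
  st4 <- sc_step(st3, input, rep(0, p$n_neurons), 0, p$dt, p)
  expect_lt(max(abs(st4$a - st3$a)), 1e-6 * p$F)
})

test_that("long-range inhibition leaves a single winning hill", {
  # two competing input sites: the stronger site saturates, its long-range
  # inhibition extinguishes the weaker one entirely. (Two exactly equal
  # self-sustaining inputs can coexist in this weight regime; selection
  # between balanced alternatives is performed upstream by the
  # basal-ganglia surround in the closed loop.)
  two <- 500 * exp(-(g$positions - 2)^2 / 0.5) +
    350 * exp(-(g$positions + 2)^2 / 0.5)
  st <- settle_sc(two, p, n_steps = 1500)
  expect_gt(sum(st$a[g$positions > 1]), 5000)
  expect_lt(sum(st$a[g$positions < -1]), 1e-6)
  # mirrored inputs select the mirrored winner
  st_l <- settle_sc(rev(two), p, n_steps = 1500)
  expect_gt(sum(st_l$a[g$positions < -1]), 5000)
  expect_lt(sum(st_l$a[g$positions > 1]), 1e-6)
})

test_that("one coarse step agrees with ten refined sub-steps", {
  input <- 300 * exp(-(g$positions - 1)^2 / 0.5)
  st0 <- settle_sc(input, p, n_steps = 100)
  coarse <- sc_step(st0, input, rep(0, p$n_neurons), 0, 0.001, p)
  fine <- st0
  for (i in 1:10) {
    fine <- sc_step(fine, input, rep(0, p$n_neurons), 0, 0.0001, p)
  }
  expect_equal(coarse$a, fine$a, tolerance = 1e-3)
})

test_that("descending projection weights have the stated spatial profiles", {
  w <- sc_projection_weights(g, p)
  expect_equal(w$opn[g$midline], 1)
  expect_equal(w$opn[c(1, p$n_neurons)], c(0, 0))
  expect_true(all(diff(w$opn[1:g$midline]) > 0))
  expect_equal(w$bn[g$midline], 0)
  expect_true(all(diff(w$bn[g$midline:p$n_neurons]) > 0))
})

test_that("output drives implement the normalized centre-of-activity code", {
  st <- sc_init(p)
  # no burst activity: zero BN drives over a positive denominator
  st$a <- rep(10, p$n_neurons)
  st$burst <- burst_layer(st$a, p)
  out <- sc_outputs(st, p)
  expect_equal(out$drive_bn_left, 0)
  expect_equal(out$drive_bn_right, 0)
  expect_gt(out$drive_opn, 0)

  # dominant single burst site at +2 mm reads out its location once the
  # burst term dominates the normalization denominator
  st$a <- rep(1e-3, p$n_neurons)
  i2 <- which.min(abs(g$positions - 2))
  st$burst <- rep(0, p$n_neurons)
  st$burst[i2] <- 5e5
  out <- sc_outputs(st, p)
  expect_equal(out$drive_bn_right, 2.0, tolerance = 0.01)
  expect_equal(out$drive_bn_left, 0)

  # symmetric activity gives symmetric drives
  st$a <- 400 * exp(-g$positions^2 / 0.18)
  st$burst <- burst_layer(st$a, p)
  out <- sc_outputs(st, p)
  expect_equal(out$drive_bn_left, out$drive_bn_right, tolerance = 1e-12)
})

test_that("BN drive depends on burst location, not amount", {
  st <- sc_init(p)
  st$a <- ifelse(abs(g$positions - 1) <= 0.5, 499, 1)
  st$burst <- burst_layer(st$a, p)
  base_drive <- sc_outputs(st, p)$drive_bn_right
  st2 <- st
  st2$burst <- 3 * st$burst      # scale the burst layer, buildup fixed
  scaled_drive <- sc_outputs(st2, p)$drive_bn_right
  expect_lt(abs(scaled_drive - base_drive) / base_drive, 0.05)
})

test_that("rostral inactivation nulls outputs without touching the dynamics", {
  input <- 350 * exp(-g$positions^2 / 0.5)
  st <- settle_sc(input, p, n_steps = 400)
  out_ctrl <- sc_outputs(st, p)

  expect_equal(sc_outputs(st, p, inactivation = NULL), out_ctrl)
  whole <- inactivation_region("right", outer = p$S)
  both <- apply_inactivation(apply_inactivation(st, whole),
                             inactivation_region("left", outer = p$S))
  expect_equal(sum(both$a[g$positions != 0]), 0)

  region <- inactivation_region("right", outer = 1)
  out_inact <- sc_outputs(st, p, inactivation = region)
  expect_lt(out_inact$drive_opn, out_ctrl$drive_opn)
  expect_equal(out_inact$drive_bn_right, 0)   # hill sat within (0, 1] mm
  # the midline neuron itself is spared
  masked <- apply_inactivation(st, region)
  expect_equal(masked$a[g$midline], st$a[g$midline])
  expect_identical(masked$u, st$u)
})
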