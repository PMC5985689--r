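#' Describe an experiment
#'
#' Bundles the stimulus and condition of one simulation: the target
#' trajectory (desired gaze location over time, degrees), an optional
#' rostral inactivation region, and a condition label carried into the
#' result metadata.
#'
#' @param target Either a single number (constant target position, deg) or
#'   a function of time `function(t)` returning the target position at `t`
#'   seconds (vectorized over `t`).
#' @param condition Free-text condition label.
#' @param inactivation Optional [inactivation_region()] silencing part of
#'   the collicular output for the whole run.
#' @return A list of class `saccsim_experiment`.
#' @examples
#' experiment(0)                                   # steady fixation
#' experiment(function(t) ifelse(t < 0.2, 0, 2))   # 2 deg rightward step
#' @export
experiment <- function(target = 0, condition = "custom",
                       inactivation = NULL) {
  if (is.numeric(target) && length(target) == 1) {
    tval <- target
    target_fn <- function(t) rep(tval, length(t))
  } else if (is.function(target)) {
    target_fn <- target
  } else {
    stop("target must be a number or a function of time", call. = FALSE)
  }
  structure(list(target = target_fn, condition = condition,
                 inactivation = inactivation),
            class = "saccsim_experiment")
}

#' Initialize the oculomotor plant
#'
#' Final common pathway: the left/right medium-lead burst rates are
#' converted into a velocity command (pulse), integrated by the neural
#' integrator (step), and low-pass filtered into a slide component; the
#' motoneuron signal pulse_gain * pulse + slide_gain * slide + step drives
#' a first-order eye plant of time constant `tau_plant`. With the default
#' matched pulse (`pulse_gain = tau_plant`, `slide_gain = 0`) the eye
#' tracks the neural integrator exactly and shows no post-saccadic drift.
#'
#' @param params A [default_parameters()] object (unused, kept for symmetry).
#' @param eye_pos Initial eye position in degrees.
#' @return A list of class `plant_state` with `integrator`, `slide`,
#'   `eye_pos` (deg) and `eye_vel` (deg/s).
#' @export
plant_init <- function(params = NULL, eye_pos = 0) {
  structure(list(integrator = eye_pos, slide = 0, eye_pos = eye_pos,
                 eye_vel = 0),
            class = "plant_state")
}

plant_derivative <- function(integrator, slide, eye, v_cmd, params) {
  motoneuron <- integrator + params$pulse_gain * v_cmd +
    params$slide_gain * slide
  c(v_cmd,
    (v_cmd - slide) / params$tau_slide,
    (motoneuron - eye) / params$tau_plant)
}

#' Advance the oculomotor plant by one time step
#'
#' @param state A [plant_init()] state.
#' @param mlebn_l,mlebn_r Medium-lead excitatory burst rates (spikes/s).
#' @param dt Time step in seconds.
#' @param params A [default_parameters()] object.
#' @param scheme `"rk3"` (default) or `"euler"`.
#' @return The updated `plant_state`; `eye_vel` is the position difference
#'   across the step divided by `dt`.
#' @export
plant_step <- function(state, mlebn_l, mlebn_r, dt, params,
                       scheme = c("rk3", "euler")) {
  scheme <- match.arg(scheme)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  v_cmd <- params$velocity_gain * (mlebn_r - mlebn_l)
  y <- c(state$integrator, state$slide, state$eye_pos)
  f <- function(y) plant_derivative(y[1L], y[2L], y[3L], v_cmd, params)
  if (scheme == "euler") {
    y_new <- y + dt * f(y)
  } else {
    k1 <- f(y)
    k2 <- f(y + dt / 2 * k1)
    k3 <- f(y + 3 * dt / 4 * k2)
    y_new <- y + dt * (2 * k1 + 3 * k2 + 4 * k3) / 9
  }
  state$eye_vel <- (y_new[3L] - state$eye_pos) / dt
  state$integrator <- y_new[1L]
  state$slide <- y_new[2L]
  state$eye_pos <- y_new[3L]
  state
}

#' Run a closed-loop simulation
#'
#' Integrates the full model — collicular map, cortical inputs, noise
#' field, brainstem trigger, cerebellar stop circuit and oculomotor plant —
#' with a 1-ms-class fixed step. Continuous states advance with a
#' fixed-step third-order Runge-Kutta scheme (Bogacki-Shampine stages);
#' the discrete elements (visual delay buffer, noise draw, noise reset at
#' saccade onset) update once per step. The retinal error feeding the
#' cortical drives is target minus eye position, both read
#' `visual_delay` seconds in the past.
#'
#' The run is deterministic given `(params, experiment, duration, seed)`.
#'
#' @param params A [default_parameters()] object.
#' @param experiment An [experiment()] description.
#' @param duration Simulated time in seconds (>= 10 dt).
#' @param seed Integer seed for the noise stream.
#' @param record_map If `TRUE`, also record the full per-step collicular
#'   activation, burst and noise maps (memory: n_steps x n_neurons doubles
#'   each).
#' @param scheme `"rk3"` (default) or `"euler"`.
#' @return An object of class `saccsim_result`: list with `time` (s),
#'   `traces` (data frame of per-step signals: target, eye position and
#'   velocity, the seven brainstem rates, the three collicular drives, the
#'   four cerebellar bursts, choke and rostral-reset drives, noise RMS,
#'   map activity peak and its position), optional `sc_map`, `burst_map`,
#'   `noise_map` matrices, and metadata (`params`, `seed`, `condition`,
#'   `duration`, `dt`, `scheme`) sufficient to reproduce the run exactly.
#' @examples
#' \donttest{
#' p <- default_parameters()
#' ex <- experiment(function(t) ifelse(t < 0.2, 0, 2), "step_2deg")
#' res <- run_simulation(modify_parameters(p, list(noise_gain = 0)),
#'                       ex, duration = 1, seed = 1)
#' detect_saccades(res)
#' }
#' @export
run_simulation <- function(params, experiment, duration, seed = 1,
                           record_map = FALSE,
                           scheme = c("rk3", "euler")) {
  scheme <- match.arg(scheme)
  validate_parameters(params)
  if (!inherits(experiment, "saccsim_experiment")) {
    stop("experiment must be built with experiment()", call. = FALSE)
  }
  dt <- params$dt
  if (duration < 10 * dt) {
    stop("duration must be at least 10 time steps", call. = FALSE)
  }
  set.seed(as.integer(seed))

  n_steps <- round(duration / dt)
  delay_steps <- max(1L, round(params$visual_delay / dt))
  geometry <- sc_geometry(params)
  n <- params$n_neurons
  pos <- geometry$positions
  W_dx <- geometry$spacing * lateral_weights(geometry, params)
  w_opn <- (1 - abs(pos) / params$S) * geometry$spacing
  mask_r <- pos > 0
  mask_l <- pos < 0
  p_r <- pos[mask_r]
  p_l <- -pos[mask_l]
  rostral_sign <- ifelse(abs(pos) <= params$rostral_width, 1, -1)
  inact <- experiment$inactivation
  inact_mask <- if (is.null(inact)) NULL else inactivation_mask(inact, geometry)
  noise <- noise_init(geometry, params)
  phi <- exp(-dt / params$tau_noise)
  sphi <- sqrt(1 - phi^2)
  use_noise <- params$noise_gain > 0

  # target sampled on the step grid (times 0, dt, ..., duration)
  t_axis <- seq(0, by = dt, length.out = n_steps + 1L)
  target <- experiment$target(t_axis)
  if (length(target) != n_steps + 1L) {
    stop("target function must be vectorized over time", call. = FALSE)
  }

  # continuous state: u (n), brainstem x (7), cerebellum (e1_l, e1_r,
  # e2_l, e2_r), plant (integrator, slide, eye)
  iu <- seq_len(n)
  ib <- n + 1:7
  ic <- n + 8:11
  ip <- n + 12:14
  y <- c(rep(0, n), rep(0, 7), rep(0, 4), c(0, 0, 0))

  pF <- params$F; pbeta <- params$beta_u
  pBm <- params$B_m; pb <- params$b; pe0 <- params$e0
  thr <- params$burst_threshold
  bf <- params$buildup_fraction
  vg <- params$velocity_gain
  tau_SC <- params$tau_SC; tau_BN <- params$tau_BN
  T1 <- params$T_cblm1; T2 <- params$T_cblm2; Tleak <- params$T_cblm_leak
  pA <- params$A; pB <- params$B; pS <- params$S
  k_c <- params$k_c; k_pow <- params$k_c_power
  F1 <- params$F1; F2 <- params$F2; F3 <- params$F3; F4 <- params$F4
  choke_gain <- params$choke_gain; choke_crossed <- params$choke_crossed
  rostral_gain <- params$rostral_gain
  k_bn <- params$k_bn; k_opn <- params$k_opn; opn_bias <- params$opn_bias
  w_OPN_LLIBN <- params$w_OPN_LLIBN; w_OPN_BN <- params$w_OPN_BN
  w_LLIBN_OPN <- params$w_LLIBN_OPN; W_IBN_BN <- params$W_IBN_BN
  w_MLIBN_OPN <- params$mlibn_opn_weight
  pulse_gain <- params$pulse_gain; slide_gain <- params$slide_gain
  tau_slide <- params$tau_slide; tau_plant <- params$tau_plant

  # per-step frozen inputs, written by the loop, read by deriv()
  input_cort <- rep(0, n)
  nvec <- rep(0, n)

  # Inlined arithmetic of the module equations (sc_derivative,
  # brainstem_inputs, cerebellum_command/bursts, plant_derivative); kept in
  # step with those functions by an equivalence test in the test suite.
  deriv <- function(y, want_diag = FALSE) {
    u <- y[iu]
    a <- pF / (1 + exp(-pbeta * u))
    a_out <- a
    if (!is.null(inact_mask)) a_out[inact_mask] <- 0
    burst <- a_out
    burst[burst < thr] <- 0
    denom <- sum(burst) + bf * sum(a_out)
    drive_opn <- sum(w_opn * a_out)
    if (denom > 0) {
      drive_l <- sum(p_l * burst[mask_l]) / denom
      drive_r <- sum(p_r * burst[mask_r]) / denom
    } else {
      drive_l <- 0
      drive_r <- 0
    }

    x <- y[ib]
    r <- pBm * (1 - exp(-(x - pe0) / pb))
    r[r < 0] <- 0

    ce <- y[ic]
    cc_l <- k_c * (pA * (exp(min(drive_l, pS) / pB) - 1))^k_pow
    cc_r <- k_c * (pA * (exp(min(drive_r, pS) / pB) - 1))^k_pow
    late_l <- max(F1 * ce[3L] - F2 * cc_l, 0)
    late_r <- max(F1 * ce[4L] - F2 * cc_r, 0)
    if (choke_crossed) {
      choke_l <- choke_gain * late_r
      choke_r <- choke_gain * late_l
    } else {
      choke_l <- choke_gain * late_l
      choke_r <- choke_gain * late_r
    }
    rostral <- rostral_gain * (late_l + late_r)

    du <- (-u + W_dx %*% a + input_cort + nvec + rostral * rostral_sign) /
      tau_SC
    cross_to_l <- W_IBN_BN * (r[3L] + r[7L])
    cross_to_r <- W_IBN_BN * (r[2L] + r[6L])
    in_l <- k_bn * drive_l
    in_r <- k_bn * drive_r
    bs_in <- c(
      opn_bias + k_opn * drive_opn - w_LLIBN_OPN * (r[2L] + r[3L]) -
        w_MLIBN_OPN * (r[6L] + r[7L]),
      in_l - w_OPN_LLIBN * r[1L] - cross_to_l,
      in_r - w_OPN_LLIBN * r[1L] - cross_to_r,
      in_l - w_OPN_BN * r[1L] - cross_to_l - choke_l,
      in_r - w_OPN_BN * r[1L] - cross_to_r - choke_r,
      in_l - w_OPN_BN * r[1L] - cross_to_l - choke_l,
      in_r - w_OPN_BN * r[1L] - cross_to_r - choke_r)
    dx <- (-x + bs_in) / tau_BN
    dce <- c((r[4L] - ce[1L]) / T1,
             (r[5L] - ce[2L]) / T1,
             ce[1L] / T2 - ce[3L] / Tleak,
             ce[2L] / T2 - ce[4L] / Tleak)
    v_cmd <- vg * (r[5L] - r[4L])
    motoneuron <- y[ip[1L]] + pulse_gain * v_cmd + slide_gain * y[ip[2L]]
    dy <- c(du, dx, dce,
            v_cmd,
            (v_cmd - y[ip[2L]]) / tau_slide,
            (motoneuron - y[ip[3L]]) / tau_plant)
    if (!want_diag) return(dy)
    list(dy = dy, r = r, drive_opn = drive_opn, drive_l = drive_l,
         drive_r = drive_r,
         early_l = max(F3 * cc_l - F4 * ce[3L], 0),
         early_r = max(F3 * cc_r - F4 * ce[4L], 0),
         late_l = late_l, late_r = late_r,
         choke_l = choke_l, choke_r = choke_r, rostral = rostral,
         a = a)
  }

  trace_names <- c(
    "target", "eye_pos", "r_opn", "r_llibn_l", "r_llibn_r",
    "r_mlebn_l", "r_mlebn_r", "r_mlibn_l", "r_mlibn_r",
    "drive_opn", "drive_bn_l", "drive_bn_r",
    "early_l", "early_r", "late_l", "late_r",
    "choke_l", "choke_r", "rostral", "noise_rms",
    "sc_peak", "sc_peak_pos"
  )
  TR <- matrix(NA_real_, nrow = n_steps + 1L, ncol = length(trace_names))
  eye_hist <- numeric(n_steps + 1L)
  if (record_map) {
    sc_map <- matrix(NA_real_, n_steps + 1L, n)
    burst_map <- matrix(NA_real_, n_steps + 1L, n)
    noise_map <- matrix(NA_real_, n_steps + 1L, n)
  }

  record_row <- function(i, d) {
    peak_i <- which.max(d$a)
    TR[i, ] <<- c(target[i], y[ip[3L]], d$r[1L], d$r[2L], d$r[3L],
                  d$r[4L], d$r[5L], d$r[6L], d$r[7L],
                  d$drive_opn, d$drive_l, d$drive_r,
                  d$early_l, d$early_r, d$late_l, d$late_r,
                  d$choke_l, d$choke_r, d$rostral,
                  sqrt(mean(nvec^2)), d$a[peak_i], pos[peak_i])
    eye_hist[i] <<- y[ip[3L]]
    if (record_map) {
      sc_map[i, ] <<- d$a
      b <- d$a
      if (!is.null(inact_mask)) b[inact_mask] <- 0
      burst_map[i, ] <<- ifelse(b >= thr, b, 0)
      noise_map[i, ] <<- nvec
    }
  }

  err_prev <- NA_real_
  in_saccade <- FALSE

  for (i in seq_len(n_steps)) {
    j <- max(1L, i - delay_steps)
    err <- target[j] - eye_hist[j]
    if (is.na(err_prev) || err != err_prev) {
      cd <- cortical_drive(err, geometry, params)
      input_cort <- cd$fef + cd$bg
      err_prev <- err
    }
    if (use_noise) {
      noise$z <- phi * noise$z + sphi * drop(noise$M %*% stats::rnorm(n))
      nvec <- params$noise_gain * noise$z
    }

    d1 <- deriv(y, want_diag = TRUE)
    record_row(i, d1)
    if (scheme == "euler") {
      y <- y + dt * d1$dy
    } else {
      k2 <- deriv(y + dt / 2 * d1$dy)
      k3 <- deriv(y + 3 * dt / 4 * k2)
      y <- y + dt * (2 * d1$dy + 3 * k2 + 4 * k3) / 9
    }
    if (!all(is.finite(y))) {
      bad <- which(!is.finite(y))[1L]
      part <- if (bad <= n) "sc_u" else if (bad <= n + 7) "brainstem_x"
        else if (bad <= n + 11) "cerebellum_e" else "plant"
      stop("non-finite state (", part, ") at step ", i, call. = FALSE)
    }

    # online event flag from the updated omnipause state
    r_opn_now <- max(0, pBm * (1 - exp(-(y[ib[1L]] - pe0) / pb)))
    if (!in_saccade && r_opn_now < 1) {
      in_saccade <- TRUE
    } else if (in_saccade && r_opn_now >= 1) {
      in_saccade <- FALSE
      noise$z[] <- 0          # reset the noise pattern after each saccade
      nvec[] <- 0
    }
  }
  d_end <- deriv(y, want_diag = TRUE)
  record_row(n_steps + 1L, d_end)

  traces <- as.data.frame(TR)
  names(traces) <- trace_names
  traces$eye_vel <- c(0, diff(traces$eye_pos)) / dt

  res <- list(
    time = t_axis,
    traces = traces,
    sc_map = if (record_map) sc_map else NULL,
    burst_map = if (record_map) burst_map else NULL,
    noise_map = if (record_map) noise_map else NULL,
    geometry = geometry,
    params = params,
    seed = as.integer(seed),
    condition = experiment$condition,
    duration = duration,
    dt = dt,
    scheme = scheme
  )
  class(res) <- "saccsim_result"
  res
}

#' @export
print.saccsim_result <- function(x, ...) {
  cat("<saccsim_result> ", x$condition, ": ", x$duration, " s at dt = ",
      x$dt * 1000, " ms, seed ", x$seed, "\n", sep = "")
  ev <- detect_saccades(x)
  cat("  saccades detected: ", nrow(ev), "\n", sep = "")
  rng <- range(x$traces$eye_pos)
  cat(sprintf("  eye position range: [%.3f, %.3f] deg\n", rng[1], rng[2]))
  invisible(x)
}
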