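#' Initialize the cerebellar stop circuit
#'
#' Fastigial-like machinery that ends saccades: for each movement side it
#' integrates an efference copy of the medium-lead excitatory burst-neuron
#' rate through a second-order system (a lag stage with time constant
#' `T_cblm1` feeding a leaky integrator with gain 1/`T_cblm2` and slow leak
#' `T_cblm_leak`), and compares the integrated copy `e` against the
#' collicular command `c`. The late burst switches on when F1 e exceeds
#' F2 c; the early burst carries the collicular command until the efference
#' copy catches up (F3 c - F4 e, rectified).
#'
#' @param params A [default_parameters()] object (unused, kept for symmetry).
#' @return A list of class `cerebellum_state` with lag states `e1_l`,
#'   `e1_r` and integrator states `e2_l`, `e2_r`, all zero.
#' @export
cerebellum_init <- function(params = NULL) {
  structure(list(e1_l = 0, e1_r = 0, e2_l = 0, e2_r = 0),
            class = "cerebellum_state")
}

# Scaled collicular command: the side's normalized burst drive (mm of
# collicular surface) decoded into the desired displacement in degrees via
# the inverse retinotopic map, times the command gain. This makes the
# e-vs-c crossing rule size-proportional, giving accurate stops across
# saccade amplitudes.
cerebellum_command <- function(c_drive, params) {
  d_deg <- params$A * (exp(pmin(c_drive, params$S) / params$B) - 1)
  params$k_c * d_deg^params$k_c_power
}

cerebellum_derivative <- function(st, mlebn_l, mlebn_r, params) {
  c(
    (mlebn_l - st[1L]) / params$T_cblm1,
    (mlebn_r - st[2L]) / params$T_cblm1,
    st[1L] / params$T_cblm2 - st[3L] / params$T_cblm_leak,
    st[2L] / params$T_cblm2 - st[4L] / params$T_cblm_leak
  )
}

#' Early and late cerebellar bursts
#'
#' Late burst_s = max(F1 e_s - F2 c_s, 0): fires once the integrated
#' efference copy surpasses the collicular command, i.e. when the eye has
#' moved as far as the command requested. Early burst_s =
#' max(F3 c_s - F4 e_s, 0): carries the command from saccade onset until
#' the efference copy builds up. Sides index the movement direction.
#'
#' @param state A [cerebellum_init()] state.
#' @param c_left,c_right Collicular burst drives per side (mm).
#' @param params A [default_parameters()] object.
#' @return List with `early_l`, `early_r`, `late_l`, `late_r` (>= 0).
#' @export
cerebellum_bursts <- function(state, c_left, c_right, params) {
  cc_l <- cerebellum_command(c_left, params)
  cc_r <- cerebellum_command(c_right, params)
  list(
    early_l = max(params$F3 * cc_l - params$F4 * state$e2_l, 0),
    early_r = max(params$F3 * cc_r - params$F4 * state$e2_r, 0),
    late_l = max(params$F1 * state$e2_l - params$F2 * cc_l, 0),
    late_r = max(params$F1 * state$e2_r - params$F2 * cc_r, 0)
  )
}

#' Advance the cerebellar circuit by one time step
#'
#' Integrates the two second-order efference-copy systems (inputs held
#' constant over the step) with the same fixed-step third-order Runge-Kutta
#' scheme as the rest of the model, then recomputes the bursts.
#'
#' @param state A [cerebellum_init()] state.
#' @param mlebn_l,mlebn_r Medium-lead excitatory burst rates per side
#'   (spikes/s, >= 0).
#' @param c_l,c_r Collicular burst drives per side (mm).
#' @param dt Time step in seconds.
#' @param params A [default_parameters()] object.
#' @param scheme `"rk3"` (default) or `"euler"`.
#' @return The updated state, with the current bursts attached as
#'   `$bursts`.
#' @export
cerebellum_step <- function(state, mlebn_l, mlebn_r, c_l, c_r, dt, params,
                            scheme = c("rk3", "euler")) {
  scheme <- match.arg(scheme)
  if (mlebn_l < 0 || mlebn_r < 0) {
    stop("burst rates must be non-negative", call. = FALSE)
  }
  st <- c(state$e1_l, state$e1_r, state$e2_l, state$e2_r)
  f <- function(s) cerebellum_derivative(s, mlebn_l, mlebn_r, params)
  if (scheme == "euler") {
    st_new <- st + dt * f(st)
  } else {
    k1 <- f(st)
    k2 <- f(st + dt / 2 * k1)
    k3 <- f(st + 3 * dt / 4 * k2)
    st_new <- st + dt * (2 * k1 + 3 * k2 + 4 * k3) / 9
  }
  state$e1_l <- st_new[1L]
  state$e1_r <- st_new[2L]
  state$e2_l <- st_new[3L]
  state$e2_r <- st_new[4L]
  state$bursts <- cerebellum_bursts(state, c_l, c_r, params)
  state
}

#' Choke inhibition onto the brainstem burst neurons
#'
#' The late burst "chokes" the medium-lead burst neurons driving the
#' ongoing movement, ending the saccade regardless of any remaining
#' collicular drive. By default the late burst associated with movement
#' side s inhibits side s's burst neurons; `choke_crossed = TRUE` swaps the
#' sides (strict anatomical crossing) for sensitivity analyses.
#'
#' @param state A [cerebellum_step()] state with `$bursts` attached.
#' @param params A [default_parameters()] object.
#' @return List with `choke_left`, `choke_right` (>= 0).
#' @export
choke_signal <- function(state, params) {
  b <- state$bursts
  if (is.null(b)) stop("state carries no bursts; call cerebellum_step first",
                       call. = FALSE)
  if (params$choke_crossed) {
    list(choke_left = params$choke_gain * b$late_r,
         choke_right = params$choke_gain * b$late_l)
  } else {
    list(choke_left = params$choke_gain * b$late_l,
         choke_right = params$choke_gain * b$late_r)
  }
}

#' Rostral reset drive to the collicular map
#'
#' Scaled sum of the two late bursts; routed to the map as excitation of
#' the rostral pole and inhibition of the caudal zones, terminating the
#' saccade-related burst and restarting rostral fixation activity at the
#' end of the movement.
#'
#' @param state A [cerebellum_step()] state with `$bursts` attached.
#' @param params A [default_parameters()] object.
#' @return Non-negative scalar drive.
#' @export
rostral_reset_drive <- function(state, params) {
  b <- state$bursts
  if (is.null(b)) stop("state carries no bursts; call cerebellum_step first",
                       call. = FALSE)
  params$rostral_gain * (b$late_l + b$late_r)
}
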