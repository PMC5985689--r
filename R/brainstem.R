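#' Burst-neuron rate function
#'
#' Exponential saturating output nonlinearity shared by every brainstem
#' neuron, B(x) = B_m (1 - exp(-(x - e0) / b)), rectified at zero so rates
#' are never negative (the raw formula is negative for x < e0).
#'
#' @param x Integrator state(s).
#' @param params A [default_parameters()] object.
#' @return Firing rate(s) in spikes/s, bounded in \[0, B_m\].
#' @export
bn_rate <- function(x, params) {
  pmax(0, params$B_m * (1 - exp(-(x - params$e0) / params$b)))
}

# State ordering used throughout the brainstem module.
BS_NAMES <- c("opn", "llibn_l", "llibn_r", "mlebn_l", "mlebn_r",
              "mlibn_l", "mlibn_r")

#' Initialize the brainstem state
#'
#' One omnipause neuron and three burst neurons per side (long-lead
#' inhibitory, medium-lead excitatory, medium-lead inhibitory), each a leaky
#' integrator (time constant `tau_BN`) with the [bn_rate()] output function.
#'
#' @param params A [default_parameters()] object (unused, kept for symmetry).
#' @return A named numeric vector of integrator states, all zero, of class
#'   `brainstem_state` with names `opn`, `llibn_l/r`, `mlebn_l/r`,
#'   `mlibn_l/r`.
#' @export
brainstem_init <- function(params = NULL) {
  structure(stats::setNames(rep(0, 7), BS_NAMES), class = "brainstem_state")
}

#' Firing rates of a brainstem state
#'
#' @param x A [brainstem_init()] state (named vector of integrator states).
#' @param params A [default_parameters()] object.
#' @return Named vector of rates in spikes/s.
#' @export
brainstem_rates <- function(x, params) {
  r <- bn_rate(unclass(x), params)
  names(r) <- BS_NAMES
  r
}

# Net synaptic input to each brainstem neuron given the current rates.
# Wiring: the OPN inhibits all six BNs (weakly the LLIBNs, strongly the
# medium-lead neurons); the inhibitory BNs of each side (LLIBN + MLIBN)
# inhibit the OPN (LLIBN only, unless mlibn_opn_weight > 0) and the three
# contralateral BNs; the cerebellar choke subtracts from the medium-lead
# neurons of its side.
brainstem_inputs <- function(x, drive_bn_left, drive_bn_right, drive_opn,
                             choke_left, choke_right, params) {
  r <- bn_rate(x, params)
  cross_to_l <- params$W_IBN_BN * (r[3L] + r[7L])  # right IBNs -> left BNs
  cross_to_r <- params$W_IBN_BN * (r[2L] + r[6L])  # left IBNs -> right BNs
  opn_in <- params$opn_bias + params$k_opn * drive_opn -
    params$w_LLIBN_OPN * (r[2L] + r[3L]) -
    params$mlibn_opn_weight * (r[6L] + r[7L])
  in_l <- params$k_bn * drive_bn_left
  in_r <- params$k_bn * drive_bn_right
  c(
    opn_in,
    in_l - params$w_OPN_LLIBN * r[1L] - cross_to_l,
    in_r - params$w_OPN_LLIBN * r[1L] - cross_to_r,
    in_l - params$w_OPN_BN * r[1L] - cross_to_l - choke_left,
    in_r - params$w_OPN_BN * r[1L] - cross_to_r - choke_right,
    in_l - params$w_OPN_BN * r[1L] - cross_to_l - choke_left,
    in_r - params$w_OPN_BN * r[1L] - cross_to_r - choke_right
  )
}

brainstem_derivative <- function(x, drive_bn_left, drive_bn_right, drive_opn,
                                 choke_left, choke_right, params) {
  (-x + brainstem_inputs(x, drive_bn_left, drive_bn_right, drive_opn,
                         choke_left, choke_right, params)) / params$tau_BN
}

#' Advance the brainstem network by one time step
#'
#' Integrates the seven leaky integrators with a fixed-step third-order
#' Runge-Kutta scheme, the descending drives and choke held constant across
#' the step. Rates are recomputed from the states at every stage, so the
#' mutual-inhibition dynamics (the saccadic trigger) are resolved within the
#' step.
#'
#' @param state A [brainstem_init()] state.
#' @param drive_bn_left,drive_bn_right Collicular burst drives (>= 0, mm).
#' @param drive_opn Collicular omnipause drive (>= 0).
#' @param choke_left,choke_right Cerebellar choke inhibition (>= 0).
#' @param dt Time step in seconds.
#' @param params A [default_parameters()] object.
#' @param scheme `"rk3"` (default) or `"euler"`.
#' @return The updated `brainstem_state`.
#' @export
brainstem_step <- function(state, drive_bn_left, drive_bn_right, drive_opn,
                           choke_left = 0, choke_right = 0, dt,
                           params, scheme = c("rk3", "euler")) {
  scheme <- match.arg(scheme)
  if (any(c(drive_bn_left, drive_bn_right, drive_opn) < 0)) {
    stop("collicular drives must be non-negative", call. = FALSE)
  }
  x <- unclass(state)
  f <- function(x) brainstem_derivative(x, drive_bn_left, drive_bn_right,
                                        drive_opn, choke_left, choke_right,
                                        params)
  if (scheme == "euler") {
    x_new <- x + dt * f(x)
  } else {
    k1 <- f(x)
    k2 <- f(x + dt / 2 * k1)
    k3 <- f(x + 3 * dt / 4 * k2)
    x_new <- x + dt * (2 * k1 + 3 * k2 + 4 * k3) / 9
  }
  if (any(!is.finite(x_new))) {
    stop("non-finite brainstem state after step", call. = FALSE)
  }
  structure(stats::setNames(x_new, BS_NAMES), class = "brainstem_state")
}

#' Quasi-static hysteresis thresholds of the saccadic trigger
#'
#' Slowly ramps the one-sided collicular burst drive up and back down while
#' holding the omnipause drive at a fixation-like level, and records where
#' the system switches into the saccade state (medium-lead excitatory burst
#' rate exceeding `rate_eps`) and back out of it. The mutual inhibition
#' between the omnipause neuron and the inhibitory burst neurons makes the
#' two thresholds differ (Schmitt-trigger hysteresis); zeroing
#' `w_LLIBN_OPN` removes the positive feedback and collapses them.
#'
#' @param params A [default_parameters()] object.
#' @param drive_opn Omnipause drive held during the ramp (defaults to a
#'   fixation-like value scaled from the default parameters).
#' @param drive_max Peak of the ramped burst drive (mm).
#' @param ramp_duration One-way ramp duration in seconds; must be slow
#'   relative to `tau_BN` for a quasi-static estimate.
#' @param rate_eps Rate (spikes/s) defining "bursting".
#' @return List with `up` and `down` thresholds in drive units (mm).
#'   Error if no switch occurs within the ramp range.
#' @export
trigger_hysteresis_curve <- function(params, drive_opn = 650,
                                     drive_max = 1, ramp_duration = 0.5,
                                     rate_eps = 5) {
  n <- max(10L, round(ramp_duration / params$dt))
  ramp <- c(seq(0, drive_max, length.out = n),
            seq(drive_max, 0, length.out = n))
  x <- brainstem_init(params)
  up <- NA_real_
  down <- NA_real_
  for (i in seq_along(ramp)) {
    x <- brainstem_step(x, 0, ramp[i], drive_opn, 0, 0, params$dt, params)
    r_mlebn <- bn_rate(x[["mlebn_r"]], params)
    if (i <= n && is.na(up) && r_mlebn > rate_eps) up <- ramp[i]
    if (i > n && !is.na(up) && is.na(down) && r_mlebn < rate_eps) {
      down <- ramp[i]
    }
  }
  if (is.na(up) || is.na(down)) {
    stop("trigger did not switch within the ramp range [0, ", drive_max,
         "]; increase drive_max or check parameters", call. = FALSE)
  }
  list(up = up, down = down)
}
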