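#' Lateral connection weight between two map neurons
#'
#' Mexican-hat connectivity: short-range excitation, long-range inhibition,
#' w_ij = (A_w + C) exp(-dist(i,j)^2 / (2 sigma_SC^2)) - C, with dist the
#' absolute distance in mm between the neurons. The self-weight (dist 0)
#' equals A_w; the far-field limit is -C.
#'
#' @param i,j Neuron indices (1-based).
#' @param geometry A [sc_geometry()] object.
#' @param params A [default_parameters()] object.
#' @return The scalar connection weight.
#' @export
lateral_weight <- function(i, j, geometry, params) {
  d <- abs(geometry$positions[i] - geometry$positions[j])
  (params$A_w + params$C) * exp(-d^2 / (2 * params$sigma_SC^2)) - params$C
}

#' Full lateral weight matrix
#'
#' @param geometry A [sc_geometry()] object.
#' @param params A [default_parameters()] object.
#' @return A symmetric `n_neurons` x `n_neurons` matrix with diagonal `A_w`
#'   and minimum bounded below by `-C`.
#' @export
lateral_weights <- function(geometry, params) {
  d <- outer(geometry$positions, geometry$positions, function(a, b) abs(a - b))
  (params$A_w + params$C) * exp(-d^2 / (2 * params$sigma_SC^2)) - params$C
}

#' Collicular activation function
#'
#' Logistic transform of the integrator state, a(u) = F / (1 + exp(-beta_u u)).
#' Strictly increasing with range (0, F).
#'
#' @param u Integrator state(s).
#' @param params A [default_parameters()] object.
#' @return Activation(s) in spikes/s.
#' @export
sc_activation <- function(u, params) {
  params$F / (1 + exp(-params$beta_u * u))
}

#' Burst layer
#'
#' Thresholded copy of the buildup activation: a neuron's burst output
#' equals its buildup activation when that activation is at or above
#' `burst_threshold` (inclusive boundary) and is zero otherwise. The same
#' threshold applies across the whole map. This is the output nonlinearity
#' that keeps slow buildup activity from reaching the brainstem trigger.
#'
#' @param a Buildup activation vector (spikes/s).
#' @param params A [default_parameters()] object.
#' @return Burst output vector (spikes/s).
#' @export
burst_layer <- function(a, params) {
  ifelse(a >= params$burst_threshold, a, 0)
}

#' Initialize the collicular map state
#'
#' @param params A [default_parameters()] object.
#' @param geometry Optional [sc_geometry()]; built from `params` if missing.
#' @return A list of class `sc_state` with integrator states `u`, buildup
#'   activations `a`, burst outputs `burst`, the lateral weight matrix `W`
#'   (unscaled), and the geometry.
#' @export
sc_init <- function(params, geometry = sc_geometry(params)) {
  u <- rep(0, params$n_neurons)
  a <- sc_activation(u, params)
  st <- list(
    u = u,
    a = a,
    burst = burst_layer(a, params),
    W = lateral_weights(geometry, params),
    geometry = geometry
  )
  class(st) <- "sc_state"
  st
}

# Time derivative of the SC integrator states. `input_ext` is the summed
# external per-neuron input (cortical + noise + rostral reset). The lateral
# term uses Riemann-sum scaling (weights x neuron spacing) so the recurrent
# input approximates the continuous-field integral and is grid-invariant.
sc_derivative <- function(u, input_ext, W, spacing, params) {
  a <- sc_activation(u, params)
  (-u + spacing * drop(W %*% a) + input_ext) / params$tau_SC
}

#' Advance the collicular map by one time step
#'
#' Integrates the leaky-integrator field equation
#' tau_SC du/dt = -u + sum_j w_ij a_j + input with a fixed-step third-order
#' Runge-Kutta scheme (external inputs held constant across the step), then
#' recomputes the activation and burst layers.
#'
#' @param state An [sc_init()] state.
#' @param cortical_input Per-neuron cortical drive (FEF + BG), length
#'   `n_neurons`.
#' @param noise Per-neuron noise input.
#' @param cblm_rostral_drive Scalar rostral-reset drive from the cerebellum;
#'   applied as excitation within `rostral_width` mm of the pole and
#'   equal-magnitude inhibition beyond it.
#' @param dt Time step in seconds.
#' @param params A [default_parameters()] object.
#' @param scheme `"rk3"` (default) or `"euler"`.
#' @return The updated `sc_state`.
#' @export
sc_step <- function(state, cortical_input, noise, cblm_rostral_drive, dt,
                    params, scheme = c("rk3", "euler")) {
  scheme <- match.arg(scheme)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  input_ext <- cortical_input + noise +
    rostral_input_profile(cblm_rostral_drive, state$geometry, params)
  spacing <- state$geometry$spacing
  u <- state$u
  if (scheme == "euler") {
    u_new <- u + dt * sc_derivative(u, input_ext, state$W, spacing, params)
  } else {
    k1 <- sc_derivative(u, input_ext, state$W, spacing, params)
    k2 <- sc_derivative(u + dt / 2 * k1, input_ext, state$W, spacing, params)
    k3 <- sc_derivative(u + 3 * dt / 4 * k2, input_ext, state$W, spacing,
                        params)
    u_new <- u + dt * (2 * k1 + 3 * k2 + 4 * k3) / 9
  }
  if (any(!is.finite(u_new))) {
    stop("non-finite collicular state after step", call. = FALSE)
  }
  state$u <- u_new
  state$a <- sc_activation(u_new, params)
  state$burst <- burst_layer(state$a, params)
  state
}

# Spatial profile of the cerebellar rostral-reset drive: excitation within
# rostral_width mm of the pole, equal-magnitude inhibition elsewhere.
rostral_input_profile <- function(drive, geometry, params) {
  if (drive == 0) return(rep(0, length(geometry$positions)))
  ifelse(abs(geometry$positions) <= params$rostral_width, drive, -drive)
}

#' Projection weight vectors from the map to the brainstem
#'
#' The omnipause projection weight declines linearly from 1 at the rostral
#' pole to 0 at the caudal ends, w_OPN(i) = 1 - |dist(i, 0)| / S; the
#' burst-neuron projection weight grows linearly with distance from the
#' pole, w_BN(i) = dist(i, 0).
#'
#' @param geometry A [sc_geometry()] object.
#' @param params A [default_parameters()] object.
#' @return List with `opn` and `bn` weight vectors.
#' @export
sc_projection_weights <- function(geometry, params) {
  list(
    opn = 1 - abs(geometry$positions) / params$S,
    bn = abs(geometry$positions)
  )
}

#' Collicular output drives to the brainstem
#'
#' Computes the three descending drives: the omnipause drive (rostrally
#' weighted sum of the buildup layer) and the left/right burst-neuron drives
#' (distance-weighted sums of the burst layer on each side, normalized by
#' the total burst activity plus a small fraction of the buildup activity so
#' the drive encodes the location rather than the amount of activity).
#'
#' @param state An [sc_init()] state (fields `a`, `burst`, `geometry` used).
#' @param params A [default_parameters()] object.
#' @param inactivation Optional [inactivation_region()]; output of neurons in
#'   the region is nulled before the drives are computed (the map dynamics
#'   themselves are untouched).
#' @return List of class `sc_outputs` with non-negative scalars `drive_opn`,
#'   `drive_bn_left`, `drive_bn_right`.
#' @export
sc_outputs <- function(state, params, inactivation = NULL) {
  g <- state$geometry
  a <- state$a
  burst <- state$burst
  if (!is.null(inactivation)) {
    mask <- inactivation_mask(inactivation, g)
    a[mask] <- 0
    burst[mask] <- 0
  }
  pos <- g$positions
  w_opn <- 1 - abs(pos) / params$S
  denom <- sum(burst) + params$buildup_fraction * sum(a)
  out <- list(
    drive_opn = g$spacing * sum(w_opn * a),
    drive_bn_left = if (denom > 0) {
      sum(-pos[pos < 0] * burst[pos < 0]) / denom
    } else 0,
    drive_bn_right = if (denom > 0) {
      sum(pos[pos > 0] * burst[pos > 0]) / denom
    } else 0
  )
  class(out) <- "sc_outputs"
  out
}

#' Define a rostral inactivation region
#'
#' Describes a one-sided interval of the map whose *output* is silenced,
#' emulating focal inactivation close to the midline: on the right side the
#' region is (inner, outer] mm, mirrored for the left side. The midline
#' neuron itself (0 mm) is never included when `inner = 0`.
#'
#' @param side `"left"` or `"right"`.
#' @param outer Outer edge of the region in mm (default 1).
#' @param inner Inner edge in mm (default 0, i.e. from the pole outwards).
#' @return A list of class `sc_inactivation`.
#' @export
inactivation_region <- function(side = c("right", "left"), outer = 1,
                                inner = 0) {
  side <- match.arg(side)
  if (outer < inner) stop("outer edge must be >= inner edge", call. = FALSE)
  structure(list(side = side, inner = inner, outer = outer),
            class = "sc_inactivation")
}

inactivation_mask <- function(region, geometry) {
  p <- geometry$positions
  if (region$side == "right") {
    p > region$inner & p <= region$outer
  } else {
    p < -region$inner & p >= -region$outer
  }
}

#' Null the output of an inactivated region
#'
#' Applies an [inactivation_region()] to a map state, zeroing the buildup
#' and burst *outputs* of the affected neurons while leaving the integrator
#' states untouched. An empty region is a no-op.
#'
#' @param state An [sc_init()] state.
#' @param region An [inactivation_region()], or `NULL` for no-op.
#' @return The state with masked `a` and `burst`.
#' @export
apply_inactivation <- function(state, region) {
  if (is.null(region)) return(state)
  mask <- inactivation_mask(region, state$geometry)
  state$a[mask] <- 0
  state$burst[mask] <- 0
  state
}
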