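#' Initialize the spatiotemporally correlated noise field
#'
#' One independent white-noise source per map neuron is mixed spatially with
#' Gaussian distance-dependent weights (SD `sigma_noise`) and then filtered
#' temporally through per-neuron leaky integrators of time constant
#' `tau_noise`. Each mixing row is normalized so every neuron has identical
#' stationary marginal variance; the temporal update uses the exact
#' Ornstein-Uhlenbeck discretization, so the stationary SD equals
#' `noise_gain` independently of the step size.
#'
#' Random draws use R's global RNG stream; seed it (e.g. via the `seed`
#' argument of [run_simulation()]) for reproducibility.
#'
#' @param geometry A [sc_geometry()] object.
#' @param params A [default_parameters()] object.
#' @return A list of class `noise_state` with the filtered states `z`
#'   (unit stationary variance) and mixing matrix `M`.
#' @export
noise_init <- function(geometry, params) {
  d <- outer(geometry$positions, geometry$positions,
             function(a, b) abs(a - b))
  M <- exp(-d^2 / (2 * params$sigma_noise^2))
  M <- M / sqrt(rowSums(M^2))   # unit marginal variance for every neuron
  structure(list(z = rep(0, length(geometry$positions)), M = M),
            class = "noise_state")
}

#' Advance the noise field by one step
#'
#' Draws one white sample per neuron, mixes spatially, and applies the exact
#' one-step Ornstein-Uhlenbeck update
#' z <- phi z + sqrt(1 - phi^2) eta, phi = exp(-dt / tau_noise).
#'
#' @param state A [noise_init()] state.
#' @param dt Time step in seconds.
#' @param params A [default_parameters()] object.
#' @return List with the updated `state` and the per-neuron `noise` vector
#'   (`noise_gain` times the unit-variance filtered field).
#' @export
noise_step <- function(state, dt, params) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  xi <- stats::rnorm(length(state$z))
  eta <- drop(state$M %*% xi)
  phi <- exp(-dt / params$tau_noise)
  state$z <- phi * state$z + sqrt(1 - phi^2) * eta
  list(state = state, noise = params$noise_gain * state$z)
}

#' Reset the noise field
#'
#' Zeroes the filtered states without touching the RNG stream, so that two
#' runs with the same seed and the same reset times produce identical
#' realizations. Called by the engine when the omnipause neuron resumes firing at the end
#' of each saccade, so persistent noise at one location cannot trigger
#' staircases of saccades. Idempotent.
#'
#' @param state A [noise_init()] state.
#' @return The reset state.
#' @export
reset_noise <- function(state) {
  state$z[] <- 0
  state
}

#' Theoretical spatial correlation implied by the mixing matrix
#'
#' Correlation of the stationary field between neuron pairs, M M' for the
#' row-normalized mixing matrix. Useful as the reference when checking the
#' empirical correlation structure of a long noise run.
#'
#' @param state A [noise_init()] state.
#' @return The `n_neurons` x `n_neurons` correlation matrix (unit diagonal).
#' @export
noise_spatial_correlation <- function(state) {
  tcrossprod(state$M)
}
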