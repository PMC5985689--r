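#' Collicular map geometry
#'
#' Builds the coordinate frame of the one-dimensional collicular map: the
#' left and right colliculi are represented as a single structure of
#' `n_neurons` equally spaced neurons spanning \[-S, +S\] mm, with the
#' rostral pole (0 degree eccentricity) at the middle neuron. Rightward
#' eccentricities map to positive mm, leftward to negative.
#'
#' @param params A [default_parameters()] object.
#' @return A list of class `sc_geometry` with `positions` (mm, strictly
#'   increasing), `eccentricities` (deg, strictly increasing), `spacing`
#'   (mm between neighbours) and `midline` (index of the 0-mm neuron).
#' @examples
#' g <- sc_geometry(default_parameters())
#' g$positions[g$midline]      # 0 mm
#' g$spacing                   # 0.1 mm at defaults
#' @export
sc_geometry <- function(params) {
  n <- params$n_neurons
  positions <- seq(-params$S, params$S, length.out = n)
  midline <- (n + 1L) / 2L
  positions[midline] <- 0   # guard against floating fuzz at the pole
  g <- list(
    positions = positions,
    eccentricities = collicular_to_retinotopic(positions, params),
    spacing = 2 * params$S / (n - 1),
    midline = midline
  )
  class(g) <- "sc_geometry"
  g
}

#' Retinotopic to collicular coordinate mapping
#'
#' Logarithmic magnification of retinal eccentricity onto the collicular
#' surface, d(D) = B log((D + A) / A), extended to signed eccentricities by
#' odd symmetry: sign(D) B log((|D| + A) / A). Natural logarithm.
#'
#' @param D Signed eccentricity in degrees (vectorized).
#' @param params A [default_parameters()] object (uses `A`, `B`).
#' @return Signed collicular position(s) in mm.
#' @seealso [collicular_to_retinotopic()] for the exact inverse.
#' @examples
#' retinotopic_to_collicular(3, default_parameters())   # 1.4 * log(2)
#' @export
retinotopic_to_collicular <- function(D, params) {
  if (any(!is.finite(D))) stop("eccentricity must be finite", call. = FALSE)
  sign(D) * params$B * log((abs(D) + params$A) / params$A)
}

#' Collicular to retinotopic coordinate mapping
#'
#' Exact inverse of [retinotopic_to_collicular()]:
#' D(d) = sign(d) A (exp(|d| / B) - 1). Positions beyond the map edge
#' (|d| > S) are a domain error.
#'
#' @param d Signed collicular position(s) in mm.
#' @param params A [default_parameters()] object (uses `A`, `B`, `S`).
#' @return Signed eccentricity(ies) in degrees.
#' @export
collicular_to_retinotopic <- function(d, params) {
  if (any(abs(d) > params$S + 1e-9)) {
    stop("collicular position outside the map (|d| > S = ", params$S,
         " mm)", call. = FALSE)
  }
  sign(d) * params$A * (exp(abs(d) / params$B) - 1)
}
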