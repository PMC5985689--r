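#' Eccentricity dependence of the FEF drive
#'
#' The strength of the frontal-eye-field command grows with the retinal
#' eccentricity of the target, G(e) = g0 + g1 (1 - exp(-|e| / e_half)),
#' saturating at g0 + g1. G(0) = g0 > 0: fixation is still actively driven,
#' but small retinal errors produce a weaker command, so tiny errors do not
#' deterministically trigger corrective saccades.
#'
#' @param eccentricity Target eccentricity in degrees (vectorized; absolute
#'   value is used).
#' @param params A [default_parameters()] object.
#' @return Drive amplitude(s) in collicular input units.
#' @export
fef_eccentricity_gain <- function(eccentricity, params) {
  params$fef_g0 +
    params$fef_g1 * (1 - exp(-abs(eccentricity) / params$fef_e_half))
}

#' Cortical input profiles to the collicular map
#'
#' Builds the two complementary cortical drives from the (delayed) retinal
#' target error: an excitatory FEF Gaussian of width `sigma_FEF` centred at
#' the collicular location of the error, scaled by
#' [fef_eccentricity_gain()], and an inhibitory basal-ganglia profile that
#' suppresses the whole map except a Gaussian window of width `sigma_BG`
#' around the same location, bg = -K_bg (1 - exp(-(p - d_t)^2 / 2 sigma_BG^2)).
#'
#' @param target_error Retinal error in degrees (desired gaze location minus
#'   delayed eye position).
#' @param geometry A [sc_geometry()] object.
#' @param params A [default_parameters()] object.
#' @return A list of class `cortical_drive` with per-neuron vectors `fef`
#'   (>= 0) and `bg` (<= 0), and the scalar `target_error`.
#' @export
cortical_drive <- function(target_error, geometry, params) {
  d_t <- retinotopic_to_collicular(target_error, params)
  p <- geometry$positions
  fef <- fef_eccentricity_gain(target_error, params) *
    exp(-(p - d_t)^2 / (2 * params$sigma_FEF^2))
  bg <- -params$K_bg * (1 - exp(-(p - d_t)^2 / (2 * params$sigma_BG^2)))
  structure(list(fef = fef, bg = bg, target_error = target_error),
            class = "cortical_drive")
}
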