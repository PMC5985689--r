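#' Default model parameters
#'
#' Returns the full parameter set of the saccade-triggering model. The neural
#' constants (time constants, synaptic weights, map geometry, noise
#' correlation scales, cerebellar gains) take the published values of the
#' model; the remaining entries are engine, plant, input-gain and analysis
#' constants that the published description leaves open. Those were
#' calibrated once so that, at defaults, a 2 degree target step yields a
#' single accurate saccade and fixation yields 1-2 microsaccades per second
#' of median magnitude below 1 degree (see the methods vignette).
#'
#' Units: time constants in seconds, map coordinates in mm, eccentricities in
#' degrees, firing rates in spikes/s, synaptic weights dimensionless.
#'
#' @return An object of class `saccsim_params`: a named list with components
#' \describe{
#'   \item{tau_BN, b, B_m, e0}{brainstem leaky-integrator time constant,
#'     rate-function curvature, maximum burst rate, rate-function offset.}
#'   \item{F, A, B, A_w, C, sigma_SC, tau_SC, S, beta_u}{collicular map:
#'     maximum activation, retinal magnification offset (deg), map scale
#'     (mm), maximum lateral excitation, maximum lateral inhibition, lateral
#'     excitation width (mm), integrator time constant, half-map length
#'     (mm), activation slope.}
#'   \item{sigma_FEF, sigma_BG}{widths (mm) of the frontal-eye-field drive
#'     and basal-ganglia disinhibition profiles.}
#'   \item{tau_noise, sigma_noise, noise_gain}{temporal correlation constant,
#'     spatial correlation width, and stationary amplitude of the collicular
#'     noise field.}
#'   \item{w_OPN_LLIBN, w_OPN_BN, w_LLIBN_OPN, W_IBN_BN, opn_bias,
#'     mlibn_opn_weight}{brainstem synaptic weights (`w_X_Y` = projection
#'     from X to Y) and tonic omnipause drive. `mlibn_opn_weight` enables an
#'     optional MLIBN-to-OPN projection (0 = absent).}
#'   \item{T_cblm1, T_cblm2, T_cblm_leak, F1, F2, F3, F4, k_c, choke_gain,
#'     rostral_gain, rostral_width, choke_crossed}{cerebellar stop circuit:
#'     efference-copy lag and integration constants, integrator leak, burst
#'     gains, collicular-command gain, choke and rostral-reset gains, rostral
#'     region half-width (mm), and the laterality switch for the choke.}
#'   \item{k_opn, k_bn}{gains scaling the collicular output drives into
#'     omnipause and burst-neuron input units.}
#'   \item{fef_g0, fef_g1, fef_e_half}{eccentricity dependence of the FEF
#'     drive, G(e) = g0 + g1 (1 - exp(-e / e_half)).}
#'   \item{K_bg}{depth of the basal-ganglia surround inhibition.}
#'   \item{velocity_gain, tau_plant, tau_slide, pulse_gain, slide_gain}{final
#'     common pathway: burst-rate-to-velocity gain (deg/s per spikes/s), eye
#'     plant lag, slide lag, pulse and slide mixing gains.}
#'   \item{dt, visual_delay, n_neurons}{integration step (s), visual feedback
#'     delay (s), number of map neurons (odd, one neuron at 0 mm).}
#'   \item{burst_threshold, buildup_fraction}{burst-layer threshold
#'     (spikes/s) and the fraction of buildup activity included in the
#'     drive-normalization denominator.}
#'   \item{v_thresh, min_dur, merge_interval}{saccade detector: velocity
#'     threshold (deg/s), minimum event duration (s), merge interval (s).}
#'   \item{k_pd, k_psp, psp_B_m, sca_choke_factor, inactivation_width,
#'     inactivation_side}{disease/lesion preset constants: noise scaling for
#'     the parkinsonian and supranuclear-palsy conditions, reduced burst gain
#'     for the latter, choke attenuation for the ataxia condition, and the
#'     default rostral inactivation region.}
#' }
#' @examples
#' p <- default_parameters()
#' p$B_m
#' p$n_neurons
#' @export
default_parameters <- function() {
  p <- list(
    # brainstem
    tau_BN = 0.001,
    b = 8,
    B_m = 800,
    e0 = 0,
    # superior colliculus map
    F = 500,
    A = 3,
    B = 1.4,
    A_w = 1,
    C = 1,
    sigma_SC = 0.5,
    tau_SC = 0.005,
    S = 5,
    beta_u = 0.1,
    # cortical inputs
    sigma_FEF = 0.5,
    sigma_BG = 1,
    # noise field
    tau_noise = 0.02,
    sigma_noise = 0.2,
    noise_gain = 115,
    # brainstem weights
    w_OPN_LLIBN = 0.0015,
    w_OPN_BN = 0.2,
    w_LLIBN_OPN = 10,
    W_IBN_BN = 0.1,
    opn_bias = 50,
    mlibn_opn_weight = 0,
    # cerebellum
    T_cblm1 = 0.02,
    T_cblm2 = 0.02,
    T_cblm_leak = 0.04,
    F1 = 0.1,
    F2 = 0.03,
    F3 = 1,
    F4 = 0.13,
    k_c = 108,
    k_c_power = 1.5,
    choke_gain = 25,
    rostral_gain = 15,
    rostral_width = 1,
    choke_crossed = FALSE,
    # collicular output gains into the brainstem
    k_opn = 2.91,
    k_bn = 12,
    # FEF / BG input scales
    fef_g0 = 100,
    fef_g1 = 300,
    fef_e_half = 1,
    K_bg = 3000,
    # final common pathway / plant
    velocity_gain = 0.3,
    tau_plant = 0.15,
    tau_slide = 0.05,
    pulse_gain = 0.15,
    slide_gain = 0,
    # engine
    dt = 0.001,
    visual_delay = 0.05,
    n_neurons = 101L,
    burst_threshold = 300,
    buildup_fraction = 0.05,
    # saccade detection
    v_thresh = 5,
    min_dur = 0.003,
    merge_interval = 0.01,
    # condition presets
    k_pd = 2,
    k_psp = 3,
    psp_B_m = 400,
    sca_choke_factor = 0.3,
    inactivation_width = 1,
    inactivation_side = "right"
  )
  class(p) <- "saccsim_params"
  validate_parameters(p)
  p
}

#' Validate a parameter set
#'
#' Checks the structural invariants of a [default_parameters()] object:
#' strictly positive time constants, widths and rate ceilings, an odd neuron
#' count (so one neuron sits exactly at the 0-mm rostral pole), and sane
#' engine constants. Called by [default_parameters()] and [load_config()].
#'
#' @param params A `saccsim_params` list.
#' @return `params`, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_parameters <- function(params) {
  need_positive <- c(
    "tau_BN", "b", "B_m", "F", "A", "B", "sigma_SC", "tau_SC", "S",
    "beta_u", "sigma_FEF", "sigma_BG", "tau_noise", "sigma_noise",
    "T_cblm1", "T_cblm2", "T_cblm_leak", "dt", "visual_delay",
    "tau_plant", "tau_slide", "velocity_gain", "burst_threshold",
    "v_thresh", "min_dur"
  )
  need_nonneg <- c(
    "e0", "A_w", "C", "noise_gain", "w_OPN_LLIBN", "w_OPN_BN",
    "w_LLIBN_OPN", "W_IBN_BN", "opn_bias", "mlibn_opn_weight",
    "F1", "F2", "F3", "F4", "k_c", "choke_gain", "rostral_gain",
    "rostral_width", "k_opn", "k_bn", "k_c_power", "fef_g0", "fef_g1", "K_bg",
    "buildup_fraction", "merge_interval", "pulse_gain", "slide_gain",
    "k_pd", "k_psp", "psp_B_m", "sca_choke_factor", "inactivation_width"
  )
  missing <- setdiff(
    c(need_positive, need_nonneg, "fef_e_half", "n_neurons",
      "choke_crossed", "inactivation_side"),
    names(params)
  )
  if (length(missing) > 0) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (nm in c(need_positive, need_nonneg, "fef_e_half")) {
    v <- params[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop("parameter '", nm, "' must be a finite numeric scalar",
           call. = FALSE)
    }
  }
  for (nm in need_positive) {
    if (params[[nm]] <= 0) {
      stop("parameter '", nm, "' must be strictly positive (got ",
           params[[nm]], ")", call. = FALSE)
    }
  }
  for (nm in need_nonneg) {
    if (params[[nm]] < 0) {
      stop("parameter '", nm, "' must be non-negative (got ",
           params[[nm]], ")", call. = FALSE)
    }
  }
  if (params$fef_e_half <= 0) {
    stop("parameter 'fef_e_half' must be strictly positive", call. = FALSE)
  }
  n <- params$n_neurons
  if (!is.numeric(n) || length(n) != 1 || n != round(n) || n < 3) {
    stop("parameter 'n_neurons' must be an integer >= 3", call. = FALSE)
  }
  if (n %% 2 == 0) {
    stop("parameter 'n_neurons' must be odd so that one neuron sits at 0 mm",
         call. = FALSE)
  }
  if (!is.logical(params$choke_crossed) || length(params$choke_crossed) != 1) {
    stop("parameter 'choke_crossed' must be TRUE or FALSE", call. = FALSE)
  }
  if (!params$inactivation_side %in% c("left", "right")) {
    stop("parameter 'inactivation_side' must be \"left\" or \"right\"",
         call. = FALSE)
  }
  invisible(params)
}

#' Load a model configuration from a YAML file
#'
#' Reads a flat YAML mapping whose keys are parameter names (see
#' [default_parameters()]). Missing keys fall back to the defaults; unknown
#' keys are an error, so typos do not silently become no-ops. The merged set
#' is validated before it is returned.
#'
#' @param path Path to a YAML file. An empty file yields the defaults.
#' @return A validated `saccsim_params` object.
#' @seealso [save_config()]
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("B_m: 400", f)
#' load_config(f)$B_m
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) {
    stop("config file must be a YAML mapping of parameter: value pairs",
         call. = FALSE)
  }
  p <- default_parameters()
  unknown <- setdiff(names(cfg), names(p))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    if (nm == "n_neurons") v <- as.integer(v)
    p[[nm]] <- v
  }
  validate_parameters(p)
  p
}

#' Save a model configuration to a YAML file
#'
#' Writes every parameter (not just the non-default ones) so that a saved
#' file reloads to an identical parameter set regardless of future default
#' changes. `save_config(); load_config()` round-trips exactly.
#'
#' @param params A `saccsim_params` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(params, path) {
  validate_parameters(params)
  out <- unclass(params)
  writeLines(yaml::as.yaml(out, precision = 15), path)
  invisible(path)
}

#' Apply named overrides to a parameter set
#'
#' @param params A `saccsim_params` object.
#' @param overrides Named list of replacement values.
#' @return A validated `saccsim_params` object.
#' @examples
#' modify_parameters(default_parameters(), list(B_m = 400))$B_m
#' @export
modify_parameters <- function(params, overrides) {
  if (length(overrides) == 0) return(params)
  unknown <- setdiff(names(overrides), names(params))
  if (length(unknown) > 0) {
    stop("unknown parameter(s) in overrides: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (nm in names(overrides)) params[[nm]] <- overrides[[nm]]
  validate_parameters(params)
  params
}

#' @export
print.saccsim_params <- function(x, ...) {
  cat("<saccsim_params>", length(x), "parameters\n")
  cat("  map: ", x$n_neurons, " neurons on [-", x$S, ", ", x$S,
      "] mm, dt = ", x$dt * 1000, " ms, delay = ",
      x$visual_delay * 1000, " ms\n", sep = "")
  cat("  noise_gain =", x$noise_gain, " B_m =", x$B_m,
      " choke_gain =", x$choke_gain, "\n")
  invisible(x)
}
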