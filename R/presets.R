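#' Named experiment presets
#'
#' Encodes the standard simulation scenarios as pure parameter edits on top
#' of the defaults — each disease condition changes only one or two
#' parameters:
#' \describe{
#'   \item{`single_saccade_2deg`}{noise disabled, target steps from 0 to 2
#'     degrees rightward at t = 0.2 s; 1 s.}
#'   \item{`fixation_default`}{default parameters, constant target at 0;
#'     100 s.}
#'   \item{`sc_inactivation`}{fixation with the output of the rostral map
#'     nulled on one side close to the midline; 20 s.}
#'   \item{`pd`}{parkinsonian fixation: collicular noise raised by `k_pd`
#'     (one parameter).}
#'   \item{`psp`}{supranuclear-palsy fixation: noise raised by `k_psp` and
#'     burst-neuron gain `B_m` lowered to `psp_B_m` (two parameters).}
#'   \item{`sca`}{cerebellar-ataxia fixation: cerebellar choke gain reduced
#'     by `sca_choke_factor` (one parameter).}
#' }
#'
#' @param name One of the preset names above.
#' @param params Base parameters the overrides apply to (defaults to
#'   [default_parameters()]); the scaling constants `k_pd`, `k_psp`,
#'   `psp_B_m`, `sca_choke_factor` and the inactivation region are read
#'   from it.
#' @return A list of class `saccsim_preset` with `name`, `overrides`
#'   (named list of parameter deltas from default), `experiment` (an
#'   [experiment()]), and `duration` (s).
#' @export
preset <- function(name, params = default_parameters()) {
  known <- c("single_saccade_2deg", "fixation_default", "sc_inactivation",
             "pd", "psp", "sca")
  if (!name %in% known) {
    stop("unknown preset '", name, "'; available: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  overrides <- list()
  ex <- experiment(0, condition = name)
  duration <- 5
  switch(name,
    single_saccade_2deg = {
      overrides <- list(noise_gain = 0)
      ex <- experiment(function(t) ifelse(t < 0.2, 0, 2), condition = name)
      duration <- 1
    },
    fixation_default = {
      duration <- 100
    },
    sc_inactivation = {
      ex <- experiment(0, condition = name,
                       inactivation = inactivation_region(
                         side = params$inactivation_side,
                         outer = params$inactivation_width))
      duration <- 20
    },
    pd = {
      overrides <- list(noise_gain = params$noise_gain * params$k_pd)
    },
    psp = {
      overrides <- list(noise_gain = params$noise_gain * params$k_psp,
                        B_m = params$psp_B_m)
    },
    sca = {
      overrides <- list(
        choke_gain = params$choke_gain * params$sca_choke_factor)
    }
  )
  structure(list(name = name, overrides = overrides, experiment = ex,
                 duration = duration, base_params = params),
            class = "saccsim_preset")
}

#' Run a preset under one seed
#'
#' @param p A [preset()] object.
#' @param seed Integer seed.
#' @param duration Optional duration override in seconds.
#' @return A `saccsim_result`.
#' @export
run_preset <- function(p, seed = 1, duration = NULL) {
  stopifnot(inherits(p, "saccsim_preset"))
  params <- modify_parameters(p$base_params, p$overrides)
  run_simulation(params, p$experiment,
                 duration = if (is.null(duration)) p$duration else duration,
                 seed = seed)
}

#' Run a battery of presets over seeds
#'
#' Runs every requested preset under every seed, detects saccades, and
#' tabulates the fixation statistics, plus one median row per preset
#' (medians taken across seeds, NA-removed).
#'
#' @param presets Character vector of preset names, or a list of
#'   [preset()] objects.
#' @param seeds Integer vector of seeds (each preset is run once per seed).
#' @param duration Optional duration override (s) applied to every run.
#' @param params Base parameters (defaults to [default_parameters()]).
#' @return A data frame with one row per preset x seed and one
#'   `seed = NA` median row per preset; columns: `preset`, `seed`,
#'   `n_events`, `rate`, `median_magnitude`, `median_isi`,
#'   `main_sequence_slope`, `mean_eye_position`, `swj_count`,
#'   `oscillation_count`.
#' @export
run_preset_battery <- function(presets, seeds = 1:3, duration = NULL,
                               params = default_parameters()) {
  if (length(seeds) < 1) stop("need at least one seed", call. = FALSE)
  if (is.character(presets)) {
    presets <- lapply(presets, preset, params = params)
  }
  rows <- list()
  for (p in presets) {
    per_seed <- list()
    for (s in seeds) {
      res <- tryCatch(
        run_preset(p, seed = s, duration = duration),
        error = function(e) {
          stop("preset '", p$name, "', seed ", s, ": ",
               conditionMessage(e), call. = FALSE)
        })
      ev <- detect_saccades(res)
      st <- summarize_fixation(ev, res)
      per_seed[[as.character(s)]] <- data.frame(
        preset = p$name, seed = s, n_events = st$n_events, rate = st$rate,
        median_magnitude = st$magnitude_quantiles[["q50"]],
        median_isi = st$isi_quantiles[["q50"]],
        main_sequence_slope = st$main_sequence_slope,
        mean_eye_position = st$mean_eye_position,
        swj_count = st$swj_count,
        oscillation_count = st$oscillation_count
      )
    }
    tab <- do.call(rbind, per_seed)
    med <- tab[1, ]
    med$seed <- NA_integer_
    for (cl in names(tab)[-(1:2)]) {
      med[[cl]] <- stats::median(tab[[cl]], na.rm = TRUE)
    }
    rows[[p$name]] <- rbind(tab, med)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Noise x burst-gain sweep of fixation statistics
#'
#' Reproduces the two-parameter characterization of fixational saccadic
#' intrusions: for each burst-neuron gain level (`B_m`), fixation is
#' simulated at several noise amplitudes and the rate, median magnitude and
#' main-sequence slope tabulated. Raising noise raises the rate (and
#' somewhat the magnitude) without affecting peak velocity; lowering the
#' burst gain lowers the velocity and raises the magnitude.
#'
#' @param noise_factors Multiplies of the default `noise_gain`.
#' @param B_m_values Burst-gain levels to cross with the noise sweep.
#' @param seeds Seeds per cell (statistics are medians across seeds).
#' @param duration Duration per run in seconds.
#' @param params Base parameters.
#' @return Data frame with one row per (B_m, noise factor) cell.
#' @export
sweep_noise_bn_gain <- function(noise_factors = c(1, 1.5, 2, 3),
                                B_m_values = c(800, 400),
                                seeds = 1:3, duration = 20,
                                params = default_parameters()) {
  rows <- list()
  for (bm in B_m_values) {
    for (nf in noise_factors) {
      stats_seed <- lapply(seeds, function(s) {
        pp <- modify_parameters(params, list(
          B_m = bm, noise_gain = params$noise_gain * nf))
        res <- run_simulation(pp, experiment(0, "sweep"), duration, seed = s)
        ev <- detect_saccades(res)
        summarize_fixation(ev, res)
      })
      med <- function(f) stats::median(
        vapply(stats_seed, f, numeric(1)), na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        B_m = bm, noise_factor = nf,
        rate = med(function(x) x$rate),
        median_magnitude = med(function(x) x$magnitude_quantiles[["q50"]]),
        main_sequence_slope = med(function(x) x$main_sequence_slope)
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
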