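# Shared simulations, computed lazily and cached for the whole test run so
# several test files can interrogate the same traces.
.sim_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .sim_cache)) {
    assign(name, force(expr), envir = .sim_cache)
  }
  get(name, envir = .sim_cache)
}

# 20 s of default-parameter fixation (noise on), seed 1.
fixation_run <- function() {
  cached("fixation_run", run_simulation(
    default_parameters(), experiment(0, "fixation"), 20, seed = 1))
}

# 1 s noise-free run with a 2 degree rightward target step at t = 0.2 s.
step2_run <- function() {
  cached("step2_run", {
    p <- modify_parameters(default_parameters(), list(noise_gain = 0))
    run_simulation(p, experiment(function(t) ifelse(t < 0.2, 0, 2),
                                 "step_2deg"), 1, seed = 1)
  })
}

# Noise-free step run of arbitrary size.
step_run <- function(size, duration = 1.2) {
  p <- modify_parameters(default_parameters(), list(noise_gain = 0))
  run_simulation(p, experiment(function(t) ifelse(t < 0.2, 0, size),
                               sprintf("step_%g", size)), duration, seed = 1)
}

# Settle the collicular map alone under constant external input.
settle_sc <- function(input, params, n_steps = 500, rostral = 0,
                      state = NULL) {
  if (is.null(state)) state <- sc_init(params)
  for (i in seq_len(n_steps)) {
    state <- sc_step(state, input, rep(0, params$n_neurons), rostral,
                     params$dt, params)
  }
  state
}

# Settle the brainstem alone under constant drives.
settle_brainstem <- function(params, drive_l = 0, drive_r = 0,
                             drive_opn = 384, choke_l = 0, choke_r = 0,
                             n_steps = 200, state = brainstem_init()) {
  for (i in seq_len(n_steps)) {
    state <- brainstem_step(state, drive_l, drive_r, drive_opn,
                            choke_l, choke_r, params$dt, params)
  }
  state
}
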