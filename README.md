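# saccsim

Closed-loop simulation of saccade and microsaccade triggering.

## The problem this package addresses

Even when we try to hold our gaze on a spot, the oculomotor system launches
small involuntary saccades — microsaccades — once or twice per second,
usually smaller than 1°. They arise at the knife edge of the decision
"maintain fixation versus start a saccade", so they expose the saccadic
*trigger* circuit: the mutually inhibitory brainstem network of omnipause
neurons (OPNs, tonically active during fixation) and burst neurons (BNs,
active during movements), whose state is controlled by the spatial pattern
of activity in the superior colliculus (SC). `saccsim` is a research
simulator for that circuit, aimed at oculomotor and computational
neuroscientists who want to probe how noise, collicular topography,
hysteresis and the cerebellar stop signal jointly shape fixational eye
movements — in health and in disorders with saccadic intrusions
(Parkinson's disease, progressive supranuclear palsy, spinocerebellar
ataxia).

## The model

A 101-neuron one-dimensional SC spans both colliculi (−5 … +5 mm, rostral
pole at 0 mm), with retinal eccentricity `D` mapped to the surface as
`d = B log((D + A)/A)`. Each neuron is a leaky integrator (τ_SC = 5 ms)
with logistic activation `a(u) = F / (1 + e^(−β_u u))` and Mexican-hat
lateral connectivity `w_ij = (A_w + C) e^(−dist²/2σ²_SC) − C`. A burst
layer (the activation thresholded at 0.6 F) feeds the BNs through
distance-weighted, activity-normalized projections — a centre-of-activity
code — while the OPN receives the buildup layer weighted by
`1 − |dist|/S`. The brainstem neurons (one OPN, three BNs per side) are
1-ms leaky integrators with the saturating rate function
`B(x) = B_m (1 − e^(−(x − e0)/b))`; the OPN–IBN double inhibition forms a
positive feedback loop, so the trigger behaves as a Schmitt trigger with
distinct on/off thresholds. A fastigial-like cerebellar circuit integrates
the BN efference copy and fires a "late burst"
`max(F1 e − F2 c, 0)` once the integrated copy surpasses the collicular
command, choking the active BNs and resetting the map rostrally. A matched
pulse–step motoneuron signal drives a first-order plant; eye position is
fed back with a 50-ms visual delay. Spatiotemporally correlated noise
(Gaussian spatial mixing, SD 0.2 mm; Ornstein–Uhlenbeck temporal filtering,
τ = 20 ms) perturbs the map and is the sole source of spontaneous
microsaccades.

## Worked example

```r
library(saccsim)
p <- default_parameters()          # published constants + calibrated gains

# a visually guided 2 degree saccade, noise disabled
quiet <- modify_parameters(p, list(noise_gain = 0))
step  <- experiment(function(t) ifelse(t < 0.2, 0, 2), "single_saccade_2deg")
res   <- run_simulation(quiet, step, duration = 1, seed = 1)
detect_saccades(res)
#>   onset offset amplitude magnitude peak_velocity direction
#> 1 0.256  0.275  2.078922  2.078922      149.1815     right

# 20 s of fixation with the default collicular noise
fix <- run_simulation(p, experiment(0, "fixation"), 20, seed = 1)
summarize_fixation(detect_saccades(fix), fix)
#> <fixation_statistics> 36 events, 1.80 /s
#>   median magnitude 0.495 deg, median ISI 0.221 s
#>   main-sequence slope 131.7 (deg/s)/deg, mean position 0.015 deg
#>   SWJs 28, oscillation runs 5
```

The first run shows the trigger flipping ~56 ms after the (delayed) target
step and producing a single rightward saccade of 2.08° at 149°/s — then
returning cleanly to fixation. The second shows spontaneous microsaccades:
1.8 per second, median magnitude just under 0.5°, with square-wave-jerk
couplets, exactly the fixational phenomenology the model is built around.

Named presets reproduce the disease conditions by editing one or two
parameters only (`pd`: noise ×2; `psp`: noise ×3 and B_m halved; `sca`:
cerebellar choke ×0.3; `sc_inactivation`: rostral output nulled on one
side):

```r
run_preset_battery(c("fixation_default", "pd", "psp", "sca"),
                   seeds = 1:3, duration = 20)
```

A thin command-line front end is installed with the package
(`exec/saccsim`): `saccsim simulate --experiment psp --seed 3 --out dir/`
writes the traces, detected events and full parameter set of one run;
`saccsim battery` tabulates conditions × seeds.

See `vignette("saccade-triggering-model")` for the full account of the
model, every tunable parameter, the numerical scheme, and known
limitations.

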