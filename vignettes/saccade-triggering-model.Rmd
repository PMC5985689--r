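---
title: "A closed-loop model of saccade and microsaccade triggering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A closed-loop model of saccade and microsaccade triggering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saccsim)
```

## The scientific problem

During attempted fixation the oculomotor system still launches small
involuntary saccades — microsaccades — once or twice per second, usually
smaller than one degree. Because these movements sit exactly at the boundary
of the decision "hold fixation versus move", they are a window onto the
saccadic *trigger*: the circuit that flips the brainstem between a fixation
state (omnipause neurons firing, burst neurons silent) and a saccade state
(the reverse). `saccsim` implements that trigger as a closed-loop dynamical
model and uses it to simulate normal fixation, visually guided saccades,
focal collicular inactivation, and the saccadic intrusions of parkinsonian
and cerebellar disease.

## Model architecture

The model couples five interacting stages inside a visual feedback loop with
a 50-ms delay:

1. **Cortical inputs.** The frontal eye fields drive the collicular map with
   a Gaussian hill (SD `sigma_FEF` = 0.5 mm) centred at the collicular
   image of the retinal error, while the basal ganglia release only that
   neighbourhood from a map-wide inhibitory surround (SD `sigma_BG` = 1 mm,
   depth `K_bg`). The FEF amplitude grows with target eccentricity,
   G(e) = g0 + g1 (1 − exp(−|e|/e_half)), so small retinal errors command
   the map more weakly than large ones.
2. **Superior colliculus.** A single one-dimensional structure of 101
   leaky-integrator neurons spans both colliculi (−5 to +5 mm, rostral pole
   at 0 mm). Retinal eccentricity D maps to the surface as
   d = B log((D + A)/A) with A = 3 deg and B = 1.4 mm. Each neuron passes
   its integrator state through a logistic activation with ceiling
   F = 500 spikes/s and is connected to every other neuron with a
   Mexican-hat weight (A_w + C) exp(−dist²/2σ²_SC) − C. A *burst layer*
   copies the buildup activation wherever it exceeds `burst_threshold`
   (300 spikes/s, i.e. 0.6 F); only this thresholded layer reaches the
   burst neurons, which keeps slow buildup from firing the trigger.
3. **Descending drives.** The omnipause neuron receives the buildup layer
   weighted by 1 − |d|/S (strongest from the rostral pole); each side's
   burst neurons receive the burst layer weighted by distance from the pole
   and normalized by the total burst activity (plus a 5% buildup leak for
   stability), so the drive encodes the *location* of activity rather than
   its amount.
4. **Brainstem trigger.** One omnipause neuron (OPN) and three burst
   neurons per side (long-lead inhibitory, medium-lead excitatory,
   medium-lead inhibitory), each a leaky integrator (τ = 1 ms) with the
   saturating rate function B(x) = B_m (1 − e^(−x/b)), rectified at zero.
   The OPN inhibits all burst neurons — weakly the LLIBNs (weight 0.0015),
   strongly the medium-lead neurons (0.2); the inhibitory burst neurons
   inhibit the OPN (weight 10) and the contralateral burst neurons (0.1).
   The OPN–LLIBN double inhibition is a positive feedback loop: the system
   is a Schmitt trigger with distinct switch-on and switch-off thresholds
   (`trigger_hysteresis_curve()` measures both), which keeps fluctuating
   drives from chattering between states.
5. **Cerebellar stop and plant.** The fastigial-like stop circuit
   integrates an efference copy of the medium-lead excitatory rate through
   a second-order system (a 20-ms lag feeding a leaky integrator) and
   compares it against the collicular command: the *late burst*
   max(F1 e − F2 c, 0) fires once the integrated copy surpasses the
   command, chokes the burst neurons of the moving side, and resets the
   collicular map (rostral excitation, caudal inhibition, scaled by the
   summed late bursts). The resulting burst-rate difference drives a
   matched pulse–step motoneuron signal into a first-order eye plant.

Spatiotemporally correlated noise — one white source per neuron, mixed with
Gaussian distance weights (SD `sigma_noise` = 0.2 mm) and filtered through
leaky integrators (τ = 20 ms) — perturbs the map continuously. When a noise
excursion displaces the burst-layer centre of activity far enough from the
pole, the trigger flips and a microsaccade results; the intent to move the
eyes acts through exactly the same pathway.

## What a simulation looks like

```{r example, eval = FALSE}
p <- default_parameters()

# a 2 degree visually guided saccade, noise disabled
quiet <- modify_parameters(p, list(noise_gain = 0))
step <- experiment(function(t) ifelse(t < 0.2, 0, 2), "single_saccade_2deg")
res <- run_simulation(quiet, step, duration = 1, seed = 1)
detect_saccades(res)

# 100 s of fixation with the default noise
fix <- run_simulation(p, experiment(0, "fixation"), 100, seed = 1)
summarize_fixation(detect_saccades(fix), fix)
```

## Parameters

The neural constants — time constants, synaptic weights, map geometry,
noise correlation scales, cerebellar channel gains — take the published
values of the model (`default_parameters()` documents every entry with its
units). The published description leaves a number of quantities open; they
are first-class parameters here, chosen once as follows and then frozen:

* **Input gains** (`k_bn` = 12, `k_opn` = 2.91). Chosen jointly so that at
  fixation the LLIBNs sit just below their firing threshold (the weak
  OPN→LLIBN inhibition exceeds the fixation drive by ~15%) while the
  switch-on threshold lands at ≈0.22 mm of drive — low enough that a
  0.5-degree target step still triggers deterministically, high enough
  that fixation is stable without noise. With these values the OPN input at
  fixation is ≈1170 units, which makes the switch require ≈115 spikes/s of
  LLIBN rate; this is the regime in which *lowering* the burst-neuron
  ceiling B_m raises the trigger threshold, the mechanism invoked for
  supranuclear palsy.
* **Burst threshold** (300 spikes/s = 0.6 F). Above the buildup plateau's
  skirts, below its saturated crown, so the fixation hill keeps the
  burst-neuron drive small while modest noise displacements change it.
* **FEF/BG scales** (g0 = 100, g1 = 300, e_half = 1 deg, K_bg = 3000).
  g0 sustains the central fixation hill; K_bg is deep enough to extinguish
  an abandoned hill when the target moves and to confine the hill's width;
  g1 and e_half let 0.5-degree errors move the hill decisively while
  leaving sub-threshold residual errors (< ≈0.4 deg) untriggered.
* **Stop-rule gains** (`k_c` = 108 with exponent `k_c_power` = 1.5,
  efference leak `T_cblm_leak` = 40 ms). The collicular command is decoded
  to degrees through the inverse retinotopic map and raised to a mild
  power before entering the late-burst comparison. The exponent
  compensates the square-root compression introduced by the 20-ms
  efference-copy lag (for movements shorter than the lag, displacement at
  the crossing grows as the square root of the threshold), and was set so
  that noise-free steps of 0.5, 1, 2 and 3 degrees all land within 10%.
  The leak lets each saccade's integral decay to zero between events
  (hard resetting it at movement end removes the post-saccadic late-burst
  tail, which is what suppresses re-triggering at the stale target site
  during the 50-ms feedback dead time).
* **Choke and reset gains** (`choke_gain` = 25, `rostral_gain` = 15,
  rostral window ±1 mm). Large enough to end movements crisply and restart
  the rostral hill without oscillation at default parameters.
* **Plant** (`velocity_gain` = 0.3 deg/s per spikes/s, τ_plant = 150 ms,
  pulse gain = τ_plant, slide gain 0). The published description names a
  pulse–slide–step final common path without equations. A matched
  pulse–step on a single-pole plant (pulse gain equal to the plant time
  constant) makes the eye track the neural integrator exactly, with zero
  post-saccadic drift; a slide pathway (50-ms lag) is wired but has zero
  gain by default because a single-pole plant needs no slide component.
  The velocity gain puts 2-degree saccades at ≈150 deg/s peak velocity and
  microsaccades at 40–70 deg/s, inside the physiological main sequence.
* **Noise amplitude** (`noise_gain` = 115 input units). The published
  constants fix the noise's correlation structure but not its amplitude.
  This value was calibrated once so that default fixation yields 1–2
  microsaccades/s with median magnitude below 1 degree (measured: ≈1.8/s,
  ≈0.47 deg over 3 × 100 s), and not revisited.
* **Condition presets** (`k_pd` = 2, `k_psp` = 3, `psp_B_m` = 400,
  `sca_choke_factor` = 0.3, inactivation window (0, 1] mm). Each disease
  preset edits only the one or two parameters named for it: parkinsonian
  fixation raises noise only; supranuclear palsy raises noise and lowers
  B_m; ataxia lowers the cerebellar choke only; inactivation nulls the
  *output* of one side's rostral neurons while leaving the dynamics
  untouched.

## Numerical scheme

The continuous states (101 map integrators, 7 brainstem integrators, 4
cerebellar states, 3 plant states) advance with a fixed-step third-order
Runge–Kutta scheme (Bogacki–Shampine stages) at dt = 1 ms; an explicit
Euler fallback is available for debugging (`scheme = "euler"`). Discrete
elements update once per step: the visual delay buffer (50 steps), the
noise draw (exact Ornstein–Uhlenbeck one-step update, so the stationary SD
is independent of dt), and the noise reset. The noise pattern is reset when
the OPN resumes firing at the end of each movement — resetting at onset
instead collapses the drive mid-movement and truncates saccades before the
cerebellar stop can act. All randomness flows through R's global RNG,
seeded per run; a result object carries everything needed to reproduce the
run bit-for-bit. Halving or quartering dt changes the noise-free 2-degree
saccade amplitude by < 0.2%.

Boundary conventions: the burst-layer threshold is inclusive (a ≥ threshold
bursts); the map has no wraparound, so end neurons simply have fewer strong
neighbours; the midline neuron sits exactly at 0 mm and is never included
in an inactivation region that starts at the pole.

## What the simulations do and do not show

The generator reproduces the *phenomenology* the model targets: single
accurate saccades over 0.5–3 degrees, spontaneous microsaccades with a
main-sequence velocity–magnitude relationship, square-wave-jerk couplets,
rate increases under raised collicular noise with unchanged peak
velocities, slowed saccades under reduced burst gain, macrosaccadic
oscillation runs under a weakened cerebellar choke, and reduced rate plus a
fixation shift under rostral inactivation. It contains no ocular drift,
tremor, pursuit, vergence or vestibular pathway, no vertical component, and
no sensory noise outside the collicular map — so intersaccadic intervals
are cleaner than in real recordings and the saccade detector can run with a
low velocity threshold (5 deg/s) that would be inappropriate for real data.

## Design choices where the architecture was genuinely open

* **Signed single-map convention.** Both colliculi form one signed axis
  (rightward eccentricities positive), with the logarithmic mapping
  extended by odd symmetry and both rostral poles coinciding at the map
  centre. Projection weights measure distance from the midline neuron.
* **Lateral-input scaling.** The recurrent term uses Riemann-sum scaling
  (weights × 0.1-mm neuron spacing), so the lateral input approximates the
  continuous-field integral and is invariant to the grid resolution. In
  this regime an active hill saturates into a plateau whose location, not
  height, carries the command — consistent with the normalization stage.
  Two *equal* competing input sites can then coexist as separate hills;
  selection between balanced alternatives is performed upstream by the
  basal-ganglia surround, while an unequal competitor is extinguished by
  long-range inhibition alone.
* **Cerebellar integrator.** The "second-order integrator" is realized as
  a 20-ms lag cascaded into a leaky integrator (gain 1/T_cblm2, leak
  40 ms). A unity-gain low-pass would track the burst *rate* rather than
  accumulate displacement and cannot express the "integrated copy
  surpasses the command" stop rule.
* **Burst laterality.** The early/late burst equations are indexed by
  movement side: side s integrates its own medium-lead rate and compares
  against its own collicular command; the late burst chokes the burst
  neurons of the moving side. A `choke_crossed` switch applies strict
  anatomical crossing instead, for sensitivity analyses.
* **Optional MLIBN→OPN projection.** The strong MLIBN→OPN inhibition that
  the circuit description mentions has no published weight; it is wired
  but zero by default (`mlibn_opn_weight`), because with it active the
  trigger's hysteresis no longer collapses when the LLIBN→OPN weight is
  removed — the LLIBN loop is the hysteresis mechanism under study.

## Known limitations

* The supranuclear-palsy preset reproduces the higher intrusion rate and
  the lower main-sequence slope, but not reliably the *larger* median
  magnitude seen in patients. In this implementation microsaccade size is
  limited by the lifetime of the noise-displaced drive rather than by the
  cerebellar stop rule, and lowering B_m simultaneously narrows the
  trigger's hysteresis (its width is proportional to the OPN→LLIBN weight
  times B_m), truncating movements earlier — the two effects cancel the
  threshold-driven size increase almost exactly.
* Near-balanced bilateral supra-threshold drives leave the brainstem in
  fixation (the crossed inhibitory neurons annihilate) rather than picking
  a side; a winner emerges only when one drive clearly dominates, which is
  what the collicular normalization delivers in the closed loop.
* Long-lead burst activity is brief: with single neurons per type and a
  1-ms time constant, the LLIBNs lead the medium-lead neurons by a few
  milliseconds only.
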