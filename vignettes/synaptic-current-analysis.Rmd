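---
title: "Quantifying inhibitory synaptic currents: detection, kinetics, fluctuation analysis and clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying inhibitory synaptic currents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synaptoscope)
```

## The problem

Spontaneous inhibitory postsynaptic currents (sIPSCs) recorded under
whole-cell voltage clamp carry quantitative information well beyond their
mean amplitude: the shape of each event constrains receptor kinetics, the
trial-to-trial fluctuations of the decaying current constrain the unitary
current `i` and the number of receptors `N` activated at the peak, and the
joint distribution of amplitude-independent event features can reveal
whether a treatment effect is confined to a subset of synaptic inputs or
spread across all of them.  A long-term increase in sIPSC amplitude
(inhibitory LTP) can in principle come from larger unitary currents, more
receptors, or changed presynaptic statistics, and the analyses bundled
here are exactly the ones that separate those hypotheses.

`synaptoscope` implements that analysis chain — Bessel filtering,
scaled-template event detection with explicit selection rules, per-event
feature extraction, multi-exponential decay fitting, paired-pulse
re-sensitization curves, peak-scaled non-stationary fluctuation analysis
(NSFA), and skew-t mixture clustering — together with a stochastic
simulator of binomial channel ensembles that provides exact ground truth
for every stage.  All user-facing functions take and return tibbles, so
the stages chain naturally.

## The generative model used for validation

No raw recordings ship with the package; every quantitative claim is
validated against the bundled simulator, whose defaults were chosen once
to emulate the experimental regime the analyses were designed for:

* **Channel ensemble.** A synapse is `N` identical receptors with unitary
  current `i` (pA, inward negative).  The open-probability time course is
  a difference of exponentials (rise time constant 0.8 ms, decay 15 ms,
  peak open probability 0.8), and at every sample the open count is drawn
  independently as Binomial(`N`, `p(t)`).  Per-sample independence is a
  deliberate idealisation: it makes the variance–mean relation exactly
  the parabola `sigma^2 = i*I - I^2/N`, so NSFA has a clean oracle.  Real
  channels have correlated gating; what passing the NSFA recovery tests
  shows is that the estimator is unbiased *given* the binomial model, not
  that correlated gating cannot bias it.
* **Defaults for the two study conditions.** Control ensembles use
  `N = 26`, `i = -3.33` pA (mean peak near −69 pA before noise);
  potentiated ensembles use `N = 63` with `i` unchanged, i.e. a pure
  receptor-number change of ×2.42.  Event times are homogeneous Poisson
  at 1 Hz, sweeps 40–100 s, and baseline noise is additive white Gaussian
  (SD 2 pA) — values a practitioner would call a typical, moderately
  noisy culture recording.  Simulations in the tests run at 10 kHz
  (patch-style hardware runs at 20–50 kHz); this halves memory and run
  time while leaving >10 samples on every rise, and all rise-time
  estimators interpolate between samples.
* **Macroscopic desensitization.** A three-state C–O–D scheme (closed,
  open, desensitized) driven by an agonist waveform.  Rate presets
  (`preset_scheme()`) are calibrated only qualitatively: `"wild_type"`
  (δ = 250 s⁻¹, ρ = 2 s⁻¹) desensitizes partially and recovers in
  ~0.5 s; `"non_desensitizing"` (δ = 0) shows no paired-pulse
  suppression; `"hyper_desensitizing"` (δ = 1200 s⁻¹, ρ = 0.4 s⁻¹)
  suppresses deeply and recovers slowly.  No quantitative rate constants
  are claimed for any real receptor; the presets exist to reproduce the
  *ordering* of suppression durations, which is what the paired-pulse
  analysis consumes.  Deterministic trajectories are computed exactly
  (matrix exponential per constant-agonist segment, so stiffness is not
  an issue); the stochastic mode runs exact Gillespie jumps on the
  aggregated channel counts.

## Filtering

The low-pass stage mirrors amplifier hardware: an analogue Bessel
prototype (poles of the reverse Bessel polynomial, magnitude-normalised
so the cutoff is the −3 dB point, as on an amplifier's filter dial) is
discretised by the bilinear transform with frequency pre-warping at the
cutoff.  Filtering is causal by default, matching acquisition; a
zero-phase forward–backward mode exists for offline feature extraction,
where phase delay would bias rise-time and slope estimates — both are
provided because offline re-filtering conventions differ between labs.
The filter starts in steady state relative to the first sample, so a
constant trace maps to itself exactly.  One consequence of the −3 dB
normalisation is worth stating: an 8-pole filter at 2 kHz attenuates
4 kHz power by a factor of ~20, not the larger figures sometimes quoted
for delay-normalised Bessel prototypes; the tests pin the implemented
response to the analogue prototype's magnitude curve directly.

## Event detection and its two calibrated guards

Detection slides a difference-of-exponentials template along the trace;
at each offset the template is fitted by optimal scale and offset, and
the detection criterion is `scale / sqrt(SSE/(L-1))` — the fitted scale
in units of the local residual noise, with the conventional threshold
of 4.  Two further rules proved necessary once the detector was run
against ground-truth simulations, and both are documented here because
they are calibrations, not free parameters:

* **Template length 2 decay constants (default 30 ms).**  Long windows
  average more noise, but any true event falling inside a neighbour's
  window inflates that window's residual SD and can mask the neighbour
  entirely — at 1 Hz spontaneous rates a 5-τ window puts a sizeable
  fraction of events inside a neighbour's span.  With the 2-τ default the
  detection tests hold recall and precision at or above 0.95.
* **Rise-slope gate (`min_rise_frac`, default 0.2/ms).**  Because the
  template is decay-dominated, the criterion forms a plateau over every
  decay, and plateau maxima masquerade as events.  A genuine event
  deepens at roughly `0.5/rise-time` of its own amplitude per ms, while a
  decay shoulder deepens at `1/tau_decay` (~0.07/ms here); requiring a
  rolling-regression slope (2 ms window, 2 kHz-filtered) of at least 0.2
  of the amplitude per ms separates the two with a wide margin.  The
  slope is also used to split summated events: two candidates are
  distinct only if the current relaxes above the slope-noise floor
  between them, which resolves pairs ~3 ms apart while collapsing
  duplicate maxima on a single rise.

The selection rules then follow the standard practice for these
recordings: `clean_rise` (no inflection on the rising phase) gates mean
amplitude statistics, `clean_decay` (clean rise *and* no secondary peak
before the decay reaches 10% of the peak) gates kinetic fits and NSFA,
and all-event analyses (rise rates, intervals, cumulative distributions)
ignore both flags.  The secondary-peak threshold is the larger of 3
baseline-noise SDs and 25% of the event amplitude — channel-gating
flicker scales with the event, a summated event does not.

## Decay kinetics

Decays are fitted as sums of 1–3 exponentials by variable projection
(amplitudes solved linearly for trial time constants, time constants
optimised on the log scale from log-spaced multi-starts).  An extra
component must reduce the SSE by at least 2% (relative) to be accepted:
an added exponential always reduces SSE, so a tolerance is required, and
2% is permissive enough to find genuine second components yet stable
under noise.  The amplitude-weighted time constant is
`T_w = sum(a_k tau_k) / sum(a_k)`; the desensitization extent is
`(1 - steady/peak) * 100`.  Patch-current fits include a constant offset
(the desensitized plateau); sIPSC decay fits do not, since synaptic
currents return to baseline.  The steady state for the extent calculation
defaults to the mean of the final 10% of the agonist pulse.  Flat
segments raise an explicit "insufficient decay" error rather than
returning a meaningless time constant.

## Peak-scaled NSFA

Clean-decay events are aligned on their peaks; the mean waveform, scaled
to each event's peak, is subtracted; and the across-event variance of the
residuals is paired with the mean current along the decay (peak → 10% of
peak).  Pairs are averaged in 50 equal-count bins along the mean current
(equal-count rather than equal-width because samples crowd near baseline
on an exponential decay), and the parabola is fitted by ordinary least
squares on the basis `(I, I^2, 1)`, with the quadratic basis averaged
within bins so that exact parabola input remains exact after binning.
`i` is the linear coefficient, `N = -1/b` the negative reciprocal of the
quadratic one, and the intercept estimates the baseline variance.  No
downward curvature is an error, not a number.

Two refinements remove a bias of about 10% that the naive procedure
shows on simulated ground truth: the per-event scale factor is taken
from a ±0.5 ms window around the peak rather than the single noisy peak
sample, and the first 1 ms after the peak is excluded from the pairs
because peak-scaling pins the residuals to ~0 there, creating an
artificial variance deficit at the highest currents.  With both in
place, recovery on the control regime (N = 26, i = −3.33 pA, 300 events,
2 pA noise) sits well inside the 10% (i) and 20% (N) bands the test
suite asserts.  Fits are
performed per cell; group statistics act on per-cell `(i, N)`.

## Paired-pulse re-sensitization

The ratio of the second to the first peak, as a function of the
inter-pulse interval, probes recovery from desensitization.  The second
peak is measured from the current level just before the second pulse, not
the original baseline — with incompletely decayed inter-pulse current the
two conventions differ, and the local-level convention isolates the
releasable response.  The curve is summarised by fitting
`1 - d*exp(-dt/tau_rec)`; for the C–O–D scheme the recovery is genuinely
single-exponential in the re-sensitization rate once the open state has
emptied; the tests pin the deterministic fitted `tau_rec` to `1/rho`
within 2% and stochastic runs at 200 trials/interval to the closed form
with RMSE below 0.05.

## Skew-t mixture clustering

Nine amplitude-independent features describe each event: instantaneous
frequency (defined as the reciprocal of the preceding interevent
interval; the first event of a record has no value and is excluded from
frequency-bearing analyses), the 10–90%, 20–80% and 30–70% rise times,
the maximum rise slope normalized to the peak, the mean 20–80% rise
slope normalized to the peak, the interevent interval, the burst window
(shortest span containing three consecutive events including the one in
question), and the coefficient of variation within the burst window —
interpreted as the CV of the two intervals inside the chosen triplet,
since the feature set was constructed to be amplitude-independent and an
amplitude CV would violate that.  Features are standardized before
fitting (on by default).

The mixture family is the restricted multivariate skew-t: each component
has a location vector, a positive-definite scale matrix, a single skew
direction vector and its own degrees of freedom, estimated by EM.  The
E-step posterior moments of the latent gamma weight and half-normal skew
variable are computed by 32-node generalized Gauss–Laguerre quadrature
(the only non-gamma factor in the posterior is a smooth normal CDF, so
the quadrature converges fast; above ν = 5000 the closed-form ν→∞ limit
is used).  Location, skew and scale updates are closed-form conditional
maximizations; the degrees of freedom are updated every fifth iteration
by direct maximization of the observed log-likelihood, box-constrained to
[2.5, 200] because unbounded ν is ill-conditioned near the Gaussian
limit.  Every step is a conditional maximization of the observed
likelihood or of the EM minorant, so the log-likelihood is non-decreasing
— the test suite asserts this on every fitted trace.  Initialization is
k-means with zero skew and ν = 40, several short runs, best continued to
convergence.  Model size is chosen by BIC with
`p = (G-1) + G(2d + d(d+1)/2 + 1)` free parameters.

The tests validate this machinery along two independent routes: the
density against direct numerical integration and against samples drawn
through the hierarchical representation; the E-step moments against a
Monte Carlo importance estimate; and the Gaussian limit (skew fixed at
zero, large fixed ν) against the closed-form Gaussian MLE likelihood.

## Group-level statistics

Per-cell summaries — mean clean-rise amplitude, median interevent
interval, mean 20–80% rise time, `T_w`, NSFA `i` and `N` — are compared
with a two-tailed Student's t-test (equal variances by default, matching
pooled-df reporting conventions for these designs; Welch by flag) for two
groups and one-way ANOVA with Tukey's HSD beyond that.  Aggregation to
cells always precedes testing: events are never treated as replicates.
Cumulative probability curves average per-cell empirical CDFs on a common
grid so every cell carries equal weight.

## Problem sizes in the shipped tests

The test-suite simulations use 40–100 s sweeps at 10 kHz, 200–600 events
for NSFA and clustering fixtures, 200 Gillespie trials per paired-pulse
interval, and 10 seeded repetitions for the BIC-selection check — sizes
chosen so the full chain exercises every code path while a complete run
stays comfortable on a laptop.  The same generators accept larger values
for heavier validation.

## Known limitations

* The binomial per-sample-independence idealisation excludes gating
  correlations and multivesicular release; NSFA results on real data
  should be read with those caveats.
* Detection calibration (threshold 4, rise-slope gate 0.2/ms) was tuned
  on the simulator's waveforms; very slow-rising events (20–80% rise
  ≳ 4 ms) approach the slope gate and may need a lower `min_rise_frac`.
* The C–O–D scheme is a phenomenological stand-in — no ligand-binding
  steps, no subunit stoichiometry — and its presets make qualitative,
  not quantitative, claims.
* Skew-t EM is multimodal; multi-start mitigates but does not guarantee
  the global optimum, and BIC selection inherits that caveat.
* ABF (Axon Binary Format) ingestion is not built in; sweeps are
  exchanged as TSV + JSON manifests, and any external converter that
  produces two-column sweep files plugs in upstream.
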