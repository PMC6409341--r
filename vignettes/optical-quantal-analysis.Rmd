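---
title: "Optical quantal analysis with epscat: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optical quantal analysis with epscat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epscat)
```

## The measurement and its statistical model

Transmitter release at a single synapse is quantal and stochastic: each
action potential releases a vesicle with probability p_r. At glutamatergic
spine synapses, release drives a postsynaptic Ca²⁺ transient (EPSCaT) that
is confined to the spine head and — crucially — behaves as an all-or-none
event: its occurrence, not its amplitude, reports release. Optical quantal
analysis therefore reduces each imaging trial to a binary outcome and
models the session as `n` Bernoulli draws:

* `success_i ~ Bernoulli(p_r)`, independent across trials,
* `p_hat = k / n`, `SE = sqrt(p_hat (1 - p_hat) / n)`.

The package's estimator (`estimatePr`) is exactly this proportion with the
binomial SE; everything upstream exists to produce defensible binary
outcomes from noisy kymographs, and everything downstream
(`requiredTrials`, `comparePr`, `facilitation`) is standard binomial
inference.

Key assumptions, and where they are visible in the code:

* **All-or-none readout.** Detection thresholds the windowed mean ΔF/F;
  amplitudes are never used for inference. The amplitude-robustness test
  (acceptance suite) verifies that halving or doubling event amplitude
  leaves `p_hat` unchanged as long as events stay well above threshold.
* **Uniquantal regime.** Multivesicular release would change amplitudes,
  not the binary calls, so `p_hat` estimates the probability of *at least
  one* release; vesicular release probability is out of scope.
* **Stationarity within an epoch.** Trials are exchangeable;
  `estimatePr` is invariant to trial order (tested).
* **Pulse-1 convention.** Under paired-pulse stimulation p_r is computed
  from pulse-1 calls only; pulse 2 quantifies short-term facilitation.

## From kymograph to ΔF/F (`extractTrace`)

For ROI `r` with pixel span `S_r`, raw fluorescence per line is the
unweighted pixel mean. With `F_background` the grand mean of the
background ROI over the whole scan and `F_baseline` the mean ROI
fluorescence over the baseline window (scan start up to the first
stimulus, by default):

```
ΔF/F(t) = (F(t) − F_baseline) / (F_baseline − F_background)
```

This ratio is exactly invariant to multiplicative gain and to any offset
common to all pixels (both tested to machine precision), so detector
decisions cannot depend on PMT gain or DC offsets. A trial with
`F_baseline ≤ F_background` has no interpretable normalization and is
rejected with an explicit error — flagged, never silently dropped.

Numerical conventions, stated once and used everywhere: pixel and line
indices are 0-based; ROI spans and all analysis windows are half-open
`[start, end)`; line `i` is timestamped `t = i / line_rate`, so the line
containing the stimulus instant belongs to the response window. Any
non-finite ΔF/F inside an analysis window voids the trial with an error
rather than propagating NA into a call.

Options kept off by default because the standard workflow does not apply
them: per-line background subtraction (for slow background drift) and
exponential bleach detrending fitted on the baseline. `smoothTrace`
exists for figures only; smoothed traces carry a flag and the detector
refuses them.

## Event detection (`callEvent`, `DetectionConfig`)

The transient statistic is the mean ΔF/F over the 50 ms window starting at
the stimulus. The noise term is the SE of the mean of the ΔF/F samples in
the last 50 ms of baseline (n = 25 lines at 500 Hz): `sd / sqrt(25)`. A
pulse succeeds when `statistic ≥ 2.5 × noise`; *at least* is read as a
closed inequality, so a statistic exactly at threshold is a success. The
noise multiple and window length are configurable
(`threshold_multiple`, `response_window_ms`); "sd" is available as an
alternative noise definition (`noise_definition`) because the prose
convention "SE of the ΔF/F" admits both readings — SE-of-mean is the
default since the statistic it calibrates is itself a 50 ms mean.

**Calibration of the criterion.** Under the null, the statistic divided by
the noise term is not a unit-normal z: the windowed mean retains the
variance of the estimated baseline mean (variance `σ²(1/25 + 1/50)`
against the `σ²/25` that the SE measures), and the SE is itself estimated
from 25 lines. The null success ("false positive") rate is therefore
roughly 2–3%, several times the naive `P(Z ≥ 2.5) ≈ 0.6%`. This is a
property of the criterion as practiced, not of this implementation: the
acceptance suite recomputes the same rate from raw Poisson draws with an
independent Monte-Carlo oracle and verifies agreement. Two practical
consequences, both visible in the validation runs: estimates of small p_r
carry a small positive bias of order `(1 − p_r) × 0.02`, and the spread of
`p_hat` across sessions is marginally wider than the closed-form SE at low
p_r. Raising `threshold_multiple` trades this against sensitivity;
misses are essentially zero for events several-fold above threshold.

**Contamination.** Back-propagating action potentials and dendritic
spikes produce synchronous Ca²⁺ transients of similar amplitude in spine
and dendrite, so both ROIs are always analyzed. A trial is *flagged* when
the dendrite transient is itself significant
(`≥ contamination_multiple × dendrite noise`). The default policy,
`subtract_and_test`, implements the field's rule for such trials
quantitatively: the trial still counts as a success only if
`spine − dendrite ≥ contamination_multiple × pooled noise` (pooled = root
sum of squared SEs). The excess test applies only to flagged trials, so
clean trials are judged by the plain threshold. Two alternatives exist:
`reject_trial` excludes flagged trials from numerator and denominator
(the report itemizes every exclusion so denominators stay auditable), and
`off` disables the screen.

`subtract_and_test` is the default rather than `reject_trial` for a
reason worth recording: the flag is a significance screen, not an
amplitude comparison. Whenever diffusional bleed-through of the spine
signal into the dendrite ROI (`dendrite_bleed_fraction`, default 10% in
the simulator) is detectable above the dendrite's noise floor — which at
realistic photon budgets it is — every true release trial gets flagged,
and a rejection policy would discard exactly the successes. The excess
test handles both nuisances with one rule: bleed-through passes it
(spine ≫ dendrite), global events fail it (spine ≈ dendrite). By the same
logic, the flag's accuracy against ground truth is validated on
simulations without bleed, where "flagged" and "global event injected"
should coincide; with bleed present the flag deliberately stays sensitive
and the excess test does the discriminating.

**Paired-pulse overlap.** With a 70 ms interval and slow high-affinity
indicator decay (τ ≈ 200 ms), a pulse-1 transient is still near its peak
throughout the pulse-2 window, so an uncorrected pulse-2 statistic
measures "pulse 1 *or* pulse 2 released". No correction is applied by
default (the standard workflow defines none); for quantitative
facilitation measurements `p2_tail_correction = "prewindow"` re-baselines
each later pulse by subtracting the mean ΔF/F over the 20 ms immediately
before its stimulus. This local re-baseline slightly over-subtracts (the
tail keeps decaying through the window) — a conservative bias that is
irrelevant for binary calls at realistic amplitudes, and far more robust
on 10–15 lines than fitting an exponential tail. The facilitation
validation runs with this correction enabled.

## Estimation, planning, comparison (`estimatePr` and friends)

* **CI method.** The workflow's printed uncertainty is the binomial SE;
  for an interval the default is Wilson score (well-behaved at `p_hat`
  of 0 or 1, where the Wald interval collapses), with Wald — the SE
  formula's literal companion — and Clopper–Pearson as options. All three
  are delegated to `stats::prop.test` / `stats::binom.test` or the
  textbook formula.
* **Planner.** `requiredTrials(p, se)` is the exact inversion
  `N = ceiling(p (1 − p) / se²)`; at p = 0.5 a target SE of ~0.09–0.11
  yields the familiar 20–30 trials, with fewer needed at extreme p.
* **Pre/post comparison.** `comparePr` reports `Δp_r`, its
  root-sum-square SE, and a two-proportion test. Fisher's exact test is
  the default because trial counts are small; it is conservative (true
  type-I error below nominal at n = 30), so the normal-approximation
  `method = "z"` is provided when calibrated-at-nominal behavior matters;
  the test suite checks Fisher for validity and the z test for
  calibration. No multiple-testing correction is applied — this is a
  single-synapse workflow; batch users can apply `p.adjust` across
  synapses.

## What the simulator emulates — and what it does not

`SimParams` defaults are the standard acquisition protocol: 200 lines at
500 Hz (400 ms), paired pulses 70 ms apart at 100 ms, 50 ms windows.
The generative model per trial:

| parameter | default | meaning |
|---|---|---|
| `true_pr` | 0.5 | Bernoulli release probability, pulse 1 |
| `facilitation_factor` | 1.5 | multiplier on the marginal pulse-2 probability, capped at 1; typical paired-pulse facilitation at 70 ms |
| `amplitude_dff` | 1.0 | mean peak ΔF/F of a uniquantal event — a convention for a well-loaded high-affinity indicator (a single bAP gives ΔF/F ≈ 0.8 at adequate loading), not a measured constant |
| `amplitude_cv` | 0.2 | lognormal amplitude variability (keeps amplitudes positive) |
| `tau_rise_ms`, `tau_decay_ms` | 10, 200 | difference-of-exponentials kernel, normalized to peak 1; conventions typical of OGB-1-class dyes |
| `dendrite_bleed_fraction` | 0.1 | fraction of the spine signal appearing in the dendrite ROI by diffusion |
| `contamination_rate` | 0 | per-trial probability of a global (bAP/dendritic-spike) transient, equal amplitude in both ROIs, at the pulse-1 time |
| `baseline_photon_rate` | 50 | photons·pixel⁻¹·line⁻¹ in structures; sets shot noise via a Poisson draw per pixel |
| `background_level` | 5 | additive photon offset everywhere |
| `bleach_tau_s` | Inf | exponential scaling of the whole expectation |
| `roi_geometry` | 48 px; spine [6,16), dendrite [20,32), background [36,46) | disjoint spans along the scanned line |

Facilitation is modeled on the *marginal* pulse-2 probability,
independent of the pulse-1 outcome — the smallest model that produces the
"P2 more likely than P1" structure; conditional facilitation
(P2 given P1 failure) is not modeled. Contamination is synchronous with
pulse 1 and equal-amplitude in both ROIs, operationalizing how bAPs and
dendritic spikes present in practice.

Deliberately absent, so passing tests say nothing about them: biophysics
of the Ca²⁺ sources (NMDAR/VGCC/store release), indicator binding
kinetics and saturation, detector read noise and dark counts (Poisson
shot noise only), mechanical drift and z-motion of electrode or tissue,
frame-scan (xy–t) geometries, and amplitude-based multivesicular
quantification. Against real recordings the pipeline's weakest points
will be drift (violates the constant-baseline assumption) and indicator
saturation (compresses amplitudes — harmless for binary calls, fatal for
amplitude-based extensions).

Reproducibility: every random draw in a simulated experiment derives
deterministically from `seed` (one sub-stream per trial, recorded in the
ground-truth table), so an experiment is reproducible bit for bit and
trials remain independent. `runPipeline` writes report bundles without
timestamps; the same configuration reproduces the same bytes.

## Validation sizes

The shipped validation suite exercises the pipeline at sizes chosen to
make Monte-Carlo error small relative to the tolerances checked: 1,000
replicate 30-trial experiments for estimator recovery (four release
probabilities), 10,000 null trials against the independent
false-positive oracle, 600 experiments for amplitude robustness, 1,000
trials at 20% contamination for the screen, and 5,000 paired-pulse trials
for facilitation. `scripts/acceptance.R` re-derives the headline
quantities at smaller sizes in under a minute.

```{r example}
sim <- simulateExperiment(SimParams(true_pr = 0.5, seed = 2), 30)
calls <- callTrials(sim$records,
    DetectionConfig(p2_tail_correction = "prewindow"))
estimatePr(calls)
facilitation(calls)
```

## Known limitations

* The 2.5×-noise criterion's null false-positive rate (~2–3%, see above)
  biases small-p_r estimates slightly upward; users estimating p_r ≲ 0.1
  should consider a higher `threshold_multiple` and plan trials
  accordingly.
* The contamination flag cannot distinguish strong diffusional
  bleed-through from weak global events; only the excess test
  discriminates, and only when the spine signal is genuinely larger.
* Single-ROI-per-compartment, single-synapse design: no automatic ROI
  segmentation, no motion correction, no multi-synapse bookkeeping beyond
  what `p.adjust` provides.
* `F_background` is a scan-wide mean by default; strongly time-varying
  backgrounds need `background_per_line = TRUE`.
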