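---
title: "Methods: trace-level analysis of ultrasound neuromodulation"
author: "sonotrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trace-level analysis of ultrasound neuromodulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonotrace)
```

## The problem

Low-intensity focused ultrasound can modulate cortical activity, but only a
sparse subpopulation of neurons responds directly, and in hearing animals the
effect is confounded by indirect auditory activation. Two-photon calcium
imaging of the primary visual cortex in deafened mice gives a trace per
neuron at single-cell resolution; the analysis question is then purely
trace-level: given raw ROI fluorescence, matched background traces and
stimulus timing, which neurons respond to ultrasound, how does that
population scale with pressure, and how does concurrent ultrasound reshape
the responses of visually driven neurons?

`sonotrace` implements that pipeline end to end, together with the stimulus
schedule and acoustic-exposure arithmetic of the pulsed protocol and a
Rayleigh-Sommerfeld model of the annular transducer field. Because raw
recordings of this kind are rarely deposited, the package ships a
synthetic-trace generator with exact ground truth; every stage of the
pipeline is validated as a parameter-recovery exercise on that generator.

## The pipeline

Starting from a `trace_set` (frames x neurons ROI and background matrices at
30 Hz plus stimulus onsets):

1. **Background subtraction** - the corrected trace is `roi - background`,
   elementwise.
2. **Frame averaging** - every 10 consecutive frames are averaged
   (30 Hz to 3 Hz), mirroring acquisition-block averaging used to raise SNR;
   a non-divisible tail is dropped.
3. **Epoching** - each analyzed onset is snapped to its nearest frame (worst
   misalignment 167 ms at 3 Hz, recorded in the tensor) and a half-open
   `[-5, 25)` s window is cut: 90 frames, onset at frame 16. One extra
   leading train is always scheduled and discarded because no baseline
   precedes it, leaving 9 analyzed trials per condition.
4. **dF/F** - `(F - F0)/F0` with `F0` the mean of the same epoch's
   `[-5, 0)` s baseline.
5. **z-score** - baseline mean/SD of the same epoch (per-epoch scope;
   per-session pooling is available behind `zscore_scope = "session"`).
   A zero baseline SD flags that neuron-trial invalid rather than erroring.
6. **Excited-trial detection** - a trial is excited when the maximum z over
   `(0, 3]` s strictly exceeds 2.
7. **Pre-excited exclusion** - trials whose maximum z over `[-3, 0)` s
   exceeds the same threshold are dropped from numerator and denominator
   (per-trial mode; a neuron-level mode that discards the whole neuron is
   available via `exclusion_mode = "neuron"` and is the more destructive
   reading of the same screening rule).
8. **Response-rate classification** - rate = excited / non-excluded trials;
   strictly above 30% the neuron is a robust responder (UN under ultrasound,
   VN under visual stimulation), in (0, 30%] a weak responder (NUN/NVN),
   at 0 non-responsive; with no usable trials it is unclassifiable.
9. **Modulation subgrouping** - visual responders are compared between the
   visual-only and the combined visual+ultrasound condition on their
   per-trial dF/F maxima over `(0, 3]` s with a two-sided Welch test at
   alpha = 0.05: significant decrease = inhibited (VNs2), increase = excited
   (VNs3), otherwise unchanged (VNs1). A pure effect-size rule
   (`|log2 gain| > 0.585`) is available as an alternative. No multiplicity
   correction is applied within the per-neuron subgrouping; with ~tens of
   VNs per field this overstates VNs2/VNs3 membership by about the test's
   alpha, which is documented rather than corrected to keep the rule
   direction-aware and per-neuron.

Both thresholds are strict (`z > 2`, `rate > 0.30`): a trial peaking at
exactly z = 2, or a neuron at exactly 3-of-10 valid trials ... 30%, does not
pass. Units are tracked on the epoch tensor (`raw_F -> dff -> zscored`) and
each transform rejects inputs in the wrong unit, so the normalization path
cannot be applied twice. The whole chain is invariant to rescaling the raw
fluorescence (ROI and background together), which is tested as a property.

### Design choices that were genuinely open

* **z-score basis.** Published heatmaps of this kind sometimes show z-scored
  raw F and sometimes z-scored dF/F. The classification path here is
  raw -> dF/F -> z, which matches the usual processing description;
  `zscore_basis = "raw"` reproduces the raw-F variant for display parity.
* **Baseline window for F0.** The full `[-5, 0)` s pre-window. The narrower
  `[-3, 0)` s window is reserved for pre-excited screening, matching how
  pre-stimulus statistics are usually reported.
* **Order of exclusion and rate.** The response-rate denominator counts
  trials *after* pre-excited exclusion (default). The alternative fixed
  9-trial denominator is a config switch away (`exclusion_mode`,
  `response_rate` composition), because the published wording does not pin
  this down.
* **Threshold monotonicity.** Over a fixed trial set, raising the excited
  threshold can only remove excited trials, and the package tests that
  invariant at the detection level. Jointly with pre-excited re-screening
  the *rate* need not be monotone: a higher threshold can un-flag a
  pre-excited trial and re-admit it to both numerator and denominator. This
  interaction is easy to miss and worth knowing when sweeping thresholds.
* **VN screening for modulation.** VNs are screened on the visual-only
  condition alone (not pooled across conditions), so the combined condition
  remains a pure test set for the modulation comparison.

## The synthetic-data generator

Each neuron's ROI trace is

```
roi(t) = F0 * (1 + sum_k a_k * K(t - t_k)) + r_np * b(t) + e(t)
```

with `K` a peak-normalized double-exponential indicator kernel
(`tau_rise = 0.18 s`, `tau_decay = 1.8 s`, typical slow high-sensitivity
GCaMP kinetics; the peak time has the closed form
`tau_r tau_d / (tau_d - tau_r) * log(tau_d / tau_r)`), `a_k` lognormal
transient amplitudes in dF/F units, event times `t_k` at stimulus onsets
(Bernoulli per trial with the neuron's response probability) plus a
spontaneous Poisson process, `e` i.i.d. Gaussian noise, and `b` a slow
bounded background oscillation (offset + sinusoid, 0.2-0.45 Hz,
per-neuron amplitude/frequency/phase).

The background enters the ROI trace with a neuropil contamination
coefficient `r_np = 0.7` (the conventional neuropil correction factor in
two-photon processing), while the *recorded* background trace is `b(t)`
itself. Exact subtraction therefore leaves a bounded residual
`(r_np - 1) b(t)` in the corrected trace - deliberately so. This is the
load-bearing feature of the noise model: the per-epoch baseline SD is then
dominated by a bounded, slowly oscillating component whose max-to-SD ratio
is about sqrt(2), so the "max z > 2 in 9 frames" rule almost never fires on
noise alone (~0.2% of trials). Had the corrected trace been plain i.i.d.
Gaussian, that same rule would fire on 25-35% of trials *regardless of the
noise amplitude* (the z-score is scale-free), and no spontaneous-rate
setting could produce a realistic sham session. Real recordings behave like
the bounded model, not the Gaussian one: baseline variance is dominated by
neuropil residuals and slow physiological fluctuation, with genuine calcium
transients - not noise excursions - driving threshold crossings.

With the default residual-to-noise amplitude ratio (~10x at 3 Hz), the sham
false-excitation probability is ~0.2% per trial, and the spontaneous
transient rate of 0.003 events/s adds ~1% per trial (a transient beginning
within roughly `[-0.3, 3]` s of an onset crosses the threshold). Nine
analyzed trials then give ~10% weak responders and a robust-responder
false-positive fraction of order 0.01% in sham sessions - the generator's
calibration target for the sham regime, chosen once. The spontaneous rate is
a calibration constant of the generator, not an empirical claim about
cortex: published recordings do not report spontaneous event statistics at
this granularity.

Planted structure: ultrasound responders are an exact-count sparse
population (default 1.2% of the field) whose per-trial response probability
follows a logistic pressure curve (`p_max = 0.9`, half-max 250 kPa, slope
100 kPa, 0 at 0 kPa); visual responders (default 1.4%) respond with
probability 0.95 and are split into unchanged / suppressed (gain 0.4) /
enhanced (gain 1.8) thirds for the combined condition. Exact-count planting
(rather than per-neuron Bernoulli roles) was chosen so that
parameter-recovery checks compare against a fixed planted count; role
placement therefore depends on the population size, while all per-neuron
noise and event substreams derive from the master seed by fixed offsets, so
enlarging the field never changes existing traces.

What the generator does *not* emulate: motion artifacts, photobleaching,
neuropil dynamics correlated across neurons, bursting statistics, or any
spatial structure. Passing recovery tests on this generator therefore
demonstrates that the pipeline's logic is correct and well calibrated for
its stated detection model - not that in-vivo percentages (for example the
~1.1% robust responders reported at 450 kPa in deafened mice) would be
reproduced from real data, which depend on biology the generator does not
model. Those in-vivo numbers are treated as qualitative context throughout.

## Acoustics

Exposure metrics are closed-form: duty cycle `PD/PRI` (50% for 50/100 ms),
on-time `SD * duty` (0.25 s per 0.5 s train), mechanical index
`MI = P/sqrt(f)` with P in MPa and f in MHz (0.45 at 450 kPa, 1 MHz),
`Isppa = P^2 / (2 rho c)` using the peak negative pressure under the
plane-wave relation (6.75 W/cm2 at 450 kPa in water - the interpretation
that reproduces the standard printed value), and
`Ispta = Isppa * duty * SD / period` with period `SD + SI = 30.5 s`
(55.33 mW/cm2). Pulse count per train is `floor((SD - PD)/PRI) + 1` for
`SD >= PD` (5 pulses for the standard condition). Each pulse is smoothed by
a quarter-sine ramp `sin(pi t / (2 RD))`; with PD = 50 ms and RD = 25 ms the
plateau has zero length, i.e. the pulse is a half-sine window - accepted
as-is since only "sine-based" smoothing is specified.

The transducer field is modeled with the first Rayleigh-Sommerfeld integral
over the annulus (11/19 mm, 1 MHz), evaluated by midpoint quadrature on a
polar source grid: radial step `lambda/60`, 64 azimuthal nodes. The
closed-form on-axis solution of the circular piston,
`|p(z)| = 2 rho c v0 |sin(k(sqrt(z^2+a^2) - z)/2)|`, is the independent
oracle: the disc reduction of the quadrature matches it to better than 1e-3
relative error over z in [1, 100] mm, and the annulus field equals the
pointwise difference of two disc fields (superposition). Attenuation enters
as `exp(-alpha R)` with alpha from the dB/(MHz^2 cm) coefficient -
negligible in water at 1 MHz over millimeters but kept for correctness; the
oracle comparison is run lossless for exactness. The -6 dB beamwidth is the
distance between the outermost crossings of half the peak amplitude
(20 log10(0.5) = -6.02 dB), linearly interpolated. This is a deliberate
simplification relative to full-wave (k-space/FDTD) simulation: it captures
the free-field beam geometry but not reverberation or refraction in
layered media; the glass window is optionally represented by a
normal-incidence single-layer transmission factor, and measured trans-window
attenuation (which includes skull remnants and bonding) is out of the
model's scope.

## Numerical choices and degenerate inputs

* Onset snapping is nearest-frame; window membership uses half-open
  intervals with a 1e-9 s tolerance so exact boundary times are assigned
  deterministically.
* `F0 <= 0` in an epoch baseline is an error (it would make dF/F
  meaningless); zero baseline *SD* is not - the trial is flagged invalid and
  excluded, since all-flat baselines are expected in edge cases
  (noise-free simulations, dead ROIs).
* Ties at thresholds resolve to "not excited" / "not a robust responder"
  (strict inequalities).
* The Welch subgrouping falls back to direct mean comparison when both
  trial vectors are exactly constant (degenerate variance), and reports
  `not_vn` with a warning when fewer than 2 valid trials remain.
* Quadrature density for the field model was fixed from a refinement study
  against the on-axis oracle (1e-3 tolerance with a 2.5x margin at the
  default density).

## Problem sizes used in validation

The validation suite runs the full chain on: 50 sham seeds of 3000-neuron
fields (specificity), 3000-neuron fields at planted fractions 0.1/0.5/1.2%
and a response-probability ladder 0.1-0.9 (recovery and monotonicity,
4-6 seeds per point), and 600-neuron two-condition sessions with 150 visual
responders (modulation subgrouping, 2 seeds). These sizes give binomial
confidence bands a few times narrower than the effects being checked while
keeping the whole suite in the tens of minutes on one core; they are
validation choices, not biological claims.

## Known limitations

* The generator's event model is linear in the kernel; indicator saturation
  and nonlinear summation are not modeled, so amplitude-recovery claims
  beyond the classification thresholds should not be over-read.
* Per-neuron modulation subgrouping without multiplicity correction inflates
  VNs2/VNs3 membership by ~alpha under the null.
* The Rayleigh model assumes a rigid baffled source with uniform velocity;
  real transducers have non-uniform apodization, so absolute pressures
  require the measured voltage-pressure calibration
  (`fit_pressure_voltage()`), and simulated widths are indicative only.
* Classification operates on extracted traces; motion correction and ROI
  segmentation quality are upstream concerns outside this package.
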