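---
title: "Methods: mapping cochlear frequency-place shifts from CAP reduction times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping cochlear frequency-place shifts from CAP reduction times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capmap)
```

## The measurement model

An apex-to-base perfusion of a kainic-acid solution through scala tympani
silences the inner-hair-cell/auditory-nerve synapse progressively from the
low-frequency apex toward the high-frequency base.  Because a low-level
tone burst evokes a compound action potential (CAP) from the cochlear
region tuned to its frequency, the perfusion time at which that CAP falls
to 50% of its baseline amplitude estimates when the front arrived at the
tone's characteristic-frequency (CF) place.  Three ingredients turn
reduction times into frequency-place statements:

1. **Front kinematics.**  Position is linear in time,
   `x(t) = (t − t0) · v`, with `v = 0.5` mm/min and no dead time by
   default (`perfusion_model()`).
2. **Frequency-place map.**  `CF(x) = A (10^{a x / L} − k)` with guinea-pig
   defaults `A = 0.35` kHz, `a = 2.1` decades, `k = 0.85`, `L = 18.5` mm
   (`freq_place_map()`).  The source map for this species does not come
   with a single canonical set of printed constants; these Greenwood
   values are the package's documented defaults, and they are validated
   against the two rule-of-thumb conversions the experimental literature
   uses — about 5 min of perfusion per CF octave at 0.5 mm/min, and a
   5-min-earlier reduction corresponding to about one octave more apical.
   All four constants and both flow parameters are overridable through the
   run configuration.
3. **Octave conversion.**  `octave_shift(t_ref, t_test)` is
   `log2(CF(x(t_ref)) / CF(x(t_test)))`.  For the exponential part of the
   map this is linear in the time difference with slope
   `1 / minutes_per_octave()` = 1/5.30 oct/min; the additive constant `k`
   bends the map near the apex, where a minute of perfusion crosses
   slightly more than 1/5.30 octave.  The identity
   `minutes_per_octave() × octave_shift(t1, t2) = t1 − t2` is therefore
   exact only at `k = 0`, and approximate (to a few percent above ~6 kHz)
   on the default map.

Distances are measured from the *apex*, matching the perfusion direction;
a positive octave shift means "more apical / lower CF than the reference".

## Reduction times and tuning curves

Amplitude trajectories are normalized by the mean of the samples falling
in a −5 to +5 min window around perfusion start (at least two samples
required).  A reduction time for fraction `q` ∈ {0.8, 0.5, 0.2} is the
first downward crossing of `q` that stays at or below `q` for `k = 2`
consecutive samples (a run reaching the end of the record also counts),
with the crossing instant linearly interpolated between the bracketing
samples; a sample exactly at `q` is itself the crossing time.  The
sustained-crossing rule rejects isolated noise dips at the ~6 dB SNR
typical of low-level CAPs; `k` and an optional 3-point median pre-smoother
are configurable, with the raw trace the default.

Two numerical points deserve note:

- **Interpolation error.**  Linear interpolation of a logistic decline
  sampled every minute carries a curvature error of up to ~0.05 min at the
  80/20 crossings (slope 0.8 min); the 50% crossing, lying in the nearly
  linear centre, is much more accurate.  The closed-form-agreement tests
  therefore sample at 0.25 min, where linear interpolation is within
  0.02 min of the exact logistic inverse everywhere.  Group *differences*
  of 50% times at 1-min sampling are unbiased to well below the
  between-ear variability, which is what the statistics consume.
- **Tuning-curve assembly.**  The curve's tip is the 50% time of the
  10 dB SL trajectory; each higher level contributes an 80% (apical-edge)
  and 20% (basal-edge) time.  Levels whose crossings cannot be determined,
  or whose extracted edges are inverted by noise, are omitted with a
  warning rather than imputed.  Group averages are per-level means with a
  SEM reported only when at least two ears contribute.

## The permutation tests

For each frequency with complete data (all N = 5 operated and M = 8
control ears), the statistic is the observed set difference
`OSD = mean(control t50) − mean(operated t50)`.  Under the null that both
groups share one distribution, ear labels are exchangeable: the 13 values
are pooled and pseudo-operated sets of 5 are drawn either exhaustively
(`exact_perm_test()`, all C(13,5) = 1287 assignments) or by random
permutation (`mc_perm_test()`).  The p value is the fraction of
assignments with `PD ≥ OSD`; ties count as exceedances, and the exact
enumeration includes the observed assignment, so `p ≥ 1/1287`.  One-sided
testing (operated earlier than control) is the default, the direction the
hydrops hypothesis predicts; the two-sided variant uses `|PD| ≥ |OSD|`
(a doubling rule would be an alternative; the magnitude rule is what is
implemented and tested).  The Monte-Carlo estimator is the plain
`count / n_perm` for fidelity to the original procedure — it can return 0
when the observed OSD is never matched — with the `(count+1)/(n_perm+1)`
variant available as `estimator = "plus_one"`.

The five frequencies are combined by summing their set differences, in
two ways that bracket the dependence question:

- **Method 1 (`grand_perm_test(method = "independent")`)** permutes ear
  labels independently at each frequency (an assignment space of
  1287⁵ ≈ 3.5 × 10¹⁵, hence Monte-Carlo).  This treats frequencies as
  independent evidence and is anti-conservative when the same ears are
  extreme at every frequency.
- **Method 2 (`method = "common"`)** applies one permutation to all
  frequencies, preserving the across-frequency correlation of ear
  effects.  With identical columns it provably reduces to the
  single-frequency test (both PD-sum and OSD-sum scale by the number of
  frequencies), a degenerate case the test suite checks exactly.

Each Monte-Carlo routine takes an explicit seed, restores the caller's
RNG state, and (for method 1) derives a fixed per-frequency stream from
the master seed so results do not depend on frequency order.  Default
`n_perm` is 10⁵, configurable upward; the exact test is preferred
whenever a single frequency is in question.

## OAE extraction

Tone amplitudes are estimated by closed-form least squares at exactly the
analysis frequency over a window truncated to an integer number of
cycles, reported as RMS re 20 µPa.  The DPOAE amplitude is taken at
2f₁ − f₂ (f₂/f₁ = 1.22 enforced within a configurable tolerance) from the
coherent mean of the stimulus repetitions — coherent-first averaging is
the package's choice where the original procedure is ambiguous — and the
SFOAE is the probe-frequency component of the double-evoked residual
`probe + suppressor − both`.  Noise floors are the standard error of the
per-repetition amplitudes in dB SPL; the SE is computed on the complex
amplitudes by default (real and imaginary parts in quadrature, capturing
phase jitter), with a magnitude-based mode switchable, and a −120 dB SPL
sentinel when repetitions are identical.

## The synthetic-data generator

`sim_config()` encodes the study conditions: 5 operated + 8 control ears;
frequencies 2, 4, 6, 8, 12 kHz; expected control-minus-operated shifts
(5.8, 3.8, 4.3, 2.4, 3.4) min; responder probability 0.8 (mirroring the
one non-responding operated ear in five).  Ground-truth 50% times are

```
t50(ear, f) = time_from_cf(f) + u_ear − I[operated] · z_ear · s_f + ε
```

with `u_ear ~ N(0, 2²)` min shared across frequency — this single shared
effect is what makes ear variation "highly correlated across frequency"
and method 2 conservative relative to method 1 — `z_ear ~
Bernoulli(0.8)`, `ε ~ N(0, 0.5²)` min, and the per-responder shift
`s_f = shift_f / 0.8` scaled so the *configured* shifts are the expected
group-mean differences even though one ear in five (in expectation)
carries none of it.  Trajectories are logistic declines
`1/(1 + exp((t − centre)/slope))` (slope 0.8 min) sampled every minute
from −10 to +45 min with additive Gaussian amplitude noise (SD 0.02 of
baseline); above 10 dB SL the 80% point moves earlier by 0.8 min and the
20% point later by 2.0 min per 10 dB, the basal edge moving more, as in
normal-ear tuning curves.  The within-ear variance parameters (`ear_sd`,
`resid_sd`, `noise_sd`, slope, level spread) are not published quantities;
they are fixed, documented assumptions chosen for physiologically
plausible SNR, and the parameter-recovery tests show the pipeline is
calibrated under them — not that real recordings share them.  Real data
differ in ways the generator does not attempt: non-logistic decline
shapes, SNR-adaptive averaging, drifting baselines, occasional missing
levels.

Problem sizes used by the test suite are chosen for tight Monte-Carlo
control at desk scale: 2000 simulated null datasets for the size check of
the exact test (rejection rate in [0.035, 0.065] at α = 0.05), 500
replicates for full-pipeline shift recovery (within 3 MC standard
errors), and 10⁵ permutations where Monte-Carlo is compared with exact
enumeration (3σ binomial band).

## Interfaces and open choices

The run configuration (JSON or YAML; `read_run_config()`) validates
every block and rejects unknown keys.  `run_study()` executes
simulate → normalize → extract → tuning curves → octave shifts →
permutation inference and optionally writes CSV/JSON artifacts plus a
log; identical seeds give identical files.  Choices made where the
procedure was genuinely open, all switchable: raised-cosine ANOW ramps;
N1/P1 search window 0.5–6 ms; linear threshold interpolation on an
isotonic-monotonized level series; ANOW magnitude as steady-state RMS (a
stand-in — how the original low-frequency thresholds were quantified is
not established, so no fidelity is claimed for them); complex-domain OAE
noise floors.  Known limitations: the map constants are defaults rather
than measured values for any individual ear; the exact test is limited to
enumerable group sizes (C(N+M, N) ≤ 10⁷); and printed group p values from
the original experiment cannot be reproduced because per-ear reduction
times were never published — the package reproduces the *procedure* and
verifies it on synthetic ground truth instead.
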