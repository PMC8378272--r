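---
title: "Methods: optical electrophysiology analysis for cardiac MPS dose escalation"
author: "cardiomps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optical electrophysiology analysis for cardiac MPS dose escalation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiomps)
```

## The measurement problem

Cardiac microphysiological systems (MPS) are microfluidic chips in which
hiPSC-derived cardiomyocytes self-organize into small beating tissues. In
acute safety-pharmacology screens, each tissue is recorded optically — a
voltage-sensitive dye reports the action potential, a genetically encoded
calcium indicator reports the calcium transient — while a drug is escalated
through a ladder of doses anchored at the clinical Cmax. The camera delivers
a scalar fluorescence intensity trace per recording at a nominal 100 frames
per second, in 6-s and 30-s takes, spontaneous or field-paced at 1–1.5 Hz.

From those traces this package computes the readouts that map onto clinical
cardiology:

* **APD80**, the action potential duration at 80% repolarization, as a proxy
  for the ECG QT interval; rate-corrected by the **Fridericia** rule
  (duration divided by the cube root of the RR interval in seconds), or by
  pacing the tissue at a fixed rate.
* **Triangulation**, `(APD80 − APD30)/APD80`: loss of the plateau phase, a
  proarrhythmic repolarization shape.
* **Maximum upstroke velocity** (max dF/dt) of both channels, an optical
  surrogate for depolarizing current availability.
* **Poincaré beat-to-beat instability** of successive APD80s.
* **EAD/DAD detection** and a per-tissue, per-dose classification into
  `normal`, `arrhythmic`, or `weak_or_silent`.

The cohort layer reproduces the acute dose-escalation design: seven tissues
per drug in 4-plex chips, a 30-minute incubation per rung, inclusion
restricted to tissues with baseline APD80 under 500 ms (the clinical
torsades-risk threshold mapped onto the dish), per-tissue normalization to
the dose-0 baseline, one-way ANOVA with Dunnett many-to-one comparisons
against dose 0, and pairwise chi-squared tests of arrhythmic incidence. An
effluent proteomics panel can be filtered by the standard limit-of-detection
rule: LOD = mean + 3 SD of negative controls, markers kept only when
detected in more than 65% of samples.

## Per-beat analysis

**Detrending.** Photobleaching is removed before any amplitude rule is
applied. The rolling lower envelope (5th percentile of consecutive windows,
each anchored at the time of the sample realizing it, at least four points)
is fitted with a linear drift (voltage dyes) or a three-parameter
exponential (GCaMP). Degenerate exponential fits — growth instead of decay,
or a drift larger than the data range — fall back to the linear model.
The fitted drift is subtracted, preserving the level at the start of the
recording.

**Segmentation.** Peaks are detected on a Savitzky–Golay–smoothed copy of
the signal (cubic, 11 points at 100 Hz) with two prominence requirements:
a fractional one (default 0.3 of the trace's dynamic range) and a
noise-adaptive absolute floor (8 robust noise SDs). The floor matters for
silent tissues: a beat-free trace is pure noise, and a fractional rule alone
would hallucinate beats from its own noise range. Activations closer than
the 200-ms refractory default to the previous one are rejected.

**Activation and APD.** The activation point is the maximum upstroke
(max dF/dt), refined to sub-sample precision by a parabolic fit through the
neighbouring first differences. APD at fraction *r* is the time from
activation to the first post-peak crossing of
`baseline + (1 − r)·amplitude`, located by linear interpolation between the
bracketing samples. One frame is 10 ms at 100 Hz, so crossings are located
on the smoothed signal when noise is measurable (the first-crossing statistic
on raw noisy samples is biased early), and on the raw samples when the
robust noise estimate is negligible (sharp synthetic edges are then located
exactly). The per-beat diastolic baseline is the median of the 100-ms window
ending 20 ms before activation; the first beat uses the global 5th
percentile, which is robust to DADs in diastole. Beats whose APD80 never
resolves before the next activation are flagged and excluded from APD and
triangulation aggregates but retained for arrhythmia analysis — mirroring
the exclusion of poor-quality high-dose recordings from dose-response
panels.

**Routing.** When a paced recording passes the capture check (beat rate
within 5% of the stimulus frequency and RR coefficient of variation below
5%), APD metrics come from it and the RR used for Fridericia correction is
the pacing period; otherwise the spontaneous recording and its measured RR
are used. Triangulation, beat rate and Poincaré instability always come
from spontaneous recordings; classification uses the 30-s spontaneous
calcium recording. Per recording, APD statistics are the median over
resolved beats (the choice between a representative beat and an average is
open in optical-mapping practice; the median is robust and configurable).
Triangulation is computed from raw, not rate-corrected, APDs.

## Arrhythmia analysis

**EADs.** An early afterdepolarization is a depolarizing deflection during
repolarization: within each beat's peak-to-APD90 window, a local minimum
followed by a rise of at least `theta_ead` (default 0.05) of the beat
amplitude. Detection proceeds in three stages: (1) an isotonic
(monotone-nonincreasing) regression of the smoothed window isolates the
regions that violate monotone repolarization — a monotone signal of *any*
shape, including the piecewise-linear synthetic templates, pools to nothing,
which makes the screen immune to waveform kinks; (2) cumulative
minimum-to-maximum swings within those regions are measured on a 5-point
quadratic smoothing of the signal, corrected for that smoother's computable
attenuation of a deflection of the nominal 50-ms width; (3) magnitude gates
calibrated on the synthetic generator (smoothed rise at 1.2× the corrected
threshold plus a raw-sample crest-versus-dip confirmation at 0.8×) decide
the call. The calibration target was under 1% of clean 30-s traces
triggering at noise SD 0.02 while deflections of 10% amplitude and above are
retained; shape heuristics (swing duration, pooled-region length) carry
almost no discrimination at 100 Hz, so the operating point is
magnitude-limited by design. The reported relative amplitude corrects for
the in-situ attenuation of a bump riding the local repolarization slope
(two fixed-point iterations of a deterministic model), so a 15% injected
deflection reads back as ≈0.15.

**DADs.** A delayed afterdepolarization is a sub-threshold deflection in
diastole (APD90 crossing to just before the next upstroke foot; the window
stops 60 ms short of the next activation so the rising foot cannot
masquerade as an event). Candidate local maxima are measured against the
local diastolic *level* — the median of the window with the candidate's
neighbourhood excluded — never against window-extreme minima, which on a
flat noisy diastole would equal the full noise range. Deflections of at
least `theta_dad` (default 0.10) and below `beat_threshold` (default 0.60)
of the preceding beat amplitude are events; anything at or above 0.60 is a
beat and belongs to segmentation. Candidates closer than 50 ms merge.

**Waveform irregularity.** The torsades-like pattern — continuous change of
amplitude and configuration with plateau loss — is captured by the larger of
the population coefficients of variation of beat amplitudes and of APD50s;
four beats minimum, `NA` otherwise. The arrhythmic call uses a threshold of
0.2, chosen on the generator so that clean traces never trigger.

**Poincaré instability.** Successive APD80s, each divided by the recording
mean, are paired with their predecessors. The instability index is the
root-mean-square perpendicular distance from the identity line — an
SD1-style short-term variability on mean-normalized durations. Perfect
alternans of relative depth ε gives exactly `ε·√2`; a constant sequence
gives exactly 0. The instability flag threshold is 0.05 (5% of the mean
APD80): on synthetic alternans this separates the tight diagonal cluster of
stable rhythms from the two-cluster and disorganized-polygon geometries.
Visual Poincaré reading is qualitative; a numeric criterion is required for
automation, and 0.05 is configurable.

**Classification.** Strict precedence per tissue × dose, on the 30-s
spontaneous calcium recording: `weak_or_silent` when no beats are detected
or the maximum beat amplitude falls below 60% of the same tissue's dose-0
control; else `arrhythmic` when any EAD or DAD is detected (a single event
suffices by default; configurable) or irregularity exceeds its threshold;
else `normal`. The categories are mutually exclusive and weakness dominates:
a suppressed tissue is reported as weak even if events are also present.

## Statistics

The Dunnett many-to-one comparisons are computed in-package from the
multivariate-t distribution of the comparison t statistics. Because the
statistics share only the reference group, their correlation matrix has the
factor structure `λ_j λ_k` with `λ_j = √(n_j/(n_j + n_0))`; conditioning on
the reference deviate and the pooled scale turns the joint CDF into a
product of univariate normal probabilities, integrated on a 48 × 48
Gauss–Legendre grid. The computation is deterministic with absolute accuracy
around 1e-5, agrees with the reference `multcomp` implementation to better
than 1e-3 in p, reduces exactly to the pooled two-sample t-test for a single
comparison, and its family-wise error at α = 0.05 calibrates into
[0.04, 0.06] over 10,000 null simulations at the cohort's size (5 doses × 7
tissues). Dose groups with fewer than two measurable values (toxic or silent
rungs) are excluded from the model and listed with a reason rather than
imputed. Incidence contrasts use the chi-squared test of homogeneity on 2×2
arrhythmic-or-not tables for every dose pair, without continuity correction
by default (Yates correction available by flag). Significance stars follow
the conventional 0.05/0.01/0.001/0.0001 ladder.

The LOD filter reads ">65%" and "above LOD" strictly: a marker is retained
only when the fraction of non-missing study samples strictly above
`mean + 3·SD` (sample SD) of its negative controls strictly exceeds 0.65.
Exactly 65% is dropped; samples missing for technical reasons are excluded
from the denominator.

## The synthetic generator

No raw recordings accompany the study design this package implements, so
validation rests on a generator with exact ground truth.

**Templates.** A beat is a sigmoid upstroke (20 ms for voltage, 80 ms for
calcium — the indicator kinetics ordering is built in) followed by
piecewise-linear repolarization through `(APD30, 0.7A)` and `(APD80, 0.2A)`,
reaching zero at `APD80 + 0.5·(APD80 − APD30)` so APD90 stays defined and
analytic. The APD30/APD80 of the noise-free template equal their targets
exactly, which is what makes recovery tests meaningful.

**Traces.** Beat trains at spontaneous or paced rates; APD and amplitude
alternans by ±ε on alternate beats; multiplicative exponential
photobleaching applied to baseline plus signal; additive Gaussian noise
(default SD 0.02) last. EADs are injected as a smooth local segment
replacement during phase 3 — an approach dip, a cosine rise of exactly the
requested fraction of the beat amplitude (default width 50 ms), and a
cosine return to the repolarization track — so the deflection's measurable
minimum-to-maximum rise equals its nominal amplitude; a purely additive bump
of ≤15% amplitude riding a steep repolarization would present a much smaller
rise than its nominal height and make amplitude bookkeeping incoherent.
DADs are additive Gaussian bumps (default width 100 ms) on the flat
diastolic baseline, where no such correction is needed.

**Cohorts.** Tissue baselines are drawn once per tissue: APD80 from
Normal(350, 60) truncated to [200, 600] ms — wide enough that some tissues
genuinely violate the 500-ms inclusion screen — triangulation from
U(0.27, 0.33), amplitude from U(0.9, 1.1), spontaneous rate from
U(0.85, 1.05) Hz. These are explicit assumptions: the study design states
only the inclusion screen, not a baseline distribution. Drug effects are
monotone Hill/logistic families (APD multiplier, triangulation shift, EAD
and DAD probabilities, amplitude suppression, silencing, alternans), all
null at dose 0. Per-dose arrhythmia and silencing incidences are realized
by quota — exactly `round(p·n)` tissues receive the condition, identities
randomized — rather than independent Bernoulli draws: with n = 7 the
binomial noise of independent draws would frequently scramble the designed
monotone incidence curve, and the quota realization reproduces the designed
incidence exactly in every cohort at the cost of slightly understating
cohort-to-cohort variability. Four recordings are rendered per tissue ×
dose (paced/spontaneous 6-s voltage, paced 6-s calcium, spontaneous 30-s
calcium); events go into the 30-s calcium trace, the classification
substrate. One master seed drives everything; per-trace substreams derive
deterministically from (seed, tissue, dose, channel, rhythm, length), so
identical seeds give bit-identical cohorts and partial regeneration is
reproducible.

**What the generator does not emulate.** Motion artifacts, spatially
heterogeneous activation, dual-channel crosstalk, shot-noise statistics
(additive Gaussian noise is a deliberate simplification; Poisson noise would
change detector calibration constants, not structure), beat-to-beat APD
correlations beyond alternans, and drug kinetics within an incubation step.
Passing tests therefore demonstrate correctness of the analysis on signals
with the assumed structure, not performance on arbitrary real recordings;
the detector operating points (smoothing widths, gate constants) would need
recalibration for cameras or indicators with different noise.

## Numerical choices and degenerate inputs

* Thresholds live in one place per layer (`call_thresholds()`,
  `study_config()`) and every value quoted above is an overridable default.
* The trace CSV dialect stores numbers at full decimal precision
  (`%.17g`), so write–read round trips are bit-exact; the explicit time
  column is validated against the implicit uniform clock with tolerance
  1e-6 s.
* Constant traces refuse to normalize; empty segmentations are valid
  results, not errors; `capture_check` with fewer than 3 beats reports
  non-capture; `shape_irregularity` with fewer than 4 beats reports `NA`;
  Poincaré pairs require 3 APDs.
* Boundary conventions are strict and documented: baseline APD80 of exactly
  500 ms is excluded; an amplitude ratio of exactly 0.60 is not weak; a
  detection fraction of exactly 0.65 is dropped.
* Validation problem sizes (100 recovery beats, 100–200 calibration traces
  per arm, 50 biomarker panels, 10,000 null simulations, one full 7-tissue
  cohort) were chosen so the whole suite exercises every code path on a
  single CPU in minutes while keeping Monte-Carlo standard errors well
  inside the asserted tolerances.

## Known limitations

Single-pixel (mean-ROI) analysis only — no conduction or activation maps;
no contractility readouts; no mechanistic attribution of effects to ion
currents; rate correction assumes the Fridericia form rather than fitting a
subject-specific exponent; EAD/DAD minimum amplitudes are operational
choices (a 4% deflection is invisible at this SNR by design); and the
classification rules, while faithful to the screening protocol they
implement, compress a rich electrophysiological phenotype into three
categories.
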