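---
title: "Quantifying atrial fibrillation burden from minute-epoch rhythm monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying atrial fibrillation burden from minute-epoch rhythm monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afburden)
```

## The problem

Atrial fibrillation (AF) burden — how much of a monitoring period a patient
spends in AF, and how that time is organised — is increasingly used for risk
stratification and rhythm-management decisions. Wrist-worn
photoplethysmography (PPG) devices can sample the pulse once per minute for
days at a time, but their rhythm calls are an imperfect observation of the
truth that a simultaneous 24-hour Holter ECG would record. `afburden`
implements the full analysis chain for this setting:

1. a minute-epoch data model with ternary rhythm labels (AF / non-AF /
   missing) and episode extraction;
2. an optional windowed detector turning pulse-level inter-beat intervals
   into minute labels;
3. five families of burden statistics computed per subject;
4. cohort-level concordance of a device stream against the gold standard;
5. a synthetic paired-cohort generator so the whole pipeline can be
   exercised, calibrated and tested without clinical data.

## The minute-epoch data model

The unit of interpretation is one minute. Each epoch carries a beat count,
an AF-beat count, a mean pulse rate and a validity flag; a valid minute is
labeled **AF** when its AF-beat fraction *strictly* exceeds a threshold
$\tau$ (default $\tau = 0.40$, i.e. more than 40% AF beats per minute), and
**missing** when the monitor produced no usable output. Three conventions
are applied uniformly and deserve emphasis, because the literature rarely
states them:

* **Denominators count valid minutes only.** "Total monitoring time" and
  "total measurements" exclude missing minutes, matching the notion of a
  device's daily output rate. Whether unreadable minutes should instead
  dilute the denominator is genuinely ambiguous in the field; we chose the
  valid-minute convention once and use it everywhere.
* **Strict inequalities.** The beat-fraction rule is strict (`> 0.40`), and
  the episode-duration categories "over 6 minutes" and "over 1 hour" mean
  at least 7 and at least 61 whole minutes at 1-minute resolution.
* **Half-open, 0-based minute intervals** `[start, end)` throughout.

Episodes are maximal runs of AF minutes. By default a missing minute breaks
a run (`gap_bridge_min = 0`); a configurable bridge may merge runs separated
by short missing gaps, motivated by the continuity of real AF episodes, with
bridged gaps never adding to the episode's duration. Non-AF minutes always
terminate a run.

## The windowed detector

Production wearables use proprietary trained classifiers; this package
instead documents a transparent stand-in with the same interface, because
the analysis surface we care about — burden and concordance — only needs a
plausible, deterministic detector. The recording is tiled into
non-overlapping windows of 8, 16, 24, 32, 40 or 48 seconds (deterministic
tiling from time zero at inference; randomised start offsets exist only as
an augmentation option). Each window passes a quality gate (artifact
fraction at most `q_max = 0.2` and at least 5 inter-beat intervals; both
values are package choices, stated in the configuration, since no standard
exists) and is then scored by a fixed two-feature logistic rule:

$$\mathrm{score} = \mathrm{logit}^{-1}(a z_1 + b z_2 + c),$$

where $z_1$ is the root mean square of successive inter-beat-interval
differences divided by the mean interval (normalised RMSSD) and $z_2$ is the
Shannon entropy (natural log) of those differences histogrammed into 8
fixed-width bins spanning ±300 ms, out-of-range differences clamped to the
edge bins. The defaults $a = 28$, $b = 1.2$, $c = -7.5$ were calibrated once
on simulated segments — uniformly dispersed intervals for AF against
sinusoidally modulated quasi-regular intervals for sinus rhythm — and then
frozen; perfectly regular intervals give $z_1 = z_2 = 0$ and a score near
zero, so the intercept alone fixes the no-irregularity operating point.

Minute fusion assigns each beat the call of its covering quality-passing
window; a minute is valid when at least half of its seconds are covered.
After labeling, a single context pass re-labels any lone discordant minute
whose two neighbours agree (majority-of-three). This is the minimal
realisation of context-aware fusion over episode continuity: it provably
never alters a run of two or more identical labels, and its window width is
configurable. How a production system fuses the six window durations into
one prediction is not public; we deliberately expose duration as a parameter
rather than invent a cross-scale rule.

## The five burden metric families

For a labeled timeline with $T$ valid minutes the package computes fifteen
statistics:

* **M1, duration.** Total minutes of qualifying AF episodes divided by $T$,
  with episode-duration filters of ≥1, ≥7 and ≥61 minutes.
* **M2, frequency.** Count of qualifying episodes divided by $T$ (one
  minute = one measurement), same three filters.
* **M3, density.** How clustered the burden is. With valid minutes
  compacted to a contiguous axis, let $C(t)$ be the piecewise-linear
  cumulative fraction of all AF minutes accrued by time $t$ and
  $U(t) = t/T$ the uniform-accrual line. The raw area
  $A = \int_0^T |C - U|\,dt$ is integrated exactly on the minute grid
  (trapezoids, with the sign-crossing case split into two triangles). We
  normalise by $T(1-b)/2$, where $b$ is the burden fraction — the area
  attained by a single contiguous AF block at a record boundary, which is
  the maximum over arrangements — so density lies in $[0,1]$: 0 for evenly
  interleaved AF, 1 for one boundary block. An unnormalised area would not
  be comparable across subjects with different $T$ and $b$; reported
  clinical medians on a unit scale are consistent with this choice. Density
  is defined as 0 when $b \in \{0, 1\}$, and is invariant under time
  reversal of the label sequence.
* **M4, circadian variability.** From the 24 hourly AF counts $h_k$
  (AF minutes per clock hour by default; episode onsets per hour are
  available, since "hourly AF counts" is ambiguous): the sample standard
  deviation of $h$; the variability $\mathrm{sd}(h)/\bar h$ (SD normalised
  by the 24-hour mean, i.e. a coefficient of variation), also restricted to
  the daytime (06:00–22:00) and nighttime (22:00–06:00) windows; the
  average real variability $\mathrm{ARV} = (\mathrm{sd}(h) + \mathrm{MAD}(h))/2$
  with MAD the mean absolute deviation about the mean; and the variation of
  the mean $\mathrm{VOM} = |\bar h_{day} - \bar h_{night}|/\bar h \times 100\%$.
  Sample ($n-1$) SD and mean-absolute deviation about the mean are package
  choices where the definitions are silent. VOM is reported as an absolute
  value by default with a signed variant behind `signed_vom`, because
  published interquartile ranges for this quantity are sometimes negative,
  implying a signed version; we surface the ambiguity as a flag rather than
  resolve it. Hours with no valid minute are excluded; all-zero counts give
  zeros with a degeneracy flag, and recordings spanning fewer than two
  clock hours flag the whole family.
* **M5, rapid ventricular rate.** AF minutes whose mean rate strictly
  exceeds 120 bpm, divided by $T$ (duration form) and per-measurement
  (count form; identical at 1-minute resolution — an episode-level variant
  using beat-weighted episode mean rates sits behind a flag).

## Concordance evaluation

With the gold stream defining truth and AF the positive class, epoch-level
confusion counts are accumulated over minutes valid in *both* streams and
pooled across subjects. Sensitivity, specificity, precision, accuracy and
F1 are evaluated formula-exactly; each gets a Wilson score interval
(no continuity correction) on its own numerator/denominator pair, F1 being
treated as the proportion $2TP / (2TP + FP + FN)$. Because epoch-level
intervals ignore within-subject clustering, a subject-level percentile
bootstrap (resampling whole subjects' confusion counts, 2000 resamples,
seeded) is provided alongside and clearly labeled.

The ROC sweeps the AF-beat-fraction threshold over every distinct observed
value by default, making the trapezoidal AUC equal to the pairwise-ordering
probability with half-credit for ties; a Table-style sweep at the
40–70% cut points (device relabeled, gold held at 40%) is also emitted.

Per-metric cohort concordance reports medians and IQRs per source, the mean
absolute error over subject pairs, the Mann–Whitney p-value comparing the
two metric distributions, and the Spearman rank correlation (mid-ranks,
two-sided p from the $t$ approximation with $n-2$ degrees of freedom).
Mann–Whitney is used for the unpaired comparison because it is the standard
distribution-level test in this literature even though the design is
paired; a paired Wilcoxon signed-rank alternative sits behind
`paired_test = TRUE`. The U test enumerates all group assignments exactly
(ties included) whenever the arrangement count is at most 200,000 and
otherwise uses the tie-corrected normal approximation; identical samples
return $p = 1$ by convention. Undefined cases — zero rank variance, fewer
than three pairs — are flagged, never silently dropped.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes, not
the physiology beneath it. Per subject, a two-state per-minute chain with
geometric dwell times produces the latent rhythm sequence: entry into AF at
a base rate (default 1/400 per minute) scaled by a per-clock-hour circadian
multiplier (default 1.3 by day, 0.55 by night, giving the day-dominant
asymmetry seen in circadian burden statistics) and by a subject-level
log-normal frailty (default SD 1, mean 1) that spreads the cohort from
AF-free through paroxysmal to persistent-like patterns; exit at rate 1/40
per minute makes episodes a mix of short runs with a tail beyond one hour.
Geometric dwells are the simplest process whose burden and episode-length
mix are controllable; the defaults are fixtures chosen to look like a
paroxysmal-AF clinic population, not estimates of any real cohort.

Each minute then receives a beat count and rate (sinus
$\mathcal N(75, 8)$ bpm; AF minutes exceed 120 bpm with probability
`p_rvr = 0.15`, drawn above-threshold from a shifted exponential and
otherwise from a below-truncated $\mathcal N(100, 12)$) and an AF-beat
fraction drawn per state (Beta means ≈0.9 in AF, ≈0.05 otherwise,
constrained away from the 0.40 boundary so the derived labels reproduce the
latent state exactly — the reference annotation is definitionally
consistent with the truth). The device stream shares the gold minute's
physiology; its label is flipped with probability $1-\text{sensitivity}$
(AF minutes) or $1-\text{specificity}$ (non-AF), flipped minutes get their
AF-beat count redrawn on the other side of the rule, and each minute is
masked invalid with probability $1-\text{output rate}$. Defaults
(0.915 / 0.972 / 0.866) are set at the operating point a validated
smartwatch algorithm reports. An optional beat mode emits pulse-level
series (respiratory-modulated sinus intervals against uniformly dispersed
AF intervals, with Bernoulli artifact masking) to exercise the windowed
detector end to end.

Seeding is strict: a master seed yields per-subject seeds through one
`sample.int` draw recorded in the manifest; no global RNG state leaks
(caller state is saved and restored), and identical configurations produce
byte-identical outputs.

What the generator does **not** emulate: optical waveform morphology and
its artifact structure, atrial flutter or AV-block confounders,
autocorrelated (burst-like) detection errors — the channel flips minutes
independently — and drift in device rate estimates. Tests passing on this
cohort therefore demonstrate the correctness and calibration of the
*analysis*, not the clinical accuracy of any detector on real signals.

## Problem sizes and numerical choices

The test suite verifies episode extraction, hourly tallies, MAE, Spearman
(with ties), exact Mann–Whitney and pairwise-ordering AUC against
independent brute-force oracles on over a thousand randomly generated small
instances, and runs cohort-level checks on a 50-subject × 1440-minute
simulated cohort — sizes at which every Monte-Carlo band used in the
assertions is comfortably narrow. Density values are clamped to $[0,1]$
against floating-point overshoot at the extremes; the stationary occupancy
of the rhythm chain is used to initialise the first minute, so short
records are unbiased. Burden metrics raise explicit errors on timelines
with zero valid minutes rather than returning silent zeros.

## Limitations

The detector stand-in is calibrated on idealised interval distributions and
makes no claim of parity with trained production classifiers. The
observation channel's independence assumption understates the clustering of
real device errors, which will make cohort MAE look better than a field
deployment. Only single-session (one recording per subject) analyses are
supported; longitudinal burden trajectories are out of scope.
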