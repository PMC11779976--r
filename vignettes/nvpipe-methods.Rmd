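---
title: "Methods: quantifying neurovascular function from imaging data"
author: "nvpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying neurovascular function from imaging data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`nvpipe` implements the full quantification chain used in awake-mouse
neurovascular imaging studies of the APOE3/APOE4 x exercise design: from
two-photon vessel movies, line-scan kymographs, Oxy-CBF probe traces,
calcium traces, home-cage tracking tables and post-mortem vessel stacks
through to derived measures — diameter and velocity time series, vasomotion
power, stimulus responsiveness, CMRO2, the neurovascular coupling index,
vascular and pericyte densities, daily running distance, and the Fisher-Z /
PCA statistics that tie the measures together. A synthetic-data module
generates every input with known ground truth, so the whole chain is
testable without any raw recording. This vignette explains the models and
the choices behind each stage.

## Vessel diametry (FWHM along skeleton perpendiculars)

The mean image of a registered movie is Otsu-thresholded, the largest
connected component is kept, and a one-pixel centreline is extracted by
homotopic thinning. Tangents come from a local principal-direction fit over
a sliding window of 5 skeleton points (an odd window keeps the tangent
centred; shorter windows are noisy, longer ones round off bends). At every
skeleton point and every frame, an intensity profile is sampled
perpendicular to the tangent by bilinear interpolation, one sample per
pixel, over a half-width of twice the expected diameter (so both
half-maximum crossings always lie inside the profile for physiological
dilations).

The diameter of a profile is its full width at half maximum: the baseline
is the mean of the outer 10% of samples on each side, the half-maximum
level is `baseline + (peak - baseline)/2`, and the two crossings flanking
the global peak are found by linear interpolation after a 10x cubic-spline
refinement of the profile. The refinement matters: with a transition
spanning ~1 pixel, plain linear interpolation between adjacent samples
biases a Gaussian profile's width by ~4%, while the spline-refined crossing
is accurate to better than 1% for Gaussian sigma down to one pixel.
Profiles whose crossings fall outside the sampling window are flagged
(reason codes `no_left_crossing` / `no_right_crossing`), and a frame is
invalid when fewer than half of its skeleton points yield a width. Flagged
frames are excluded from averaging and interpolated over only for spectral
analysis.

Thinning artefacts are handled explicitly: boundary bumps from noise anchor
short lateral spurs (the thinning preserves curve endpoints, so a
single-pixel bump survives as a whole branch); spurs shorter than ~1.5x the
vessel half-width are pruned before tangents are computed.

## Red blood cell velocimetry (radon projection variance)

Moving cells leave dark streaks in a line-scan kymograph; the streak slope
is displacement per scan line, so velocity is
`slope x pixel_size x line_rate` (motion toward increasing position index
is positive). The classic estimator finds the angle at which the variance
of the image's line integrals (radon projections) is maximal. `rbcv_radon`
implements exactly that statistic, but parameterised directly by slope
rather than angle: at steep streak angles (fast cells) a fixed angular step
maps to a rapidly growing velocity step, whereas a logarithmic slope grid
keeps the relative velocity resolution uniform. The search is a two-sided
log-spaced coarse sweep (40 slopes per sign spanning 2 px/window to half
the scan width per line) followed by multiplicative refinement from the
three best coarse candidates (final step ~0.15%); the multi-start guards
against secondary bumps in the variance curve at steep slopes.

Each 128-line window (50% overlap) is mean-subtracted and tapered with a
2D Hann window before projection. The taper is load-bearing: without it,
the number of in-bounds samples per projection offset varies with the
candidate slope, which systematically biases the variance peak by several
percent at high velocities; with the taper every offset has identical
support and out-of-bounds samples contribute zero.

Window quality is the ratio of peak to median projection variance over the
coarse sweep, compared against the same statistic computed on a
deterministically shuffled copy of the window (a no-signal surrogate). A
window is flagged when its contrast fails to exceed twice the surrogate's —
pure-noise kymographs flag every window rather than reporting spurious
velocities.

## Stimulus-locked trials and responsiveness

Traces are cut into 30-s trials: 5 s baseline, 5 s stimulus, 20 s post.
Trials overlapping the recording edges are kept as rows but excluded with
reason `partial`. Locomotion gating excludes any trial during which speed
exceeds `speed_eps` (default 0: any encoder motion counts as running)
anywhere in the 2 s before or during the stimulus; the post-stimulus
interval is deliberately not gated. Trials are normalised to the mean of
the final 1 s of baseline — divisively for diameter and haemodynamic
signals (percent change), subtractively for ΔF/F calcium, whose near-zero
baseline makes division meaningless.

Per-trial metrics follow the 2-SD rule: the baseline SD is computed over
the full 5 s baseline of the normalised trial, the maximum peak and
trapezoidal AUC over the 5 s stimulus window, and a trial is responsive
when its peak exceeds twice the baseline SD. Responsiveness is the percent
of *retained* trials responsive. Both surfaces are exposed: per-trial
metrics (for responsiveness) and metrics of the mean normalised trace
(for group-average response figures).

One property of the 2-SD rule deserves emphasis: on pure white noise at
7.63 Hz the expected responsive fraction is `1 - pnorm(2)^38`, about 58% —
the rule compares the *maximum* of 38 stimulus samples against a 2-SD
threshold, so the null rate is far above 5%. The test suite calibrates the
implementation against an independent Monte-Carlo oracle of exactly this
event. The consequence for study design is that observed responsiveness is
approximately `0.58 + 0.42 p` where `p` is the true per-trial response
probability: group differences in `p` are compressed by ~2.4x.

## Vasomotion

Spontaneous ~0.1 Hz diameter oscillations are quantified from baseline
(no-stimulus) recordings, running bouts included. The trace is linearly
detrended, Welch's PSD is estimated (Hann taper, 50% overlap, segment
length `sample_rate / df` for a default resolution of `df = 0.01` Hz),
linearly interpolated onto a common frequency grid that contains 0.1 Hz,
truncated above 1 Hz, and read out at the grid point nearest 0.1 Hz.
"Relative power" divides that value by the total power at or below 1 Hz,
making the readout unit-free across vessels of different calibre. When a
trace is too short for two overlapping segments at the requested
resolution, the segment length is reduced to two-thirds of the trace with
a warning; the hard error fires only when even that cannot resolve 0.1 Hz
(segment under 20 s). No pwelch-style estimator ships with the available
toolchain, so the Welch mean-of-tapered-periodograms estimator is
implemented in the package on top of `stats::fft`.

## Haemodynamics

`CMRO2 = CBF x Hbd / Hbt`, evaluated per sample and then averaged (the
alternative — averaging channels first — differs only at second order in
the fluctuations; per-sample evaluation keeps the quantity defined under
channel drift). Rest baselines average each channel over the union of all
no-locomotion periods of at least 10 s, which weights periods by duration.
Baseline values are normalised to the mean of the reference group
(exercising APOE3 mice) within each timepoint, to cancel probe-sensitivity
drift between cohorts; `Hbt ≈ Hbo + Hbd` is validated with a 5% warning
(not an error — real probes drift).

## Calcium analysis and the coupling index

Baseline event statistics detect excursions above `median + 3 x MAD`
within each rest period; each excursion contributes one event and its
maximum. Counting excursions rather than raw local maxima keeps noise
wiggles riding on an indicator decay tail from being counted as separate
events. Rates are per minute, averaged across rest periods weighted by
duration.

Cells are classified from trial-averaged, baseline-subtracted traces: the
on-flag uses the 5 s stimulus window and the off-flag the 5 s after
offset, both against the same 2-SD threshold (floored at 1% of the trace's
dynamic range so that, in the noiseless limit, indicator decay tails are
not called responses). `BOTH` requires both flags, `NONE` neither.

The neurovascular coupling index divides each vessel's stimulus AUC by the
mean neuronal AUC of its genotype (the default grouping, because calcium
data is not available for every animal; finer grouping is a config
option). The index is linear in the vessel AUC and inversely proportional
to the neuronal mean, so a shared drive scaling both vascular and neuronal
responses cancels — the defining property the index exists for. The mean
is taken over all cells by default (restricting to ON/BOTH cells is an
option).

## Ex vivo morphometry

Stacks are denoised by a 3-plane running mean along z and binarised with
the classical histogram threshold family (IsoData/"Default", Huang, a
quadratic-fuzziness Huang variant, Li). The original workflow had a
blinded observer pick the best of the four; the package substitutes a
deterministic score — fraction of foreground in the largest connected
component divided by boundary roughness — and logs every candidate's score
and threshold. Roughness is measured against a majority-smoothed copy of
the same mask, so it penalises speckled boundaries without rewarding plain
dilation (a surface-to-volume ratio would prefer fatter masks).

Skeletonisation is distance-ordered homotopic thinning with 3D
simple-point tests (26-connectivity for foreground, 6 for background) and
six directional subiterations peeling true border voxels (background on
the direction side, foreground opposite). The directional peeling prevents
even-width structures from zippering away; an infinitesimal coordinate
gradient added to the distance-map priority breaks exact medial ties so
the centreline does not wander between equivalent layers. Remaining
voxel-scale artefacts are cleaned in graph space: chord edges whose
endpoints stay connected by a short alternative path are removed, and
terminal spurs below 5 µm are pruned. Total centreline length is measured
on moving-average-smoothed branch paths, which removes the staircase
quantisation excess (up to +40% for oblique tubes if summed naively);
branch points are skeleton voxels with three or more neighbours, merged
into clusters when adjacent. Length density is reported as mm of vessel
per mm^3 — the field's convention when no unit is stated.

Radii are the anisotropy-aware Euclidean distance transform sampled at
skeleton voxels (accurate to about one voxel — the dominant resolution
limit for capillary-scale constrictions; the phantom tests use 0.45 µm
in-plane voxels, matching the stated confocal resolution, for this
reason). Pericyte somata are read from a coordinates table, snapped to the
nearest skeleton point within 5 µm, and capillary diameter is profiled
against *path* distance along the skeleton (not Euclidean distance, which
would fold bends), in 2 µm bins out to 50 µm, with the sign distinguishing
the two directions the vessel leaves the soma in; points are assigned to
the nearest soma by path distance.

## Home-cage activity

Pose tables (tidy or wide three-header export) are filtered at a
likelihood threshold of 1 — the strictest possible rule, honoured as the
default because the upstream workflow used it; the removed fraction is
always reported so its effect is visible. The mouse centroid is the mean
of whatever body labels survive in each frame (head/tail and the two
headplate markers are symmetric in the synthetic generator, so the
centroid is exact when all four are present); the wheel marker is the mean
of its inner and outer labels. Per-frame distance is
`|Δcentroid| + |Δwheel|` in cm, with gaps bridged by differencing across
them. Distances are summed over 10-minute windows, the top and bottom 1%
of the window distribution is trimmed (`floor(trim x n)` per tail — with
fewer than 100 windows nothing is trimmed, with a warning), and daily
totals and per-clock-hour means are computed from the surviving windows.
Wheel displacement is used as measured in the camera plane; no
rotations-to-circumference conversion is attempted.

## Statistics

Pearson correlations of per-mouse measures against exercise use
pairwise-complete observations, 95% confidence intervals from `cor.test`,
and Fisher's transform `Z = atanh(r)`; the Z distribution across measures
is location-tested against zero, and per-measure p-values are
Benjamini-Hochberg adjusted. Exercise is z-scored within timepoint before
correlating (min-max scaling would give identical `r`; the choice is
documented, not consequential).

PCA preparation excludes variables with strictly more than 20% missing
values, imputes the remainder (column mean by default — deterministic; a
seeded iterated-regression scheme is available for users who want
chained-equation-style imputation), standardises, and eigendecomposes the
correlation matrix (variables are on incommensurable scales, so the
covariance matrix would be dominated by units). Components with eigenvalue
strictly greater than 1 are retained; variable contributions are squared
loadings as a fraction per component. Linear mixed models and their ANOVA
are deliberately not reimplemented: the pipeline emits tidy per-vessel and
per-mouse tables that drop directly into `lme4::lmer` with the study's
factor structure (genotype x exercise x timepoint x vessel class, animal
as a random effect).

## The synthetic cohort

`gen_cohort()` writes a study bundle to disk in the pipeline's input
formats: per-vessel stimulus and baseline diameter traces, calcium traces,
haemodynamic recordings, locomotion, an optional pose-tracking table, the
stimulus schedule and a ground-truth manifest. It operates at the trace
level: raw movies, kymographs and anatomy stacks have their own generators
and tests, and re-rendering them for every vessel of every mouse would add
nothing but runtime. Defaults mirror the study conditions: 20 trials of
5 s drifting grating / 25 s grey screen, 7.63 Hz frame-equivalent
sampling, 40 Hz probe channels, a 2x2 genotype-by-exercise design with
responses weakest in sedentary APOE4 mice, 10% peak dilation and 0.85
per-trial response probability in the reference group, ~1.5% vasomotion
amplitude at 0.1 Hz, and gamma-shaped transients (the standard
single-peaked haemodynamic impulse shape). Effect multipliers span
{1, 0.8, 0.6, 0.4} (amplitude) and {1, 0.75, 0.55, 0.35} (response
probability) so that, after the ~2.4x compression imposed by the 2-SD
rule's null rate, observed group responsiveness spans the wide range the
real study reports rather than saturating near 100%. Calcium class
composition is fixed at 50% ON / 20% OFF / 10% BOTH / 20% NONE per mouse,
so the per-genotype neuronal mean reflects the planted amplitude rather
than class-sampling noise.

What the generator does *not* emulate: photon shot noise and detector
artefacts (noise is additive Gaussian), motion artefacts (inputs are
assumed registered; an integer-shift cross-correlation aligner is provided
as a convenience), vessel branching in vivo (one vessel per movie, per the
per-vessel analysis design), and locomotion speed magnitudes (units are
arbitrary; only the zero/non-zero distinction feeds gating). Passing
recovery tests on these constructions therefore validates the estimators'
correctness and calibration, not their robustness to every artefact of
real two-photon data.

## Problem sizes and numerical choices

The test and acceptance workloads use desk-scale sizes chosen to keep the
statistics meaningful: 240 s baseline traces for vasomotion (24 cycles of
0.1 Hz; Welch resolution 0.0125 Hz so the grid contains 0.1 Hz exactly),
384-line kymographs (5 windows at defaults), anatomy phantoms of 10^5-10^6
voxels, 10,000-trial null calibrations, and cohorts of 2-4 mice per group
with 2-4 vessels each over 5-20 seeds for ordering and cancellation
checks. Tie-breaks worth knowing: exactly 7 µm and exactly 12 µm vessels
classify as intermediate (the source ranges are open); the 0.1 Hz readout
is the nearest grid point (the grid is built to contain it); trial length
in samples is rounded once and reused for every trial; and all generator
randomness flows through one seeded RNG per call, with the seed recorded
in the ground-truth manifest.

## Known limitations

Velocimetry assumes a single dominant streak population per window
(no multi-file flow separation), and its per-window precision degrades at
the fast end: at 5 mm/s a streak crosses a 96-pixel scan in about four
lines, the projection-variance peak becomes a broad plateau, and single
windows can err by ~5-7% even though slower velocities recover to well
under 1%; longer scan lines are the only real remedy. The skeleton length estimator is accurate
to ~5% for oblique vessels (voxel quantisation after smoothing). The
distance-map radius is quantised at the voxel scale, which bounds how
small a pericyte constriction can be resolved. The deterministic threshold
chooser is a reproducible heuristic, not a re-implementation of a human
judgement; on low-contrast stacks it can prefer a different member of the
threshold family than an observer would. The 2-SD responsiveness rule's
high null rate is a property of the rule itself, faithfully implemented.
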