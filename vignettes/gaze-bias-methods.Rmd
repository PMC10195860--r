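---
title: "Measuring spatiotemporal gaze bias toward visual features"
author: "GazeBias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring spatiotemporal gaze bias toward visual features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GazeBias)
```

## The analysis in one page

`GazeBias` relates where and when people fixate during free viewing to
the spatial distribution of visual features in the viewed image. Its
inputs are (a) fixation event tables — pixel coordinates and
millisecond on/offsets per participant and stimulus — and (b) one
feature-intensity map per stimulus and feature. Feature maps can come
from three sources, all sharing the `FeatureMap` container: noise-averaged
gradient back-projection of a convolutional layer (`smoothGradMap()`),
the package's from-scratch bottom-up saliency model
(`ittiKochSaliency()`), or the synthetic generator (`genFeatureField()`).

Each map is min–max rescaled per stimulus and cut into ten equal-width
intensity levels; levels of the same feature are analyzed as separate
features, because gaze effects are expected to grow with feature
intensity. For every fixation the *gaze attraction* is the occupancy
rate of a level inside the 1°-radius fixation area divided by its
occupancy rate in the whole image, so that 1 is chance by construction
regardless of how much of the image a level covers. Writing each
fixation's value over its duration yields a per-millisecond time course
per trial; averaging over a participant's stimuli gives the
participant's time course, and two scalar indices summarize it:

* **spatial gaze bias** = mean of the course over the full trial grid
  (zeros between fixations included);
* **temporal gaze bias** = area under the min–max-normalized cumulative
  integral of the min–max-normalized course, in [0, 1]; early mass
  gives values above 0.5.

Chance levels are obtained by redrawing every fixation's coordinates
uniformly over the stimulus, keeping all timing, recomputing the
participant course, and averaging 100 such replicates; the two indices
of the averaged course are the matched chance values.

## Conventions and tunable parameters

| parameter | default | meaning |
|---|---|---|
| `radius_deg` | 1.0° | fixation-area radius; covers foveal extent (~2° diameter) and tracker accuracy (~1°) |
| `n_levels` | 10 | equal-width intensity levels on the rescaled map |
| `threshold_ms` | 80 ms | anticipatory-fixation exclusion: onsets earlier than this cannot be stimulus-driven |
| `grid_ms` | 1 ms | time grid, matching a 1000 Hz recording |
| `n_randomizations` | 100 | coordinate reassignments behind the chance level |
| geometry | 800×600 px, 20°×15°, 86 cm, 5000 ms | display assumed by the defaults; any geometry is accepted |

Pixel conventions are fixed once and documented so counts are
bit-stable: coordinates are 0-based with pixel centers at integers, the
stimulus window is half-open (`[0, width)`), a pixel belongs to the
fixation disk when its center is within the radius (Euclidean), and the
disk is clipped at the stimulus bounds. Out-of-bounds fixations are
dropped, not clipped — gaze that left the stimulus cannot be mapped to
its features. The anticipatory cut is strict (`onset < 80` removed; 80
kept), the standard convention for anticipatory saccades. Fixations
straddling the stimulus offset are truncated at the trial end, since no
feature is visible afterwards.

Two choices deserve emphasis because they shape the time course.
First, a fixation's gaze-attraction value persists over its full
duration rather than marking only its onset millisecond; an onset-only
delta train would integrate to nearly zero and could not produce
continuous time courses (an `onset_only` switch retains the
alternative). Second, when a feature level does not occur anywhere in
an image, its gaze attraction is undefined there, and that image is
excluded from that level's average rather than counted as zero —
zero would conflate "the feature is absent" with "the feature was
avoided".

## Feature attribution defaults

The back-projected scalar is the plain sum of the layer's rectified
activations: it makes the gradient linear in the per-unit gradients and
is the cheapest faithful choice when the target is "all units of the
layer" rather than any single unit. Noise averaging uses 50 samples
with a noise SD of 0.10 of the input dynamic range — standard practice
for noise-averaged gradient attribution. Gradients are taken per color
channel, converted to magnitude (sign is irrelevant to feature
*intensity*), averaged over channels, then over noise samples. If an
extractor declares a native input size, images are resized to it and
maps resized back, both bilinearly; this slightly smooths pixel counts
and is therefore documented rather than hidden. All of these are
exposed as arguments.

The bundled extractors are deliberately small: `tinyConvnetFixture()`
is a two-layer, bias-free, rectified convolutional network with seeded
fixed weights whose analytic gradient is validated against central
finite differences in the test suite, and `linearExtractor()` is a 1×1
convolution whose back-projected map has a closed form. A pretrained
object-recognition network can be plugged in through the same
`FeatureExtractor` contract; nothing in the package requires one.

## The saliency model

`ittiKochSaliency()` implements the classic multiscale architecture: a
9-scale Gaussian pyramid (5×5 binomial filter, decimation by 2),
center–surround differences between center scales {2, 3, 4} and
surrounds at scale offsets {3, 4}, three channels (intensity = RGB
mean; color = red–green and blue–yellow opponency with an intensity
gate at a tenth of the maximum; orientation = quadrature Gabor energy
at 0°, 45°, 90°, 135°, wavelength 7 px), per-map normalization, channel
summation at scale 4, and an equal-weight combination of the three
conspicuity maps, upsampled bilinearly to stimulus resolution. The map
normalization rescales to [0, 1] and multiplies by
`(1 − mean of the other local maxima)²`, promoting maps with one
dominant peak and suppressing maps with many rivals.

Out-of-image surround is handled by replicate-padded convolutions, and
each center–surround map is then explicitly attenuated over a thin
border ramp — the referenced model family's own treatment of locations
whose surround is partly undefined. This is kept, not corrected,
because it is a real property of such saliency maps: saliency is
systematically low near stimulus edges, which, combined with the human
center bias and a chance level drawn uniformly over the *whole*
stimulus, is exactly what pushes low-intensity saliency levels below
chance. The test suite asserts this artifact (border band darker than
the interior on seeded noise images) rather than patching it away.

Two numerical guards matter here. Convolutions are FFT-based, so a
featureless map comes back with ~1e-16 ripple; the normalization
operator treats any map whose dynamic range is below 1e-9 as constant,
otherwise the min–max rescale would amplify roundoff into spurious
structure. And images must be at least 256 px on each side for the full
9-scale pyramid; smaller inputs raise an error naming the minimum
rather than silently shrinking the model.

## Temporal bias: normalization anchors and degenerate inputs

The cumulative integral is trapezoidal on the millisecond grid, and the
final area is taken over normalized time, which makes the index
duration-invariant. A constant course has no temporal structure and is
defined to give 0.5 — the limit of vanishing transients — rather than
NaN.

One property of the double normalization is worth spelling out. For a
parametric course `b + A·exp(−(t − t_peak)²/(2s²))` on a strictly
positive baseline, min–max normalization removes both `b` and `A`
exactly, so the index cannot depend on the transient amplitude.
Measured gaze-attraction courses are not like that: they are exactly
zero before the first fixation ever lands (about 270 ms in), so their
minimum is anchored at zero and the baseline survives normalization at
height `b/(b + A)` — a larger transient then genuinely shifts
normalized mass toward the early peak. `hypotheticalGATimeCourse()`
therefore includes a zero-valued head (default 270 ms) so the validation
courses share this anchoring; with it, the index decreases strictly as
`t_peak` moves from 500 to 4500 ms and increases strictly with `A` at an
early peak, which the acceptance checks sweep over ten points each.

## Chance levels and their calibration

Chance coordinates are drawn over the full stimulus, edges included —
faithful to how fixation-map chance levels are normally built, and the
very reason the saliency edge artifact surfaces as below-chance values.
Because clipped border disks make the expectation analytically awkward,
the calibration test uses an explicitly edge-free variant: `wrap = TRUE`
evaluates disks on a torus and draws centers over a full torus period.
In that setting the reassigned disk is an exactly uniform translation,
so the expected gaze attraction is exactly 1 at every level; at 10⁴
reassignments the measured chance spatial bias matches to within three
Monte-Carlo standard errors, and the averaged chance course's support
equals the original timing support exactly (timing is never touched).
Replicate draws live in one seeded stream per participant, derived from
the master seed, so enlarging a cohort never reshuffles existing
participants' chance draws.

## Inference

The bias tables are analyzed with a within-participant two-way ANOVA
(factors: feature and intensity level, one observation per participant
and cell, participant error strata); a plain fixed-effects variant is
available for comparison since the appropriate error model for such
summary tables is a genuine judgment call. Pairwise feature contrasts
are paired t-tests on participant-wise feature means with Bonferroni
correction (`min(1, p·m)`). The first-fixation comparison is the
one-way within-participant analogue. Degenerate tables (zero variance)
short-circuit to F = 0 rather than 0/0.

Transient peaks are localized by comparing, at each time point outside
the steady-state window (the last 1000 ms), participants' values with
their own steady-state means via a one-sided paired t-test; within the
contiguous p < 0.05 region(s), the group-mean maximum is the peak. No
correction across time points is applied — deliberately liberal, and
appropriate for peak localization rather than existence testing.
The type-I behavior of the feature effect is checked by simulation: on
exchangeable null tables the rejection rate at α = 0.05 stays near 5%.

## What the synthetic generator does and does not emulate

`simConfig()`/`genCohort()` simulate the full experiment: smooth
per-stimulus feature fields (periodic Gaussian-blurred uniform noise —
stationary, no edge artifacts, all ten levels occupied), and scanpaths
whose fixation locations are softmax draws over pixels with log-weights
`Σ_f β_f · g_f(t) · intensity_f(x, y)`, where
`g_f(t) = b + A_f·exp(−(t − t_peak)²/(2s²))` is a feature-specific
time-varying gain. Sampling is exact (no MCMC), which keeps every trial
bit-reproducible from its derived seed. Fixation durations are gamma
(shape 4, scale 62.5 ms: mean 250 ms), consecutive fixations are
separated by a fixed 30 ms saccade-flight gap, first-fixation latencies
are normal (270 ± 40 ms), and anticipatory events (< 80 ms onset) are
injected with a configurable probability. Defaults encode the cohort the
analysis is designed around: 20 participants, 30 stimuli, 5000 ms
trials, spatial gains ordered 1 < 2 < 4 over three features, and an
early (500 ms, width 200 ms, amplitude 1.5) transient on the third
feature only.

The generator validates the estimators — higher true β must yield
higher measured spatial bias, an earlier/stronger transient must raise
the temporal bias, unbiased scanpaths must sit at chance. It does not
claim biological realism: there is no inhibition of return, no saccadic
undershoot or amplitude statistics, no blink structure, and feature
fields are statistically stationary unlike natural scenes. Passing
these checks shows the statistics recover known structure under the
model's assumptions, not that any particular real dataset will show
such structure.

Validation problem sizes are part of the package's own test design: the
recovery cohort runs 20 × 30 trials on a 200 × 150 px grid (10 px/°, so
the geometry of the 20° × 15° display is preserved at reduced
resolution), chance calibration uses 10⁴ reassignments on a 120 × 120
grid, and saliency properties use 256 × 256 images, the smallest size
admitting the full pyramid.

## Known limitations

* Numeric equality with any particular historical saliency toolbox is
  not promised — parameters follow the published model family, and only
  family-level behavior (pop-out, edge attenuation, normalization
  dynamics) is asserted.
* The repeated-measures ANOVA assumes a balanced participant × feature
  × level table; unbalanced tables are rejected, not silently pooled.
* Transient-peak localization reports raw-threshold regions; with many
  time points the region boundaries are liberal even though the peak
  location itself is stable.
* The pipeline treats feature maps as given per stimulus; dynamic
  stimuli and gaze-contingent displays are out of scope.
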