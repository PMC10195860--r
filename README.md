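# GazeBias

Quantifying how strongly — and how early — the human gaze is attracted to
visual features of different hierarchical complexity during free viewing
of natural scenes.

When people inspect a scene, fixations cluster on some locations and
arrive at them at characteristic times. `GazeBias` measures this
spatiotemporal bias with respect to any per-pixel *feature map*: gradient
back-projections of convolutional network layers (low-level edges up to
object-like structure), a classic bottom-up Itti–Koch saliency map (built
into the package from scratch), or arbitrary user-supplied intensity
fields. It is written for eye-movement researchers who have fixation
event tables and stimulus images and want per-participant statistics that
can go straight into a factorial analysis.

## The statistic

Every feature map is min–max rescaled per stimulus and discretized into
ten equal-width intensity levels L. For a fixation at time t on image
I_n, the **gaze attraction** of feature F at level L is the relative
occupancy rate

    GA(F_L, t, I_n) = ( N_FL^FA / N_all^FA ) / ( N_FL^In / N_all^In )

where the numerator is the share of level-L pixels inside the fixation
area (a 1° circular region around the fixated point, matching foveal
extent and tracker accuracy) and the denominator is the share of level-L
pixels in the whole image. GA = 1 means the fixation area contains the
feature at exactly its image-wide density; GA > 1 means the gaze is drawn
to it. Averaging over images yields a millisecond time course GA(F_L, t)
per participant, from which two indices are derived:

* **spatial gaze bias** — the time average of GA(F_L, t): how strongly
  the feature draws fixations overall;
* **temporal gaze bias** — the area under the doubly min–max-normalized
  cumulative integral of GA(F_L, t): values above 0.5 mean the feature
  draws gaze early, 0.5 means no temporal structure.

Chance levels are empirical: fixation coordinates are redrawn uniformly
over the stimulus while their timing is kept, 100 times, and the
averaged randomized course is summarized the same way. Fixation-order
and latency summaries, repeated-measures ANOVA with Bonferroni pairwise
comparisons, and steady-state-referenced transient-peak detection
complete the analysis. A synthetic-data module simulates the entire
experiment — feature fields, scanpaths with known spatial and temporal
bias gains, gamma fixation durations, realistic first-fixation latencies
and anticipatory events — so every statistic can be validated against
ground truth.

## Worked example

Simulate a small cohort whose scanpaths are biased toward three synthetic
features with gains 1, 2 and 4, then recover the bias structure:

```r
library(GazeBias)

geom <- ViewingGeometry(width_px = 120, height_px = 90,
                        width_deg = 20, height_deg = 15)
cfg  <- simConfig(n_participants = 4, n_stimuli = 8,
                  geometry = geom, master_seed = 7)
cohort <- genCohort(cfg)
bias   <- cohortBiasTable(cohort)

aggregate(cbind(spatial_bias, temporal_bias) ~ feature,
          subset(bias, level == 10), mean)
#>    feature spatial_bias temporal_bias
#> 1 feature1     1.428024     0.5797639
#> 2 feature2     1.555571     0.4499971
#> 3 feature3     4.142185     0.5325215

twoWayAnovaPairwise(bias, "spatial_bias")
#> AnovaResult (two-way repeated-measures ANOVA)
#>          effect         F            p
#> 1       feature  43.49444 2.686339e-04
#> 2         level 103.52027 1.420286e-18
#> 3 feature:level  20.01740 1.028411e-17
#> Bonferroni pairwise comparisons:
#>                   pair           t       p_raw p_corrected significant
#> 1 feature1 vs feature2  -0.6079052 0.586181699 1.000000000       FALSE
#> 2 feature1 vs feature3  -8.5101633 0.003407844 0.010223532        TRUE
#> 3 feature2 vs feature3 -10.2357784 0.001987848 0.005963545        TRUE
```

At the top intensity level the strongest-gain feature (`feature3`,
gain 4) shows a spatial gaze bias of about 4.1 — its level-10 pixels are
four times denser inside fixation areas than in the images overall —
and the feature effect survives the repeated-measures ANOVA with
Bonferroni-corrected pairwise significance against the weaker features.
With only four participants the 1-vs-2 contrast is not yet separable,
as the pairwise table shows.

For real data, `readFixations()` loads a fixation CSV
(`participant,stimulus,x_px,y_px,onset_ms,offset_ms`), `smoothGradMap()`
back-projects any extractor implementing the `FeatureExtractor` contract,
`ittiKochSaliency()` computes bottom-up saliency, and `runPipeline()`
drives the whole analysis from a YAML config.

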