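# DropletCascade

Quantitative analysis of time-lapse bright-field microscopy from
droplet-microfluidics crystallization screens. Each aqueous droplet on the
chip is an independent nanolitre reactor in which amorphous calcium
carbonate (ACC) precipitates and may transform into a crystalline
polymorph — vaterite (spherical) or calcite (rhombohedral). The package
segments droplets and their few-pixel crystal inclusions, classifies each
droplet's content, and estimates the transformation kinetics.

The pipeline:

1. **Cascaded binary U-Nets** — stage 1 segments droplets from raw frame
   tiles; its binarized mask is *overlaid* on the frame (all non-droplet
   pixels set to black), removing background contrast and the
   dominant-feature imbalance; stages 2 and 3 then segment vaterite and
   calcite independently on the overlaid image. The U-Net (forward,
   backprop, Adam) is implemented in Rcpp/Armadillo; no external
   deep-learning framework is needed.
2. **Tiling** — large frames are cut into at most a 3×3 grid (≤ 2 cuts
   per axis, to limit seam artifacts), resized for the network, and
   reassembled after prediction.
3. **Counting** — probability maps are binarized by two-cluster K-Means
   (higher-centre cluster = foreground) and objects counted by
   connected-component labeling with a minimum-area filter.
4. **Per-droplet classification** — droplet contours are delimited by
   minimum enclosing circles (Welzl's algorithm on the boundary hull);
   each crystal component is assigned to the droplet whose inflated
   circle contains its centroid, giving per-frame counts of droplets
   containing ACC, vaterite or calcite.
5. **Kinetics** — the pooled ACC droplet count N(t) is fit with the
   exponential-plateau model

   N(t) = A·e^(−k·t) + C

   in count or ratio form by Levenberg–Marquardt least squares; the
   transformation rate k (min⁻¹), the plateau, the end-of-run ACC
   fraction and a half-life statement (exact / lower bound / unreachable)
   are reported.

A seeded synthetic scene and time-lapse generator with exact ground-truth
masks and a known transformation rate makes the full pipeline testable end
to end without any external data.

## Worked example

Simulate a 12-location, 17-timestep experiment (~660 droplets) with a
true transformation rate of 0.027 min⁻¹ and a 10% labile population,
assemble the pooled ACC time series, and fit the ratio-form decay:

```r
library(DropletCascade)

kin <- KineticsSpec(kTrue = 0.027, labileFraction = 0.1)
tl  <- generateTimelapse(SceneSpec(dropletsPerFrame = 55L), kin,
                         seed = 1, render = FALSE)
ts  <- assembleTimeseries(tl$counts)
head(ts, 3)
#>   timestep_index mean_time_min time_min time_max N_d N_d_ACC n_locations
#> 1              1          8.25      0.0     16.5 660     650          12
#> 2              2         30.75     22.5     39.0 660     627          12
#> 3              3         53.25     45.0     61.5 660     615          12

fit <- fitDecay(ts$mean_time_min, ts$N_d_ACC / ts$N_d, form = "ratio")
fit
#> DecayFit (ratio form): N(t) = 0.09613 * exp(-0.0277 t) + 0.9087
#>   RSS 7.549e-06 over 17 points
```

The fitted rate (0.0277 min⁻¹) recovers the generating 0.027 min⁻¹, and
the plateau ≈ 0.91 says that about 91% of droplets still contain ACC at
the end of the run:

```r
round(evaluateFit(fit, 360), 3)
#> [1] 0.909

halfLifeBound(fit = fit)
#> HalfLifeBound (model): t1/2 unreachable under the fitted model
```

With the fitted plateau above one half, the ACC fraction never reaches
0.5 under the model; a late manual count gives the empirical statement —
443 of 653 droplets still amorphous after 24 h:

```r
accFraction(443, 653)
#> [1] 0.678
halfLifeBound(series = data.frame(time = 1440, fraction = 0.678))
#> HalfLifeBound (empirical): t1/2 > 1440 min
```

Training and running the segmentation cascade on synthetic scenes, and the
`simulate` / `train` / `predict` / `analyze` / `end2end` subcommands of
the CLI wrapper (`inst/cli/droplet-cascade.R`, YAML-configured; see
`inst/extdata/config-example.yaml`), are described in the methods
vignette (`vignettes/droplet-cascade-methods.Rmd`).

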