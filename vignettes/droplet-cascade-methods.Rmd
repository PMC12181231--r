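---
title: "Methods: cascaded segmentation and transformation kinetics for droplet microfluidics"
author: "DropletCascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cascaded segmentation and transformation kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Droplet microfluidics turns a crystallization experiment into thousands of
independent nanolitre reactors: each aqueous droplet, suspended in oil on a
chip, precipitates amorphous calcium carbonate (ACC) which may later
transform into a crystalline polymorph — metastable vaterite (spherical) or
stable calcite (rhombohedral). Time-lapse bright-field microscopy of the
chip yields very large RGB frames in which droplets are large, bright,
high-contrast objects while the crystals of interest span only a few pixels
at analysis resolution. Counting, over time, how many droplets still
contain only ACC gives direct access to the transformation kinetics.

Two obstacles make this a poor fit for a single segmentation network:

* **Feature imbalance** — a 1–3 px crystal competes against droplets that
  are thousands of pixels each, and against a textured background; a
  jointly trained model drifts toward the dominant class.
* **Background contrast** — chip features and illumination gradients mimic
  the intensity excursions of crystals.

`DropletCascade` addresses both with a *cascade* of three binary U-Nets:
stage 1 segments droplets from the raw frame; its binarized output is
*overlaid* on the frame (every non-droplet pixel set to black), and stages
2 (vaterite) and 3 (calcite) run independently on the overlaid image, which
now contains droplet interiors and nothing else. Binary outputs are
binarized by two-cluster K-Means, objects are counted by
connected-component labeling, droplets are delimited by minimum enclosing
circles, crystals are assigned to droplets by centroid containment, and the
ACC droplet count over time is fit with an exponential-plateau model.

# The network

No deep-learning framework is required: the package implements a compact
U-Net (forward pass, backpropagation and Adam) in C++ via Rcpp/Armadillo,
with convolutions realised as im2col + BLAS matrix products. Architectural
choices that the encoder–decoder family leaves open are fixed as follows
and verified by a finite-difference gradient test in the suite:

* two zero-padded 3×3 convolutions + ReLU per resolution level;
* 2×2 max pooling between encoder levels; filter counts double per level
  (`baseFilters * 2^(level-1)`);
* nearest-neighbour 2× upsampling followed by skip concatenation on the
  decoder path (an upsample-then-convolve decoder avoids checkerboard
  artifacts of transposed convolutions and keeps backpropagation simple);
* a 1×1 convolution with sigmoid output; no normalisation layers (the
  networks trained here are small and Adam handles the conditioning);
* He-normal weight initialisation, seeded, so parameter counts and
  training runs are exactly reproducible;
* Adam on binary cross-entropy. Losses are reported either summed over
  pixels (`lossMode = "sum"`, the default, matching the magnitude
  convention of the published per-model error table) or as per-pixel
  means; comparisons must use one mode consistently.

Input spatial dimensions must be divisible by `2^(nEncoders - 1)`;
[cutAndResize()] enforces this on request and the model itself rejects
incompatible inputs with the required divisor in the message.

`unetPresets()` exposes the three published stage configurations
(5/32, 6/64, 5/64 encoders/filters with their learning rates, batch sizes
and epoch counts) as configuration presets. They are *presets, not test
requirements*: the test suite and examples run `deskUnetSpec()`-sized
networks (2–3 levels, 4–8 filters, tens of epochs) that train in minutes
on one CPU.

Training applies an 80:20 train/validation split by default, seeded
augmentation on training samples only (horizontal/vertical flips,
90° rotations on square tiles, ±5% brightness jitter), and returns the
best-on-validation weights with the full loss trace. With a single labeled
pair the validation set degenerates to the training pair; this is accepted
so that smoke-scale experiments remain possible.

Whether the stage-1 output should be binarized before the overlay or used
as a soft mask is genuinely open; the package binarizes first, with the
same K-Means binarizer used for counting, so that the overlay is exactly
the mask later used to delimit droplets.

# Tiling

Very large frames are cut into a grid of at most `(2+1)×(2+1)` tiles —
more cuts are rejected, because every seam is a reconstruction artifact
risk — and each tile is resized to the network input size (bilinear for
intensity data, nearest-neighbour for masks). Tiles partition the frame
exactly; reconstruction resizes each prediction back to its source
rectangle and reassembles without blending. Round trips are lossless when
no resizing occurs, and label displacement is bounded by the resize scale
factor (tested on rendered disks). The default tile target is 512×512 and
is freely configurable; the tests use 64×64.

# Binarization and counting

Probability maps are binarized by k = 2 K-Means on pixel intensities; the
cluster with the higher centre becomes foreground. Centres are initialised
at the intensity extremes, which for a one-dimensional two-cluster problem
makes Lloyd's iteration deterministic — masks are bit-stable across runs
and platforms, which we value over stochastic restarts. A map whose two
centres are separated by less than 0.1 carries no signal and becomes
all-background; this threshold is the package's choice of "near-constant".

Cluster centres alone cannot yield object *counts*, so counting is
implemented as connected-component labeling (8-connectivity by default,
4 available) followed by a minimum-area filter: 50 px for droplets (a
droplet at analysis resolution is hundreds of pixels), 1 px for crystals
(they may occupy a single pixel). Whether a minimum-area filter was part
of the original counting procedure is not documented; we expose both
parameters. Counts are verified against an independent flood-fill oracle
over dozens of random masks.

# Droplet delimitation and content assignment

External component boundaries are reduced to their convex hull and the
minimum enclosing circle is computed with Welzl's algorithm. A crystal
component is assigned to the droplet whose (2 px inflated) circle contains
its centroid; of several containing circles the nearest centre wins; a
centroid contained by none is an *orphan* — logged, counted, and excluded
from droplet classification. Centroid-in-inflated-circle is deliberately
more robust than exact point-in-contour for 1–3 px crystals sitting at the
mask-resolution droplet boundary. Border-truncated droplets are flagged
but counted, since nothing in the analysis requires excluding them.

Per-frame detections collapse to a time-point row
(`N_d`, `N_vaterite_droplets`, `N_calcite_droplets`, `N_d_ACC`) satisfying
`N_d_ACC + |transformed| = N_d` exactly, orphans included.

# Kinetics

The ACC droplet count (or fraction) over time is fit with
$$N(t) = A\,e^{-kt} + C,$$
unweighted nonlinear least squares via Levenberg–Marquardt
(`minpack.lm::nlsLM`), parameter tolerance `1e-10`, rate constrained
nonnegative, and in ratio form the plateau constrained to [0, 1].
Initialisation is deterministic: `C0 = min(y)`, `A0 = max(y) - C0`, and
`k0` from a log-linear regression of `y - 0.99 C0` on time. A series whose
amplitude is numerically zero short-circuits to the flagged
`A = 0, k = 0, C = mean(y)` "no decay detected" result rather than running
the optimiser against a degenerate surface.

Counts from several chip locations are *pooled* per timestep (not
averaged), the representative time being the mean of the per-location
acquisition times with the span retained — locations are imaged
sequentially, so one "timestep" is really a short time window. Fitting
uses time relative to the start of monitoring.

The half-life of the ACC fraction is reported in three mutually exclusive
forms: exact (`ln(A/(0.5 - C))/k`, when the fitted plateau lies below
0.5), *unreachable* (plateau at or above 0.5 — the fitted model never
crosses one half), or an empirical lower bound (the latest observation
with fraction above 0.5). Parameter uncertainty, which the original
analysis does not report, is available as a seeded 200-resample binomial
bootstrap and is clearly labeled as an additive feature.

# The synthetic world

Every downstream stage is testable without any external data because the
generator produces scenes with exact ground truth:

* bright droplet disks (interior 0.85, 2 px rim at 0.25) of ~170 µm
  diameter at ~0.26 px/µm (radius ≈ 22 px, ±8% jitter), placed without
  overlap by rejection sampling, fully inside the 768×384 px default frame
  (a 3 mm × 1.5 mm field of view), ~55 per frame;
* a background at 0.45 with an illumination gradient and low-frequency
  Gaussian blobs whose amplitude scales with `backgroundContrast` — the
  distractors the cascade must ignore; the real chip's texture is not
  quantified anywhere, so this amplitude is a free parameter with default
  0.5;
* crystals of at most `crystalSizePx` (default 3) pixels: vaterite as a
  small dark disk (0.30), calcite as a darker square (0.06). At 3 px,
  *shape* cannot separate the polymorphs, but their optical contrast can —
  which is faithful to bright-field reality, where the polymorphs are
  visually distinguishable;
* additive Gaussian intensity noise (sd 5/255) on the RGB frame only;
  masks are exact renderings;
* kinetics from a two-population model: a labile fraction (default 0.1)
  transforms with exponential waiting times at rate `kTrue`
  (default 0.027 min⁻¹), the rest never do, so the expected ACC fraction
  is `(1-L) + L e^{-kt}` — an exponential decay onto a plateau whose
  parameters the fitter must recover. The polymorph is Bernoulli
  (`pVaterite = 0.5`; no polymorph ratio is documented for the real
  system). Droplet positions and crystal offsets are fixed per location
  across time; a droplet transformed at τ shows its crystal in every
  frame at t ≥ τ. Locations are imaged sequentially with a 1.5 min lag.

What the generator does **not** emulate: photorealistic droplet optics,
oil-phase physics, droplet shrinkage (none was observed in the real
system), touching droplets (real frames can have them; the counting module
does not split them — a known limitation), drifting illumination, or
crystals straddling droplet boundaries. Passing tests therefore
demonstrate the pipeline's correctness and the method's internal
consistency, not segmentation performance on real microscopy.

# Problem sizes used by the test suite

The suite favours small, exactly checkable configurations: 128×128 scenes
with 5 droplets of radius 11 px for learned-segmentation checks (12
training scenes → 48 tiles of 64×64; 3-level, 8-filter networks; 40–80
epochs; five held-out scenes), 30 seeded simulations of 660 droplets × 16
timesteps for rate recovery, and 17-point noiseless series for fit
self-consistency. These sizes were chosen as the smallest at which each
property is cleanly measurable.

# Known limitations

* The cascade assumes the droplet segmenter is good: crystals outside the
  predicted droplet mask survive stacking (with a warning) but are
  orphaned during classification.
* K-Means binarization is global per frame; strong per-tile illumination
  differences would call for per-tile binarization.
* Droplet identity is not tracked across timesteps; counts are sufficient
  for rate estimation, and tracking is left as an extension.
* The two-population kinetic model is phenomenological; it does not
  attempt mechanistic nucleation modeling or vaterite→calcite ripening.
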