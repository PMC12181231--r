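#' @useDynLib DropletCascade, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom methods new validObject is slot
#' @importFrom stats kmeans rexp runif rbinom rnorm coef lm median sd var
#' @importFrom utils head read.csv write.csv
NULL

.posInt <- function(x) length(x) == 1 && is.finite(x) && x == as.integer(x) && x > 0
.nonNegInt <- function(x) length(x) == 1 && is.finite(x) && x == as.integer(x) && x >= 0
.prob <- function(x) length(x) == 1 && is.finite(x) && x >= 0 && x <= 1

# ---------------------------------------------------------------- SceneSpec

#' Scene specification for the synthetic droplet generator
#'
#' Describes one synthetic bright-field frame: bright circular droplets
#' (dark 2 px rim) on a textured high-contrast background, each droplet
#' optionally containing a single small crystal (vaterite rendered as a dark
#' disk, calcite as a darker square) of at most `crystalSizePx` pixels.
#' Defaults emulate the study conditions: a 3 mm x 1.5 mm field of view
#' imaged at roughly 0.26 px/um (768 x 384 px), ~55 droplets of 170 um
#' diameter (radius ~22 px) and crystals spanning at most 3 px.
#'
#' @slot imageHeight,imageWidth frame size in pixels.
#' @slot dropletRadius mean droplet radius, px.
#' @slot radiusJitter fractional radius jitter (uniform).
#' @slot dropletsPerFrame number of non-overlapping droplets per frame.
#' @slot crystalSizePx maximum crystal extent in px, between 1 and 5.
#' @slot backgroundContrast amplitude in [0, 1] of the background
#'   distractor texture (low-frequency blobs plus an intensity gradient).
#' @slot noiseSd additive Gaussian intensity noise, on the 0-255 scale.
#' @slot rngSeed base seed for scene layout and rendering.
#' @export
setClass("SceneSpec", representation(
  imageHeight = "integer", imageWidth = "integer",
  dropletRadius = "numeric", radiusJitter = "numeric",
  dropletsPerFrame = "integer", crystalSizePx = "integer",
  backgroundContrast = "numeric", noiseSd = "numeric", rngSeed = "integer"
))

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (!.posInt(object@imageHeight) || !.posInt(object@imageWidth))
    msg <- c(msg, "image dimensions must be positive integers")
  if (!(object@dropletRadius > 0)) msg <- c(msg, "dropletRadius must be > 0")
  if (!.prob(object@radiusJitter)) msg <- c(msg, "radiusJitter must lie in [0, 1]")
  if (!.nonNegInt(object@dropletsPerFrame))
    msg <- c(msg, "dropletsPerFrame must be a nonnegative integer")
  if (!(object@crystalSizePx >= 1 && object@crystalSizePx <= 5))
    msg <- c(msg, "crystalSizePx must lie in [1, 5]")
  if (!.prob(object@backgroundContrast))
    msg <- c(msg, "backgroundContrast must lie in [0, 1]")
  if (!(object@noiseSd >= 0)) msg <- c(msg, "noiseSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param imageHeight,imageWidth,dropletRadius,radiusJitter,dropletsPerFrame,crystalSizePx,backgroundContrast,noiseSd,rngSeed see slots.
#' @return A validated `SceneSpec`.
#' @rdname SceneSpec-class
#' @examples
#' SceneSpec(imageHeight = 128L, imageWidth = 128L, dropletsPerFrame = 5L)
#' @export
SceneSpec <- function(imageHeight = 384L, imageWidth = 768L,
                      dropletRadius = 22, radiusJitter = 0.08,
                      dropletsPerFrame = 55L, crystalSizePx = 3L,
                      backgroundContrast = 0.5, noiseSd = 5,
                      rngSeed = 1L) {
  new("SceneSpec",
      imageHeight = as.integer(imageHeight), imageWidth = as.integer(imageWidth),
      dropletRadius = dropletRadius, radiusJitter = radiusJitter,
      dropletsPerFrame = as.integer(dropletsPerFrame),
      crystalSizePx = as.integer(crystalSizePx),
      backgroundContrast = backgroundContrast, noiseSd = noiseSd,
      rngSeed = as.integer(rngSeed))
}

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec: %d x %d px, %d droplets (r = %.1f px +/- %.0f%%), crystals <= %d px\n",
              object@imageHeight, object@imageWidth, object@dropletsPerFrame,
              object@dropletRadius, 100 * object@radiusJitter, object@crystalSizePx))
  cat(sprintf("  background contrast %.2f, noise sd %.1f/255, seed %d\n",
              object@backgroundContrast, object@noiseSd, object@rngSeed))
})

# ------------------------------------------------------------- KineticsSpec

#' Transformation-kinetics specification
#'
#' Two-population first-order model of the ACC-to-crystal transformation:
#' a fraction `labileFraction` of droplets can transform, each with an
#' exponential waiting time of rate `kTrue` (1/min); the remainder stay
#' amorphous indefinitely, so the expected ACC fraction at time t is
#' `(1 - labileFraction) + labileFraction * exp(-kTrue * t)`, an
#' exponential decay onto a plateau. On transformation a droplet becomes
#' vaterite with probability `pVaterite`, else calcite.
#'
#' @slot kTrue transformation rate, 1/min.
#' @slot labileFraction fraction of droplets able to transform.
#' @slot initialTransformedFraction fraction already crystalline at t = 0.
#' @slot pVaterite probability a transforming droplet becomes vaterite.
#' @slot timesteps acquisition times in minutes, strictly increasing.
#' @slot nLocations number of monitored chip locations.
#' @slot perLocationTimeOffsetMin acquisition lag between consecutive
#'   locations (snapshots are taken sequentially), minutes.
#' @export
setClass("KineticsSpec", representation(
  kTrue = "numeric", labileFraction = "numeric",
  initialTransformedFraction = "numeric", pVaterite = "numeric",
  timesteps = "numeric", nLocations = "integer",
  perLocationTimeOffsetMin = "numeric"
))

setValidity("KineticsSpec", function(object) {
  msg <- character()
  if (!(object@kTrue >= 0)) msg <- c(msg, "kTrue must be >= 0")
  if (!.prob(object@labileFraction)) msg <- c(msg, "labileFraction must lie in [0, 1]")
  if (!(object@initialTransformedFraction >= 0 && object@initialTransformedFraction < 1))
    msg <- c(msg, "initialTransformedFraction must lie in [0, 1)")
  if (!.prob(object@pVaterite)) msg <- c(msg, "pVaterite must lie in [0, 1]")
  if (length(object@timesteps) < 1 || any(diff(object@timesteps) <= 0) ||
      any(object@timesteps < 0))
    msg <- c(msg, "timesteps must be nonnegative and strictly increasing")
  if (!.posInt(object@nLocations)) msg <- c(msg, "nLocations must be a positive integer")
  if (!(object@perLocationTimeOffsetMin >= 0))
    msg <- c(msg, "perLocationTimeOffsetMin must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param kTrue,labileFraction,initialTransformedFraction,pVaterite,timesteps,nLocations,perLocationTimeOffsetMin see slots.
#' @return A validated `KineticsSpec`.
#' @rdname KineticsSpec-class
#' @examples
#' KineticsSpec(kTrue = 0.027, labileFraction = 0.1)
#' @export
KineticsSpec <- function(kTrue = 0.027, labileFraction = 0.1,
                         initialTransformedFraction = 0, pVaterite = 0.5,
                         timesteps = seq(0, 360, by = 22.5),
                         nLocations = 12L, perLocationTimeOffsetMin = 1.5) {
  new("KineticsSpec", kTrue = kTrue, labileFraction = labileFraction,
      initialTransformedFraction = initialTransformedFraction,
      pVaterite = pVaterite, timesteps = as.numeric(timesteps),
      nLocations = as.integer(nLocations),
      perLocationTimeOffsetMin = perLocationTimeOffsetMin)
}

setMethod("show", "KineticsSpec", function(object) {
  cat(sprintf("KineticsSpec: k = %.4g /min, labile %.3f, p(vaterite) %.2f\n",
              object@kTrue, object@labileFraction, object@pVaterite))
  cat(sprintf("  %d timesteps in [%g, %g] min, %d locations (offset %.2g min)\n",
              length(object@timesteps), min(object@timesteps),
              max(object@timesteps), object@nLocations,
              object@perLocationTimeOffsetMin))
})

# ----------------------------------------------------------------- UNetSpec

#' U-Net architecture and optimisation hyperparameters
#'
#' One binary encoder-decoder segmenter: `nEncoders` resolution levels with
#' `baseFilters` channels at the first level doubling at each deeper level,
#' two zero-padded 3x3 convolutions (ReLU) per level, 2x2 max pooling,
#' nearest-neighbour upsampling with skip concatenation, and a 1x1 sigmoid
#' output head. Trained with Adam on binary cross-entropy.
#'
#' `unetPresets()` returns the three published stage configurations
#' (droplet, vaterite, calcite); `deskUnetSpec()` returns a small
#' configuration that trains in minutes on one CPU for synthetic scenes.
#'
#' @slot nEncoders number of resolution levels (>= 2).
#' @slot baseFilters filters in the first encoder level.
#' @slot learningRate Adam step size.
#' @slot batchSize minibatch size.
#' @slot nEpochs training epochs.
#' @slot seed weight-initialisation / shuffling seed.
#' @export
setClass("UNetSpec", representation(
  nEncoders = "integer", baseFilters = "integer", learningRate = "numeric",
  batchSize = "integer", nEpochs = "integer", seed = "integer"
))

setValidity("UNetSpec", function(object) {
  msg <- character()
  if (!(.posInt(object@nEncoders) && object@nEncoders >= 2))
    msg <- c(msg, "nEncoders must be an integer >= 2")
  if (!.posInt(object@baseFilters)) msg <- c(msg, "baseFilters must be a positive integer")
  if (!(object@learningRate > 0)) msg <- c(msg, "learningRate must be > 0")
  if (!.posInt(object@batchSize)) msg <- c(msg, "batchSize must be a positive integer")
  if (!.posInt(object@nEpochs)) msg <- c(msg, "nEpochs must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' @param nEncoders,baseFilters,learningRate,batchSize,nEpochs,seed see slots.
#' @return A validated `UNetSpec`.
#' @rdname UNetSpec-class
#' @examples
#' deskUnetSpec()
#' unetPresets()$droplet
#' @export
UNetSpec <- function(nEncoders, baseFilters, learningRate, batchSize,
                     nEpochs, seed = 0L) {
  new("UNetSpec", nEncoders = as.integer(nEncoders),
      baseFilters = as.integer(baseFilters), learningRate = learningRate,
      batchSize = as.integer(batchSize), nEpochs = as.integer(nEpochs),
      seed = as.integer(seed))
}

#' @rdname UNetSpec-class
#' @export
unetPresets <- function() {
  list(droplet  = UNetSpec(5L, 32L, 4.4e-4, 2L, 9269L),
       vaterite = UNetSpec(6L, 64L, 4.9e-4, 16L, 3853L),
       calcite  = UNetSpec(5L, 64L, 6.9e-4, 13L, 2997L))
}

#' @rdname UNetSpec-class
#' @export
deskUnetSpec <- function(nEncoders = 3L, baseFilters = 8L,
                         learningRate = 2e-3, batchSize = 4L,
                         nEpochs = 60L, seed = 0L) {
  UNetSpec(nEncoders, baseFilters, learningRate, batchSize, nEpochs, seed)
}

#' Per-level filter counts of a U-Net specification
#'
#' @param spec a [UNetSpec-class].
#' @return Integer vector, `baseFilters * 2^(0:(nEncoders - 1))`.
#' @examples filterSchedule(deskUnetSpec())
#' @export
filterSchedule <- function(spec) {
  stopifnot(is(spec, "UNetSpec"))
  as.integer(spec@baseFilters * 2^(seq_len(spec@nEncoders) - 1L))
}

setMethod("show", "UNetSpec", function(object) {
  cat(sprintf("UNetSpec: %d levels, filters %s; lr %.2g, batch %d, %d epochs, seed %d\n",
              object@nEncoders,
              paste(filterSchedule(object), collapse = "-"),
              object@learningRate, object@batchSize, object@nEpochs,
              object@seed))
})

# -------------------------------------------------------------- TrainConfig

#' Training configuration shared by the three cascade stages
#'
#' @slot splitFraction training share of the labeled pairs (default 0.8,
#'   i.e. an 80:20 train/validation split).
#' @slot hflip,vflip,rot90 augmentation toggles.
#' @slot brightnessJitter amplitude of multiplicative brightness jitter
#'   (0 disables).
#' @slot lossMode `"sum"` or `"mean"`: report binary cross-entropy summed
#'   over pixels or averaged per pixel.
#' @slot seed split/augmentation seed.
#' @export
setClass("TrainConfig", representation(
  splitFraction = "numeric", hflip = "logical", vflip = "logical",
  rot90 = "logical", brightnessJitter = "numeric", lossMode = "character",
  seed = "integer"
))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (!(object@splitFraction > 0 && object@splitFraction < 1))
    msg <- c(msg, "splitFraction must lie in (0, 1)")
  if (!object@lossMode %in% c("sum", "mean"))
    msg <- c(msg, "lossMode must be 'sum' or 'mean'")
  if (!(object@brightnessJitter >= 0))
    msg <- c(msg, "brightnessJitter must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param splitFraction,hflip,vflip,rot90,brightnessJitter,lossMode,seed see slots.
#' @return A validated `TrainConfig`.
#' @rdname TrainConfig-class
#' @export
TrainConfig <- function(splitFraction = 0.8, hflip = TRUE, vflip = TRUE,
                        rot90 = TRUE, brightnessJitter = 0.05,
                        lossMode = "sum", seed = 0L) {
  new("TrainConfig", splitFraction = splitFraction, hflip = hflip,
      vflip = vflip, rot90 = rot90, brightnessJitter = brightnessJitter,
      lossMode = lossMode, seed = as.integer(seed))
}

# ------------------------------------------------------------------ TileSet

#' A partition of a frame into tiles for model input
#'
#' Produced by [cutAndResize()]. The source rectangles partition the frame
#' exactly (no overlap, no gap); at most two cuts per axis are allowed to
#' limit seam artifacts on reconstruction.
#'
#' @slot sourceDim spatial size (rows, cols) of the source frame.
#' @slot nChannels channels of the source (1 for masks, 3 for RGB).
#' @slot grid number of cuts (rowCuts, colCuts), each in 0..2.
#' @slot rects n x 4 integer matrix (r0, r1, c0, c1), 1-based inclusive.
#' @slot tiles list of resized tiles (matrix or H x W x C array).
#' @slot targetHw tile size (rows, cols) after resizing.
#' @slot kind `"image"` (bilinear resize) or `"mask"` (nearest).
#' @export
setClass("TileSet", representation(
  sourceDim = "integer", nChannels = "integer", grid = "integer",
  rects = "matrix", tiles = "list", targetHw = "integer", kind = "character"
))

setValidity("TileSet", function(object) {
  msg <- character()
  if (any(object@grid < 0L) || any(object@grid > 2L))
    msg <- c(msg, "grid cuts must lie in 0..2 per axis")
  n <- nrow(object@rects)
  if (n != length(object@tiles)) msg <- c(msg, "one tile per rectangle required")
  if (n != prod(object@grid + 1L)) msg <- c(msg, "rectangle count must equal grid size")
  # exact partition: areas sum to the source area and rects stay in bounds
  if (n > 0) {
    a <- sum((object@rects[, 2] - object@rects[, 1] + 1) *
             (object@rects[, 4] - object@rects[, 3] + 1))
    if (a != prod(object@sourceDim)) msg <- c(msg, "rectangles must partition the source")
    if (min(object@rects[, c(1, 3)]) < 1 ||
        max(object@rects[, 2]) > object@sourceDim[1] ||
        max(object@rects[, 4]) > object@sourceDim[2])
      msg <- c(msg, "rectangles exceed the source extent")
  }
  if (!object@kind %in% c("image", "mask")) msg <- c(msg, "kind must be image|mask")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TileSet", function(object) {
  cat(sprintf("TileSet: %d %s tile(s) of %d x %d from a %d x %d frame (grid %d x %d cuts)\n",
              length(object@tiles), object@kind, object@targetHw[1],
              object@targetHw[2], object@sourceDim[1], object@sourceDim[2],
              object@grid[1], object@grid[2]))
})

# ---------------------------------------------------------------- UNetModel

#' A (possibly trained) binary U-Net
#'
#' @slot spec the [UNetSpec-class] used to build the network.
#' @slot inChannels input channels (3 for RGB stages).
#' @slot params named list of weight matrices and biases.
#' @slot trained whether [trainUnet()] has been run.
#' @slot history per-epoch data.frame with `trainBce` and `valBce`.
#' @export
setClass("UNetModel", representation(
  spec = "UNetSpec", inChannels = "integer", params = "list",
  trained = "logical", history = "data.frame"
))

setMethod("show", "UNetModel", function(object) {
  cat(sprintf("UNetModel (%s): %d levels, %d input channel(s), %d parameters\n",
              if (object@trained) "trained" else "untrained",
              object@spec@nEncoders, object@inChannels, nParams(object)))
  if (nrow(object@history) > 0) {
    last <- object@history[nrow(object@history), ]
    cat(sprintf("  final epoch %d: train BCE %.4g, validation BCE %.4g\n",
                last$epoch, last$trainBce, last$valBce))
  }
})

#' Number of trainable parameters of a U-Net
#' @param model a [UNetModel-class].
#' @return Integer parameter count.
#' @export
nParams <- function(model) {
  stopifnot(is(model, "UNetModel"))
  sum(vapply(model@params, length, integer(1)))
}

#' @rdname UNetModel-class
#' @param model a [UNetModel-class].
#' @export
isTrained <- function(model) {
  stopifnot(is(model, "UNetModel"))
  model@trained
}

# ----------------------------------------------------------------- DecayFit

#' Exponential-plateau decay fit N(t) = A exp(-k t) + C
#'
#' Result of [fitDecay()]: the three-parameter first-order transformation
#' model in count form (N droplets still amorphous) or ratio form
#' (fraction of droplets still amorphous).
#'
#' @slot form `"count"` or `"ratio"`.
#' @slot A amplitude (droplets, or dimensionless in ratio form).
#' @slot k transformation rate, 1/min (constrained nonnegative).
#' @slot C plateau.
#' @slot rss residual sum of squares.
#' @slot nPoints number of fitted points.
#' @slot noDecay flag set when the series carries no decay signal.
#' @export
setClass("DecayFit", representation(
  form = "character", A = "numeric", k = "numeric", C = "numeric",
  rss = "numeric", nPoints = "integer", noDecay = "logical"
))

setValidity("DecayFit", function(object) {
  msg <- character()
  if (!object@form %in% c("count", "ratio")) msg <- c(msg, "form must be count|ratio")
  if (!(object@k >= 0)) msg <- c(msg, "k must be >= 0")
  if (object@form == "ratio") {
    if (object@C < -1e-8 || object@C > 1 + 1e-8)
      msg <- c(msg, "ratio-form plateau must lie in [0, 1]")
    if (object@A + object@C > 1.05)
      msg <- c(msg, "ratio-form A + C must not exceed 1 (up to noise tolerance)")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname DecayFit-class
#' @param form,A,k,C,rss,nPoints,noDecay see slots.
#' @export
DecayFit <- function(form, A, k, C, rss = NA_real_, nPoints = NA_integer_,
                     noDecay = FALSE) {
  # bind Class exactly: an argument named `C` would otherwise partially
  # match new()'s `Class` formal
  do.call(new, list(Class = "DecayFit", form = form, A = A, k = k, C = C,
                    rss = rss, nPoints = as.integer(nPoints),
                    noDecay = noDecay))
}

setMethod("show", "DecayFit", function(object) {
  cat(sprintf("DecayFit (%s form): N(t) = %.4g * exp(-%.4g t) + %.4g\n",
              object@form, object@A, object@k, object@C))
  cat(sprintf("  RSS %.4g over %d points%s\n", object@rss, object@nPoints,
              if (object@noDecay) "  [no decay detected]" else ""))
})

#' Accessors for decay-fit parameters
#' @param fit a [DecayFit-class].
#' @return The rate `k` (1/min), plateau `C`, or amplitude `A`.
#' @export
kRate <- function(fit) { stopifnot(is(fit, "DecayFit")); fit@k }

#' @rdname kRate
#' @export
plateau <- function(fit) { stopifnot(is(fit, "DecayFit")); fit@C }

#' @rdname kRate
#' @export
amplitude <- function(fit) { stopifnot(is(fit, "DecayFit")); fit@A }

# ------------------------------------------------------------ HalfLifeBound

#' Half-life statement for the ACC droplet fraction
#'
#' The half-life is the time at which the fraction of droplets still
#' amorphous falls to 0.5. Under a fitted plateau above 0.5 it is never
#' reached; from data alone only a lower bound (the latest observation
#' with fraction > 0.5) can be stated.
#'
#' @slot kind `"exact"`, `"lower_bound"` or `"unreachable"`.
#' @slot valueMin half-life (or its lower bound) in minutes; `NA` when
#'   unreachable.
#' @slot basis `"model"` or `"empirical"`.
#' @export
setClass("HalfLifeBound", representation(
  kind = "character", valueMin = "numeric", basis = "character"
))

setValidity("HalfLifeBound", function(object) {
  msg <- character()
  if (!object@kind %in% c("exact", "lower_bound", "unreachable"))
    msg <- c(msg, "kind must be exact|lower_bound|unreachable")
  if (!object@basis %in% c("model", "empirical"))
    msg <- c(msg, "basis must be model|empirical")
  if (length(msg)) msg else TRUE
})

setMethod("show", "HalfLifeBound", function(object) {
  lab <- switch(object@kind,
                exact = sprintf("t1/2 = %.4g min", object@valueMin),
                lower_bound = sprintf("t1/2 > %.4g min", object@valueMin),
                unreachable = "t1/2 unreachable under the fitted model")
  cat(sprintf("HalfLifeBound (%s): %s\n", object@basis, lab))
})
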