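#' Run the three-stage segmentation cascade on one frame
#'
#' Stage 1 segments droplets from the raw frame tiles; its K-Means
#' binarized output is overlaid on the frame (background zeroed), and the
#' vaterite and calcite stages then run independently on the overlaid
#' frame. Per-tile probability maps are merged back to full-frame
#' resolution before binarization.
#'
#' @param models list of three trained [UNetModel-class] objects, in order
#'   droplet, vaterite, calcite (names `droplet`, `vaterite`, `calcite`
#'   are honoured when present).
#' @param rgb H x W x 3 frame in [0, 1].
#' @param grid tile cuts per axis, each in 0..2 (see [cutAndResize()]).
#' @param targetHw tile size fed to the networks; default: uncut frame
#'   size when `grid = c(0,0)`, else 512 x 512.
#' @param kmeansSeed seed recorded for the K-Means binarizer.
#' @param oracleDropletMask optional known droplet mask; when supplied,
#'   stage 1 is skipped and this mask drives the overlay (oracle bypass).
#' @return list with binary masks `dropletMask`, `vateriteMask`,
#'   `calciteMask` ({0, 255}) and full-frame probability maps in `probs`.
#' @export
runCascade <- function(models, rgb, grid = c(0L, 0L), targetHw = NULL,
                       kmeansSeed = 0L, oracleDropletMask = NULL) {
  if (length(models) != 3) stop("three models are required (droplet, vaterite, calcite)")
  if (!is.null(names(models)) && all(c("droplet", "vaterite", "calcite") %in% names(models)))
    models <- models[c("droplet", "vaterite", "calcite")]
  for (m in models) {
    if (!is(m, "UNetModel")) stop("models must be UNetModel objects")
    if (!m@trained) stop("untrained model handle; run trainUnet() first")
  }
  predictFull <- function(model, frame) {
    div <- 2^(model@spec@nEncoders - 1)
    ts <- cutAndResize(frame, grid = grid, targetHw = targetHw,
                       kind = "image", requiredDivisor = div)
    probTiles <- lapply(ts@tiles, function(t) predictUnet(model, t))
    reconstruct(ts, probTiles, method = "bilinear")
  }
  probs <- list(droplet = NULL, vaterite = NULL, calcite = NULL)
  if (is.null(oracleDropletMask)) {
    probs$droplet <- predictFull(models[[1]], rgb)
    dropletMask <- binarizeKmeans(probs$droplet, seed = kmeansSeed)
  } else {
    if (!.isBinaryMask(oracleDropletMask)) stop("oracle droplet mask must be binary")
    dropletMask <- matrix(as.integer(oracleDropletMask != 0) * 255L,
                          nrow(oracleDropletMask))
  }
  overlaid <- overlayMask(rgb, dropletMask)
  # vaterite and calcite stages are independent given the overlay
  probs$vaterite <- predictFull(models[[2]], overlaid)
  probs$calcite <- predictFull(models[[3]], overlaid)
  list(dropletMask = dropletMask,
       vateriteMask = binarizeKmeans(probs$vaterite, seed = kmeansSeed),
       calciteMask = binarizeKmeans(probs$calcite, seed = kmeansSeed),
       probs = probs)
}

#' Stack binary stage outputs into one RGB label image
#'
#' Background black, droplets white, vaterite red, calcite green; every
#' pixel receives exactly one of the four colours. Crystal colours take
#' precedence over droplet white. A pixel claimed by both crystal masks is
#' assigned by comparing stage probabilities when supplied, with vaterite
#' winning ties (and winning outright when no probabilities are given).
#' Crystal pixels outside the droplet mask are still rendered in their
#' crystal colour but reported in a warning.
#'
#' @param dropletMask,vateriteMask,calciteMask binary masks, {0, 255}.
#' @param vateriteProb,calciteProb optional probability maps used to break
#'   two-crystal conflicts.
#' @return H x W x 3 array with values in {0, 255}.
#' @export
stackSegmentations <- function(dropletMask, vateriteMask, calciteMask,
                               vateriteProb = NULL, calciteProb = NULL) {
  if (!all(dim(dropletMask) == dim(vateriteMask)) ||
      !all(dim(dropletMask) == dim(calciteMask)))
    stop("masks must share dimensions")
  d <- dropletMask != 0
  v <- vateriteMask != 0
  cl <- calciteMask != 0
  both <- v & cl
  if (any(both)) {
    vWins <- if (!is.null(vateriteProb) && !is.null(calciteProb))
      vateriteProb[both] >= calciteProb[both] else TRUE
    v[both] <- vWins
    cl[both] <- !vWins
  }
  stray <- sum((v | cl) & !d)
  if (stray > 0)
    warning(sprintf("%d crystal pixel(s) fall outside the droplet mask", stray))
  H <- nrow(dropletMask); W <- ncol(dropletMask)
  out <- array(0, dim = c(H, W, 3))
  white <- d & !v & !cl
  out[, , 1][white | v] <- 255
  out[, , 2][white | cl] <- 255
  out[, , 3][white] <- 255
  out
}
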