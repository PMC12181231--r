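#' Cut a frame into a bounded grid of tiles and resize for model input
#'
#' The frame is partitioned exactly (no overlap, no gap) into
#' `(rowCuts + 1) x (colCuts + 1)` rectangles, with at most two cuts per
#' axis to limit reconstruction seam artifacts; each rectangle is resized
#' to `targetHw` (bilinear for images, nearest-neighbour for masks).
#'
#' @param image matrix (grayscale/mask) or H x W x C array.
#' @param grid integer vector `(rowCuts, colCuts)`, each in 0..2.
#' @param targetHw target tile size `(rows, cols)`; default 512 x 512, or
#'   the uncut frame size when `grid = c(0, 0)` and no target is given.
#' @param kind `"image"` or `"mask"`; selects the resize interpolation.
#' @param requiredDivisor both target dimensions must be divisible by this
#'   (set it to `2^(nEncoders - 1)` of the downstream network).
#' @return A [TileSet-class].
#' @examples
#' ts <- cutAndResize(matrix(runif(64), 8, 8), grid = c(1, 1),
#'                    targetHw = c(4, 4))
#' length(ts@tiles)
#' @export
cutAndResize <- function(image, grid = c(0L, 0L), targetHw = NULL,
                         kind = c("image", "mask"), requiredDivisor = 1L) {
  kind <- match.arg(kind)
  grid <- as.integer(grid)
  if (length(grid) != 2 || any(grid < 0L) || any(grid > 2L))
    stop("a maximum of two cuts per axis is allowed (grid entries in 0..2)")
  dims <- dim(image)
  H <- dims[1]; W <- dims[2]
  nCh <- if (length(dims) == 3) dims[3] else 1L
  if (is.null(targetHw)) {
    targetHw <- if (all(grid == 0L)) c(H, W) else c(512L, 512L)
  }
  targetHw <- as.integer(targetHw)
  if (any(targetHw %% requiredDivisor != 0))
    stop(sprintf("target tile size (%d x %d) must be divisible by %d for the downstream network depth",
                 targetHw[1], targetHw[2], requiredDivisor))
  rowBreaks <- floor(seq(0, H, length.out = grid[1] + 2))
  colBreaks <- floor(seq(0, W, length.out = grid[2] + 2))
  rects <- NULL
  tiles <- list()
  method <- if (kind == "image") "bilinear" else "nearest"
  for (i in seq_len(grid[1] + 1)) {
    for (j in seq_len(grid[2] + 1)) {
      r0 <- rowBreaks[i] + 1L; r1 <- rowBreaks[i + 1]
      c0 <- colBreaks[j] + 1L; c1 <- colBreaks[j + 1]
      sub <- if (nCh == 1) image[r0:r1, c0:c1, drop = FALSE]
             else image[r0:r1, c0:c1, , drop = FALSE]
      tiles[[length(tiles) + 1L]] <- .resizeImage(sub, targetHw[1], targetHw[2],
                                                  method)
      rects <- rbind(rects, c(r0, r1, c0, c1))
    }
  }
  storage.mode(rects) <- "integer"
  new("TileSet", sourceDim = c(H, W), nChannels = as.integer(nCh),
      grid = grid, rects = rects, tiles = tiles, targetHw = targetHw,
      kind = kind)
}

#' Reassemble a full-frame map from per-tile predictions
#'
#' Each predicted tile is resized back to its source rectangle
#' (nearest-neighbour for masks/labels, bilinear for continuous maps) and
#' placed; the output has the source frame's dimensions.
#'
#' @param tileset the [TileSet-class] the predictions correspond to.
#' @param predictedTiles list of matrices, one per tile, each of the
#'   tileset's target size.
#' @param method resize interpolation used on the way back; defaults to
#'   nearest for mask tilesets and bilinear for image tilesets.
#' @return Matrix of the source dimensions.
#' @export
reconstruct <- function(tileset, predictedTiles,
                        method = if (tileset@kind == "mask") "nearest" else "bilinear") {
  stopifnot(is(tileset, "TileSet"))
  validObject(tileset)
  n <- nrow(tileset@rects)
  if (length(predictedTiles) != n)
    stop(sprintf("expected %d predicted tiles, got %d (rectangles: %s)",
                 n, length(predictedTiles),
                 paste(apply(tileset@rects, 1, paste, collapse = ":"),
                       collapse = "; ")))
  bad <- which(!vapply(predictedTiles, function(t)
    is.matrix(t) && all(dim(t) == tileset@targetHw), logical(1)))
  if (length(bad))
    stop(sprintf("predicted tiles %s do not match the target tile size %d x %d",
                 paste(bad, collapse = ", "),
                 tileset@targetHw[1], tileset@targetHw[2]))
  out <- matrix(0, tileset@sourceDim[1], tileset@sourceDim[2])
  for (i in seq_len(n)) {
    rc <- tileset@rects[i, ]
    out[rc[1]:rc[2], rc[3]:rc[4]] <-
      .resizeMatrix(predictedTiles[[i]], rc[2] - rc[1] + 1L,
                    rc[4] - rc[3] + 1L, method)
  }
  out
}
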