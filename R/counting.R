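#' Binarize a probability map with two-cluster K-Means
#'
#' Pixel intensities are clustered into two groups; the cluster with the
#' higher centre becomes foreground (255). Near-constant maps whose two
#' cluster centres are separated by less than `minSeparation` carry no
#' foreground signal and return an all-background mask.
#'
#' Cluster centres are initialised at the intensity extremes, which for
#' k = 2 on a 1-D distribution makes Lloyd's iteration deterministic and
#' the resulting masks bit-stable; `seed` is honoured for interface
#' stability but does not influence the result.
#'
#' @param probMap numeric matrix with values in [0, 1].
#' @param seed retained for reproducibility bookkeeping.
#' @param minSeparation minimum centre separation below which the map is
#'   treated as degenerate (default 0.1).
#' @return Integer matrix in {0, 255}, same dimensions as `probMap`.
#' @examples
#' p <- matrix(0.05, 8, 8); p[3:5, 3:5] <- 0.95
#' table(binarizeKmeans(p))
#' @export
binarizeKmeans <- function(probMap, seed = 0L, minSeparation = 0.1) {
  if (length(probMap) == 0) stop("empty probability map")
  if (min(probMap) < -1e-9 || max(probMap) > 1 + 1e-9)
    stop("probability map values must lie in [0, 1]")
  v <- as.vector(probMap)
  out <- matrix(0L, nrow(probMap), ncol(probMap))
  if (diff(range(v)) < 1e-12) return(out)
  set.seed(seed)
  km <- kmeans(v, centers = matrix(range(v), ncol = 1), iter.max = 100)
  if (abs(diff(km$centers[, 1])) < minSeparation) return(out)
  fg <- which.max(km$centers[, 1])
  out[km$cluster == fg] <- 255L
  out
}

#' Count distinct objects in a binary mask
#'
#' Connected-component labeling at 4- or 8-connectivity; components
#' smaller than `minArea` pixels are discarded. Centroids are component
#' pixel means in (row, col) coordinates.
#'
#' @param mask matrix in {0, 255} (or {0, 1}).
#' @param minArea minimum component area in pixels (default 1).
#' @param connectivity 4 or 8 (default 8).
#' @return list with `nObjects`, `centroids` (n x 2 matrix, row/col),
#'   `areas`, and the integer `labels` matrix (small components zeroed).
#' @examples
#' m <- matrix(0L, 10, 10); m[2:3, 2:3] <- 255L; m[7:9, 6:8] <- 255L
#' countObjects(m)$nObjects
#' @export
countObjects <- function(mask, minArea = 1L, connectivity = 8L) {
  if (!.isBinaryMask(mask)) stop("mask must be binary ({0, 255} or {0, 1})")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  lab <- label_components_cpp(matrix(as.integer(mask != 0), nrow(mask)),
                              as.integer(connectivity))
  nLab <- max(lab)
  if (nLab == 0)
    return(list(nObjects = 0L, centroids = matrix(numeric(), 0, 2,
                                                  dimnames = list(NULL, c("row", "col"))),
                areas = integer(), labels = lab))
  areas <- tabulate(lab[lab > 0], nbins = nLab)
  keep <- which(areas >= minArea)
  if (length(keep) == 0)
    return(list(nObjects = 0L, centroids = matrix(numeric(), 0, 2,
                                                  dimnames = list(NULL, c("row", "col"))),
                areas = integer(), labels = matrix(0L, nrow(lab), ncol(lab))))
  idx <- which(lab > 0, arr.ind = TRUE)
  labv <- lab[lab > 0]
  cenRow <- rowsum(as.numeric(idx[, 1]), labv)[, 1] / areas
  cenCol <- rowsum(as.numeric(idx[, 2]), labv)[, 1] / areas
  lab[!(lab %in% keep)] <- 0L
  # relabel kept components 1..n in first-encounter order
  relab <- integer(nLab); relab[keep] <- seq_along(keep)
  lab[lab > 0] <- relab[lab[lab > 0]]
  list(nObjects = length(keep),
       centroids = cbind(row = cenRow[keep], col = cenCol[keep]),
       areas = as.integer(areas[keep]), labels = lab)
}
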