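# --- minimum enclosing circle (Welzl) --------------------------------------

.circleFrom2 <- function(p, q) {
  ctr <- (p + q) / 2
  list(center = ctr, radius = sqrt(sum((p - q)^2)) / 2)
}

.circleFrom3 <- function(a, b, c) {
  # circumcircle; falls back to the widest pair when nearly collinear
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12) {
    cands <- list(.circleFrom2(a, b), .circleFrom2(a, c), .circleFrom2(b, c))
    return(cands[[which.max(vapply(cands, `[[`, numeric(1), "radius"))]])
  }
  ux <- (sum(a^2) * (b[2] - c[2]) + sum(b^2) * (c[2] - a[2]) +
         sum(c^2) * (a[2] - b[2])) / d
  uy <- (sum(a^2) * (c[1] - b[1]) + sum(b^2) * (a[1] - c[1]) +
         sum(c^2) * (b[1] - a[1])) / d
  ctr <- c(ux, uy)
  list(center = ctr, radius = sqrt(sum((a - ctr)^2)))
}

.inCircle <- function(circ, p, tol = 1e-7) {
  sqrt(sum((p - circ$center)^2)) <= circ$radius + tol
}

.trivialCircle <- function(R) {
  n <- nrow(R)
  if (n == 0) return(list(center = c(0, 0), radius = 0))
  if (n == 1) return(list(center = R[1, ], radius = 0))
  if (n == 2) return(.circleFrom2(R[1, ], R[2, ]))
  .circleFrom3(R[1, ], R[2, ], R[3, ])
}

# Welzl's move-to-front algorithm on a small point set (convex hull of a
# component boundary); iterative support growth keeps it robust for the
# few dozen hull points of a digital disk.
.minEnclosingCircle <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n == 0) stop("no points")
  circ <- list(center = pts[1, ], radius = 0)
  for (i in seq_len(n)) {
    if (.inCircle(circ, pts[i, ])) next
    circ <- list(center = pts[i, ], radius = 0)
    for (j in seq_len(i - 1L)) {
      if (.inCircle(circ, pts[j, ])) next
      circ <- .circleFrom2(pts[i, ], pts[j, ])
      for (k in seq_len(j - 1L)) {
        if (.inCircle(circ, pts[k, ])) next
        circ <- .circleFrom3(pts[i, ], pts[j, ], pts[k, ])
      }
    }
  }
  circ
}

#' Detect droplet circles in a binary droplet mask
#'
#' External boundary pixels of each connected component are extracted and
#' the minimum enclosing circle of the component boundary (restricted to
#' its convex hull) is computed. Components smaller than `minArea` are
#' discarded; components touching the frame border are flagged as
#' truncated but kept.
#'
#' @param mask droplet mask, {0, 255}.
#' @param minArea minimum component area in pixels (default 50: a droplet
#'   is large against crystals and noise specks).
#' @param connectivity component connectivity, 4 or 8.
#' @return data.frame with columns `row`, `col`, `radius`, `area`,
#'   `truncatedAtBorder`; one row per detected droplet.
#' @examples
#' m <- matrix(0L, 64, 64)
#' d2 <- outer((1:64 - 30)^2, (1:64 - 33)^2, "+")
#' m[d2 <= 12^2] <- 255L
#' findDropletCircles(m)
#' @export
findDropletCircles <- function(mask, minArea = 50L, connectivity = 8L) {
  co <- countObjects(mask, minArea = minArea, connectivity = connectivity)
  if (co$nObjects == 0)
    return(data.frame(row = numeric(), col = numeric(), radius = numeric(),
                      area = integer(), truncatedAtBorder = logical()))
  H <- nrow(mask); W <- ncol(mask)
  lab <- co$labels
  out <- vector("list", co$nObjects)
  for (i in seq_len(co$nObjects)) {
    idx <- which(lab == i, arr.ind = TRUE)
    # boundary: component pixel with a 4-neighbour outside the component
    r <- idx[, 1]; c <- idx[, 2]
    inComp <- function(rr, cc) {
      ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
      res <- logical(length(rr))
      res[ok] <- lab[cbind(rr[ok], cc[ok])] == i
      res
    }
    interior <- inComp(r - 1, c) & inComp(r + 1, c) &
                inComp(r, c - 1) & inComp(r, c + 1)
    bnd <- idx[!interior, , drop = FALSE]
    if (nrow(bnd) >= 3) {
      hull <- grDevices::chull(bnd[, 2], bnd[, 1])
      bnd <- bnd[hull, , drop = FALSE]
    }
    circ <- .minEnclosingCircle(bnd)
    out[[i]] <- data.frame(
      row = circ$center[1], col = circ$center[2], radius = circ$radius,
      area = co$areas[i],
      truncatedAtBorder = any(r == 1 | r == H | c == 1 | c == W))
  }
  do.call(rbind, out)
}

#' Assign crystal components to droplet circles
#'
#' Each crystal component's centroid is tested against the droplet circles
#' inflated by `marginPx`; when several circles contain it, the nearest
#' centre wins; a centroid contained by none is recorded as an orphan (it
#' classifies no droplet) and a warning summarises the orphan count.
#'
#' @param circles data.frame from [findDropletCircles()].
#' @param vateriteMask,calciteMask binary crystal masks, {0, 255}.
#' @param marginPx circle inflation in pixels (default 2; robust to 1-3 px
#'   crystals near the mask-resolution droplet boundary).
#' @param minArea minimum crystal component area (default 1 px; crystals
#'   span at most a few pixels at analysis resolution).
#' @param connectivity component connectivity, 4 or 8.
#' @return data.frame of per-droplet detections: `row`, `col`, `radius`,
#'   `truncatedAtBorder`, `hasVaterite`, `hasCalcite`, `hasAcc`
#'   (`hasAcc = !(hasVaterite | hasCalcite)`); the orphan table is
#'   attached as `attr(, "orphans")`.
#' @export
assignCrystals <- function(circles, vateriteMask, calciteMask, marginPx = 2,
                           minArea = 1L, connectivity = 8L) {
  if (!all(dim(vateriteMask) == dim(calciteMask)))
    stop("crystal masks must share frame dimensions")
  n <- nrow(circles)
  det <- data.frame(row = circles$row, col = circles$col,
                    radius = circles$radius,
                    truncatedAtBorder = circles$truncatedAtBorder,
                    hasVaterite = rep(FALSE, n), hasCalcite = rep(FALSE, n))
  orphans <- data.frame(phase = character(), row = numeric(), col = numeric())
  for (phase in c("vaterite", "calcite")) {
    msk <- if (phase == "vaterite") vateriteMask else calciteMask
    co <- countObjects(msk, minArea = minArea, connectivity = connectivity)
    flagCol <- if (phase == "vaterite") "hasVaterite" else "hasCalcite"
    for (i in seq_len(co$nObjects)) {
      cen <- co$centroids[i, ]
      if (n == 0) {
        orphans <- rbind(orphans, data.frame(phase = phase, row = cen[1],
                                             col = cen[2]))
        next
      }
      d <- sqrt((circles$row - cen[1])^2 + (circles$col - cen[2])^2)
      containing <- which(d <= circles$radius + marginPx)
      if (length(containing) == 0) {
        orphans <- rbind(orphans, data.frame(phase = phase, row = cen[1],
                                             col = cen[2]))
      } else {
        win <- containing[which.min(d[containing])]
        det[win, flagCol] <- TRUE
      }
    }
  }
  det$hasAcc <- !(det$hasVaterite | det$hasCalcite)
  attr(det, "orphans") <- orphans
  if (nrow(orphans) > 0)
    warning(sprintf("%d orphan crystal component(s) outside every droplet circle",
                    nrow(orphans)))
  det
}

#' Summarise one frame's detections into a time-point count row
#'
#' @param detections data.frame from [assignCrystals()].
#' @param locationId,timestepIndex frame metadata.
#' @param timeMin acquisition time, minutes.
#' @return One-row data.frame with `location_id`, `timestep_index`,
#'   `acquisition_time_min`, `N_d`, `N_vaterite_droplets`,
#'   `N_calcite_droplets`, `N_d_ACC`. The conservation identity
#'   `N_d_ACC + |transformed droplets| = N_d` holds by construction.
#' @export
countTimepoint <- function(detections, locationId = NA_integer_,
                           timestepIndex = NA_integer_, timeMin = NA_real_) {
  nD <- nrow(detections)
  nTrans <- if (nD) sum(detections$hasVaterite | detections$hasCalcite) else 0L
  data.frame(location_id = locationId, timestep_index = timestepIndex,
             acquisition_time_min = timeMin, N_d = nD,
             N_vaterite_droplets = if (nD) sum(detections$hasVaterite) else 0L,
             N_calcite_droplets = if (nD) sum(detections$hasCalcite) else 0L,
             N_d_ACC = nD - nTrans)
}
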