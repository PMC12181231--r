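#' Expected ACC fraction under the two-population kinetic model
#'
#' Closed-form survival of the amorphous phase:
#' `(1 - i0) * ((1 - L) + L * exp(-k * t))` where `L` is the labile
#' fraction, `i0` the initially transformed fraction and `k` the
#' transformation rate.
#'
#' @param kinetics a [KineticsSpec-class].
#' @param t time(s) in minutes.
#' @return Expected fraction of droplets still amorphous at `t`.
#' @examples
#' accSurvival(KineticsSpec(kTrue = 0.027, labileFraction = 1), 360)
#' @export
accSurvival <- function(kinetics, t) {
  stopifnot(is(kinetics, "KineticsSpec"), all(t >= 0))
  L <- kinetics@labileFraction
  (1 - kinetics@initialTransformedFraction) *
    ((1 - L) + L * exp(-kinetics@kTrue * t))
}

# RNG-stream version; callers seed. Columns: droplet, transformationTime
# (minutes; 0 = transformed before monitoring, Inf = never), phase.
.sampleScheduleRaw <- function(kinetics, nDroplets) {
  n <- nDroplets
  if (n == 0)
    return(data.frame(droplet = integer(), transformationTime = numeric(),
                      phase = character()))
  uInit <- runif(n)
  uLabile <- runif(n)
  tWait <- if (kinetics@kTrue > 0) rexp(n, rate = kinetics@kTrue) else rep(Inf, n)
  phase <- ifelse(runif(n) < kinetics@pVaterite, "vaterite", "calcite")
  tt <- ifelse(uInit < kinetics@initialTransformedFraction, 0,
               ifelse(uLabile < kinetics@labileFraction, tWait, Inf))
  data.frame(droplet = seq_len(n), transformationTime = tt, phase = phase,
             stringsAsFactors = FALSE)
}

#' Draw per-droplet transformation times and polymorph identities
#'
#' Each droplet is labile with probability `labileFraction`; labile
#' droplets transform after an exponential waiting time of rate `kTrue`
#' (never, when the rate is zero), inert droplets never transform. The
#' polymorph adopted on transformation is vaterite with probability
#' `pVaterite`, else calcite.
#'
#' @param kinetics a [KineticsSpec-class].
#' @param nDroplets number of droplets.
#' @param seed RNG seed; identical seeds give identical schedules.
#' @return data.frame with columns `droplet`, `transformationTime`
#'   (minutes, `Inf` = never) and `phase`.
#' @examples
#' sampleTransformationSchedule(KineticsSpec(), 5, seed = 1)
#' @export
sampleTransformationSchedule <- function(kinetics, nDroplets, seed = 1L) {
  stopifnot(is(kinetics, "KineticsSpec"))
  validObject(kinetics)
  if (!(length(nDroplets) == 1 && nDroplets >= 0 &&
        nDroplets == as.integer(nDroplets)))
    stop("nDroplets must be a nonnegative integer")
  set.seed(seed)
  .sampleScheduleRaw(kinetics, as.integer(nDroplets))
}

# Non-overlapping droplet layout by rejection sampling; also fixes each
# droplet's crystal offset so time-lapse frames keep crystals in place.
# Uses the current RNG stream.
.placeDroplets <- function(scene) {
  n <- scene@dropletsPerFrame
  H <- scene@imageHeight; W <- scene@imageWidth
  if (n == 0)
    return(data.frame(row = numeric(), col = numeric(), radius = numeric(),
                      crystalRow = numeric(), crystalCol = numeric()))
  radii <- scene@dropletRadius *
    (1 + runif(n, -scene@radiusJitter, scene@radiusJitter))
  if (any(2 * radii + 2 > min(H, W)))
    stop("droplets do not fit the frame; use fewer or smaller droplets")
  rows <- numeric(n); cols <- numeric(n)
  maxAttempts <- 300L * n
  attempts <- 0L
  placed <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > maxAttempts)
      stop(sprintf(paste0("could not place %d non-overlapping droplets after ",
                          "%d attempts; use fewer or smaller droplets"),
                   n, maxAttempts))
    i <- placed + 1L
    r <- runif(1, radii[i] + 1, H - radii[i])
    c <- runif(1, radii[i] + 1, W - radii[i])
    if (placed > 0) {
      d2 <- (rows[seq_len(placed)] - r)^2 + (cols[seq_len(placed)] - c)^2
      if (any(d2 <= (radii[seq_len(placed)] + radii[i] + 1)^2)) next
    }
    rows[i] <- r; cols[i] <- c
    placed <- i
  }
  # crystal strictly inside the droplet interior, clear of the rim
  maxOff <- pmax(radii - 2 - scene@crystalSizePx / 2 - 1, 0)
  ang <- runif(n, 0, 2 * pi)
  off <- maxOff * sqrt(runif(n))
  data.frame(row = rows, col = cols, radius = radii,
             crystalRow = rows + off * sin(ang),
             crystalCol = cols + off * cos(ang))
}

# crystal footprints at integer centers: vaterite = digital disk,
# calcite = filled square; both span at most sizePx pixels
.crystalPixels <- function(rowC, colC, sizePx, shape, H, W) {
  r0 <- round(rowC); c0 <- round(colC)
  half <- floor((sizePx - 1) / 2)
  dr <- rep(-half:half, times = 2 * half + 1)
  dc <- rep(-half:half, each = 2 * half + 1)
  keep <- if (shape == "disk") sqrt(dr^2 + dc^2) <= sizePx / 2 - 0.1 else TRUE
  rr <- r0 + dr[keep]; cc <- c0 + dc[keep]
  ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
  cbind(rr[ok], cc[ok])
}

# background: base level + linear gradient + low-frequency Gaussian blobs,
# amplitude controlled by backgroundContrast; uses the current RNG stream
.renderBackground <- function(scene) {
  H <- scene@imageHeight; W <- scene@imageWidth
  bc <- scene@backgroundContrast
  base <- matrix(0.45, H, W)
  grad <- outer(seq(-1, 1, length.out = H), seq(-1, 1, length.out = W),
                function(r, c) 0.06 * bc * (r + c))
  bg <- base + grad
  nBlobs <- max(3L, round(H * W / 15000))
  for (b in seq_len(nBlobs)) {
    r0 <- runif(1, 1, H); c0 <- runif(1, 1, W)
    s <- runif(1, 0.4, 1.2) * scene@dropletRadius
    a <- runif(1, -1, 1) * 0.25 * bc
    bg <- bg + a * outer(exp(-(seq_len(H) - r0)^2 / (2 * s^2)),
                         exp(-(seq_len(W) - c0)^2 / (2 * s^2)))
  }
  bg
}

# Renders one frame from a fixed layout; uses the current RNG stream for
# background texture and noise. Masks are exact (no noise).
.renderScene <- function(scene, layout, phases) {
  H <- scene@imageHeight; W <- scene@imageWidth
  n <- nrow(layout)
  stopifnot(length(phases) == n)
  img <- .renderBackground(scene)
  dropletMask <- matrix(0L, H, W)
  vateriteMask <- matrix(0L, H, W)
  calciteMask <- matrix(0L, H, W)
  rowIdx <- matrix(seq_len(H), H, W)
  colIdx <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (i in seq_len(n)) {
    d2 <- (rowIdx - layout$row[i])^2 + (colIdx - layout$col[i])^2
    R <- layout$radius[i]
    inside <- d2 <= R^2
    rim <- inside & d2 > (R - 2)^2
    img[inside] <- 0.85
    img[rim] <- 0.25
    dropletMask[inside] <- 255L
    if (phases[i] == "vaterite") {
      px <- .crystalPixels(layout$crystalRow[i], layout$crystalCol[i],
                           scene@crystalSizePx, "disk", H, W)
      vateriteMask[px] <- 255L
      img[px] <- 0.30
    } else if (phases[i] == "calcite") {
      px <- .crystalPixels(layout$crystalRow[i], layout$crystalCol[i],
                           scene@crystalSizePx, "square", H, W)
      calciteMask[px] <- 255L
      img[px] <- 0.06
    }
  }
  rgb <- array(0, dim = c(H, W, 3))
  for (ch in 1:3)
    rgb[, , ch] <- pmin(pmax(img + rnorm(H * W, 0, scene@noiseSd / 255), 0), 1)
  list(rgb = rgb, dropletMask = dropletMask, vateriteMask = vateriteMask,
       calciteMask = calciteMask)
}

#' Generate one synthetic droplet scene with exact ground truth
#'
#' Places non-overlapping droplets fully inside the frame (rejection
#' sampling), renders the RGB frame with background distractors and noise,
#' and returns exact binary masks for droplets, vaterite and calcite.
#'
#' @param scene a [SceneSpec-class].
#' @param phases character vector, one of `"acc"`, `"vaterite"`,
#'   `"calcite"` per droplet; defaults to all-ACC.
#' @param seed RNG seed; identical seeds give bit-identical output.
#' @return list with `rgb` (H x W x 3, values in [0, 1]), the three
#'   `{0, 255}` masks, and `truth` (droplet circles + phases).
#' @examples
#' sc <- generateScene(SceneSpec(imageHeight = 96L, imageWidth = 96L,
#'                               dropletRadius = 12, dropletsPerFrame = 3L),
#'                     phases = c("acc", "vaterite", "calcite"), seed = 7)
#' dim(sc$rgb)
#' @export
generateScene <- function(scene, phases = NULL, seed = scene@rngSeed) {
  stopifnot(is(scene, "SceneSpec"))
  validObject(scene)
  if (is.null(phases)) phases <- rep("acc", scene@dropletsPerFrame)
  if (length(phases) != scene@dropletsPerFrame)
    stop("phase list length must equal dropletsPerFrame")
  if (!all(phases %in% c("acc", "vaterite", "calcite")))
    stop("phases must be 'acc', 'vaterite' or 'calcite'")
  set.seed(seed)
  layout <- .placeDroplets(scene)
  rend <- .renderScene(scene, layout, phases)
  c(rend, list(truth = list(circles = layout[, c("row", "col", "radius")],
                            phases = phases, layout = layout)))
}

#' Generate a seeded synthetic time-lapse with known kinetics
#'
#' Droplet positions are fixed per location across time; each droplet's
#' transformation time is drawn once from the kinetic model, and a droplet
#' transformed at time tau shows its crystal in every frame acquired at or
#' after tau. Location `l` acquires timestep `j` at
#' `timesteps[j] + (l - 1) * perLocationTimeOffsetMin`, mimicking
#' sequential snapshot acquisition.
#'
#' @param scene a [SceneSpec-class].
#' @param kinetics a [KineticsSpec-class].
#' @param seed master seed.
#' @param render render RGB frames and masks (set `FALSE` to obtain the
#'   manifest and exact truth counts only, e.g. for kinetic recovery
#'   studies).
#' @param outDir if non-`NULL`, frames and masks are written there as PNG
#'   as they are generated (memory-frugal) and `frame_path` is filled in.
#' @return list with `manifest` (location_id, timestep_index,
#'   acquisition_time_min, frame_path relative to `outDir`), `counts` (the exact per-frame
#'   truth table with `N_d`, `N_vaterite_droplets`, `N_calcite_droplets`,
#'   `N_d_ACC`), and `frames` (per-frame rendered data + truth, or `NULL`
#'   entries when written to disk / not rendered).
#' @export
generateTimelapse <- function(scene, kinetics, seed = 1L, render = TRUE,
                              outDir = NULL) {
  stopifnot(is(scene, "SceneSpec"), is(kinetics, "KineticsSpec"))
  validObject(scene); validObject(kinetics)
  if (length(kinetics@timesteps) == 0) stop("timesteps must be non-empty")
  nLoc <- kinetics@nLocations
  nT <- length(kinetics@timesteps)
  set.seed(seed)
  locSeeds <- sample.int(.Machine$integer.max - 1L, nLoc)
  manifest <- NULL
  counts <- NULL
  frames <- vector("list", nLoc * nT)
  layouts <- vector("list", nLoc)
  schedules <- vector("list", nLoc)
  if (!is.null(outDir)) {
    dir.create(file.path(outDir, "frames"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(outDir, "masks"), recursive = TRUE, showWarnings = FALSE)
  }
  for (l in seq_len(nLoc)) {
    set.seed(locSeeds[l])
    layout <- .placeDroplets(scene)
    sched <- .sampleScheduleRaw(kinetics, scene@dropletsPerFrame)
    layouts[[l]] <- layout
    schedules[[l]] <- sched
    for (j in seq_len(nT)) {
      tAcq <- kinetics@timesteps[j] + (l - 1) * kinetics@perLocationTimeOffsetMin
      phases <- ifelse(sched$transformationTime <= tAcq, sched$phase, "acc")
      if (length(phases) == 0) phases <- character(0)
      nVat <- sum(phases == "vaterite")
      nCal <- sum(phases == "calcite")
      nD <- length(phases)
      counts <- rbind(counts, data.frame(
        location_id = l, timestep_index = j, acquisition_time_min = tAcq,
        N_d = nD, N_vaterite_droplets = nVat, N_calcite_droplets = nCal,
        N_d_ACC = nD - nVat - nCal))
      framePath <- NA_character_
      idx <- (l - 1) * nT + j
      if (render) {
        rend <- .renderScene(scene, layout, phases)
        fr <- c(rend, list(truth = list(
          circles = layout[, c("row", "col", "radius")], phases = phases,
          layout = layout)))
        if (!is.null(outDir)) {
          stem <- sprintf("loc%02d_t%02d", l, j)
          framePath <- file.path("frames", paste0(stem, ".png"))
          writeFrame(fr$rgb, file.path(outDir, framePath))
          for (cl in c("droplet", "vaterite", "calcite"))
            writeMask(fr[[paste0(cl, "Mask")]],
                      file.path(outDir, "masks", paste0(stem, "_", cl, ".png")))
        } else {
          frames[[idx]] <- fr
        }
      }
      manifest <- rbind(manifest, data.frame(
        location_id = l, timestep_index = j, acquisition_time_min = tAcq,
        frame_path = framePath, stringsAsFactors = FALSE))
    }
  }
  list(manifest = manifest, counts = counts, frames = frames,
       layouts = layouts, schedules = schedules)
}
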