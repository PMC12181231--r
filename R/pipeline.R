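# ---- configuration ---------------------------------------------------------

.cfgScene <- function(x) {
  if (is.null(x)) x <- list()
  SceneSpec(
    imageHeight = x$image_height %||% 384L,
    imageWidth = x$image_width %||% 768L,
    dropletRadius = x$droplet_radius %||% 22,
    radiusJitter = x$radius_jitter %||% 0.08,
    dropletsPerFrame = x$droplets_per_frame %||% 55L,
    crystalSizePx = x$crystal_size_px %||% 3L,
    backgroundContrast = x$background_contrast %||% 0.5,
    noiseSd = x$noise_sd %||% 5,
    rngSeed = x$rng_seed %||% 1L)
}

.cfgKinetics <- function(x) {
  if (is.null(x)) x <- list()
  KineticsSpec(
    kTrue = x$k_true %||% 0.027,
    labileFraction = x$labile_fraction %||% 0.1,
    initialTransformedFraction = x$initial_transformed_fraction %||% 0,
    pVaterite = x$p_vaterite %||% 0.5,
    timesteps = x$timesteps %||% seq(0, 360, by = 22.5),
    nLocations = x$n_locations %||% 12L,
    perLocationTimeOffsetMin = x$per_location_time_offset_min %||% 1.5)
}

.cfgUnet <- function(x, seed) {
  if (is.null(x)) return(deskUnetSpec(seed = seed))
  UNetSpec(nEncoders = x$n_encoders %||% 3L,
           baseFilters = x$base_filters %||% 8L,
           learningRate = x$learning_rate %||% 2e-3,
           batchSize = x$batch_size %||% 4L,
           nEpochs = x$n_epochs %||% 60L,
           seed = x$seed %||% seed)
}

.cfgTrain <- function(x, seed) {
  if (is.null(x)) x <- list()
  TrainConfig(splitFraction = x$split_fraction %||% 0.8,
              hflip = x$hflip %||% TRUE, vflip = x$vflip %||% TRUE,
              rot90 = x$rot90 %||% TRUE,
              brightnessJitter = x$brightness_jitter %||% 0.05,
              lossMode = x$loss_mode %||% "sum",
              seed = x$seed %||% seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build or read the pipeline configuration
#'
#' The configuration is a nested list holding validated S4 specification
#' objects for every pipeline stage plus scalar counting/detection/tiling
#' parameters and a global seed. `readPipelineConfig()` parses the same
#' structure from a YAML file (snake_case keys, see the packaged example
#' in `inst/extdata/config-example.yaml`).
#'
#' @param raw nested list of raw (YAML-style) settings; missing entries
#'   take the documented defaults.
#' @return list with elements `seed`, `scene`, `kinetics`, `unet`
#'   (sub-lists `droplet`, `vaterite`, `calcite`), `train`, `tiling`,
#'   `counting`, `detection`, `kineticsOptions`.
#' @export
pipelineConfig <- function(raw = list()) {
  seed <- as.integer(raw$seed %||% 1L)
  tiling <- raw$tiling %||% list()
  counting <- raw$counting %||% list()
  detection <- raw$detection %||% list()
  kin <- raw$kinetics_options %||% list()
  cfg <- list(
    seed = seed,
    scene = .cfgScene(raw$scene),
    kinetics = .cfgKinetics(raw$kinetics),
    unet = list(droplet = .cfgUnet(raw$unet$droplet, seed),
                vaterite = .cfgUnet(raw$unet$vaterite, seed + 1L),
                calcite = .cfgUnet(raw$unet$calcite, seed + 2L)),
    train = .cfgTrain(raw$train, seed),
    tiling = list(grid = as.integer(tiling$grid %||% c(0L, 0L)),
                  targetHw = if (is.null(tiling$target_hw)) NULL
                             else as.integer(tiling$target_hw)),
    counting = list(minAreaDroplet = counting$min_area_droplet %||% 50L,
                    minAreaCrystal = counting$min_area_crystal %||% 1L,
                    connectivity = counting$connectivity %||% 8L,
                    kmeansSeed = counting$kmeans_seed %||% 0L),
    detection = list(marginPx = detection$margin_px %||% 2),
    kineticsOptions = list(bootstrap = kin$bootstrap %||% TRUE,
                           nBoot = kin$n_boot %||% 200L))
  for (s in c("scene", "kinetics", "train")) validObject(cfg[[s]])
  for (s in names(cfg$unet)) validObject(cfg$unet[[s]])
  cfg
}

#' @rdname pipelineConfig
#' @param path YAML file.
#' @param overrides named list merged over the file contents.
#' @export
readPipelineConfig <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  raw <- utils::modifyList(raw, overrides)
  pipelineConfig(raw)
}

.cfgHash <- function(config) {
  # stable short provenance tag for output headers
  s <- paste(deparse(config$seed), config$scene@rngSeed,
             config$kinetics@kTrue, collapse = "|")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% .Machine$integer.max)
}

# ---- subcommands -----------------------------------------------------------

#' Write a synthetic time-lapse dataset to disk
#'
#' Renders every frame of the configured time-lapse, writes frames and
#' exact ground-truth masks as PNG, the frame manifest and true counts as
#' CSV (with a provenance header), and the per-droplet ground truth as
#' CSV + JSON.
#'
#' @param config a [pipelineConfig()] list.
#' @param outDir output directory (created if needed).
#' @return The manifest data.frame, invisibly.
#' @export
cmdSimulate <- function(config, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(outDir, 2) != 0) stop("output directory is not writable")
  tl <- generateTimelapse(config$scene, config$kinetics, seed = config$seed,
                          render = TRUE, outDir = outDir)
  prov <- sprintf("# config: %s", .cfgHash(config))
  .writeCsvProv(tl$manifest, file.path(outDir, "manifest.csv"),
                seed = config$seed, extra = prov)
  .writeCsvProv(tl$counts, file.path(outDir, "truth_counts.csv"),
                seed = config$seed, extra = prov)
  gt <- do.call(rbind, lapply(seq_along(tl$layouts), function(l) {
    lay <- tl$layouts[[l]]; sch <- tl$schedules[[l]]
    if (nrow(lay) == 0) return(NULL)
    data.frame(location_id = l, droplet = seq_len(nrow(lay)),
               row = lay$row, col = lay$col, radius = lay$radius,
               transformation_time_min = sch$transformationTime,
               phase = sch$phase)
  }))
  if (is.null(gt)) gt <- data.frame()
  .writeCsvProv(gt, file.path(outDir, "ground_truth.csv"),
                seed = config$seed, extra = prov)
  jsonlite::write_json(
    list(seed = config$seed, config = .cfgHash(config),
         n_frames = nrow(tl$manifest),
         n_droplets_total = sum(tl$counts$N_d)),
    file.path(outDir, "provenance.json"), auto_unbox = TRUE)
  message(sprintf("simulate: %d frames (%d locations x %d timesteps), %d droplet observations",
                  nrow(tl$manifest), config$kinetics@nLocations,
                  length(config$kinetics@timesteps), sum(tl$counts$N_d)))
  invisible(tl$manifest)
}

# labeling scheme mirrored from the published protocol: 5 timesteps from
# the first labeled location, 2 each from up to three further locations
.defaultLabeledFrames <- function(manifest) {
  locs <- sort(unique(manifest$location_id))
  tsteps <- sort(unique(manifest$timestep_index))
  pick <- function(l, k) {
    idx <- tsteps[unique(round(seq(1, length(tsteps), length.out = k)))]
    which(manifest$location_id == l & manifest$timestep_index %in% idx)
  }
  sel <- pick(locs[1], 5L)
  for (l in locs[-1][seq_len(min(3, length(locs) - 1))])
    sel <- c(sel, pick(l, 2L))
  sort(unique(sel))
}

.loadPairs <- function(dataDir, manifest, rows) {
  lapply(rows, function(i) {
    stem <- sprintf("loc%02d_t%02d", manifest$location_id[i],
                    manifest$timestep_index[i])
    maskPath <- function(cl) file.path(dataDir, "masks",
                                       paste0(stem, "_", cl, ".png"))
    list(stem = stem,
         rgb = readFrame(file.path(dataDir, manifest$frame_path[i])),
         droplet = maskPath("droplet"), vaterite = maskPath("vaterite"),
         calcite = maskPath("calcite"))
  })
}

#' Train the three cascade stages from a simulated (or labeled) dataset
#'
#' Stage 1 trains on raw frames against droplet masks; stages 2 and 3
#' train on frames overlaid with the ground-truth droplet mask against
#' the vaterite and calcite masks. Frames are tiled per the configured
#' grid. Checkpoints are written as RDS with a JSON sidecar recording the
#' architecture and seed, plus a `metrics.json` with final train and
#' validation binary cross-entropy per stage.
#'
#' @param config a [pipelineConfig()] list.
#' @param dataDir dataset directory (layout of [cmdSimulate()]).
#' @param outDir checkpoint/metrics output directory.
#' @param frameRows manifest rows to use as the labeled set; the default
#'   mirrors a small manual-labeling protocol (5 timesteps from one
#'   location, 2 each from up to three more).
#' @return list of the three trained models, invisibly.
#' @export
cmdTrain <- function(config, dataDir, outDir,
                     frameRows = NULL) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- .readCsvProv(file.path(dataDir, "manifest.csv"))
  if (is.null(frameRows)) frameRows <- .defaultLabeledFrames(manifest)
  if (length(frameRows) == 0) stop("no labeled frames selected")
  pairs <- .loadPairs(dataDir, manifest, frameRows)
  missing <- lapply(c(droplet = "droplet", vaterite = "vaterite",
                      calcite = "calcite"), function(cl)
    vapply(pairs, function(p) !file.exists(p[[cl]]), logical(1)))
  for (cl in names(missing)) if (all(missing[[cl]]))
    stop(sprintf("stage %s: no label masks found (e.g. %s)",
                 switch(cl, droplet = "1 (droplet)", vaterite = "2 (vaterite)",
                        calcite = "3 (calcite)"),
                 pairs[[1]][[cl]]))
  for (cl in names(missing)) if (any(missing[[cl]]))
    stop(sprintf("stage %s: missing masks: %s", cl,
                 paste(vapply(pairs[missing[[cl]]], `[[`, character(1), cl),
                       collapse = ", ")))
  grid <- config$tiling$grid
  thw <- config$tiling$targetHw
  maxDiv <- max(vapply(config$unet, function(s) 2^(s@nEncoders - 1), numeric(1)))
  tileUp <- function(img, kind) {
    ts <- cutAndResize(img, grid = grid, targetHw = thw, kind = kind,
                       requiredDivisor = maxDiv)
    ts@tiles
  }
  x1 <- list(); y1 <- list(); x23 <- list(); y2 <- list(); y3 <- list()
  for (p in pairs) {
    dm <- readMask(p$droplet)
    x1 <- c(x1, tileUp(p$rgb, "image"))
    y1 <- c(y1, tileUp(dm, "mask"))
    ov <- overlayMask(p$rgb, dm)
    x23 <- c(x23, tileUp(ov, "image"))
    y2 <- c(y2, tileUp(readMask(p$vaterite), "mask"))
    y3 <- c(y3, tileUp(readMask(p$calcite), "mask"))
  }
  models <- list()
  metrics <- list()
  stages <- list(droplet = list(x = x1, y = y1),
                 vaterite = list(x = x23, y = y2),
                 calcite = list(x = x23, y = y3))
  for (nm in names(stages)) {
    message(sprintf("train: stage %s on %d tiles", nm, length(stages[[nm]]$x)))
    model <- buildUnet(config$unet[[nm]], inChannels = 3L)
    model <- trainUnet(model, stages[[nm]]$x, stages[[nm]]$y, config$train)
    models[[nm]] <- model
    last <- model@history[nrow(model@history), ]
    metrics[[nm]] <- list(finalTrainBce = last$trainBce,
                          finalValBce = last$valBce,
                          epochs = nrow(model@history))
    saveRDS(model, file.path(outDir, sprintf("unet_%s.rds", nm)))
    spec <- config$unet[[nm]]
    jsonlite::write_json(
      list(stage = nm, n_encoders = spec@nEncoders,
           base_filters = spec@baseFilters, learning_rate = spec@learningRate,
           batch_size = spec@batchSize, n_epochs = spec@nEpochs,
           seed = spec@seed, loss_mode = config$train@lossMode),
      file.path(outDir, sprintf("unet_%s.json", nm)), auto_unbox = TRUE)
  }
  jsonlite::write_json(c(list(seed = config$seed, config = .cfgHash(config)),
                         metrics),
                       file.path(outDir, "metrics.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(models)
}

#' Segment, classify and count every manifest frame
#'
#' Runs the cascade (or, with `oracleMasks = TRUE`, reads the exact
#' ground-truth masks instead of predicting) on every frame in the
#' manifest, writes the three binary masks and the stacked RGB label
#' image per frame, per-droplet detections and per-frame counts as CSV.
#'
#' @param config a [pipelineConfig()] list.
#' @param dataDir dataset directory (layout of [cmdSimulate()]).
#' @param checkpointDir directory holding `unet_*.rds` checkpoints
#'   (ignored in oracle mode).
#' @param outDir output directory.
#' @param oracleMasks bypass the networks and consume ground-truth masks.
#' @return The per-frame counts data.frame, invisibly.
#' @export
cmdPredict <- function(config, dataDir, checkpointDir = NULL, outDir,
                       oracleMasks = FALSE) {
  dir.create(file.path(outDir, "segmentation"), recursive = TRUE,
             showWarnings = FALSE)
  manifest <- .readCsvProv(file.path(dataDir, "manifest.csv"))
  models <- NULL
  if (!oracleMasks) {
    paths <- file.path(checkpointDir, sprintf("unet_%s.rds",
                                              c("droplet", "vaterite", "calcite")))
    if (any(!file.exists(paths)))
      stop("missing checkpoint(s): ", paste(paths[!file.exists(paths)],
                                            collapse = ", "))
    models <- lapply(paths, readRDS)
    names(models) <- c("droplet", "vaterite", "calcite")
  }
  counts <- NULL; detAll <- NULL; objAll <- NULL
  for (i in seq_len(nrow(manifest))) {
    stem <- sprintf("loc%02d_t%02d", manifest$location_id[i],
                    manifest$timestep_index[i])
    t0 <- proc.time()[3]
    if (oracleMasks) {
      mp <- function(cl) file.path(dataDir, "masks", paste0(stem, "_", cl, ".png"))
      seg <- list(dropletMask = readMask(mp("droplet")),
                  vateriteMask = readMask(mp("vaterite")),
                  calciteMask = readMask(mp("calcite")),
                  probs = list(vaterite = NULL, calcite = NULL))
    } else {
      rgb <- tryCatch(readFrame(file.path(dataDir, manifest$frame_path[i])),
                      error = function(e) NULL)
      if (is.null(rgb)) {
        message(sprintf("predict: frame %s unreadable, skipped", stem))
        next
      }
      seg <- runCascade(models, rgb, grid = config$tiling$grid,
                        targetHw = config$tiling$targetHw,
                        kmeansSeed = config$counting$kmeansSeed)
    }
    circles <- findDropletCircles(seg$dropletMask,
                                  minArea = config$counting$minAreaDroplet,
                                  connectivity = config$counting$connectivity)
    det <- withCallingHandlers(
      assignCrystals(circles, seg$vateriteMask, seg$calciteMask,
                     marginPx = config$detection$marginPx,
                     minArea = config$counting$minAreaCrystal,
                     connectivity = config$counting$connectivity),
      warning = function(w) { message("predict: ", stem, ": ",
                                      conditionMessage(w))
                              invokeRestart("muffleWarning") })
    tp <- countTimepoint(det, manifest$location_id[i],
                         manifest$timestep_index[i],
                         manifest$acquisition_time_min[i])
    counts <- rbind(counts, tp)
    objAll <- rbind(objAll,
                    data.frame(frame = stem,
                               class = c("droplet", "vaterite", "calcite"),
                               n_objects = c(tp$N_d,
                                             countObjects(seg$vateriteMask,
                                                          config$counting$minAreaCrystal,
                                                          config$counting$connectivity)$nObjects,
                                             countObjects(seg$calciteMask,
                                                          config$counting$minAreaCrystal,
                                                          config$counting$connectivity)$nObjects)))
    if (nrow(det) > 0) detAll <- rbind(detAll, cbind(frame = stem, det))
    stacked <- suppressWarnings(
      stackSegmentations(seg$dropletMask, seg$vateriteMask, seg$calciteMask,
                         seg$probs$vaterite, seg$probs$calcite))
    for (cl in c("dropletMask", "vateriteMask", "calciteMask"))
      writeMask(seg[[cl]], file.path(outDir, "segmentation",
                                     paste0(stem, "_", sub("Mask", "", cl),
                                            "_pred.png")))
    writeFrame(stacked / 255,
               file.path(outDir, "segmentation", paste0(stem, "_stacked.png")))
    message(sprintf("predict: %s: %d droplets (%.2f s)", stem, tp$N_d,
                    proc.time()[3] - t0))
  }
  .writeCsvProv(counts, file.path(outDir, "counts.csv"), seed = config$seed)
  .writeCsvProv(objAll, file.path(outDir, "objects.csv"), seed = config$seed)
  if (!is.null(detAll))
    .writeCsvProv(detAll, file.path(outDir, "detections.csv"),
                  seed = config$seed)
  invisible(counts)
}

#' Assemble the time series, fit the decay and report kinetics
#'
#' @param config a [pipelineConfig()] list.
#' @param countsCsv per-frame counts CSV (from [cmdPredict()] or the
#'   generator truth table).
#' @param outDir report output directory.
#' @param manualTotal,manualAcc,manualTimeMin optional late manual count
#'   (total droplets, ACC droplets, time in minutes) appended to the
#'   report as an ACC fraction plus an empirical half-life lower bound.
#' @return The report list, invisibly; written as `fit_report.json`, with
#'   the plot-ready series as `timeseries.csv`.
#' @export
cmdAnalyze <- function(config, countsCsv, outDir, manualTotal = NULL,
                       manualAcc = NULL, manualTimeMin = NULL) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  counts <- .readCsvProv(countsCsv)
  ts <- assembleTimeseries(counts)
  if (any(ts$N_d == 0)) {
    warning(sprintf("excluding %d timestep(s) with zero detected droplets (undefined ACC ratio)",
                    sum(ts$N_d == 0)))
    ts <- ts[ts$N_d > 0, , drop = FALSE]
  }
  if (nrow(ts) < 4)
    stop("at least 4 points are required to fit 3 parameters")
  countFit <- fitDecay(ts$mean_time_min, ts$N_d_ACC, form = "count")
  ratioFit <- fitDecay(ts$mean_time_min, ts$N_d_ACC / ts$N_d, form = "ratio")
  hlModel <- halfLifeBound(fit = ratioFit)
  hlEmp <- halfLifeBound(series = data.frame(
    time = ts$mean_time_min, fraction = ts$N_d_ACC / ts$N_d))
  report <- list(
    n_timesteps = nrow(ts),
    count_fit = list(A = countFit@A, k = countFit@k, C = countFit@C,
                     rss = countFit@rss, no_decay = countFit@noDecay),
    ratio_fit = list(A = ratioFit@A, k = ratioFit@k, C = ratioFit@C,
                     rss = ratioFit@rss, no_decay = ratioFit@noDecay),
    end_of_run_acc_fraction = evaluateFit(ratioFit, max(ts$mean_time_min)),
    half_life = list(
      model = list(kind = hlModel@kind, value_min = hlModel@valueMin),
      empirical_lower_bound_min = hlEmp@valueMin))
  if (isTRUE(config$kineticsOptions$bootstrap)) {
    report$rate_bootstrap <- bootstrapRateCI(
      ts, nBoot = config$kineticsOptions$nBoot, seed = config$seed)
  }
  if (!is.null(manualTotal) && !is.null(manualAcc)) {
    frac <- accFraction(manualAcc, manualTotal)
    mb <- list(n_total = manualTotal, n_acc = manualAcc,
               acc_fraction = frac)
    if (!is.null(manualTimeMin)) {
      hl <- halfLifeBound(series = data.frame(time = manualTimeMin,
                                              fraction = frac))
      mb$half_life_lower_bound_min <- hl@valueMin
    }
    report$manual_count <- mb
  }
  jsonlite::write_json(report, file.path(outDir, "fit_report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  .writeCsvProv(ts, file.path(outDir, "timeseries.csv"), seed = config$seed)
  message(sprintf("analyze: k = %.4g /min, plateau %.4g (%s)%s",
                  ratioFit@k, ratioFit@C, ratioFit@form,
                  if (ratioFit@noDecay) " [no decay detected]" else ""))
  invisible(report)
}

#' Simulate, train, predict and analyze in one run
#'
#' @param config a [pipelineConfig()] list.
#' @param outDir run directory; subdirectories `data/`, `checkpoints/`,
#'   `predictions/` and `report/` are created.
#' @param oracleMasks skip training and predict from ground-truth masks.
#' @return The analysis report, invisibly.
#' @export
cmdEnd2End <- function(config, outDir, oracleMasks = FALSE) {
  dataDir <- file.path(outDir, "data")
  ckptDir <- file.path(outDir, "checkpoints")
  predDir <- file.path(outDir, "predictions")
  repDir <- file.path(outDir, "report")
  cmdSimulate(config, dataDir)
  if (!oracleMasks) cmdTrain(config, dataDir, ckptDir)
  cmdPredict(config, dataDir, ckptDir, predDir, oracleMasks = oracleMasks)
  cmdAnalyze(config, file.path(predDir, "counts.csv"), repDir)
}
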