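# canonical parameter order shared with the C++ pass:
# enc1 W1,b1,W2,b2 ... encN; then dec(N-1) ... dec1; then out_W, out_b
.unetParamShapes <- function(spec, inChannels) {
  f <- filterSchedule(spec)
  n <- spec@nEncoders
  shapes <- list()
  cin <- inChannels
  for (i in seq_len(n)) {
    shapes[[sprintf("enc%d_W1", i)]] <- c(9 * cin, f[i])
    shapes[[sprintf("enc%d_b1", i)]] <- c(1, f[i])
    shapes[[sprintf("enc%d_W2", i)]] <- c(9 * f[i], f[i])
    shapes[[sprintf("enc%d_b2", i)]] <- c(1, f[i])
    cin <- f[i]
  }
  for (i in rev(seq_len(n - 1))) {
    cat_in <- f[i] + f[i + 1]
    shapes[[sprintf("dec%d_W1", i)]] <- c(9 * cat_in, f[i])
    shapes[[sprintf("dec%d_b1", i)]] <- c(1, f[i])
    shapes[[sprintf("dec%d_W2", i)]] <- c(9 * f[i], f[i])
    shapes[[sprintf("dec%d_b2", i)]] <- c(1, f[i])
  }
  shapes[["out_W"]] <- c(f[1], 1)
  shapes[["out_b"]] <- c(1, 1)
  shapes
}

#' Build an untrained binary U-Net
#'
#' Weights are He-normal initialised (seeded from the spec), biases zero.
#' The deepest level carries `baseFilters * 2^(nEncoders - 1)` filters.
#'
#' @param spec a [UNetSpec-class].
#' @param inChannels input channels (3 for RGB microscopy frames).
#' @return An untrained [UNetModel-class].
#' @examples
#' m <- buildUnet(deskUnetSpec(nEncoders = 2L, baseFilters = 4L))
#' nParams(m)
#' @export
buildUnet <- function(spec, inChannels = 3L) {
  stopifnot(is(spec, "UNetSpec"))
  validObject(spec)
  shapes <- .unetParamShapes(spec, as.integer(inChannels))
  set.seed(spec@seed)
  params <- lapply(names(shapes), function(nm) {
    sh <- shapes[[nm]]
    if (grepl("_b", nm)) return(matrix(0, sh[1], sh[2]))
    fanIn <- sh[1]
    matrix(rnorm(prod(sh), sd = sqrt(2 / fanIn)), sh[1], sh[2])
  })
  names(params) <- names(shapes)
  new("UNetModel", spec = spec, inChannels = as.integer(inChannels),
      params = params, trained = FALSE,
      history = data.frame(epoch = integer(), trainBce = numeric(),
                           valBce = numeric()))
}

.asInputCube <- function(image, inChannels) {
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1))
  if (dim(image)[3] != inChannels)
    stop(sprintf("expected %d input channel(s), got %d", inChannels,
                 dim(image)[3]))
  image
}

.checkDivisible <- function(model, h, w) {
  div <- 2^(model@spec@nEncoders - 1)
  if (h %% div != 0 || w %% div != 0)
    stop(sprintf("input size %d x %d must be divisible by %d (2^(nEncoders-1))",
                 h, w, div))
}

#' Predict a probability map for one frame or tile
#'
#' @param model a [UNetModel-class].
#' @param image matrix or H x W x C array with intensities in [0, 1];
#'   spatial dimensions must be divisible by `2^(nEncoders - 1)`.
#' @return Matrix of per-pixel foreground probabilities in [0, 1].
#' @export
predictUnet <- function(model, image) {
  stopifnot(is(model, "UNetModel"))
  x <- .asInputCube(image, model@inChannels)
  .checkDivisible(model, dim(x)[1], dim(x)[2])
  res <- unet_pass_cpp(model@params, model@spec@nEncoders,
                       filterSchedule(model@spec), x,
                       matrix(0, dim(x)[1], dim(x)[2]), FALSE, FALSE)
  res$prob
}

#' @rdname predictUnet
#' @param object a [UNetModel-class].
#' @param ... passed on (expects `image`).
#' @export
setMethod("predict", "UNetModel", function(object, ...) predictUnet(object, ...))

# geometric + photometric augmentation of an (image, mask) pair
.augmentPair <- function(img, msk, cfg) {
  flipR <- cfg@hflip && runif(1) < 0.5
  flipC <- cfg@vflip && runif(1) < 0.5
  rot <- if (cfg@rot90 && nrow(msk) == ncol(msk)) sample(0:3, 1) else 0L
  tf <- function(m) {
    if (flipR) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    if (flipC) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    for (q in seq_len(rot)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
    m
  }
  if (is.matrix(img)) img <- tf(img) else
    for (ch in seq_len(dim(img)[3])) img[, , ch] <- tf(img[, , ch])
  if (cfg@brightnessJitter > 0)
    img <- pmin(pmax(img * (1 + runif(1, -cfg@brightnessJitter,
                                      cfg@brightnessJitter)), 0), 1)
  list(img = img, msk = tf(msk))
}

.lossScale <- function(mode, nPix) if (mode == "mean") 1 / nPix else 1

#' Train a binary U-Net on paired images and masks
#'
#' Seeded Adam training on binary cross-entropy with an 80:20 (by default)
#' train/validation split; augmentation (flips, 90-degree rotations on
#' square tiles, brightness jitter) is applied to training samples only.
#' The returned model carries the best-on-validation weights and the
#' per-epoch loss trace.
#'
#' @param model an untrained (or pre-trained) [UNetModel-class].
#' @param images list of matrices / H x W x C arrays in [0, 1].
#' @param masks list of binary masks ({0, 255} or {0, 1}) matching
#'   `images` spatially.
#' @param cfg a [TrainConfig-class].
#' @return The trained [UNetModel-class]; `@history` holds per-epoch
#'   binary cross-entropy (summed over pixels, or per-pixel mean when
#'   `cfg@lossMode == "mean"`), averaged over samples.
#' @export
trainUnet <- function(model, images, masks, cfg = TrainConfig()) {
  stopifnot(is(model, "UNetModel"), is(cfg, "TrainConfig"))
  validObject(cfg)
  n <- length(images)
  if (n == 0) stop("empty training set")
  if (length(masks) != n) stop("images and masks must pair up")
  for (i in seq_len(n)) {
    di <- dim(images[[i]]); dm <- dim(masks[[i]])
    if (!all(di[1:2] == dm[1:2]))
      stop(sprintf("pair %d: image and mask dimensions differ", i))
    if (!.isBinaryMask(masks[[i]]))
      stop(sprintf("pair %d: mask is not binary", i))
    .checkDivisible(model, di[1], di[2])
  }
  masks01 <- lapply(masks, .maskTo01)
  spec <- model@spec
  fs <- filterSchedule(spec)
  set.seed(cfg@seed)
  if (n == 1) {
    trainIdx <- valIdx <- 1L
  } else {
    nTrain <- min(max(1L, round(cfg@splitFraction * n)), n - 1L)
    perm <- sample(n)
    trainIdx <- perm[seq_len(nTrain)]
    valIdx <- perm[(nTrain + 1):n]
  }
  params <- model@params
  flat <- lapply(params, as.numeric)
  mAdam <- lapply(flat, function(x) x * 0)
  vAdam <- mAdam
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  bestVal <- Inf
  bestParams <- params
  hist <- data.frame(epoch = integer(), trainBce = numeric(),
                     valBce = numeric())
  evalLoss <- function(idxs) {
    tot <- 0; pix <- 0
    for (i in idxs) {
      x <- .asInputCube(images[[i]], model@inChannels)
      r <- unet_pass_cpp(params, spec@nEncoders, fs, x, masks01[[i]],
                         TRUE, FALSE)
      tot <- tot + r$loss
      pix <- pix + length(masks01[[i]])
    }
    if (cfg@lossMode == "mean") tot / pix else tot / length(idxs)
  }
  for (epoch in seq_len(spec@nEpochs)) {
    order <- sample(trainIdx, length(trainIdx))
    batches <- split(order, ceiling(seq_along(order) / spec@batchSize))
    epochLoss <- 0; epochPix <- 0
    for (batch in batches) {
      gAcc <- NULL
      for (i in batch) {
        aug <- .augmentPair(images[[i]], masks01[[i]], cfg)
        x <- .asInputCube(aug$img, model@inChannels)
        r <- unet_pass_cpp(params, spec@nEncoders, fs, x, aug$msk, TRUE, TRUE)
        epochLoss <- epochLoss + r$loss
        epochPix <- epochPix + length(aug$msk)
        g <- lapply(r$grads, as.numeric)
        gAcc <- if (is.null(gAcc)) g else Map(`+`, gAcc, g)
      }
      gAcc <- lapply(gAcc, function(g) g / length(batch))
      step <- step + 1L
      corr <- sqrt(1 - b2^step) / (1 - b1^step)
      for (p in seq_along(flat)) {
        mAdam[[p]] <- b1 * mAdam[[p]] + (1 - b1) * gAcc[[p]]
        vAdam[[p]] <- b2 * vAdam[[p]] + (1 - b2) * gAcc[[p]]^2
        upd <- spec@learningRate * corr * mAdam[[p]] /
          (sqrt(vAdam[[p]]) + eps)
        newv <- flat[[p]] - upd
        flat[[p]] <- newv
        params[[p]] <- matrix(newv, nrow(params[[p]]), ncol(params[[p]]))
      }
    }
    trainBce <- if (cfg@lossMode == "mean") epochLoss / epochPix
                else epochLoss / length(trainIdx)
    valBce <- evalLoss(valIdx)
    hist <- rbind(hist, data.frame(epoch = epoch, trainBce = trainBce,
                                   valBce = valBce))
    if (valBce <= bestVal) {
      bestVal <- valBce
      bestParams <- params
    }
  }
  model@params <- bestParams
  model@trained <- TRUE
  attr(hist, "split") <- list(train = trainIdx, validation = valIdx)
  model@history <- hist
  model
}

#' Overlay: keep droplet-interior pixels, black out everything else
#'
#' Pixels where the droplet mask is foreground keep their original values;
#' all other pixels are set to zero. Applied between cascade stages so the
#' crystal segmenters see only droplet interiors, removing background
#' contrast and with it the dominant-feature imbalance.
#'
#' @param image matrix or H x W x C array.
#' @param mask binary droplet mask ({0, 255} or {0, 1}), same spatial size.
#' @return The masked image, same shape as `image`. Idempotent:
#'   `overlayMask(overlayMask(x, m), m) == overlayMask(x, m)`.
#' @examples
#' overlayMask(matrix(1, 2, 2), matrix(c(255L, 0L, 0L, 255L), 2, 2))
#' @export
overlayMask <- function(image, mask) {
  di <- dim(image)
  if (!all(di[1:2] == dim(mask)))
    stop("image and mask spatial dimensions differ")
  m01 <- .maskTo01(mask)
  if (is.matrix(image)) return(image * m01)
  out <- image
  for (ch in seq_len(di[3])) out[, , ch] <- image[, , ch] * m01
  out
}
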