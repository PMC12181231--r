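test_that("filter schedule doubles per level", {
  expect_equal(filterSchedule(UNetSpec(5L, 32L, 1e-3, 1L, 1L)),
               c(32L, 64L, 128L, 256L, 512L))
  expect_error(UNetSpec(1L, 8L, 1e-3, 1L, 1L), "nEncoders")
})

test_that("builds are deterministic and sized by the spec", {
  spec <- tinyUnetSpec(seed = 9L)
  a <- buildUnet(spec, inChannels = 3L)
  b <- buildUnet(spec, inChannels = 3L)
  expect_identical(a@params, b@params)
  expect_identical(nParams(a), nParams(b))
  expect_false(isTrained(a))
  # changing depth or width changes the parameter count
  expect_gt(nParams(buildUnet(tinyUnetSpec(nEncoders = 3L))), nParams(a))
})

test_that("prediction preserves shape and stays in [0, 1]", {
  m <- buildUnet(tinyUnetSpec(), inChannels = 1L)
  x <- matrix(runif(16 * 24), 16, 24)
  p <- predictUnet(m, x)
  expect_equal(dim(p), c(16L, 24L))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(predictUnet(m, matrix(0, 15, 16)), "divisible")
  expect_equal(predict(m, image = x), p)
})

test_that("analytic gradients agree with finite differences", {
  spec <- UNetSpec(2L, 2L, 1e-3, 1L, 1L, seed = 3L)
  m <- buildUnet(spec, inChannels = 1L)
  # positive biases keep activations off ReLU kinks and max-pool ties
  for (p in grep("_b", names(m@params))) m@params[[p]][] <- 0.5
  set.seed(4)
  x <- array(runif(64, 0.2, 0.9), dim = c(8, 8, 1))
  y <- matrix(rbinom(64, 1, 0.5), 8, 8)
  fs <- filterSchedule(spec)
  pass <- DropletCascade:::unet_pass_cpp(m@params, 2L, fs, x, y, TRUE, TRUE)
  eps <- 1e-5
  for (p in seq_along(m@params)) {
    P <- m@params
    for (q in seq_len(min(3, length(P[[p]])))) {
      P[[p]][q] <- P[[p]][q] + eps
      lp <- DropletCascade:::unet_pass_cpp(P, 2L, fs, x, y, TRUE, FALSE)$loss
      P[[p]][q] <- P[[p]][q] - 2 * eps
      lm_ <- DropletCascade:::unet_pass_cpp(P, 2L, fs, x, y, TRUE, FALSE)$loss
      P[[p]][q] <- P[[p]][q] + eps
      num <- (lp - lm_) / (2 * eps)
      ana <- as.numeric(pass$grads[[p]])[q]
      expect_lt(abs(num - ana) / max(1, abs(num)), 1e-6)
    }
  }
})

test_that("training reduces the loss on a separable pair", {
  img <- diskMask(16, 16, 8, 8, 5) / 255
  msk <- diskMask(16, 16, 8, 8, 5)
  spec <- tinyUnetSpec(nEpochs = 50L, seed = 1L)
  m <- trainUnet(buildUnet(spec, inChannels = 1L), list(img), list(msk),
                 TrainConfig(brightnessJitter = 0, seed = 1L))
  expect_true(isTrained(m))
  expect_lt(m@history$trainBce[nrow(m@history)], m@history$trainBce[1])
})

test_that("training is reproducible under a fixed seed", {
  imgs <- lapply(1:3, function(i) diskMask(16, 16, 5 + 2 * i, 8, 4) / 255)
  msks <- lapply(1:3, function(i) diskMask(16, 16, 5 + 2 * i, 8, 4))
  run <- function() {
    trainUnet(buildUnet(tinyUnetSpec(nEpochs = 5L, seed = 2L), inChannels = 1L),
              imgs, msks, TrainConfig(seed = 7L))
  }
  a <- run(); b <- run()
  expect_identical(a@history, b@history)
  expect_identical(a@params, b@params)
})

test_that("the default split is 80:20", {
  imgs <- lapply(1:10, function(i) matrix(runif(64), 8, 8))
  msks <- lapply(1:10, function(i) diskMask(8, 8, 4, 4, 2))
  m <- trainUnet(buildUnet(tinyUnetSpec(nEpochs = 1L), inChannels = 1L),
                 imgs, msks, TrainConfig(seed = 1L))
  split <- attr(m@history, "split")
  expect_length(split$train, 8L)
  expect_length(split$validation, 2L)
  expect_setequal(c(split$train, split$validation), 1:10)
})

test_that("training rejects malformed inputs", {
  m <- buildUnet(tinyUnetSpec(), inChannels = 1L)
  expect_error(trainUnet(m, list(), list()), "empty")
  expect_error(trainUnet(m, list(matrix(0, 8, 8)),
                         list(matrix(0.5, 8, 8))), "binary")
  expect_error(trainUnet(m, list(matrix(0, 8, 8)),
                         list(matrix(0L, 8, 10))), "differ")
})

test_that("overlay keeps droplet pixels and blacks out the rest", {
  img <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  m0 <- matrix(0L, 8, 8)
  m1 <- matrix(255L, 8, 8)
  expect_true(all(overlayMask(img, m0) == 0))
  expect_equal(overlayMask(img, m1), img)
  mm <- diskMask(8, 8, 4, 4, 2)
  ov <- overlayMask(img, mm)
  expect_equal(overlayMask(ov, mm), ov)            # idempotent
  expect_true(all(ov[, , 1][mm == 0] == 0))        # restricted to the mask
  expect_error(overlayMask(img, matrix(0L, 4, 4)), "differ")
})

test_that("stacked segmentations partition every pixel into one colour", {
  d <- diskMask(16, 16, 8, 8, 5)
  v <- matrix(0L, 16, 16); v[8, 8] <- 255L
  cl <- matrix(0L, 16, 16); cl[7, 7] <- 255L
  s <- stackSegmentations(d, v, cl)
  colourOf <- function(i, j) paste(s[i, j, ], collapse = ",")
  expect_equal(colourOf(8, 8), "255,0,0")    # vaterite red
  expect_equal(colourOf(7, 7), "0,255,0")    # calcite green
  expect_equal(colourOf(8, 9), "255,255,255")
  expect_equal(colourOf(1, 1), "0,0,0")
  # one colour per pixel: channel-wise memberships sum to the pixel count
  white <- s[, , 1] == 255 & s[, , 2] == 255 & s[, , 3] == 255
  red <- s[, , 1] == 255 & s[, , 2] == 0
  green <- s[, , 2] == 255 & s[, , 1] == 0
  black <- s[, , 1] == 0 & s[, , 2] == 0 & s[, , 3] == 0
  expect_equal(sum(white) + sum(red) + sum(green) + sum(black), 256L)
  expect_equal(sum(white), sum(d != 0) - 2L)
  # a two-crystal conflict resolves by probability, ties to vaterite
  v2 <- v; v2[7, 7] <- 255L
  s2 <- stackSegmentations(d, v2, cl)
  expect_equal(paste(s2[7, 7, ], collapse = ","), "255,0,0")
  pv <- matrix(0.2, 16, 16); pc <- matrix(0.8, 16, 16)
  s3 <- stackSegmentations(d, v2, cl, pv, pc)
  expect_equal(paste(s3[7, 7, ], collapse = ","), "0,255,0")
  # crystal outside the droplet mask is rendered but flagged
  vOut <- matrix(0L, 16, 16); vOut[1, 16] <- 255L
  expect_warning(s4 <- stackSegmentations(d, vOut, cl), "outside")
  expect_equal(paste(s4[1, 16, ], collapse = ","), "255,0,0")
  # all masks empty -> all black
  z <- matrix(0L, 4, 4)
  expect_true(all(stackSegmentations(z, z, z) == 0))
})

test_that("cascade with an oracle droplet mask honours the overlay contract", {
  sc <- mkScene(21)
  blank <- buildUnet(tinyUnetSpec(nEpochs = 1L), inChannels = 3L)
  # force strongly negative output bias so untrained stages predict nothing
  blank@params$out_b[] <- -25
  blank@trained <- TRUE
  seg <- runCascade(list(droplet = blank, vaterite = blank, calcite = blank),
                    sc$rgb, grid = c(1, 1), targetHw = c(64, 64),
                    oracleDropletMask = sc$dropletMask)
  expect_equal(seg$dropletMask, sc$dropletMask)
  expect_true(all(seg$vateriteMask == 0) && all(seg$calciteMask == 0))
  # background distractors vanish from stage-2/3 inputs after overlay
  ov <- overlayMask(sc$rgb, sc$dropletMask)
  expect_true(all(ov[, , 1][sc$dropletMask == 0] == 0))
  # untrained models are rejected
  un <- buildUnet(tinyUnetSpec(), inChannels = 3L)
  expect_error(runCascade(list(un, un, un), sc$rgb), "untrained")
})
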