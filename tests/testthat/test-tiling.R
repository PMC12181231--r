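test_that("an uncut tile at source size is pixel-identical", {
  m <- matrix(runif(48), 6, 8)
  ts <- cutAndResize(m, grid = c(0, 0))
  expect_equal(length(ts@tiles), 1L)
  expect_equal(ts@tiles[[1]], m)
  expect_equal(reconstruct(ts, ts@tiles), m)
})

test_that("a (1,1) grid produces the four quadrants", {
  m <- matrix(1:16, 4, 4)
  ts <- cutAndResize(m, grid = c(1, 1), targetHw = c(2, 2), kind = "mask")
  expect_equal(length(ts@tiles), 4L)
  expect_equal(ts@rects,
               matrix(as.integer(c(1, 2, 1, 2,  1, 2, 3, 4,
                                   3, 4, 1, 2,  3, 4, 3, 4)),
                      ncol = 4, byrow = TRUE))
  expect_equal(ts@tiles[[1]], matrix(as.numeric(m[1:2, 1:2]), 2, 2))
})

test_that("more than two cuts per axis is rejected", {
  m <- matrix(0, 8, 8)
  expect_error(cutAndResize(m, grid = c(3, 0)), "maximum of two")
  expect_error(cutAndResize(m, grid = c(0, 5)), "maximum of two")
})

test_that("target size incompatible with network depth is named", {
  m <- matrix(0, 64, 64)
  expect_error(cutAndResize(m, grid = c(0, 0), targetHw = c(30, 30),
                            requiredDivisor = 4), "divisible by 4")
})

test_that("mask round trips are lossless when tiles keep their size", {
  msk <- diskMask(64, 64, 30, 28, 14)
  ts <- cutAndResize(msk, grid = c(1, 1), targetHw = c(32, 32), kind = "mask")
  expect_equal(reconstruct(ts, ts@tiles), matrix(as.numeric(msk), 64, 64))
})

test_that("all-white predictions reconstruct to an all-white frame", {
  ts <- cutAndResize(matrix(runif(64 * 64), 64, 64), grid = c(1, 1),
                     targetHw = c(16, 16))
  white <- lapply(1:4, function(i) matrix(1, 16, 16))
  expect_true(all(reconstruct(ts, white, method = "nearest") == 1))
})

test_that("missing or malformed tiles are reported", {
  ts <- cutAndResize(matrix(0, 8, 8), grid = c(1, 0), targetHw = c(4, 8))
  expect_error(reconstruct(ts, ts@tiles[1]), "expected 2")
  expect_error(reconstruct(ts, list(matrix(0, 4, 8), matrix(0, 2, 2))),
               "do not match")
  # an off-grid rectangle violates the TileSet partition invariant
  bad <- ts
  bad@rects[2, ] <- c(3L, 8L, 1L, 8L)
  expect_error(validObject(bad), "partition")
})

test_that("resized label masks displace objects by at most the scale factor", {
  msk <- diskMask(64, 64, 24, 40, 10)
  ts <- cutAndResize(msk, grid = c(0, 0), targetHw = c(32, 32), kind = "mask")
  back <- reconstruct(ts, ts@tiles)
  co <- countObjects(matrix(as.integer(back), 64, 64))
  expect_equal(co$nObjects, 1L)
  expect_lt(abs(co$centroids[1, 1] - 24), 2)
  expect_lt(abs(co$centroids[1, 2] - 40), 2)
  expect_gt(maskIoU(back, msk), 0.85)
})
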