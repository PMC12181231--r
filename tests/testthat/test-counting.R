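test_that("near-constant probability maps binarize to background", {
  expect_true(all(binarizeKmeans(matrix(0.02, 16, 16)) == 0))
  expect_true(all(binarizeKmeans(matrix(0.98, 16, 16)) == 0))
  p <- matrix(0.5, 8, 8); p[1, 1] <- 0.55   # separation below 0.1
  expect_true(all(binarizeKmeans(p) == 0))
  expect_error(binarizeKmeans(matrix(numeric(), 0, 0)), "empty")
  expect_error(binarizeKmeans(matrix(1.5, 2, 2)), "\\[0, 1\\]")
})

test_that("well-separated bimodal maps binarize like a 0.5 threshold", {
  set.seed(1)
  p <- matrix(0.1, 20, 20)
  hi <- sample(400, 40)
  p[hi] <- 0.9
  b <- binarizeKmeans(p)
  expect_identical(b != 0, p > 0.5)
  # inverting the map inverts the mask
  binv <- binarizeKmeans(1 - p)
  expect_identical(binv != 0, !(b != 0))
})

test_that("disjoint squares are counted with exact centroids", {
  m <- matrix(0L, 32, 32)
  at <- list(c(4, 4), c(4, 20), c(24, 10))
  for (a in at) m[a[1]:(a[1] + 4), a[2]:(a[2] + 4)] <- 255L
  co <- countObjects(m)
  expect_equal(co$nObjects, 3L)
  expect_equal(co$areas, rep(25L, 3))
  want <- do.call(rbind, lapply(at, function(a) a + 2))
  got <- co$centroids[order(co$centroids[, 1], co$centroids[, 2]), ]
  expect_equal(unname(got), want[order(want[, 1], want[, 2]), ] + 0)
})

test_that("the minimum-area filter removes specks", {
  m <- matrix(0L, 8, 8); m[3, 3] <- 255L
  expect_equal(countObjects(m, minArea = 2L)$nObjects, 0L)
  expect_equal(countObjects(m, minArea = 1L)$nObjects, 1L)
})

test_that("counts agree with an independent flood-fill oracle", {
  for (seed in 1:50) {
    set.seed(seed)
    m <- matrix(as.integer(runif(64 * 64) < 0.35) * 255L, 64, 64)
    conn <- if (seed %% 2 == 0) 4L else 8L
    expect_equal(countObjects(m, connectivity = conn)$nObjects,
                 floodFillCount(m, conn))
  }
})

test_that("counting is invariant to translation and rotation", {
  m <- matrix(0L, 40, 40)
  m[5:9, 5:9] <- 255L; m[20:26, 12:13] <- 255L; m[30, 30] <- 255L
  n0 <- countObjects(m)$nObjects
  shifted <- matrix(0L, 40, 40)
  shifted[8:40, 4:40] <- m[1:33, 1:37]
  expect_equal(countObjects(shifted)$nObjects, n0)
  rot <- t(m)[rev(seq_len(ncol(m))), ]
  expect_equal(countObjects(rot)$nObjects, n0)
})

test_that("binarize-then-count recovers exact synthetic object counts", {
  sc <- mkScene(31)
  for (cl in c("dropletMask", "vateriteMask", "calciteMask")) {
    truthCount <- countObjects(sc[[cl]])$nObjects
    b <- binarizeKmeans(sc[[cl]] / 255)
    expect_equal(countObjects(b)$nObjects, truthCount)
  }
})

test_that("connectivity changes the verdict on diagonal contact", {
  m <- matrix(0L, 4, 4); m[1, 1] <- 255L; m[2, 2] <- 255L
  expect_equal(countObjects(m, connectivity = 8L)$nObjects, 1L)
  expect_equal(countObjects(m, connectivity = 4L)$nObjects, 2L)
  expect_error(countObjects(m, connectivity = 6L), "connectivity")
  expect_error(countObjects(matrix(3L, 2, 2)), "binary")
})
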