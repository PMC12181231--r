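test_that("a rendered disk is recovered within a pixel", {
  m <- diskMask(100, 100, 50, 50, 20)
  circ <- findDropletCircles(m)
  expect_equal(nrow(circ), 1L)
  expect_lt(abs(circ$row - 50), 1)
  expect_lt(abs(circ$col - 50), 1)
  expect_lt(abs(circ$radius - 20), 1)
  expect_false(circ$truncatedAtBorder)
})

test_that("empty masks and multiple disks are handled", {
  expect_equal(nrow(findDropletCircles(matrix(0L, 32, 32))), 0L)
  m <- diskMask(80, 120, 25, 30, 12)
  m <- pmax(m, diskMask(80, 120, 55, 90, 15))
  circ <- findDropletCircles(m)
  expect_equal(nrow(circ), countObjects(m, minArea = 50L)$nObjects)
  expect_equal(nrow(circ), 2L)
  # a border-truncated droplet is kept but flagged
  mb <- diskMask(60, 60, 3, 30, 10)
  cb <- findDropletCircles(mb)
  expect_equal(nrow(cb), 1L)
  expect_true(cb$truncatedAtBorder)
})

test_that("crystal components classify their containing droplet", {
  m <- diskMask(80, 120, 25, 30, 12)
  m <- pmax(m, diskMask(80, 120, 55, 90, 15))
  circ <- findDropletCircles(m)
  circ <- circ[order(circ$row), ]
  v <- matrix(0L, 80, 120); v[25:26, 31:32] <- 255L   # inside droplet 1
  z <- matrix(0L, 80, 120)
  det <- assignCrystals(circ, v, z)
  expect_true(det$hasVaterite[1] && !det$hasAcc[1])
  expect_true(det$hasAcc[2] && !det$hasVaterite[2] && !det$hasCalcite[2])
  expect_equal(nrow(attr(det, "orphans")), 0L)
})

test_that("orphan crystals are logged and classify nothing", {
  m <- diskMask(80, 80, 40, 40, 12)
  circ <- findDropletCircles(m)
  g <- matrix(0L, 80, 80); g[5, 5] <- 255L
  z <- matrix(0L, 80, 80)
  expect_warning(det <- assignCrystals(circ, z, g), "orphan")
  expect_false(any(det$hasCalcite))
  expect_equal(nrow(attr(det, "orphans")), 1L)
  expect_equal(attr(det, "orphans")$phase, "calcite")
})

test_that("a centroid inside two inflated circles goes to the nearer centre", {
  circ <- data.frame(row = c(40, 40), col = c(30, 52), radius = c(12, 12),
                     truncatedAtBorder = FALSE)
  v <- matrix(0L, 80, 80); v[40, 42] <- 255L  # 12 px from A, 10 px from B
  z <- matrix(0L, 80, 80)
  det <- assignCrystals(circ, v, z, marginPx = 2)
  expect_false(det$hasVaterite[1])
  expect_true(det$hasVaterite[2])
})

test_that("time-point counts satisfy conservation", {
  det <- data.frame(row = 1:3, col = 1:3, radius = 5,
                    truncatedAtBorder = FALSE,
                    hasVaterite = c(TRUE, FALSE, FALSE),
                    hasCalcite = FALSE)
  det$hasAcc <- !(det$hasVaterite | det$hasCalcite)
  tp <- countTimepoint(det, 1L, 1L, 10)
  expect_equal(tp$N_d, 3L)
  expect_equal(tp$N_d_ACC, 2L)
  expect_equal(tp$N_vaterite_droplets, 1L)
  tp0 <- countTimepoint(det[0, ])
  expect_equal(tp0$N_d, 0L)
  expect_equal(tp0$N_d_ACC, 0L)
})

test_that("ground-truth masks reproduce generator truth counts exactly", {
  scene <- smallScene(2, n = 12L, h = 128L, w = 256L)
  kin <- KineticsSpec(kTrue = 0.02, labileFraction = 0.7,
                      timesteps = seq(0, 120, length.out = 8),
                      nLocations = 2L)
  tl <- generateTimelapse(scene, kin, seed = 9, render = TRUE)
  for (idx in seq_along(tl$frames)) {
    fr <- tl$frames[[idx]]
    circ <- findDropletCircles(fr$dropletMask, minArea = 50L)
    det <- assignCrystals(circ, fr$vateriteMask, fr$calciteMask)
    tp <- countTimepoint(det)
    truth <- tl$counts[idx, ]
    expect_equal(tp$N_d, truth$N_d)
    expect_equal(tp$N_d_ACC, truth$N_d_ACC)
    expect_equal(tp$N_vaterite_droplets, truth$N_vaterite_droplets)
    expect_equal(tp$N_calcite_droplets, truth$N_calcite_droplets)
  }
})
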