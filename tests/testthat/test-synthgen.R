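test_that("degenerate kinetics never transform", {
  kin0 <- KineticsSpec(kTrue = 0, labileFraction = 1)
  s0 <- sampleTransformationSchedule(kin0, 50, seed = 1)
  expect_true(all(is.infinite(s0$transformationTime)))

  kinInert <- KineticsSpec(kTrue = 0.027, labileFraction = 0)
  s1 <- sampleTransformationSchedule(kinInert, 100, seed = 2)
  expect_equal(nrow(s1), 100)
  expect_true(all(is.infinite(s1$transformationTime)))
})

test_that("invalid kinetic probabilities are rejected", {
  expect_error(KineticsSpec(labileFraction = 1.2), "labileFraction")
  expect_error(KineticsSpec(pVaterite = -0.1), "pVaterite")
  expect_error(KineticsSpec(timesteps = c(10, 5)), "increasing")
  expect_error(sampleTransformationSchedule(KineticsSpec(), -1), "nonnegative")
})

test_that("empirical ACC survival matches the analytic closed form", {
  kin <- KineticsSpec(kTrue = 0.027, labileFraction = 1)
  n <- 10000
  sched <- sampleTransformationSchedule(kin, n, seed = 42)
  for (t in c(30, 90, 360)) {
    p <- accSurvival(kin, t)
    phat <- mean(sched$transformationTime > t)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(phat - p), 3 * se + 1e-12)
  }
})

test_that("scene rendering matches its construction", {
  sc <- generateScene(smallScene(7, n = 3L), c("acc", "vaterite", "calcite"),
                      seed = 7)
  expect_equal(countObjects(sc$dropletMask)$nObjects, 3L)
  expect_equal(countObjects(sc$vateriteMask)$nObjects, 1L)
  expect_equal(countObjects(sc$calciteMask)$nObjects, 1L)
  # each crystal sits inside its own droplet circle
  tr <- sc$truth
  vc <- countObjects(sc$vateriteMask)$centroids
  expect_lt(sqrt((vc[1, 1] - tr$circles$row[2])^2 +
                 (vc[1, 2] - tr$circles$col[2])^2), tr$circles$radius[2])
  cc <- countObjects(sc$calciteMask)$centroids
  expect_lt(sqrt((cc[1, 1] - tr$circles$row[3])^2 +
                 (cc[1, 2] - tr$circles$col[3])^2), tr$circles$radius[3])
  expect_true(all(sc$rgb >= 0 & sc$rgb <= 1))
})

test_that("empty scenes and determinism behave as contracted", {
  sc0 <- generateScene(smallScene(1, n = 0L))
  expect_true(all(sc0$dropletMask == 0) && all(sc0$vateriteMask == 0) &&
              all(sc0$calciteMask == 0))
  a <- generateScene(smallScene(3), mixedPhases(3), seed = 11)
  b <- generateScene(smallScene(3), mixedPhases(3), seed = 11)
  expect_identical(a, b)
  expect_error(generateScene(smallScene(1, n = 2L), phases = c("acc")),
               "length")
})

test_that("droplet layouts respect the frame and never overlap", {
  for (seed in 1:5) {
    sc <- generateScene(smallScene(seed, n = 6L), seed = seed)
    circ <- sc$truth$circles
    expect_true(all(circ$row - circ$radius >= 0 &
                    circ$row + circ$radius <= 128 &
                    circ$col - circ$radius >= 0 &
                    circ$col + circ$radius <= 128))
    if (nrow(circ) > 1) {
      d <- as.matrix(dist(circ[, c("row", "col")]))
      rsum <- outer(circ$radius, circ$radius, "+")
      expect_true(all(d[upper.tri(d)] > rsum[upper.tri(rsum)]))
    }
  }
  expect_error(generateScene(smallScene(1, n = 40L, h = 64L, w = 64L, r = 11)),
               "fewer or smaller")
})

test_that("time-lapse counts conserve droplets and decrease monotonically", {
  scene <- smallScene(1, n = 8L)
  kin <- KineticsSpec(kTrue = 0.02, labileFraction = 0.6,
                      timesteps = seq(0, 120, by = 15), nLocations = 3L)
  tl <- generateTimelapse(scene, kin, seed = 5, render = FALSE)
  with(tl$counts, {
    expect_true(all(N_d_ACC + N_vaterite_droplets + N_calcite_droplets == N_d))
    expect_true(all(N_d == 8))
  })
  for (l in unique(tl$counts$location_id)) {
    g <- tl$counts[tl$counts$location_id == l, ]
    g <- g[order(g$timestep_index), ]
    expect_true(all(diff(g$N_d_ACC) <= 0))
  }
  # zero rate: ACC count constant
  tl0 <- generateTimelapse(scene, KineticsSpec(kTrue = 0, timesteps = c(0, 30, 60),
                                               nLocations = 2L),
                           seed = 1, render = FALSE)
  expect_equal(length(unique(tl0$counts$N_d_ACC)), 1L)
})

test_that("a 12-location, 16-timestep run yields a 192-frame manifest", {
  kin <- KineticsSpec(timesteps = seq(0, 360, length.out = 16),
                      nLocations = 12L)
  tl <- generateTimelapse(smallScene(1, n = 2L), kin, seed = 1, render = FALSE)
  expect_equal(nrow(tl$manifest), 192L)
})

test_that("empirical ACC fraction tracks the model over many seeds", {
  kin <- KineticsSpec(kTrue = 0.01, labileFraction = 0.5)
  t <- 100
  phats <- vapply(1:30, function(s)
    mean(sampleTransformationSchedule(kin, 200, seed = s)$transformationTime > t),
    numeric(1))
  p <- accSurvival(kin, t)
  se <- sqrt(p * (1 - p) / (200 * 30))
  expect_lt(abs(mean(phats) - p), 4 * se)
})
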