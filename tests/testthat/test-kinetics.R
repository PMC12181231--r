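test_that("time-series assembly pools counts and averages times", {
  counts <- data.frame(location_id = c(1, 2), timestep_index = c(1, 1),
                       acquisition_time_min = c(10, 12),
                       N_d = c(50, 52), N_d_ACC = c(30, 31))
  ts <- assembleTimeseries(counts)
  expect_equal(ts$mean_time_min, 11)
  expect_equal(ts$N_d_ACC, 61)
  expect_equal(ts$time_min, 10)
  expect_equal(ts$time_max, 12)
  # single location: span collapses
  ts1 <- assembleTimeseries(counts[1, ])
  expect_equal(ts1$time_min, ts1$time_max)
  # shuffled input gives identical output
  counts2 <- rbind(counts, data.frame(location_id = c(1, 2),
                                      timestep_index = c(2, 2),
                                      acquisition_time_min = c(40, 42),
                                      N_d = c(50, 52), N_d_ACC = c(20, 22)))
  shuf <- counts2[c(3, 1, 4, 2), ]
  expect_equal(assembleTimeseries(shuf), assembleTimeseries(counts2))
  # pooled N_d_ACC equals the per-location sum (no double counting)
  expect_equal(sum(assembleTimeseries(counts2)$N_d_ACC),
               sum(counts2$N_d_ACC))
  # missing rows are excluded with a warning
  counts2$N_d_ACC[1] <- NA
  expect_warning(assembleTimeseries(counts2), "excluding")
})

test_that("the fit recovers published count-form coefficients exactly", {
  t <- seq(0, 360, length.out = 17)
  y <- 65.63 * exp(-0.027 * t) + 596.0
  f <- fitDecay(t, y, form = "count")
  expect_lt(abs(kRate(f) - 0.027) / 0.027, 1e-6)
  expect_lt(abs(amplitude(f) - 65.63) / 65.63, 1e-6)
  expect_lt(abs(plateau(f) - 596.0) / 596.0, 1e-6)
  expect_false(f@noDecay)
  expect_equal(f@nPoints, 17L)
})

test_that("a constant series is flagged as carrying no decay", {
  f <- fitDecay(c(0, 10, 20, 30), rep(5, 4), form = "count")
  expect_true(f@noDecay)
  expect_equal(amplitude(f), 0)
  expect_equal(plateau(f), 5)
  expect_equal(kRate(f), 0)
})

test_that("fitting guards its preconditions", {
  expect_error(fitDecay(c(0, 1, 2), c(3, 2, 1)), "4 points")
  expect_error(fitDecay(c(-1, 0, 1, 2), c(4, 3, 2, 1)), "nonnegative")
  expect_error(fitDecay(c(0, 1, 2, 3), c(2, 1.5, 1.2, 1.1), form = "ratio"),
               "\\[0, 1\\]")
})

test_that("ratio-form evaluation reproduces the published fractions", {
  rf <- DecayFit("ratio", 0.099, 0.027, 0.898)
  expect_equal(evaluateFit(rf, 0), 0.997)
  expect_equal(round(evaluateFit(rf, 360), 3), 0.898)
  # limit t -> infinity is the plateau; decreasing in t for k > 0
  expect_equal(evaluateFit(rf, 1e9), plateau(rf))
  tt <- seq(0, 500, by = 10)
  expect_true(all(diff(evaluateFit(rf, tt)) < 0))
  expect_equal(evaluateFit(rf, 0), amplitude(rf) + plateau(rf))
})

test_that("ACC fractions are exact quotients to three decimals", {
  expect_equal(accFraction(443, 653), 0.678)
  expect_equal(accFraction(0, 10), 0)
  expect_equal(accFraction(653, 653), 1)
  expect_error(accFraction(1, 0), "positive")
  expect_error(accFraction(5, 3), "nAcc")
})

test_that("half-life statements cover exact, bounded and unreachable", {
  hb <- halfLifeBound(series = data.frame(time = 1440, fraction = 0.678))
  expect_equal(hb@kind, "lower_bound")
  expect_equal(hb@valueMin, 1440)
  expect_gte(hb@valueMin, 24 * 60)

  hu <- halfLifeBound(fit = DecayFit("ratio", 0.099, 0.027, 0.898))
  expect_equal(hu@kind, "unreachable")
  expect_true(is.na(hu@valueMin))

  he <- halfLifeBound(fit = DecayFit("ratio", 1.0, 0.1, 0.0))
  expect_equal(he@kind, "exact")
  expect_equal(he@valueMin, log(2) / 0.1, tolerance = 1e-12)
  expect_error(halfLifeBound(fit = DecayFit("count", 60, 0.1, 500)), "ratio")
})

test_that("noisy count series recover the rate without gross bias", {
  set.seed(10)
  t <- seq(0, 360, length.out = 17)
  ks <- vapply(1:10, function(s) {
    mu <- 0.099 * exp(-0.027 * t) + 0.898
    y <- rbinom(length(t), 660, mu) / 660
    kRate(fitDecay(t, pmin(y, 1), form = "ratio"))
  }, numeric(1))
  expect_lt(abs(median(ks) - 0.027) / 0.027, 0.3)
})

test_that("bootstrap intervals cover the fitted rate", {
  kin <- KineticsSpec()
  tl <- generateTimelapse(SceneSpec(dropletsPerFrame = 40L), kin,
                          seed = 3, render = FALSE)
  ts <- assembleTimeseries(tl$counts)
  ci <- bootstrapRateCI(ts, nBoot = 50L, seed = 1L)
  expect_lt(ci$ciLower, ci$k)
  expect_gt(ci$ciUpper, ci$k)
})
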