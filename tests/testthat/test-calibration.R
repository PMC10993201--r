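test_that("TIMS calibration reproduces anchors exactly and interpolates", {
  ref <- tuningMixReference()
  ## already-calibrated axis: identity map
  obs <- data.frame(raw = ref$invK0, mz = ref$mz)
  cal <- fitTimsCalibration(obs, ref)
  expect_equal(applyTimsCalibration(cal, ref$invK0), ref$invK0)

  ## distorted raw axis: anchors exact, midpoints linear
  obs <- data.frame(raw = 100 + 400 * ref$invK0 + 20 * ref$invK0^2,
                    mz = ref$mz)
  cal <- fitTimsCalibration(obs, ref)
  expect_equal(applyTimsCalibration(cal, obs$raw), ref$invK0)
  mid <- (obs$raw[3] + obs$raw[4]) / 2
  expect_equal(applyTimsCalibration(cal, mid),
               (ref$invK0[3] + ref$invK0[4]) / 2)
  ## monotone between anchors
  grid <- seq(min(obs$raw), max(obs$raw), length.out = 200)
  expect_true(all(diff(applyTimsCalibration(cal, grid)) >= 0))
})

test_that("degenerate TIMS calibrations are rejected", {
  ref <- tuningMixReference()
  expect_error(fitTimsCalibration(data.frame(raw = 1, mz = 322), ref),
               "2 calibrant")
  badRef <- ref
  badRef$invK0 <- rev(badRef$invK0)
  expect_error(fitTimsCalibration(data.frame(raw = 1:8, mz = ref$mz),
                                  badRef), "strictly")
  obs <- data.frame(raw = c(1, 5, 3, 7, 9, 11, 13, 15), mz = ref$mz)
  expect_error(fitTimsCalibration(obs, ref), "monotone")
})

test_that("Mason-Schamp conversion scales with charge and reduced mass", {
  base <- mobilityToCcs(1.2, 1, 1578.95)
  expect_equal(mobilityToCcs(1.2, 2, 1578.95), 2 * base)
  expect_equal(mobilityToCcs(2.4, 1, 1578.95), 2 * base)

  ## infinite-mass limit: mu -> gas mass
  heavy <- mobilityToCcs(1.2, 1, 1e12)
  mu <- N2_MASS
  limit <- 3 * 1.602176634e-19 / (16 * 2.6867811e25) *
    sqrt(2 * pi / (mu * 1.66053906660e-27 * 1.380649e-23 * 273.15)) *
    1.2e4 * 1e20
  expect_equal(heavy, limit, tolerance = 1e-6)

  ## heavier ion at equal z and 1/K0 has the smaller CCS
  expect_gt(mobilityToCcs(1.2, 1, 500), mobilityToCcs(1.2, 1, 5000))

  ## magnitude sanity: a 1+ tuning-mix-like ion lands in the
  ## hundreds-of-Angstrom^2 range
  ccs922 <- mobilityToCcs(1.190, 1, 921.0)
  expect_gt(ccs922, 200)
  expect_lt(ccs922, 320)
})

test_that("TWIMS calibration recovers its generating power law exactly", {
  cal <- fitTwimsCalibration(syntheticTwimsCalibrants(), edc = 1.35)
  expect_equal(cal@slope, 0.55, tolerance = 1e-9)
  expect_equal(cal@intercept, 6.31, tolerance = 1e-9)
  expect_equal(cal@r2, 1, tolerance = 1e-12)

  ## calibrant self-consistency through the inverse transform
  tab <- syntheticTwimsCalibrants()
  ccs <- twimsCcs(tab$dt, cal, tab$z, tab$z * (tab$mz - 1.007276),
                  mz = tab$mz)
  expect_equal(ccs, tab$ccs_ref, tolerance = 1e-9)

  expect_error(fitTwimsCalibration(syntheticTwimsCalibrants()[1:2, ]),
               "3 calibrants")
  bad <- syntheticTwimsCalibrants()
  bad$dt[3] <- 0.01
  expect_error(fitTwimsCalibration(bad, edc = 1.35), "m/z 922")
})

test_that("TWIMS slope survives 0.5% drift-time noise within 2%", {
  tab0 <- syntheticTwimsCalibrants()
  for (seed in 0:19) {
    set.seed(seed)
    tab <- tab0
    tab$dt <- tab$dt * (1 + rnorm(nrow(tab), 0, 0.005))
    cal <- fitTwimsCalibration(tab, edc = 1.35)
    expect_lt(abs(cal@slope - 0.55) / 0.55, 0.02)
  }
})

test_that("drift-time to CCS conversion is monotone and guards dt'", {
  cal <- fitTwimsCalibration(syntheticTwimsCalibrants(), edc = 1.35)
  dts <- c(3, 4, 5, 6)
  ccs <- twimsCcs(dts, cal, 2, 3000)
  expect_true(all(diff(ccs) > 0))
  expect_error(twimsCcs(1e-4, cal, 2, 3000), "non-positive")
})

test_that("cross-platform CCS comparison reports known statistics", {
  a <- data.frame(n = c(2, 4, 6, 8), z = c(1, 2, 3, 4),
                  ccs = c(380, 620, 830, 1010))
  same <- comparePlatforms(a, a)
  expect_equal(same$meanRelDiff, 0)
  expect_equal(same$maxRelDiff, 0)
  expect_equal(same$r2, 1)

  b <- a
  b$ccs <- 1.02 * a$ccs
  scaled <- comparePlatforms(a, b, labels = c("TIMS", "TWIMS"))
  ## closed form: 100 * 0.02 / 1.01
  expect_equal(scaled$meanRelDiff, 100 * 0.02 / 1.01, tolerance = 1e-9)
  expect_equal(scaled$maxRelDiff, scaled$meanRelDiff, tolerance = 1e-9)
  expect_equal(scaled$r2, 1, tolerance = 1e-12)
  expect_equal(scaled$larger, "TWIMS")

  ## symmetry of the relative-difference statistics
  sym <- comparePlatforms(b, a)
  expect_equal(sym$meanRelDiff, scaled$meanRelDiff)
  expect_equal(sym$maxRelDiff, scaled$maxRelDiff)

  disjoint <- comparePlatforms(a, data.frame(n = 3, z = 1, ccs = 500))
  expect_equal(disjoint$nOverlap, 0)
  expect_true(is.na(disjoint$meanRelDiff))
})
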