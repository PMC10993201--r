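test_that("feature tables round-trip bit-exactly with metadata", {
  ds <- makeDataset(c(790.4822, 1579.9571, 1580.2079),
                    c(1.959, 1.203, 1.126), c(10.5, 3.25, 1e-3),
                    platform = "TIMS", quadWindow = c(1580, 5),
                    metadata = list(operator = "x1", note = "demo"))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeFeatureTable(ds, path)
  back <- readFeatureTable(path)
  expect_identical(featureTable(back), featureTable(ds))
  expect_identical(quadWindow(back), c(1580, 5))
  expect_identical(imsPlatform(back), "TIMS")
  expect_identical(back@metadata$operator, "x1")
  expect_identical(back@metadata$note, "demo")
})

test_that("malformed feature tables are rejected with a location", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#platform=TIMS", "mz\tintensity", "790.5\t10"), path)
  expect_error(readFeatureTable(path), "mobility")

  writeLines(c("mz\tmobility\tintensity", "790.5\t1.9\t10",
               "oops\t1.2\t3"), path)
  expect_error(readFeatureTable(path), "line 3")

  writeLines(c("#mobility_axis=arrival_time", "mz\tmobility\tintensity",
               "790.5\t1.9\t10"), path)
  expect_error(readFeatureTable(path), "mobility_axis")

  expect_error(IMMSDataset(data.frame(mz = 1, mobility = 1,
                                      intensity = -2)), ">= 0")
})

test_that("EIM extraction recovers planted mobility peaks", {
  ## one species as a Gaussian at 1/K0 = 1.959
  mob <- seq(1.90, 2.02, by = 0.001)
  ds <- makeDataset(rep(1579.957, length(mob)), mob,
                    exp(-(mob - 1.959)^2 / (2 * 0.004^2)))
  eim <- extractEIM(ds, center = 1580, halfwidth = 1)
  pk <- detectPeaks(eim)
  expect_equal(pk$apex[1], 1.959, tolerance = 1e-3)

  ## empty selection: zero spectrum, flagged
  expect_warning(empty <- extractEIM(ds, center = 500, halfwidth = 1),
                 "no features")
  expect_true(all(spectrumIntensity(empty) == 0))
  expect_true(empty@provenance$empty)
})

test_that("two isobaric species at one m/z give two EIM apexes", {
  mob <- seq(1.35, 1.70, by = 0.001)
  y <- exp(-(mob - 1.606)^2 / (2 * 0.004^2)) +
    0.6 * exp(-(mob - 1.416)^2 / (2 * 0.004^2))
  ds <- makeDataset(rep(1579.957, length(mob)), mob, y)
  pk <- detectPeaks(extractEIM(ds, center = 1580, halfwidth = 1))
  expect_equal(nrow(pk), 2)
  expect_equal(sort(pk$apex), c(1.416, 1.606), tolerance = 1e-3)
})

test_that("envelope-mode selection keeps out off-envelope signal", {
  comp <- peptideComposition(PHF6)
  env <- isotopeEnvelope(comp, 2, 1, minAbundance = 1e-2)
  ds <- makeDataset(c(env@mz, env@mz + 0.4), rep(1.5, 2 * length(env@mz)),
                    rep(1, 2 * length(env@mz)))
  eim <- extractEIM(ds, envelope = env)
  expect_equal(sum(spectrumIntensity(eim)), length(env@mz))
})

test_that("mobility-gated mass spectra expose isotope spacing", {
  comp <- peptideComposition(PHF6)
  env <- isotopeEnvelope(comp, 8, 4, minAbundance = 1e-2)
  ds <- makeDataset(env@mz, rep(1.299, length(env@mz)), env@abundance)
  ms <- extractMsAtMobility(ds, c(1.29, 1.31))
  expect_equal(median(diff(ms$mz)), 0.2508, tolerance = 2e-3)
  r <- inferNZ(ms$mz[which.max(ms$intensity)], median(diff(ms$mz)), M_PHF6)
  expect_equal(c(r$n, r$z), c(8, 4))
  expect_false(attr(ms, "multiComponent"))
  expect_equal(nrow(extractMsAtMobility(ds, c(2.5, 2.6))), 0)
})

test_that("superimposed charge states are flagged as multi-component", {
  comp <- peptideComposition(PHF6)
  mz <- c()
  intensity <- c()
  for (s in list(c(5, 2), c(7, 3), c(9, 4))) {
    env <- isotopeEnvelope(comp, s[1], s[2], minAbundance = 5e-2)
    mz <- c(mz, env@mz)
    intensity <- c(intensity, env@abundance)
  }
  ds <- makeDataset(mz, rep(1.203, length(mz)), intensity)
  ms <- extractMsAtMobility(ds, c(1.19, 1.22), minHeightFraction = 0.05)
  expect_true(attr(ms, "multiComponent"))
})

test_that("selection in m/z and mobility commutes (adjoint sums)", {
  set.seed(42)
  ds <- makeDataset(runif(500, 700, 2400), runif(500, 1.0, 2.0),
                    rexp(500))
  mzWin <- c(1000, 1800)
  mobWin <- c(1.2, 1.6)
  eim <- extractEIM(ds, center = mean(mzWin), halfwidth = diff(mzWin) / 2)
  viaEim <- sum(spectrumIntensity(eim)[spectrumAxis(eim) >= mobWin[1] &
                                       spectrumAxis(eim) <= mobWin[2]])
  ms <- extractMsAtMobility(ds, mobWin)
  viaMs <- sum(ms$intensity[ms$mz >= mzWin[1] & ms$mz <= mzWin[2]])
  f <- featureTable(ds)
  direct <- sum(f$intensity[f$mz >= mzWin[1] & f$mz <= mzWin[2] &
                            f$mobility >= mobWin[1] & f$mobility <= mobWin[2]])
  expect_equal(viaMs, direct, tolerance = 1e-12)
  ## EIM binning may move boundary features by at most half a bin
  expect_equal(viaEim, direct, tolerance = 0.05)
  expect_lte(sum(spectrumIntensity(eim)), sum(f$intensity) + 1e-9)
})

test_that("Savitzky-Golay smoothing reproduces low-order polynomials", {
  axis <- seq(1, 2, by = 0.002)
  const <- new("MobilitySpectrum", axis = axis,
               intensity = rep(7, length(axis)), provenance = list())
  expect_equal(spectrumIntensity(smoothSpectrum(const, 11, 3)),
               rep(7, length(axis)), tolerance = 1e-9)

  quad <- new("MobilitySpectrum", axis = axis,
              intensity = 5 + 3 * axis + 2 * axis^2, provenance = list())
  expect_equal(spectrumIntensity(smoothSpectrum(quad, 11, 2)),
               quad@intensity, tolerance = 1e-9)

  expect_error(smoothSpectrum(quad, 10, 2), "odd")
  expect_error(smoothSpectrum(quad, 3, 5), "polyorder")
  expect_error(smoothSpectrum(quad, 9999, 3), "length")
})

test_that("smoothing a noisy Gaussian moves the apex by less than a bin", {
  set.seed(7)
  axis <- seq(1.1, 1.3, by = 0.001)
  y <- exp(-(axis - 1.2)^2 / (2 * 0.004^2)) + rnorm(length(axis), 0, 0.02)
  noisy <- new("MobilitySpectrum", axis = axis, intensity = pmax(y, 0),
               provenance = list())
  pk <- detectPeaks(smoothSpectrum(noisy, 11, 3), minHeightFraction = 0.5)
  expect_lt(abs(pk$apex[1] - 1.2), 0.001)
})

test_that("peak detection refines apexes below half-bin error", {
  set.seed(11)
  centers <- runif(100, 1.2, 1.8)
  axis <- seq(1.0, 2.0, by = 0.001)
  for (ctr in centers) {
    spec <- new("MobilitySpectrum", axis = axis,
                intensity = exp(-(axis - ctr)^2 / (2 * 0.005^2)),
                provenance = list())
    pk <- detectPeaks(spec, minHeightFraction = 0.5)
    expect_lt(abs(pk$apex[1] - ctr), 0.0005)
  }
})

test_that("close peaks are suppressed by the separation rule", {
  axis <- seq(1.0, 1.4, by = 0.001)
  y <- exp(-(axis - 1.20)^2 / (2 * 0.004^2)) +
    0.8 * exp(-(axis - 1.206)^2 / (2 * 0.004^2))
  spec <- new("MobilitySpectrum", axis = axis, intensity = y,
              provenance = list())
  pk <- detectPeaks(spec, minSeparation = 0.01)
  expect_equal(nrow(pk), 1)
  zero <- new("MobilitySpectrum", axis = axis,
              intensity = numeric(length(axis)), provenance = list())
  expect_equal(nrow(detectPeaks(zero)), 0)
})
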