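test_that("species enumeration covers the reported oligomer range", {
  sp <- enumerateSpecies(M_PHF6, c(50, 3000))
  expect_true(all(sp$mz >= 50 & sp$mz <= 3000))
  expect_false(is.unsorted(sp$mz))
  hit <- sp[sp$n == 21 & sp$z == 6, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$mz, 2764, tolerance = 1e-3)
  expect_equal(hit$family, "7:2")

  expect_equal(nrow(enumerateSpecies(M_PHF6, c(790, 791), 1, 1)), 1)
  expect_equal(nrow(enumerateSpecies(M_PHF6, c(100, 101))), 0)
})

test_that("a narrow window around 1580 contains exactly the 2:1 ladder", {
  sp <- enumerateSpecies(M_PHF6, c(1579, 1581), nMax = 12, zMax = 6)
  ## brute-force oracle over the same grid
  grid <- expand.grid(n = 1:12, z = 1:6)
  grid$mz <- oligomerMz(M_PHF6, grid$n, grid$z)
  oracle <- grid[grid$mz >= 1579 & grid$mz <= 1581, ]
  expect_setequal(paste(sp$n, sp$z), paste(oracle$n, oracle$z))
  expect_setequal(paste(sp$n, sp$z),
                  c("2 1", "4 2", "6 3", "8 4", "10 5", "12 6"))
})

test_that("isobaric families share one gcd-reduced key", {
  fam <- isobaricFamily(1580, 0.5, M_PHF6)
  expect_true(all(fam$family == "2:1"))
  fam3 <- isobaricFamily(2369, 0.5, M_PHF6, nMax = 18, zMax = 6)
  expect_true(all(fam3$family == "3:1"))
  expect_setequal(paste(fam3$n, fam3$z),
                  c("3 1", "6 2", "9 3", "12 4", "15 5", "18 6"))
  mono <- isobaricFamily(790.5, 0.3, M_PHF6)
  expect_true(all(mono$family == "1:1"))
})

test_that("charge and order are inferred from m/z and isotope spacing", {
  r <- inferNZ(1580.0, 0.25, M_PHF6)
  expect_equal(r$n, 8)
  expect_equal(r$z, 4)
  expect_true(r$assigned)

  r <- inferNZ(1580.0, 1.0, M_PHF6)
  expect_equal(c(r$n, r$z), c(2, 1))

  r <- inferNZ(790.48, 1.0, M_PHF6)
  expect_equal(c(r$n, r$z), c(1, 1))

  ## far off any species: best candidate returned but flagged
  r <- inferNZ(1234.5, 1.0, M_PHF6, tolPpm = 20)
  expect_false(r$assigned)
  expect_true(is.finite(r$ppm_error))
})

test_that("inference inverts the m/z formula on the full (n, z) grid", {
  for (z in 1:8) {
    for (n in seq_len(25)) {
      r <- inferNZ(oligomerMz(M_PHF6, n, z), 1.00336 / z, M_PHF6, tolPpm = 1)
      expect_identical(c(r$n, r$z), c(n, as.integer(z)))
      expect_true(r$assigned)
    }
  }
})

test_that("screening flags planted species above the S/N threshold", {
  ## plant envelopes for (1,1), (2,1), (2,2) at 50x noise, (3,1) at 1x;
  ## a flat noise floor of unit intensity defines the MAD estimate
  comp <- peptideComposition(PHF6)
  planted <- list(list(1, 1, 50), list(2, 1, 50), list(2, 2, 50),
                  list(3, 1, 1))
  mz <- c()
  intensity <- c()
  for (p in planted) {
    env <- isotopeEnvelope(comp, p[[1]], p[[2]], minAbundance = 1e-2)
    mz <- c(mz, env@mz)
    intensity <- c(intensity, p[[3]] * env@abundance / max(env@abundance))
  }
  ## noise features away from every candidate envelope
  cand <- enumerateSpecies(M_PHF6, c(600, 2500))
  candPeaks <- as.vector(outer(cand$mz, (0:4) * 1.00336 / rep(cand$z, 5),
                               `+`))
  noiseMz <- seq(600, 2400, by = 7.13)
  noiseMz <- noiseMz[vapply(noiseMz, function(x)
    min(abs(x - candPeaks)) > 0.5, logical(1))]
  ds <- makeDataset(c(mz, noiseMz), rep(1.5, length(mz) + length(noiseMz)),
                    c(intensity, rep(1, length(noiseMz))))
  grid <- screenOligomers(ds, M_PHF6, snrThreshold = 3, nMax = 3L,
                          zMax = 2L, comp = comp)
  det <- grid[grid$detected, c("n", "z")]
  expect_setequal(paste(det$n, det$z), c("1 1", "2 1", "2 2"))
  expect_false(grid$detected[grid$n == 3 & grid$z == 1])
})

test_that("screening uses a strict threshold and is monotone in it", {
  comp <- peptideComposition(PHF6)
  env <- isotopeEnvelope(comp, 1, 1, minAbundance = 1e-2)
  noiseMz <- c(700.0, seq(1500.3, 2400, by = 13.17))
  ds <- makeDataset(c(env@mz, noiseMz),
                    rep(1.0, length(env@mz) + length(noiseMz)),
                    c(3 * env@abundance / max(env@abundance),
                      rep(1, length(noiseMz))))
  ## planted exactly at threshold S/N = 3: excluded by strict inequality
  grid <- screenOligomers(ds, M_PHF6, snrThreshold = 3, comp = comp)
  expect_false(grid$detected[grid$n == 1 & grid$z == 1])

  g1 <- screenOligomers(ds, M_PHF6, snrThreshold = 1, comp = comp)
  g5 <- screenOligomers(ds, M_PHF6, snrThreshold = 5, comp = comp)
  expect_true(all(g1$detected[g5$detected]))

  empty <- IMMSDataset(data.frame(mz = numeric(), mobility = numeric(),
                                  intensity = numeric()))
  expect_equal(nrow(screenOligomers(empty, M_PHF6)), 0)
})

test_that("detection grids serialise to TSV", {
  grid <- data.frame(n = 1:2, z = c(1L, 1L), mz = c(790.5, 1580),
                     snr = c(10, 2), detected = c(TRUE, FALSE))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeDetectionGrid(grid, path)
  back <- read.delim(path)
  expect_equal(back$detected, c(TRUE, FALSE))
  expect_equal(back$snr, grid$snr)
})
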