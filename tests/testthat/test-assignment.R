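test_that("quad-selected 1580 fixture reproduces the reference assignments", {
  simQ <- simulateDataset(fixtureConfigQuad1580(2L))
  simR <- simulateDataset(fixtureConfigNoQuad(1L))
  fam <- isobaricFamily(1580, 0.5, M_PHF6, nMax = 12, zMax = 6)
  res <- assignByCoincidence(simQ$dataset, M_PHF6, fam,
                             intactReference = simR$dataset,
                             peptide = PHF6)
  a <- assignmentTable(res)

  ## the decamer at 1.203 V s/cm^2, supported by the 1^1+, 9^4+ and 8^3+
  ## fragment channels
  i10 <- which(a$n == 10 & a$z == 5)
  expect_length(i10, 1)
  expect_equal(a$mobility[i10], 1.203, tolerance = 5e-3)
  expect_gte(a$nSupporting[i10], 3)
  ev <- assignmentEvidence(res)[[i10]]
  expect_setequal(paste(ev$channel_n, ev$channel_z),
                  c("1 1", "9 4", "8 3"))

  ## the 12-mer at 1.126 via the 1^1+ shoulder and the 11^5+ channel
  i12 <- which(a$n == 12 & a$z == 6)
  expect_length(i12, 1)
  expect_equal(a$mobility[i12], 1.126, tolerance = 5e-3)
  expect_gte(a$nSupporting[i12], 2)
  expect_true("11 5" %in% paste(assignmentEvidence(res)[[i12]]$channel_n,
                                assignmentEvidence(res)[[i12]]$channel_z))

  ## assigned mobilities decrease with oligomer order
  expect_true(all(diff(a$mobility[order(a$n)]) < 0))
  expect_length(assignmentWarnings(res), 0)
})

test_that("interface-fragmentation artifacts are attributed to their source", {
  simQ <- simulateDataset(fixtureConfigQuad1580(2L))
  simR <- simulateDataset(fixtureConfigNoQuad(1L))
  fam <- isobaricFamily(1580, 0.5, M_PHF6, nMax = 12, zMax = 6)
  res <- assignByCoincidence(simQ$dataset, M_PHF6, fam,
                             intactReference = simR$dataset,
                             peptide = PHF6)
  r <- residualPeaks(res)
  iface <- r[r$classification == "interface_fragment", ]
  ## the planted 11^5+ and 13^5+ monomer-loss chains into the 10^5+
  ## channel, and 13^6+ into the 12^6+ channel
  expect_true(all(c("11 5", "13 5", "13 6") %in%
                  paste(iface$source_n, iface$source_z)))
  ## no cluster near an assignment is left unexplained
  expect_false(any(r$classification == "unexplained" &
                   r$nChannels >= 2))
})

test_that("without a quad window or candidate family the call is rejected", {
  simR <- simulateDataset(fixtureConfigNoQuad(1L))
  fam <- isobaricFamily(1580, 0.5, M_PHF6)
  expect_error(assignByCoincidence(simR$dataset, M_PHF6, fam),
               "quadrupole")
  simQ <- simulateDataset(fixtureConfigQuad1580(2L))
  expect_error(assignByCoincidence(simQ$dataset, M_PHF6,
                                   fam[0, , drop = FALSE]),
               "at least one")
})

test_that("mutually inconsistent channel mobilities yield no assignment", {
  ## plant fragment channels of the decamer at three different
  ## mobilities: no coincidence cluster reaches two channels
  comp <- peptideComposition(PHF6)
  mzs <- c()
  mob <- c()
  intensity <- c()
  plant <- function(n, z, at, scale = 1) {
    env <- isotopeEnvelope(comp, n, z, minAbundance = 1e-2)
    grid <- seq(at - 0.016, at + 0.016, by = 0.001)
    g <- exp(-(grid - at)^2 / (2 * 0.004^2))
    mzs <<- c(mzs, rep(env@mz, times = length(grid)))
    mob <<- c(mob, rep(grid, each = length(env@mz)))
    intensity <<- c(intensity, scale * as.vector(outer(env@abundance, g)))
  }
  plant(10, 5, 1.25, 10)   # the precursor itself, in-window
  plant(1, 1, 1.20)
  plant(9, 4, 1.35)
  plant(8, 3, 1.50)
  ds <- makeDataset(mzs, mob, intensity, quadWindow = c(1579.957, 5))
  res <- assignByCoincidence(ds, M_PHF6,
                             data.frame(n = c(2, 10), z = c(1, 5)),
                             peptide = PHF6)
  expect_equal(nrow(assignmentTable(res)), 0)
  expect_true(all(residualPeaks(res)$classification %in%
                  c("unexplained", "interface_candidate")))
})

test_that("zero fragmentation yields zero assignments (no false positives)", {
  for (seed in 0:19) {
    case <- recoveryCase(seed, collisionFraction = 0)
    sim <- simulateDataset(case$config)
    res <- assignByCoincidence(sim$dataset, M_PHF6,
                               case$species[, c("n", "z")],
                               peptide = PHF6)
    expect_equal(nrow(assignmentTable(res)), 0, info = paste("seed", seed))
  }
})

test_that("planted precursor mobilities are recovered across random families", {
  ## spot-check a few seeds here; the full 20-seed sweep runs with the
  ## acceptance properties
  for (seed in 0:4) {
    out <- runRecovery(seed)
    sp <- out$case$species
    a <- assignmentTable(out$result)
    detectable <- detectableMembers(sp)
    hits <- merge(detectable, a, by = c("n", "z"))
    expect_equal(nrow(hits), nrow(detectable), info = paste("seed", seed))
    expect_true(all(abs(hits$mobility.x - hits$mobility.y) <= 0.01),
                info = paste("seed", seed))
  }
})

test_that("a planted mobility inversion triggers the family-order warning", {
  species <- data.frame(n = c(4L, 6L, 8L), z = c(2L, 3L, 4L),
                        mobility = c(1.40, 1.55, 1.20),  # 6^3+ inverted
                        abundance = c(60, 40, 30))
  cfg <- simulationConfig(PHF6, species, collisionFraction = 0.35,
                          quadWindow = c(oligomerMz(M_PHF6, 2, 1), 5),
                          noise = c(0.002, 0.005), seed = 7L)
  sim <- simulateDataset(cfg)
  expect_warning(
    res <- assignByCoincidence(sim$dataset, M_PHF6,
                               species[, c("n", "z")], peptide = PHF6),
    "not strictly decreasing")
  expect_true(length(assignmentWarnings(res)) > 0)
})

test_that("assignment reports serialise to TSV and JSON", {
  simQ <- simulateDataset(fixtureConfigQuad1580(2L))
  fam <- isobaricFamily(1580, 0.5, M_PHF6, nMax = 12, zMax = 6)
  res <- assignByCoincidence(simQ$dataset, M_PHF6, fam, peptide = PHF6)
  prefix <- file.path(withr::local_tempdir(), "report")
  writeAssignmentReport(res, prefix)
  tab <- read.delim(paste0(prefix, ".tsv"))
  expect_equal(tab$n, assignmentTable(res)$n)
  js <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_named(js, c("assignments", "evidence", "residual_peaks",
                     "parameters", "warnings"), ignore.order = TRUE)
})
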