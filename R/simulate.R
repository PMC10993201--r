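## Synthetic IM-MS data with known ground truth: intact species rendered
## as isotopic envelope x Gaussian mobility peak, fragmentation at the
## two in-instrument loci (TIMS-multipole interface before quadrupole
## selection; collision cell after it), then noise. Fragment intensity
## is redistributed, never created, so totals are conserved before noise.

## Run expr with a fixed seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Build a simulation configuration
#'
#' @param peptide A [PeptideSpec-class] or peptide string (the monomer).
#' @param species data.frame with columns `n`, `z`, `mobility`,
#'   `abundance`, plus optional per-species columns
#'   `interface_fraction` (fraction of the species' intensity lost to
#'   neutral monomer loss at the TIMS-multipole interface),
#'   `interface_loss` (number of monomers lost, default 1) and
#'   `collision_fraction` (override of the global collision-cell
#'   fraction).
#' @param mobilityPeakSigma Gaussian mobility peak sigma (axis units);
#'   the default 0.004 V s/cm^2 corresponds to a TIMS resolving power of
#'   roughly 100-150 over the 1-2 V s/cm^2 range.
#' @param collisionFraction Default fraction of post-selection intensity
#'   moved to collision-cell fragment channels.
#' @param interfaceFraction Default interface fraction for species
#'   without a per-species value.
#' @param extraPathways data.frame of additional collision-cell splits
#'   (columns `n`, `z`, `n1`, `z1`, `n2`, `z2`, `weight`); the built-in
#'   default pathway for every ion is the monomer-loss split
#'   (1,1) + (n-1,z-1).
#' @param quadWindow numeric(0) or c(center, halfwidth) in Th.
#' @param noise c(baseline, multiplicative): baseline feature level as a
#'   fraction of the strongest simulated feature, and sd of the
#'   multiplicative intensity jitter.
#' @param nNoise Number of baseline noise features.
#' @param seed Integer RNG seed.
#' @param platform `"TIMS"` or `"TWIMS"`.
#' @param mzRange Simulated instrument m/z range.
#' @param binWidth Mobility rendering grid step (defaults per platform).
#' @return A [SimulationConfig-class].
#' @export
simulationConfig <- function(peptide, species, mobilityPeakSigma = NULL,
                             collisionFraction = 0.3,
                             interfaceFraction = 0,
                             extraPathways = NULL, quadWindow = numeric(),
                             noise = c(0.003, 0.01), nNoise = 300L,
                             seed = 1L, platform = c("TIMS", "TWIMS"),
                             mzRange = c(50, 3000), binWidth = NULL) {
  if (is.character(peptide)) peptide <- parsePeptide(peptide)
  platform <- match.arg(platform)
  axis <- if (platform == "TIMS") "inverse_reduced_mobility" else "drift_time"
  if (is.null(mobilityPeakSigma))
    mobilityPeakSigma <- if (platform == "TIMS") 0.004 else 0.08
  if (is.null(binWidth)) binWidth <- .defaultBinWidth(axis)
  if (is.null(extraPathways))
    extraPathways <- data.frame(n = integer(), z = integer(),
                                n1 = integer(), z1 = integer(),
                                n2 = integer(), z2 = integer(),
                                weight = numeric())
  species <- as.data.frame(species)
  for (col in c("interface_fraction", "collision_fraction"))
    if (!col %in% names(species)) species[[col]] <- NA_real_
  if (!"interface_loss" %in% names(species))
    species$interface_loss <- 1L
  cfg <- new("SimulationConfig", peptide = peptide, species = species,
             mobilityPeakSigma = mobilityPeakSigma,
             collisionFraction = collisionFraction,
             interfaceFraction = interfaceFraction,
             extraPathways = extraPathways,
             quadWindow = as.numeric(quadWindow), noise = noise,
             seed = as.integer(seed), platform = platform,
             mobilityAxis = axis, mzRange = mzRange, binWidth = binWidth)
  attr(cfg, "nNoise") <- as.integer(nNoise)
  cfg
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: %s, %d species, %s\n",
              object@peptide@name, nrow(object@species), object@platform))
  if (length(object@quadWindow))
    cat(sprintf("  quadrupole selection %.2f +/- %.2f Th\n",
                object@quadWindow[1], object@quadWindow[2]))
  cat(sprintf("  interface/collision fractions: %.2f / %.2f, seed %d\n",
              object@interfaceFraction, object@collisionFraction,
              object@seed))
})

## Collision-cell pathways of an ion: the monomer-loss split plus any
## configured extra splits. Returns products and weights.
.collisionPathways <- function(n, z, extra) {
  paths <- list(list(products = data.frame(n = c(1L, n - 1L),
                                           z = c(1L, z - 1L)),
                     weight = 1))
  ex <- extra[extra$n == n & extra$z == z, , drop = FALSE]
  for (i in seq_len(nrow(ex)))
    paths[[length(paths) + 1L]] <-
      list(products = data.frame(n = c(ex$n1[i], ex$n2[i]),
                                 z = c(ex$z1[i], ex$z2[i])),
           weight = ex$weight[i])
  paths
}

#' Simulate an IM-MS dataset with ground truth
#'
#' Renders every configured species as its isotopic envelope crossed
#' with a Gaussian mobility peak, then applies the instrument model in
#' order: interface fragmentation (neutral monomer loss, keeping the
#' precursor's mobility), quadrupole selection (only ions inside the
#' window pass), collision-cell fragmentation (intensity redistributed
#' to charged fragment channels in proportion to product charge, again
#' keeping the post-IM mobility), and finally baseline plus
#' multiplicative noise. Fully reproducible from the config seed.
#'
#' @param config A [SimulationConfig-class].
#' @return List with `dataset` (an [IMMSDataset-class]) and `truth`
#'   (data.frame, one row per feature: `provenance` in
#'   intact/interface_fragment/collision_fragment/noise, the current ion
#'   `ion_n`/`ion_z`, its immediate precursor `precursor_n`/
#'   `precursor_z`, and the rendered `mobility` center).
#' @export
simulateDataset <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  M <- compositionMass(peptideComposition(config@peptide))
  comp <- peptideComposition(config@peptide)
  sp <- config@species

  ## skip species outside the instrument range
  spMz <- oligomerMz(M, sp$n, sp$z)
  outside <- spMz < config@mzRange[1] | spMz > config@mzRange[2]
  if (any(outside)) {
    warning(sprintf("%d species outside the m/z range were skipped",
                    sum(outside)))
    sp <- sp[!outside, , drop = FALSE]
  }
  if (nrow(sp) == 0L) stop("no species inside the m/z range")

  ## --- population bookkeeping ------------------------------------------
  pops <- data.frame(n = sp$n, z = sp$z, mobility = sp$mobility,
                     intensity = sp$abundance, provenance = "intact",
                     precursor_n = sp$n, precursor_z = sp$z)

  ## interface fragmentation (pre-quad): neutral monomer loss
  newPops <- list()
  for (i in seq_len(nrow(sp))) {
    f <- sp$interface_fraction[i]
    if (is.na(f)) f <- config@interfaceFraction
    loss <- sp$interface_loss[i]
    if (f > 0 && sp$n[i] - loss >= 1L) {
      moved <- f * pops$intensity[i]
      pops$intensity[i] <- pops$intensity[i] - moved
      newPops[[length(newPops) + 1L]] <-
        data.frame(n = sp$n[i] - loss, z = sp$z[i],
                   mobility = sp$mobility[i], intensity = moved,
                   provenance = "interface_fragment",
                   precursor_n = sp$n[i], precursor_z = sp$z[i])
    }
  }
  pops <- do.call(rbind, c(list(pops), newPops))

  ## quadrupole selection
  if (length(config@quadWindow) == 2L) {
    mz <- oligomerMz(M, pops$n, pops$z)
    pops <- pops[abs(mz - config@quadWindow[1]) <= config@quadWindow[2], ,
                 drop = FALSE]
    if (nrow(pops) == 0L) stop("no ion passes the quadrupole window")
  }

  ## collision-cell fragmentation (post-quad)
  newPops <- list()
  for (i in seq_len(nrow(pops))) {
    if (pops$n[i] < 2L) next
    j <- which(sp$n == pops$n[i] & sp$z == pops$z[i])
    cf <- if (length(j) && !is.na(sp$collision_fraction[j[1]]))
      sp$collision_fraction[j[1]] else config@collisionFraction
    if (cf <= 0) next
    paths <- .collisionPathways(pops$n[i], pops$z[i], config@extraPathways)
    w <- vapply(paths, `[[`, numeric(1), "weight")
    moved <- cf * pops$intensity[i]
    pops$intensity[i] <- pops$intensity[i] - moved
    for (p in seq_along(paths)) {
      prod <- paths[[p]]$products
      charged <- prod[prod$z >= 1L, , drop = FALSE]
      if (nrow(charged) == 0L) next
      share <- moved * w[p] / sum(w) * charged$z / sum(charged$z)
      for (q in seq_len(nrow(charged)))
        newPops[[length(newPops) + 1L]] <-
          data.frame(n = charged$n[q], z = charged$z[q],
                     mobility = pops$mobility[i], intensity = share[q],
                     provenance = "collision_fragment",
                     precursor_n = pops$n[i], precursor_z = pops$z[i])
    }
  }
  pops <- do.call(rbind, c(list(pops), newPops))
  pops <- pops[pops$intensity > 0, , drop = FALSE]

  ## --- render features --------------------------------------------------
  bw <- config@binWidth
  sigma <- config@mobilityPeakSigma
  renderOne <- function(i) {
    env <- isotopeEnvelope(comp, n = pops$n[i], z = pops$z[i],
                           minAbundance = 1e-3)
    mob <- seq(pops$mobility[i] - 4 * sigma, pops$mobility[i] + 4 * sigma,
               by = bw)
    gw <- stats::dnorm(mob, pops$mobility[i], sigma)
    gw <- gw / sum(gw)
    feat <- expand.grid(mz = env@mz, mobility = mob)
    feat$intensity <- pops$intensity[i] *
      rep(env@abundance, times = length(mob)) *
      rep(gw, each = length(env@mz))
    feat
  }
  feats <- lapply(seq_len(nrow(pops)), renderOne)
  nFeat <- vapply(feats, nrow, integer(1))
  features <- do.call(rbind, feats)
  ## ions outside the instrument m/z range are never recorded
  inRange <- features$mz >= config@mzRange[1] &
    features$mz <= config@mzRange[2]
  truth <- pops[rep(seq_len(nrow(pops)), nFeat),
                c("provenance", "precursor_n", "precursor_z")]
  truth$ion_n <- rep(pops$n, nFeat)
  truth$ion_z <- rep(pops$z, nFeat)
  truth$mobility <- rep(pops$mobility, nFeat)
  features <- features[inRange, , drop = FALSE]
  truth <- truth[inRange, , drop = FALSE]
  rownames(truth) <- NULL

  ## --- noise -------------------------------------------------------------
  out <- .withSeed(config@seed, {
    if (config@noise[2] > 0)
      features$intensity <- pmax(0, features$intensity *
                                   (1 + stats::rnorm(nrow(features), 0,
                                                     config@noise[2])))
    nNoise <- attr(config, "nNoise") %||% 300L
    if (config@noise[1] > 0 && nNoise > 0) {
      lvl <- config@noise[1] * max(features$intensity)
      mobRange <- range(features$mobility)
      noiseFeat <- data.frame(
        mz = stats::runif(nNoise, config@mzRange[1], config@mzRange[2]),
        mobility = stats::runif(nNoise, mobRange[1] - 0.05 * diff(mobRange),
                                mobRange[2] + 0.05 * diff(mobRange)),
        intensity = stats::runif(nNoise, 0, lvl))
      features <- rbind(features, noiseFeat)
      truth <- rbind(truth,
                     data.frame(provenance = "noise",
                                precursor_n = NA_integer_,
                                precursor_z = NA_integer_,
                                ion_n = NA_integer_, ion_z = NA_integer_,
                                mobility = noiseFeat$mobility))
    }
    list(features = features, truth = truth)
  })
  features <- out$features
  truth <- out$truth
  o <- order(features$mz, features$mobility)
  features <- features[o, , drop = FALSE]
  truth <- truth[o, , drop = FALSE]
  rownames(features) <- rownames(truth) <- NULL

  dataset <- IMMSDataset(features, platform = config@platform,
                         mobilityAxis = config@mobilityAxis,
                         quadWindow = config@quadWindow,
                         metadata = list(simulated = "true",
                                         seed = config@seed,
                                         peptide = config@peptide@name))
  list(dataset = dataset, truth = truth)
}

#' Crude mobility trend for peptide oligomer ions
#'
#' A power-law trend 1/K0 = c * n^beta / z, with the default
#' coefficients fitted once to the package's reference 2:1-family
#' mobility values. Used by the fixture generator to place species whose
#' mobility is not otherwise specified; it is a synthetic stand-in, not
#' a physical CCS model.
#'
#' @param n,z Oligomer order and charge.
#' @param c0,beta Trend coefficients.
#' @return Approximate 1/K0 (V s/cm^2).
#' @export
approxOligomerMobility <- function(n, z, c0 = 1.195, beta = 0.713) {
  c0 * n^beta / z
}

## Printed mobility apexes of the m/z 1580 ([2n]^(nz+)) family used by
## the fixtures, plus synthetic positions (from the power-law trend,
## one nudged for peak separation) for species without a printed value.
.FAMILY_1580_MOBILITY <- data.frame(
  n = c(2L, 4L, 6L, 8L, 10L, 12L),
  z = c(1L, 2L, 3L, 4L, 5L, 6L),
  mobility = c(1.959, 1.606, 1.416, 1.299, 1.203, 1.126))

.INTERFACE_SOURCES_1580 <- data.frame(
  n = c(11L, 12L, 13L, 13L),
  z = c(5L, 5L, 5L, 6L),
  mobility = c(1.278, 1.370, 1.451, 1.180),
  interface_loss = c(1L, 2L, 3L, 1L))

#' Write the canonical synthetic fixture suite
#'
#' Generates the reference datasets used throughout the tests and
#' documentation, each with a `.truth.tsv` ground-truth sidecar:
#' \describe{
#'   \item{fig2_no_quad}{No-selection TIMS dataset: the m/z 1580 family
#'     at its reference mobilities plus the intact channel ions and the
#'     interface-source precursors (synthetic positions), without
#'     fragmentation -- the intact reference.}
#'   \item{fig3_quad1580}{Quadrupole-selected (1580 +/- 5 Th) dataset
#'     with collision-cell fragmentation of every family member and
#'     interface monomer-loss feeding of the 10^5+ and 12^6+ channels.}
#'   \item{fig5_twims_2369}{TWIMS drift-time dataset of the m/z 2369
#'     (3:1) family.}
#'   \item{calibrants_tims}{Tuning-mix style TIMS calibrant table
#'     (columns `raw`, `mz`, `invK0`).}
#'   \item{calibrants_twims}{Synthetic TWIMS calibrant table generated
#'     from a known power law (columns `mz`, `z`, `ccs_ref`, `dt`).}
#' }
#' All mobility values not printed in the package's reference tables are
#' synthetic (see [approxOligomerMobility()]).
#'
#' @param outputDir Writable output directory (created if missing).
#' @param seed Base RNG seed for the simulated datasets.
#' @return Named character vector of the files written, invisibly.
#' @export
makeFixtureSuite <- function(outputDir, seed = 1L) {
  if (!dir.exists(outputDir))
    dir.create(outputDir, recursive = TRUE)
  if (file.access(outputDir, mode = 2) != 0)
    stop("output directory is not writable: ", outputDir)
  paths <- c()
  writeSim <- function(name, config) {
    sim <- simulateDataset(config)
    p <- file.path(outputDir, paste0(name, ".tsv"))
    writeFeatureTable(sim$dataset, p)
    utils::write.table(sim$truth, file.path(outputDir, paste0(name, ".truth.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    paths[name] <<- p
  }

  writeSim("fig2_no_quad", fixtureConfigNoQuad(seed))
  writeSim("fig3_quad1580", fixtureConfigQuad1580(seed + 1L))
  writeSim("fig5_twims_2369", fixtureConfigTwims2369(seed + 2L))

  ## TIMS calibrants: reference Tuning Mix 1/K0 values with a synthetic
  ## monotone raw axis (mildly nonlinear in 1/K0)
  ref <- tuningMixReference()
  cal <- data.frame(raw = 100 + 400 * ref$invK0 + 20 * ref$invK0^2,
                    mz = ref$mz, invK0 = ref$invK0)
  p <- file.path(outputDir, "calibrants_tims.tsv")
  utils::write.table(cal, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["calibrants_tims"] <- p

  ## TWIMS calibrants: synthetic, generated from a known power law
  p <- file.path(outputDir, "calibrants_twims.tsv")
  utils::write.table(syntheticTwimsCalibrants(), p, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths["calibrants_twims"] <- p
  invisible(paths)
}

#' Reference TIMS calibrant table (Agilent ESI Tuning Mix)
#'
#' The eight Tuning Mix ions and their reference inverse reduced
#' mobilities used for external TIMS calibration.
#'
#' @return data.frame with columns `mz`, `invK0`.
#' @export
tuningMixReference <- function() {
  data.frame(mz = c(322, 622, 922, 1222, 1522, 1822, 2122, 2422),
             invK0 = c(0.732, 0.985, 1.190, 1.382, 1.556, 1.729, 1.884, 2.03))
}

#' Synthetic TWIMS calibrant table
#'
#' A calibrant table generated from a known log-log calibration law
#' (slope 0.55, intercept 6.31, EDC 1.35), with plausible singly charged
#' calibrant masses and CCS magnitudes. Synthetic: the values are
#' constructed for exact-recovery testing, not measured.
#'
#' @param slope,intercept,edc Generating calibration parameters.
#' @return data.frame with columns `mz`, `z`, `ccs_ref`, `dt`.
#' @export
syntheticTwimsCalibrants <- function(slope = 0.55, intercept = 6.31,
                                     edc = 1.35) {
  mz <- c(322, 622, 922, 1222, 1522, 1822, 2122, 2422)
  z <- rep(1L, length(mz))
  ccs <- c(153, 202, 243, 282, 317, 351, 383, 413)
  ionMass <- z * (mz - PROTON_MASS)
  mu <- ionMass * N2_MASS / (ionMass + N2_MASS)
  ccsCorr <- ccs * sqrt(mu) / z
  dtCorr <- exp((log(ccsCorr) - intercept) / slope)
  data.frame(mz = mz, z = z, ccs_ref = ccs,
             dt = dtCorr + edc * sqrt(mz) / 1000)
}

#' @rdname makeFixtureSuite
#' @param seed RNG seed.
#' @return `fixtureConfigNoQuad()` etc.: a [SimulationConfig-class].
#' @export
fixtureConfigNoQuad <- function(seed = 1L) {
  fam <- .FAMILY_1580_MOBILITY
  src <- .INTERFACE_SOURCES_1580
  ## intact channel ions whose mobilities the assignment consults
  ## (11^5+ is already among the interface sources)
  chan <- data.frame(n = c(1L, 9L, 8L),
                     z = c(1L, 4L, 3L))
  chan$mobility <- round(approxOligomerMobility(chan$n, chan$z), 3)
  species <- rbind(
    data.frame(n = fam$n, z = fam$z, mobility = fam$mobility,
               abundance = c(100, 60, 40, 25, 15, 10)),
    data.frame(n = chan$n, z = chan$z, mobility = chan$mobility,
               abundance = c(80, 12, 10)),
    data.frame(n = src$n, z = src$z, mobility = src$mobility,
               abundance = c(8, 7, 6, 6)))
  simulationConfig("Ac-VQIVYK-NH2", species,
                   collisionFraction = 0, interfaceFraction = 0,
                   noise = c(0.002, 0.005), seed = seed)
}

#' @rdname makeFixtureSuite
#' @export
fixtureConfigQuad1580 <- function(seed = 2L) {
  fam <- .FAMILY_1580_MOBILITY
  src <- .INTERFACE_SOURCES_1580
  species <- rbind(
    data.frame(n = fam$n, z = fam$z, mobility = fam$mobility,
               abundance = c(100, 60, 40, 25, 15, 10),
               interface_fraction = 0, interface_loss = 1L,
               collision_fraction = NA_real_),
    data.frame(n = src$n, z = src$z, mobility = src$mobility,
               abundance = c(8, 0.01, 6, 6),
               interface_fraction = c(0.6, 0, 0.6, 0.6),
               interface_loss = src$interface_loss,
               collision_fraction = NA_real_))
  M <- compositionMass(peptideComposition("Ac-VQIVYK-NH2"))
  simulationConfig("Ac-VQIVYK-NH2", species,
                   collisionFraction = 0.35,
                   extraPathways = data.frame(n = 10L, z = 5L, n1 = 2L,
                                              z1 = 2L, n2 = 8L, z2 = 3L,
                                              weight = 1),
                   quadWindow = c(oligomerMz(M, 2, 1), 5),
                   noise = c(0.002, 0.005), seed = seed)
}

#' @rdname makeFixtureSuite
#' @export
fixtureConfigTwims2369 <- function(seed = 3L) {
  species <- data.frame(n = c(3L, 6L, 9L, 12L, 15L),
                        z = c(1L, 2L, 3L, 4L, 5L),
                        mobility = c(9.8, 7.4, 6.3, 5.7, 5.2),
                        abundance = c(100, 45, 25, 12, 6))
  simulationConfig("Ac-VQIVYK-NH2", species, platform = "TWIMS",
                   collisionFraction = 0, interfaceFraction = 0,
                   noise = c(0.002, 0.005), seed = seed)
}
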