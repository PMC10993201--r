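#' @import methods
NULL

#' Elemental composition of a molecule
#'
#' Holds non-negative atom counts over the elements C, H, N, O, S.
#' Compositions support addition and integer scaling via `+` and `*`,
#' which is how n-mer compositions are derived from the monomer.
#'
#' @slot counts Named numeric vector of non-negative integer atom counts,
#'   names a subset of C, H, N, O, S.
#' @export
setClass("ElementalComposition",
         representation(counts = "numeric"))

setValidity("ElementalComposition", function(object) {
  cts <- object@counts
  if (is.null(names(cts)) || !all(names(cts) %in% .ELEMENTS))
    return(sprintf("element names must be among: %s",
                   paste(.ELEMENTS, collapse = ", ")))
  if (any(cts < 0)) return("element counts must be non-negative")
  if (any(cts != round(cts))) return("element counts must be integers")
  TRUE
})

#' A capped peptide
#'
#' A peptide defined by its one-letter sequence plus the state of its
#' termini: the N-terminus may be free or acetylated, the C-terminus a
#' free acid or an amide. Terminal capping removes the terminal charges
#' and strongly modulates the aggregation propensity of amyloidogenic
#' segments such as PHF6 (VQIVYK).
#'
#' @slot sequence One-letter amino-acid string (canonical 20 residues).
#' @slot nCap `"free"` or `"acetyl"`.
#' @slot cCap `"free_acid"` or `"amide"`.
#' @slot name Display label.
#' @export
setClass("PeptideSpec",
         representation(sequence = "character", nCap = "character",
                        cCap = "character", name = "character"))

setValidity("PeptideSpec", function(object) {
  seq <- object@sequence
  if (length(seq) != 1L || !nzchar(seq)) return("sequence must be a non-empty string")
  letters1 <- strsplit(seq, "")[[1]]
  bad <- setdiff(letters1, names(.RESIDUES))
  if (length(bad))
    return(sprintf("unknown residue letter(s): %s", paste(unique(bad), collapse = ", ")))
  if (!object@nCap %in% c("free", "acetyl")) return("nCap must be 'free' or 'acetyl'")
  if (!object@cCap %in% c("free_acid", "amide")) return("cCap must be 'free_acid' or 'amide'")
  TRUE
})

#' Aggregated isotopic envelope of a charged ion
#'
#' Centroided isotopologue peaks of an [nM+zH]^z+ ion: m/z values and
#' relative abundances (normalised to sum to one). Adjacent peaks are
#' spaced by roughly one neutron mass over the charge, which is what the
#' charge-state reading in `inferNZ()` exploits.
#'
#' @slot mz Strictly increasing peak m/z values (Th).
#' @slot abundance Relative abundances, summing to 1.
#' @slot charge Positive integer charge state.
#' @export
setClass("IsotopeEnvelope",
         representation(mz = "numeric", abundance = "numeric", charge = "integer"))

setValidity("IsotopeEnvelope", function(object) {
  if (length(object@mz) != length(object@abundance))
    return("mz and abundance must have equal length")
  if (length(object@mz) == 0L) return("envelope must contain at least one peak")
  if (object@charge < 1L) return("charge must be >= 1")
  if (abs(sum(object@abundance) - 1) > 1e-9)
    return("abundances must sum to 1 within 1e-9")
  if (length(object@mz) > 1L) {
    d <- diff(object@mz)
    if (any(d <= 0)) return("m/z must be strictly increasing")
    ## aggregated peaks sit about one neutron/charge apart; allow the
    ## centroid pull from 15N/17O/2H/34S contributions while still
    ## catching a mislabelled charge state
    tol <- 2e-2 / object@charge
    if (any(abs(d - ISOTOPE_SPACING / object@charge) > tol))
      return("adjacent peak spacing inconsistent with a single charge state")
  }
  TRUE
})

#' An IM-MS feature dataset
#'
#' A collection of (m/z, mobility, intensity) features with platform
#' metadata. The mobility axis is inverse reduced mobility 1/K0
#' (V s/cm^2) on TIMS instruments or drift time (ms) on TWIMS. If the
#' dataset was acquired with the quadrupole selecting a narrow m/z
#' window, `quadWindow` records (center, half-width); features outside
#' the window are then post-selection (collision cell) fragments.
#'
#' @slot features data.frame with numeric columns `mz`, `mobility`,
#'   `intensity` (intensities >= 0).
#' @slot platform `"TIMS"` or `"TWIMS"`.
#' @slot mobilityAxis `"inverse_reduced_mobility"` or `"drift_time"`.
#' @slot quadWindow numeric(0) if no selection, else c(center, halfwidth).
#' @slot metadata Free-form key/value list, preserved on I/O round trips.
#' @export
setClass("IMMSDataset",
         representation(features = "data.frame", platform = "character",
                        mobilityAxis = "character", quadWindow = "numeric",
                        metadata = "list"))

setValidity("IMMSDataset", function(object) {
  f <- object@features
  need <- c("mz", "mobility", "intensity")
  if (!all(need %in% names(f)))
    return(sprintf("features must have columns: %s", paste(need, collapse = ", ")))
  if (nrow(f) && any(f$intensity < 0)) return("intensities must be >= 0")
  if (!object@platform %in% c("TIMS", "TWIMS"))
    return("platform must be 'TIMS' or 'TWIMS'")
  if (!object@mobilityAxis %in% c("inverse_reduced_mobility", "drift_time"))
    return("mobilityAxis must be 'inverse_reduced_mobility' or 'drift_time'")
  if (!length(object@quadWindow) %in% c(0L, 2L))
    return("quadWindow must be empty or c(center, halfwidth)")
  if (length(object@quadWindow) == 2L && object@quadWindow[2] <= 0)
    return("quadWindow half-width must be > 0")
  TRUE
})

#' An extracted ion mobility spectrum (EIM)
#'
#' Intensity as a function of mobility for the features inside one m/z
#' selection, histogrammed on a regular mobility grid.
#'
#' @slot axis Strictly monotone mobility grid (bin centers).
#' @slot intensity Non-negative intensities, same length as `axis`.
#' @slot provenance List describing the m/z selection that produced the
#'   spectrum (and an `empty` flag when the selection matched nothing).
#' @export
setClass("MobilitySpectrum",
         representation(axis = "numeric", intensity = "numeric",
                        provenance = "list"))

setValidity("MobilitySpectrum", function(object) {
  if (length(object@axis) != length(object@intensity))
    return("axis and intensity must have equal length")
  if (length(object@axis) > 1L && any(diff(object@axis) <= 0))
    return("axis must be strictly increasing")
  if (any(object@intensity < 0)) return("intensities must be >= 0")
  TRUE
})

#' TIMS mobility calibration
#'
#' Piecewise-linear monotone map from the instrument's raw mobility axis
#' to calibrated inverse reduced mobility 1/K0, anchored at calibrant
#' ions of known reference 1/K0 (e.g. Agilent ESI Tuning Mix). The map
#' reproduces the reference values exactly at the anchors.
#'
#' @slot anchors data.frame with columns `raw`, `mz`, `invK0`, sorted by
#'   `raw`, both `raw` and `invK0` strictly increasing.
#' @export
setClass("TimsCalibration",
         representation(anchors = "data.frame"))

setValidity("TimsCalibration", function(object) {
  a <- object@anchors
  if (!all(c("raw", "mz", "invK0") %in% names(a)))
    return("anchors must have columns raw, mz, invK0")
  if (nrow(a) < 2L) return("at least 2 anchor points required")
  if (any(diff(a$raw) <= 0) || any(diff(a$invK0) <= 0))
    return("anchor sequence must be strictly increasing (monotone calibration)")
  TRUE
})

#' TWIMS CCS calibration
#'
#' Power-law (log-log linear) calibration of corrected drift times
#' against reduced-mass/charge-corrected reference CCS values:
#' ln(CCS') = slope * ln(dt') + intercept, with dt' the EDC-corrected
#' drift time and CCS' = CCS * sqrt(mu) / z.
#'
#' @slot slope,intercept Fitted log-log regression coefficients.
#' @slot edc Instrument EDC delay coefficient used in the drift-time
#'   correction dt' = dt - edc * sqrt(mz) / 1000.
#' @slot r2 Coefficient of determination of the log-log fit.
#' @slot calibrants The calibrant table used for the fit (columns `mz`,
#'   `z`, `ccs_ref`, `dt`, plus derived `dt_corr`, `ccs_corr`, `fitted`).
#' @slot gasMass Drift gas mass (Da) used for reduced masses.
#' @export
setClass("TwimsCalibration",
         representation(slope = "numeric", intercept = "numeric",
                        edc = "numeric", r2 = "numeric",
                        calibrants = "data.frame", gasMass = "numeric"))

setValidity("TwimsCalibration", function(object) {
  if (nrow(object@calibrants) < 3L) return("fit requires >= 3 calibrants")
  if (object@r2 < 0 || object@r2 > 1) return("r2 must lie in [0, 1]")
  TRUE
})

#' Simulation configuration for synthetic IM-MS data
#'
#' Describes the species to simulate and the instrument model: isotopic
#' envelopes crossed with Gaussian mobility peaks, fragmentation at two
#' loci (the TIMS-multipole interface, before quadrupole selection, and
#' the collision cell, after it), optional quadrupole selection, and
#' additive/multiplicative noise. See [simulateDataset()].
#'
#' @slot peptide The [PeptideSpec-class] monomer.
#' @slot species data.frame with columns `n`, `z`, `mobility`,
#'   `abundance` and optional `interface_fraction`, `interface_loss`,
#'   `collision_fraction` per-species overrides.
#' @slot mobilityPeakSigma Gaussian mobility peak width (axis units).
#' @slot collisionFraction Default fraction of post-quad intensity moved
#'   to collision-cell fragment channels.
#' @slot interfaceFraction Default fraction of pre-quad intensity moved
#'   to the interface monomer-loss product.
#' @slot extraPathways data.frame (possibly empty) of additional
#'   collision-cell splits: columns `n`, `z`, `n1`, `z1`, `n2`, `z2`,
#'   `weight` (the default pathway is the charged monomer-loss split).
#' @slot quadWindow numeric(0) or c(center, halfwidth).
#' @slot noise c(baseline, multiplicative): baseline feature intensity
#'   level relative to the strongest simulated feature, and the sd of the
#'   multiplicative Gaussian jitter.
#' @slot seed Integer RNG seed; identical config + seed gives an
#'   identical dataset.
#' @slot platform,mobilityAxis Dataset metadata (as in
#'   [IMMSDataset-class]).
#' @slot mzRange Simulated instrument m/z range.
#' @slot binWidth Mobility grid step used to render peaks.
#' @export
setClass("SimulationConfig",
         representation(peptide = "PeptideSpec", species = "data.frame",
                        mobilityPeakSigma = "numeric",
                        collisionFraction = "numeric",
                        interfaceFraction = "numeric",
                        extraPathways = "data.frame",
                        quadWindow = "numeric", noise = "numeric",
                        seed = "integer", platform = "character",
                        mobilityAxis = "character", mzRange = "numeric",
                        binWidth = "numeric"))

setValidity("SimulationConfig", function(object) {
  sp <- object@species
  need <- c("n", "z", "mobility", "abundance")
  if (!all(need %in% names(sp)))
    return(sprintf("species must have columns: %s", paste(need, collapse = ", ")))
  if (nrow(sp) == 0L) return("at least one species required")
  if (any(sp$abundance <= 0)) return("abundances must be > 0")
  if (any(sp$n < 1) || any(sp$z < 1)) return("species must have n >= 1, z >= 1")
  if (object@mobilityPeakSigma <= 0) return("mobilityPeakSigma must be > 0")
  fr <- c(object@collisionFraction, object@interfaceFraction)
  if (any(fr < 0) || any(fr > 1)) return("fragmentation fractions must lie in [0, 1]")
  if (any(object@noise < 0)) return("noise parameters must be >= 0")
  if (!length(object@quadWindow) %in% c(0L, 2L))
    return("quadWindow must be empty or c(center, halfwidth)")
  TRUE
})

#' Results of a mobility-coincidence assignment
#'
#' Returned by [assignByCoincidence()]. Contains one row per assigned
#' family member, the per-assignment fragment-channel evidence, and the
#' classification of every residual (non-assigned) mobility peak.
#'
#' @slot assignments data.frame: `n`, `z`, `mobility`, `nSupporting`.
#' @slot evidence List (one element per assignment row) of data.frames
#'   with the supporting channels: `channel_n`, `channel_z`,
#'   `channel_mz`, `apex`, `height`.
#' @slot residualPeaks data.frame of non-assigned apex clusters:
#'   `mobility`, `nChannels`, `classification`, `source_n`, `source_z`.
#'   Classifications are `"intact"`, `"interface_fragment"`,
#'   `"interface_candidate"` or `"unexplained"`.
#' @slot family The candidate family that was screened.
#' @slot warnings Character vector of validation warnings (e.g. the
#'   family-monotonicity check).
#' @slot parameters List of algorithm parameters used.
#' @export
setClass("AssignmentSet",
         representation(assignments = "data.frame", evidence = "list",
                        residualPeaks = "data.frame", family = "data.frame",
                        warnings = "character", parameters = "list"))
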