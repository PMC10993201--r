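#' Enumerate candidate oligomer ions
#'
#' All \[nM+zH\]^z+ species with 1 <= n <= `nMax`, 1 <= z <= `zMax`
#' whose m/z falls inside `mzRange`, sorted by m/z. Each species carries
#' its isobaric family key: the gcd-reduced n:z ratio, so that e.g.
#' (2,1), (4,2) and (8,4) all belong to family "2:1" -- protonated
#' members of one family have exactly equal m/z (2M + m_H+ for the 2:1
#' family) and are separable only by ion mobility.
#'
#' @param M Monomer mass (Da).
#' @param mzRange Length-2 numeric, the instrument m/z range.
#' @param nMax,zMax Search bounds; the defaults cover the oligomer
#'   distributions seen for amyloidogenic hexapeptides (up to ~25-mers,
#'   charge states up to 8).
#' @return data.frame with columns `n`, `z`, `mz`, `family`.
#' @examples
#' M <- compositionMass(peptideComposition("Ac-VQIVYK-NH2"))
#' head(enumerateSpecies(M, c(50, 3000)))
#' @export
enumerateSpecies <- function(M, mzRange, nMax = 25L, zMax = 8L) {
  stopifnot(M > 0, length(mzRange) == 2L, nMax >= 1, zMax >= 1)
  mzRange <- sort(mzRange)
  grid <- expand.grid(n = seq_len(nMax), z = seq_len(zMax))
  grid$mz <- oligomerMz(M, grid$n, grid$z)
  grid <- grid[grid$mz >= mzRange[1] & grid$mz <= mzRange[2], , drop = FALSE]
  if (nrow(grid) == 0L)
    return(data.frame(n = integer(), z = integer(), mz = numeric(),
                      family = character()))
  g <- mapply(.gcd, grid$n, grid$z)
  grid$family <- paste0(grid$n / g, ":", grid$z / g)
  grid <- grid[order(grid$mz, grid$n), , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Isobaric family around a target m/z
#'
#' The subset of [enumerateSpecies()] within `tol` of `targetMz`. When
#' `tol` is below the minimal spacing between families, all members
#' share one family key.
#'
#' @param targetMz Target m/z (Th).
#' @param tol Absolute m/z tolerance (Th).
#' @param M Monomer mass (Da).
#' @param nMax,zMax Search bounds as in [enumerateSpecies()].
#' @return data.frame as in [enumerateSpecies()], ordered by n.
#' @examples
#' M <- compositionMass(peptideComposition("Ac-VQIVYK-NH2"))
#' isobaricFamily(1580, 0.5, M)   # the [2n]^(nz+) family
#' @export
isobaricFamily <- function(targetMz, tol, M, nMax = 25L, zMax = 8L) {
  stopifnot(tol > 0)
  sp <- enumerateSpecies(M, c(targetMz - tol, targetMz + tol), nMax, zMax)
  sp <- sp[order(sp$n), , drop = FALSE]
  rownames(sp) <- NULL
  sp
}

#' Infer oligomer order and charge from m/z and isotope spacing
#'
#' The charge state is read from the isotopologue spacing
#' (z = round(1.00336 / spacing)) and the oligomer order from the
#' deconvoluted neutral mass (n = round(z * (mz - m_H+) / M)). The
#' candidate is accepted only if its theoretical m/z matches the
#' observation within `tolPpm`; otherwise the best candidate is returned
#' with `assigned = FALSE`.
#'
#' @param observedMz Apex m/z of the observed envelope (Th). Nominal
#'   peak labels (e.g. 1580) are acceptable: the default tolerance
#'   allows for label rounding.
#' @param isotopeSpacing Observed spacing between adjacent isotopologue
#'   peaks (Th).
#' @param M Monomer mass (Da).
#' @param tolPpm Acceptance tolerance on the back-computed m/z (ppm).
#' @return List with `n`, `z`, `mz_theoretical`, `ppm_error`,
#'   `assigned`.
#' @examples
#' M <- compositionMass(peptideComposition("Ac-VQIVYK-NH2"))
#' inferNZ(1580.0, 0.25, M)  # the quadruply charged octamer
#' @export
inferNZ <- function(observedMz, isotopeSpacing, M, tolPpm = 100) {
  stopifnot(observedMz > 0, isotopeSpacing > 0, M > 0, tolPpm > 0)
  z <- max(1L, as.integer(round(ISOTOPE_SPACING / isotopeSpacing)))
  n <- as.integer(round(z * (observedMz - PROTON_MASS) / M))
  if (n < 1L)
    return(list(n = NA_integer_, z = z, mz_theoretical = NA_real_,
                ppm_error = NA_real_, assigned = FALSE))
  mzTheo <- oligomerMz(M, n, z)
  ppm <- 1e6 * abs(mzTheo - observedMz) / observedMz
  list(n = n, z = z, mz_theoretical = mzTheo, ppm_error = ppm,
       assigned = ppm <= tolPpm)
}

#' Screen a dataset for detectable oligomers
#'
#' For every candidate (n, z) species within the dataset's m/z range,
#' computes an envelope-matched signal-to-noise ratio and marks the
#' species detected when S/N strictly exceeds `snrThreshold`. Noise is
#' estimated robustly (median + 1.4826 * MAD) from features outside all
#' candidate envelope windows; signal is the strongest feature within
#' `mzTol` of any envelope peak of the species.
#'
#' @param dataset An [IMMSDataset-class].
#' @param M Monomer mass (Da).
#' @param snrThreshold Detection threshold (strict inequality). The
#'   conventional reporting threshold is S/N > 3.
#' @param nMax,zMax Candidate bounds, as in [enumerateSpecies()].
#' @param comp Optional monomer [ElementalComposition-class] for
#'   envelope-based selection; defaults to a window of +/- `mzTol`
#'   around the monoisotopic m/z plus the first few isotopologues.
#' @param mzTol m/z half-window per envelope peak (Th).
#' @return A detection grid: data.frame with columns `n`, `z`, `mz`,
#'   `snr`, `detected`. Serialise with [writeDetectionGrid()].
#' @export
screenOligomers <- function(dataset, M, snrThreshold = 3, nMax = 25L,
                            zMax = 8L, comp = NULL, mzTol = 0.05) {
  stopifnot(is(dataset, "IMMSDataset"))
  f <- dataset@features
  if (nrow(f) == 0L)
    return(data.frame(n = integer(), z = integer(), mz = numeric(),
                      snr = numeric(), detected = logical()))
  if (all(f$intensity == 0)) stop("dataset has no intensity information")
  cand <- enumerateSpecies(M, range(f$mz), nMax, zMax)
  if (nrow(cand) == 0L)
    return(data.frame(n = integer(), z = integer(), mz = numeric(),
                      snr = numeric(), detected = logical()))

  ## per-candidate envelope peak positions
  peaksOf <- function(i) {
    if (!is.null(comp)) {
      isotopeEnvelope(comp, cand$n[i], cand$z[i], minAbundance = 1e-3)@mz
    } else {
      cand$mz[i] + (0:4) * ISOTOPE_SPACING / cand$z[i]
    }
  }
  envPeaks <- lapply(seq_len(nrow(cand)), peaksOf)

  ## noise from signal-free regions: features away from every envelope
  allPeaks <- sort(unique(unlist(envPeaks)))
  nearSignal <- vapply(f$mz, function(x) {
    i <- findInterval(x, allPeaks)
    lo <- if (i >= 1) allPeaks[i] else -Inf
    hi <- if (i < length(allPeaks)) allPeaks[i + 1] else Inf
    min(x - lo, hi - x) <= 0.3
  }, logical(1))
  noiseInt <- f$intensity[!nearSignal]
  noise <- if (length(noiseInt))
    stats::median(noiseInt) + 1.4826 * stats::mad(noiseInt, constant = 1)
  else 0
  noise <- max(noise, .Machine$double.eps)

  cand$snr <- vapply(seq_len(nrow(cand)), function(i) {
    pk <- envPeaks[[i]]
    hit <- f$intensity[rowSums(abs(outer(f$mz, pk, `-`)) <= mzTol) > 0]
    if (length(hit)) max(hit) / noise else 0
  }, numeric(1))
  cand$detected <- cand$snr > snrThreshold
  cand$family <- NULL
  rownames(cand) <- NULL
  cand
}

#' Write a detection grid to TSV
#'
#' @param grid A detection grid from [screenOligomers()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeDetectionGrid <- function(grid, path) {
  utils::write.table(grid, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
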