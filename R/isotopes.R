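## Aggregated isotope-envelope computation by iterated convolution of
## per-element isotope distributions, with centroid merging and pruning
## so that 25-mer envelopes stay cheap.

## Merge peaks closer than `gap` Da into abundance-weighted centroids and
## drop peaks below `prune` (absolute abundance, distribution sums <= 1).
.iso_aggregate <- function(mass, ab, gap = 0.25, prune = 1e-12) {
  o <- order(mass)
  mass <- mass[o]
  ab <- ab[o]
  grp <- cumsum(c(TRUE, diff(mass) > gap))
  m <- vapply(split(seq_along(mass), grp),
              function(i) sum(mass[i] * ab[i]) / sum(ab[i]), numeric(1))
  a <- vapply(split(ab, grp), sum, numeric(1))
  keep <- a >= prune
  list(mass = unname(m[keep]), ab = unname(a[keep]))
}

.iso_convolve <- function(a, b, prune = 1e-12) {
  mass <- outer(a$mass, b$mass, `+`)
  ab <- outer(a$ab, b$ab)
  .iso_aggregate(as.vector(mass), as.vector(ab), prune = prune)
}

## dist^k by exponentiation-by-squaring.
.iso_power <- function(dist, k, prune = 1e-12) {
  result <- NULL
  base <- dist
  while (k > 0) {
    if (k %% 2 == 1)
      result <- if (is.null(result)) base else .iso_convolve(result, base, prune)
    k <- k %/% 2
    if (k > 0) base <- .iso_convolve(base, base, prune)
  }
  if (is.null(result)) list(mass = 0, ab = 1) else result
}

## Neutral aggregated isotope distribution of a composition.
.neutral_envelope <- function(counts, prune = 1e-12) {
  dist <- list(mass = 0, ab = 1)
  for (el in names(counts)) {
    k <- counts[[el]]
    if (k > 0) {
      tab <- .ISOTOPES[[el]]
      dist <- .iso_convolve(dist, .iso_power(list(mass = tab$mass, ab = tab$ab),
                                             k, prune), prune)
    }
  }
  dist
}

#' Isotopic envelope of a protonated n-mer ion
#'
#' Computes the aggregated (centroided) isotopologue distribution of the
#' \[nM+zH\]^z+ ion of a composition by iterated convolution of the
#' per-element isotope distributions, truncates peaks below
#' `minAbundance` and renormalises. Peak m/z values are
#' (isotopologue mass + z * m_H+) / z, so adjacent peaks sit about
#' 1.00336/z Th apart -- the spacing that reveals the charge state.
#'
#' @param comp An [ElementalComposition-class] (of the monomer), a
#'   [PeptideSpec-class], or a peptide string.
#' @param n Number of monomer units (the composition is scaled n-fold).
#' @param z Charge state.
#' @param minAbundance Peaks below this relative abundance (after
#'   normalisation) are discarded and the rest renormalised.
#' @return An [IsotopeEnvelope-class].
#' @examples
#' env <- isotopeEnvelope(peptideComposition("Ac-VQIVYK-NH2"), n = 8, z = 4)
#' head(env@mz)
#' @export
isotopeEnvelope <- function(comp, n = 1L, z = 1L, minAbundance = 1e-4) {
  if (is.character(comp) || is(comp, "PeptideSpec"))
    comp <- peptideComposition(comp)
  stopifnot(is(comp, "ElementalComposition"))
  if (n < 1 || z < 1) stop("n and z must be >= 1")
  if (minAbundance <= 0 || minAbundance >= 1)
    stop("minAbundance must lie in (0, 1)")
  counts <- comp@counts * n
  if (sum(counts) == 0) stop("empty composition")
  dist <- .neutral_envelope(counts)
  ab <- dist$ab / sum(dist$ab)
  keep <- ab >= minAbundance
  if (!any(keep)) keep <- which.max(ab)
  mass <- dist$mass[keep]
  ab <- ab[keep] / sum(ab[keep])
  o <- order(mass)
  new("IsotopeEnvelope",
      mz = (mass[o] + z * PROTON_MASS) / z,
      abundance = ab[o],
      charge = as.integer(z))
}

setMethod("show", "IsotopeEnvelope", function(object) {
  cat(sprintf("IsotopeEnvelope: %d peaks, charge %d+\n",
              length(object@mz), object@charge))
  cat(sprintf("  m/z %.4f .. %.4f (most abundant at %.4f)\n",
              min(object@mz), max(object@mz),
              object@mz[which.max(object@abundance)]))
})

#' @rdname isotopeEnvelope
#' @param object An [IsotopeEnvelope-class].
#' @return `envelopeTable()`: data.frame with columns `mz`, `abundance`.
#' @export
envelopeTable <- function(object) {
  stopifnot(is(object, "IsotopeEnvelope"))
  data.frame(mz = object@mz, abundance = object@abundance)
}
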