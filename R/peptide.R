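#' Construct an elemental composition
#'
#' @param ... Named integer atom counts, e.g. `C = 2, H = 5, N = 1, O = 2`.
#'   Supported elements: C, H, N, O, S.
#' @return An [ElementalComposition-class] object.
#' @examples
#' glycine <- ElementalComposition(C = 2, H = 5, N = 1, O = 2)
#' compositionMass(glycine)
#' @export
ElementalComposition <- function(...) {
  cts <- unlist(list(...))
  if (is.null(names(cts)) && length(cts))
    stop("atom counts must be named by element")
  full <- stats::setNames(numeric(length(.ELEMENTS)), .ELEMENTS)
  full[names(cts)] <- cts
  new("ElementalComposition", counts = full)
}

#' @rdname ElementalComposition-class
#' @export
setMethod("elementCounts", "ElementalComposition", function(object) object@counts)

#' @export
setMethod("+", signature("ElementalComposition", "ElementalComposition"),
          function(e1, e2) new("ElementalComposition", counts = e1@counts + e2@counts))

#' @export
setMethod("*", signature("ElementalComposition", "numeric"),
          function(e1, e2) new("ElementalComposition", counts = e1@counts * e2))

#' @export
setMethod("*", signature("numeric", "ElementalComposition"),
          function(e1, e2) new("ElementalComposition", counts = e2@counts * e1))

#' Chemical formula string
#'
#' @param comp An [ElementalComposition-class].
#' @return Formula such as `"C38H63N9O9"` (zero-count elements omitted).
#' @export
compositionFormula <- function(comp) {
  stopifnot(is(comp, "ElementalComposition"))
  cts <- comp@counts[comp@counts > 0]
  paste0(names(cts), ifelse(cts == 1, "", cts), collapse = "")
}

#' Neutral mass of an elemental composition
#'
#' @param comp An [ElementalComposition-class].
#' @param type `"monoisotopic"` (default; mass of the all-principal-isotope
#'   species) or `"average"` (from standard atomic weights).
#' @return Mass in Da.
#' @export
compositionMass <- function(comp, type = c("monoisotopic", "average")) {
  stopifnot(is(comp, "ElementalComposition"))
  type <- match.arg(type)
  w <- if (type == "monoisotopic") .MONO_MASS else .AVG_MASS
  sum(comp@counts * w[names(comp@counts)])
}

#' @rdname moleculeMass
#' @export
setMethod("moleculeMass", "ElementalComposition",
          function(object, ...) compositionMass(object, ...))

setMethod("show", "ElementalComposition", function(object) {
  cat("ElementalComposition:", compositionFormula(object),
      sprintf("(monoisotopic %.4f Da)\n", compositionMass(object)))
})

#' Construct a capped peptide
#'
#' @param sequence One-letter amino-acid sequence.
#' @param nCap `"free"` or `"acetyl"`.
#' @param cCap `"free_acid"` or `"amide"`.
#' @param name Optional label; defaults to the canonical string form
#'   (e.g. `"Ac-VQIVYK-NH2"`).
#' @return A [PeptideSpec-class] object.
#' @seealso [parsePeptide()] for the string form.
#' @export
PeptideSpec <- function(sequence, nCap = c("free", "acetyl"),
                        cCap = c("free_acid", "amide"), name = NULL) {
  nCap <- match.arg(nCap)
  cCap <- match.arg(cCap)
  if (is.null(name))
    name <- paste0(if (nCap == "acetyl") "Ac-" else "", sequence,
                   if (cCap == "amide") "-NH2" else "")
  new("PeptideSpec", sequence = sequence, nCap = nCap, cCap = cCap, name = name)
}

#' Parse a capped-peptide string
#'
#' Accepts strings such as `"Ac-VQIVYK-NH2"`: an optional `"Ac-"` prefix
#' marks N-terminal acetylation and an optional `"-NH2"` suffix marks
#' C-terminal amidation; the remainder is the one-letter sequence.
#'
#' @param x A peptide string.
#' @return A [PeptideSpec-class] object.
#' @examples
#' parsePeptide("Ac-VQIVYK-NH2")
#' parsePeptide("VQIVYK")
#' @export
parsePeptide <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  raw <- x
  nCap <- "free"
  cCap <- "free_acid"
  if (grepl("^Ac-", x)) {
    nCap <- "acetyl"
    x <- sub("^Ac-", "", x)
  }
  if (grepl("-NH2$", x)) {
    cCap <- "amide"
    x <- sub("-NH2$", "", x)
  }
  bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWY]", x)
  if (bad > 0)
    stop(sprintf("invalid residue '%s' at position %d of '%s'",
                 substr(x, bad, bad), as.integer(bad), raw))
  PeptideSpec(x, nCap = nCap, cCap = cCap, name = raw)
}

setMethod("show", "PeptideSpec", function(object) {
  comp <- peptideComposition(object)
  cat("PeptideSpec:", object@name, "\n")
  cat("  sequence:", object@sequence,
      sprintf("(%d residues)\n", nchar(object@sequence)))
  cat("  N-terminus:", object@nCap, " C-terminus:", object@cCap, "\n")
  cat("  composition:", compositionFormula(comp),
      sprintf(" monoisotopic %.4f Da\n", compositionMass(comp)))
})

#' Elemental composition of a capped peptide
#'
#' Sums residue compositions plus one water for the free termini, then
#' applies the cap adjustments: acetylation adds C2H2O; amidation
#' replaces the C-terminal OH by NH2 (net -O +NH).
#'
#' @param spec A [PeptideSpec-class] (or a peptide string, which is
#'   passed through [parsePeptide()]).
#' @return An [ElementalComposition-class].
#' @examples
#' compositionFormula(peptideComposition("Ac-VQIVYK-NH2"))  # C38H63N9O9
#' @export
peptideComposition <- function(spec) {
  if (is.character(spec)) spec <- parsePeptide(spec)
  stopifnot(is(spec, "PeptideSpec"))
  letters1 <- strsplit(spec@sequence, "")[[1]]
  cts <- Reduce(`+`, .RESIDUES[letters1])
  cts <- cts + c(C = 0, H = 2, N = 0, O = 1, S = 0)      # + H2O termini
  if (spec@nCap == "acetyl")
    cts <- cts + c(C = 2, H = 2, N = 0, O = 1, S = 0)    # + C2H2O
  if (spec@cCap == "amide")
    cts <- cts + c(C = 0, H = 1, N = 1, O = -1, S = 0)   # - OH + NH2
  new("ElementalComposition", counts = as.numeric(cts) |>
        stats::setNames(names(cts)))
}

#' @rdname moleculeMass
#' @export
setMethod("moleculeMass", "PeptideSpec",
          function(object, ...) compositionMass(peptideComposition(object), ...))

#' Mass of a noncovalent n-mer
#'
#' Oligomerisation is noncovalent self-assembly, so the n-mer mass is
#' exactly n times the monomer mass (no water loss).
#'
#' @param M Monomer mass (Da).
#' @param n Number of monomer units (>= 1).
#' @return n * M in Da.
#' @export
oligomerMass <- function(M, n) {
  stopifnot(M > 0)
  if (any(n < 1) || any(n != round(n))) stop("n must be a positive integer")
  n * M
}

#' m/z of a protonated oligomer ion [nM+zH]^z+
#'
#' @param M Monomer mass (Da).
#' @param n Number of monomer units (>= 1).
#' @param z Charge state (>= 1, protons only).
#' @return (n * M + z * m_H+) / z in Th.
#' @examples
#' M <- compositionMass(peptideComposition("Ac-VQIVYK-NH2"))
#' oligomerMz(M, 2, 1)  # the m/z 1580 dimer channel
#' @export
oligomerMz <- function(M, n, z) {
  stopifnot(M > 0)
  if (any(n < 1) || any(n != round(n))) stop("n must be a positive integer")
  if (any(z < 1) || any(z != round(z))) stop("z must be a positive integer")
  (n * M + z * PROTON_MASS) / z
}

#' Display label for an m/z value
#'
#' Peaks above m/z 1000 are labelled by the nearest integer, lower ones
#' with one decimal (1580 and 2106, but 790.5).
#'
#' @param mz m/z value(s) in Th.
#' @return Numeric label value(s).
#' @export
mzLabel <- function(mz) {
  ifelse(mz > 1000, round(mz), round(mz, 1))
}
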