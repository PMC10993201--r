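#' Enumerate dissociation pathways of an oligomer ion
#'
#' All binary splits of an (n, z) precursor into two products (k, c) and
#' (n - k, z - c) with 1 <= k <= n - 1 and 0 <= c <= z, deduplicated as
#' unordered pairs. A product with zero charge is a neutral loss and is
#' not detected, but still conserves monomer count. Optionally the
#' smaller product is restricted to at most `maxLosses` monomers (the
#' regime of interface fragmentation, which proceeds mainly by neutral
#' monomer loss).
#'
#' @param n,z Precursor monomer count (>= 2) and charge (>= 1).
#' @param maxLosses Optional cap on the size of the smaller product.
#' @return data.frame with columns `n1`, `z1`, `n2`, `z2` (product 1 is
#'   the lexicographically smaller fragment). A monomer precursor has no
#'   pathways (empty table).
#' @examples
#' enumerateFragmentations(10, 5)  # includes (1,1)+(9,4) and (2,2)+(8,3)
#' @export
enumerateFragmentations <- function(n, z, maxLosses = NULL) {
  stopifnot(n >= 1, z >= 1)
  if (n < 2)
    return(data.frame(n1 = integer(), z1 = integer(),
                      n2 = integer(), z2 = integer()))
  g <- expand.grid(k = seq_len(n - 1L), c = 0:z)
  a <- cbind(g$k, g$c)
  b <- cbind(n - g$k, z - g$c)
  swap <- a[, 1] > b[, 1] | (a[, 1] == b[, 1] & a[, 2] > b[, 2])
  first <- a
  first[swap, ] <- b[swap, ]
  second <- b
  second[swap, ] <- a[swap, ]
  out <- data.frame(n1 = first[, 1], z1 = first[, 2],
                    n2 = second[, 1], z2 = second[, 2])
  out <- unique(out)
  if (!is.null(maxLosses))
    out <- out[pmin(out$n1, out$n2) <= maxLosses, , drop = FALSE]
  out <- out[order(out$n1, out$z1, out$z2), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Charged fragment channels of an oligomer ion
#'
#' The distinct charged products of all [enumerateFragmentations()]
#' pathways of an (n, z) precursor, with their m/z. Neutral products are
#' excluded (they are not observed); products outside `mzRange` are
#' dropped when a range is given.
#'
#' @param n,z Precursor monomer count and charge.
#' @param M Monomer mass (Da).
#' @param mzRange Optional instrument m/z range filter.
#' @return data.frame with columns `n`, `z`, `mz`, sorted by m/z.
#' @examples
#' M <- compositionMass(peptideComposition("Ac-VQIVYK-NH2"))
#' fragmentChannels(10, 5, M)  # channels at 790.5 (1,1), 1777 (9,4), 2106 (8,3), ...
#' @export
fragmentChannels <- function(n, z, M, mzRange = NULL) {
  stopifnot(M > 0)
  paths <- enumerateFragmentations(n, z)
  prods <- rbind(data.frame(n = paths$n1, z = paths$z1),
                 data.frame(n = paths$n2, z = paths$z2))
  prods <- unique(prods[prods$z >= 1L, , drop = FALSE])
  if (nrow(prods) == 0L)
    return(data.frame(n = integer(), z = integer(), mz = numeric()))
  prods$mz <- oligomerMz(M, prods$n, prods$z)
  if (!is.null(mzRange))
    prods <- prods[prods$mz >= min(mzRange) & prods$mz <= max(mzRange), ,
                   drop = FALSE]
  prods <- prods[order(prods$mz), , drop = FALSE]
  rownames(prods) <- NULL
  prods
}

#' Possible interface-fragmentation sources of a channel ion
#'
#' Fragmentation at the TIMS-multipole interface -- after the mobility
#' cell but before quadrupole selection -- proceeds mainly by neutral
#' monomer loss, so an ion observed in an (n, z) channel may actually be
#' the product of a larger precursor (n', z) with the same charge that
#' lost n' - n neutral monomers while keeping its own (larger, hence
#' higher-1/K0) mobility signature.
#'
#' @param n,z Target channel monomer count and charge.
#' @param nMax Largest oligomer considered.
#' @param maxMonomerLoss Maximum number of neutral monomers lost.
#' @return data.frame with columns `n`, `z`, `loss` of candidate source
#'   precursors, smallest loss first.
#' @examples
#' interfaceFragmentSources(10, 5)  # (11,5), (12,5), (13,5)
#' @export
interfaceFragmentSources <- function(n, z, nMax = 25L, maxMonomerLoss = 3L) {
  stopifnot(n >= 1, z >= 1, maxMonomerLoss >= 0)
  if (maxMonomerLoss == 0L)
    return(data.frame(n = integer(), z = integer(), loss = integer()))
  hi <- min(nMax, n + maxMonomerLoss)
  if (hi <= n)
    return(data.frame(n = integer(), z = integer(), loss = integer()))
  src <- seq.int(n + 1L, hi)
  data.frame(n = src, z = z, loss = src - n)
}
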