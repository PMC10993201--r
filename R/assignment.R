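## Mobility-coincidence assignment of quadrupole-selected oligomers.
##
## In a quadrupole-selection experiment all members of one isobaric
## family pass the mass filter together and their collision-cell
## fragments inherit the precursor's recorded mobility. A precursor's
## mobility can therefore be read off as the mobility at which several
## of its predicted fragment channels show coincident EIM apexes.

.channelWindow <- function(mz, z) c(1.1 / z, 9 * ISOTOPE_SPACING / z)

## Savitzky-Golay smoothing guard: skip when the spectrum is too short.
.maybeSmooth <- function(eim, windowLength = 9L, polyorder = 3L) {
  if (windowLength > 0 && length(eim@axis) >= windowLength)
    smoothSpectrum(eim, windowLength, polyorder)
  else eim
}

.referenceApex <- function(reference, mz, z, binWidth, minHeightFraction = 0.2,
                           smoothWindow = 9L) {
  hw <- .channelWindow(mz, z)
  eim <- suppressWarnings(extractEIM(reference, center = mz, halfwidth = hw,
                                     binWidth = binWidth))
  pk <- detectPeaks(.maybeSmooth(eim, smoothWindow),
                    minHeightFraction = minHeightFraction)
  if (nrow(pk)) pk$apex[1] else NA_real_
}

#' Assign oligomer mobilities by fragment-channel apex coincidence
#'
#' Implements the quadrupole-selection assignment workflow for one
#' isobaric family: (1) predict the charged fragment channels of every
#' family member (channels falling back inside the selection window are
#' excluded as ambiguous); (2) extract and peak-pick the EIM of each
#' channel; (3) cluster apexes across channels by single linkage with
#' `tolMobility` as the link threshold; (4) a cluster supported by at
#' least `minChannels` distinct channels is attributable to any family
#' member whose predicted channel set covers all supporting channels;
#' (5) the reported assignment is the ordered maximum matching of
#' clusters (by decreasing mobility) to candidate members (by
#' increasing n) -- within one isobaric family mobility decreases
#' strictly with oligomer order, so the joint assignment must preserve
#' both orders; ties are resolved toward lower-mobility clusters
#' because interface-fragmentation artifacts of larger same-charge
#' precursors always sit above the true precursor mobility; (6)
#' residual clusters are classified
#' against the intact reference: matching an intact family-member
#' mobility gives `"intact"`, matching the intact mobility of an
#' interface source precursor (neutral monomer loss chain) gives
#' `"interface_fragment"` with the source named, otherwise clusters
#' above the member's assignment are `"interface_candidate"` and the
#' rest `"unexplained"`. A validation warning is recorded (and raised)
#' if assigned mobilities are not strictly decreasing with n.
#'
#' @param quadDataset An [IMMSDataset-class] acquired with quadrupole
#'   selection (`quadWindow` must be set).
#' @param M Monomer mass (Da).
#' @param family data.frame with columns `n`, `z`: the candidate family
#'   members inside the window (see [isobaricFamily()]).
#' @param intactReference Optional [IMMSDataset-class] measured without
#'   quadrupole selection, used to classify residual peaks. Without it
#'   the interface/intact classifications degrade to
#'   `"interface_candidate"`/`"unexplained"`.
#' @param tolMobility Coincidence tolerance (axis units); defaults to
#'   0.01 V s/cm^2 on TIMS and 0.2 ms on TWIMS.
#' @param minChannels Minimum number of distinct supporting channels.
#' @param peptide Optional monomer ([PeptideSpec-class], string or
#'   [ElementalComposition-class]) enabling envelope-based channel
#'   selection; otherwise a charge-scaled m/z window is used.
#' @param binWidth Mobility grid step (defaults per platform).
#' @param minHeightFraction Per-channel relative peak threshold
#'   (default 0: fragment channels shared by many precursors span a wide
#'   dynamic range, so peak acceptance is governed by the absolute
#'   floor).
#' @param minChannelFraction Absolute peak floor as a fraction of the
#'   precursor-channel EIM maximum; suppresses noise-only channels while
#'   keeping the weak channels of low-abundance high-order members.
#' @param maxMonomerLoss Interface-source search depth (monomers).
#' @param nMax Largest oligomer considered for interface sources.
#' @param smoothWindow Savitzky-Golay window (order 3) applied to every
#'   EIM before peak picking, as is standard practice for mobility
#'   spectra; 0 disables smoothing.
#' @param mzRange Instrument m/z range: fragment channels outside it are
#'   never observed and are excluded. Defaults to the dataset's feature
#'   m/z range padded by 10 Th.
#' @return An [AssignmentSet-class].
#' @export
assignByCoincidence <- function(quadDataset, M, family,
                                intactReference = NULL, tolMobility = NULL,
                                minChannels = 2L, peptide = NULL,
                                binWidth = NULL, minHeightFraction = 0,
                                minChannelFraction = 0.003,
                                maxMonomerLoss = 3L, nMax = 25L,
                                smoothWindow = 9L, mzRange = NULL) {
  stopifnot(is(quadDataset, "IMMSDataset"), M > 0)
  qw <- quadDataset@quadWindow
  if (length(qw) != 2L)
    stop("quadDataset must carry a quadrupole selection window")
  if (is.null(family) || nrow(family) == 0L)
    stop("family must contain at least one candidate member")
  if (is.null(tolMobility))
    tolMobility <- if (quadDataset@mobilityAxis == "inverse_reduced_mobility")
      0.01 else 0.2
  stopifnot(tolMobility >= 0)
  if (is.null(binWidth)) binWidth <- .defaultBinWidth(quadDataset@mobilityAxis)
  comp <- NULL
  if (!is.null(peptide))
    comp <- if (is(peptide, "ElementalComposition")) peptide
            else peptideComposition(peptide)

  members <- family[family$n >= 2L, c("n", "z"), drop = FALSE]
  members <- members[order(members$n), , drop = FALSE]
  if (is.null(mzRange)) {
    f <- quadDataset@features
    mzRange <- if (nrow(f)) range(f$mz) + c(-10, 10) else c(50, 3000)
  }

  ## --- predicted channels per member, excluding in-window channels ----
  chKey <- function(mz) sprintf("%.4f", mz)
  chanInfo <- new.env(parent = emptyenv())
  memberChannels <- vector("list", nrow(members))
  for (i in seq_len(nrow(members))) {
    ch <- fragmentChannels(members$n[i], members$z[i], M, mzRange = mzRange)
    ch <- ch[abs(ch$mz - qw[1]) > qw[2], , drop = FALSE]
    keys <- character(0)
    for (j in seq_len(nrow(ch))) {
      k <- chKey(ch$mz[j])
      keys <- c(keys, k)
      prev <- chanInfo[[k]]
      if (is.null(prev) || ch$n[j] < prev$n)
        chanInfo[[k]] <- list(n = ch$n[j], z = ch$z[j], mz = ch$mz[j],
                              zAll = unique(c(if (!is.null(prev)) prev$zAll,
                                              ch$z[j])))
      else
        chanInfo[[k]]$zAll <- unique(c(prev$zAll, ch$z[j]))
    }
    memberChannels[[i]] <- unique(keys)
  }
  channelKeys <- ls(chanInfo)

  ## --- reference intensity scale: the precursor channel EIM ----------
  precEIM <- suppressWarnings(extractEIM(quadDataset, center = qw[1],
                                         halfwidth = qw[2],
                                         binWidth = binWidth))
  refMax <- max(precEIM@intensity, 0)
  floorAbs <- minChannelFraction * refMax

  ## --- per-channel EIM extraction and peak picking --------------------
  apexes <- list()
  for (k in channelKeys) {
    info <- chanInfo[[k]]
    if (!is.null(comp)) {
      ## union of the envelopes of all (n, z) ions sharing this m/z
      zBig <- max(info$zAll)
      nBig <- info$n * zBig / info$z
      env <- isotopeEnvelope(comp, n = nBig, z = zBig, minAbundance = 1e-3)
      eim <- suppressWarnings(extractEIM(quadDataset, envelope = env,
                                         binWidth = binWidth))
    } else {
      eim <- suppressWarnings(extractEIM(quadDataset, center = info$mz,
                                         halfwidth = .channelWindow(info$mz, info$z),
                                         binWidth = binWidth))
    }
    pk <- detectPeaks(.maybeSmooth(eim, smoothWindow),
                      minHeightFraction = minHeightFraction,
                      minSeparation = tolMobility, minHeight = floorAbs,
                      minProminence = 0.3)
    if (nrow(pk))
      apexes[[k]] <- data.frame(channel = k, channel_n = info$n,
                                channel_z = info$z, channel_mz = info$mz,
                                apex = pk$apex, height = pk$height)
  }
  apexes <- if (length(apexes))
    do.call(rbind, c(apexes, list(make.row.names = FALSE))) else NULL

  emptyResidual <- data.frame(mobility = numeric(), nChannels = integer(),
                              classification = character(),
                              source_n = integer(), source_z = integer())
  params <- list(tolMobility = tolMobility, minChannels = minChannels,
                 minHeightFraction = minHeightFraction,
                 minChannelFraction = minChannelFraction,
                 maxMonomerLoss = maxMonomerLoss, binWidth = binWidth,
                 smoothWindow = smoothWindow)
  if (is.null(apexes) || nrow(apexes) == 0L) {
    return(new("AssignmentSet",
               assignments = data.frame(n = integer(), z = integer(),
                                        mobility = numeric(),
                                        nSupporting = integer()),
               evidence = list(), residualPeaks = emptyResidual,
               family = members, warnings = character(), parameters = params))
  }

  ## --- single-linkage clustering of apexes -----------------------------
  apexes <- apexes[order(apexes$apex), , drop = FALSE]
  grp <- cumsum(c(TRUE, diff(apexes$apex) > tolMobility))
  clusters <- lapply(split(seq_len(nrow(apexes)), grp), function(i) {
    sub <- apexes[i, , drop = FALSE]
    list(rows = sub,
         center = sum(sub$apex * sub$height) / sum(sub$height),
         support = unique(sub$channel))
  })

  ## --- candidate members per cluster -----------------------------------
  ## a cluster is attributable to any member whose predicted channel set
  ## covers all supporting channels; the smallest such member is kept as
  ## the residual-classification explainer
  K <- nrow(members)
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    covering <- which(vapply(seq_len(K), function(i)
      all(cl$support %in% memberChannels[[i]]), logical(1)))
    cl$explainer <- if (length(covering)) covering[1] else NA_integer_
    ## only clusters with enough distinct channels are assignable
    cl$cov <- if (length(cl$support) >= minChannels) covering else integer()
    cl$interfaceSource <- NULL
    clusters[[ci]] <- cl
  }

  ## --- interface-artifact exclusion ------------------------------------
  ## with an intact reference, a cluster whose mobility coincides with
  ## the intact position of an interface-source precursor (a larger
  ## same-charge ion that reaches a member's channel by neutral monomer
  ## loss after the IM cell) is an interface artifact: it is classified
  ## now and withheld from the assignment matching
  refApexMemo <- new.env(parent = emptyenv())
  lookupSourceApex <- function(n, z) {
    key <- paste(n, z)
    if (is.null(refApexMemo[[key]]))
      refApexMemo[[key]] <- .referenceApex(intactReference,
                                           oligomerMz(M, n, z), z,
                                           binWidth, smoothWindow = smoothWindow)
    refApexMemo[[key]]
  }
  if (!is.null(intactReference)) {
    for (ci in seq_along(clusters)) {
      cl <- clusters[[ci]]
      if (!length(cl$cov)) next
      for (i in cl$cov) {
        src <- interfaceFragmentSources(members$n[i], members$z[i],
                                        nMax = nMax,
                                        maxMonomerLoss = maxMonomerLoss)
        for (si in seq_len(nrow(src))) {
          apx <- lookupSourceApex(src$n[si], src$z[si])
          if (!is.na(apx) && abs(apx - cl$center) <= tolMobility) {
            cl$interfaceSource <- c(src$n[si], src$z[si])
            break
          }
        }
        if (!is.null(cl$interfaceSource)) break
      }
      if (!is.null(cl$interfaceSource)) cl$cov <- integer()
      clusters[[ci]] <- cl
    }
  }

  ## --- ordered maximum matching ----------------------------------------
  ## Within one isobaric family, mobility decreases strictly with n, so
  ## the joint assignment is the maximum matching of clusters (by
  ## decreasing mobility) to candidate members (by increasing n) that
  ## preserves both orders. Ties are broken toward lower-mobility
  ## clusters: interface-fragmentation artifacts of larger same-charge
  ## precursors always sit above the true precursor mobility, so the
  ## lowest consistent cluster is the intact position.
  ord <- order(vapply(clusters, `[[`, numeric(1), "center"),
               decreasing = TRUE)
  C <- length(ord)
  covDesc <- lapply(clusters[ord], `[[`, "cov")
  fmat <- matrix(0L, C + 1L, K + 1L)
  if (C && K) {
    for (ci in C:1) {
      for (m in K:1) {
        best <- max(fmat[ci + 1L, m], fmat[ci, m + 1L])
        if (m %in% covDesc[[ci]])
          best <- max(best, 1L + fmat[ci + 1L, m + 1L])
        fmat[ci, m] <- best
      }
    }
  }
  assignedCluster <- rep(NA_integer_, length(clusters))
  ci <- 1L
  m <- 1L
  while (ci <= C && m <= K) {
    if (fmat[ci, m] == fmat[ci + 1L, m]) {
      ci <- ci + 1L                       # prefer a lower-mobility cluster
    } else if (m %in% covDesc[[ci]] &&
               fmat[ci, m] == 1L + fmat[ci + 1L, m + 1L]) {
      assignedCluster[ord[ci]] <- m
      ci <- ci + 1L
      m <- m + 1L
    } else {
      m <- m + 1L
    }
  }

  rows <- list()
  evidence <- list()
  for (i in seq_len(K)) {
    pick <- which(assignedCluster == i)
    if (!length(pick)) next
    cl <- clusters[[pick]]
    rows[[length(rows) + 1L]] <-
      data.frame(n = members$n[i], z = members$z[i], mobility = cl$center,
                 nSupporting = length(cl$support))
    ev <- cl$rows[, c("channel_n", "channel_z", "channel_mz", "apex", "height")]
    rownames(ev) <- NULL
    evidence[[length(evidence) + 1L]] <- ev
  }
  assignments <- if (length(rows))
    do.call(rbind, rows) else data.frame(n = integer(), z = integer(),
                                         mobility = numeric(),
                                         nSupporting = integer())
  rownames(assignments) <- NULL

  ## --- classify residual clusters --------------------------------------
  intactApexes <- NULL
  if (!is.null(intactReference)) {
    famEIM <- suppressWarnings(extractEIM(intactReference, center = qw[1],
                                          halfwidth = qw[2],
                                          binWidth = binWidth))
    pkF <- detectPeaks(.maybeSmooth(famEIM, smoothWindow),
                       minHeightFraction = 0.02)
    intactApexes <- pkF$apex
  }
  residual <- list()
  for (ci in which(is.na(assignedCluster))) {
    cl <- clusters[[ci]]
    clas <- "unexplained"
    srcN <- NA_integer_
    srcZ <- NA_integer_
    if (is.null(cl$interfaceSource) && !is.null(intactReference) &&
        !is.na(cl$explainer)) {
      ## singleton clusters skip the pre-matching exclusion; test their
      ## explainer's interface-source chain here
      P <- members[cl$explainer, ]
      src <- interfaceFragmentSources(P$n, P$z, nMax = nMax,
                                      maxMonomerLoss = maxMonomerLoss)
      for (si in seq_len(nrow(src))) {
        apx <- lookupSourceApex(src$n[si], src$z[si])
        if (!is.na(apx) && abs(apx - cl$center) <= tolMobility) {
          cl$interfaceSource <- c(src$n[si], src$z[si])
          break
        }
      }
    }
    if (!is.null(cl$interfaceSource)) {
      clas <- "interface_fragment"
      srcN <- cl$interfaceSource[1]
      srcZ <- cl$interfaceSource[2]
    } else if (!is.null(intactApexes) && length(intactApexes) &&
               any(abs(intactApexes - cl$center) <= tolMobility)) {
      clas <- "intact"
    } else if (!is.na(cl$explainer)) {
      P <- members[cl$explainer, ]
      assignedMob <- assignments$mobility[assignments$n == P$n]
      if (length(assignedMob) && cl$center > assignedMob[1])
        clas <- "interface_candidate"
    }
    residual[[length(residual) + 1L]] <-
      data.frame(mobility = cl$center, nChannels = length(cl$support),
                 classification = clas, source_n = srcN, source_z = srcZ)
  }
  residualPeaks <- if (length(residual)) do.call(rbind, residual) else emptyResidual
  rownames(residualPeaks) <- NULL

  ## --- family monotonicity validation ----------------------------------
  ## the matching makes the reported assignments monotone by
  ## construction; a well-supported cluster that could not be placed
  ## (and is not an interface or intact artifact) means the observed
  ## coincidences are not strictly decreasing in n within the family
  warns <- character()
  dropped <- nrow(residualPeaks) &&
    any(residualPeaks$classification == "unexplained" &
        residualPeaks$nChannels >= minChannels)
  if (dropped) {
    warns <- paste("coincidence clusters are inconsistent with mobilities",
                   "that are not strictly decreasing in n within the",
                   "family; a mobility inversion or unmodelled",
                   "fragmentation artifact is likely")
    warning(warns)
  }

  new("AssignmentSet", assignments = assignments, evidence = evidence,
      residualPeaks = residualPeaks, family = members, warnings = warns,
      parameters = params)
}

#' @rdname AssignmentSet-class
#' @export
setMethod("assignmentTable", "AssignmentSet", function(object) object@assignments)

#' @rdname AssignmentSet-class
#' @export
setMethod("assignmentEvidence", "AssignmentSet", function(object) object@evidence)

#' @rdname AssignmentSet-class
#' @export
setMethod("residualPeaks", "AssignmentSet", function(object) object@residualPeaks)

#' @rdname AssignmentSet-class
#' @export
setMethod("assignmentWarnings", "AssignmentSet", function(object) object@warnings)

setMethod("show", "AssignmentSet", function(object) {
  a <- object@assignments
  cat(sprintf("AssignmentSet: %d assignment(s) over %d family member(s)\n",
              nrow(a), nrow(object@family)))
  if (nrow(a)) {
    for (i in seq_len(nrow(a)))
      cat(sprintf("  %d^%d+ at %.4g (%d supporting channels)\n",
                  a$n[i], a$z[i], a$mobility[i], a$nSupporting[i]))
  }
  r <- object@residualPeaks
  if (nrow(r))
    cat(sprintf("  %d residual peak cluster(s): %s\n", nrow(r),
                paste(sprintf("%.4g[%s]", r$mobility, r$classification),
                      collapse = ", ")))
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
})

#' Write an assignment report
#'
#' Serialises an [AssignmentSet-class] as TSV (assignments + residual
#' peaks) and JSON (full evidence).
#'
#' @param object An [AssignmentSet-class].
#' @param prefix Output path prefix; writes `<prefix>.tsv`,
#'   `<prefix>_residual.tsv` and `<prefix>.json`.
#' @return The JSON path, invisibly.
#' @export
writeAssignmentReport <- function(object, prefix) {
  stopifnot(is(object, "AssignmentSet"))
  utils::write.table(object@assignments, paste0(prefix, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(object@residualPeaks, paste0(prefix, "_residual.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  payload <- list(assignments = object@assignments,
                  evidence = object@evidence,
                  residual_peaks = object@residualPeaks,
                  parameters = object@parameters,
                  warnings = object@warnings)
  path <- paste0(prefix, ".json")
  jsonlite::write_json(payload, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
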