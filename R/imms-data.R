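#' Construct an IM-MS feature dataset
#'
#' @param features data.frame with numeric columns `mz`, `mobility`,
#'   `intensity`.
#' @param platform `"TIMS"` or `"TWIMS"`.
#' @param mobilityAxis `"inverse_reduced_mobility"` (V s/cm^2, TIMS) or
#'   `"drift_time"` (ms, TWIMS); defaults to the platform's native axis.
#' @param quadWindow Optional c(center, halfwidth) quadrupole selection
#'   window (Th).
#' @param metadata Free-form key/value list.
#' @return An [IMMSDataset-class] object.
#' @export
IMMSDataset <- function(features, platform = c("TIMS", "TWIMS"),
                        mobilityAxis = NULL, quadWindow = numeric(),
                        metadata = list()) {
  platform <- match.arg(platform)
  if (is.null(mobilityAxis))
    mobilityAxis <- if (platform == "TIMS") "inverse_reduced_mobility" else "drift_time"
  features <- as.data.frame(features)
  new("IMMSDataset", features = features, platform = platform,
      mobilityAxis = mobilityAxis, quadWindow = as.numeric(quadWindow),
      metadata = metadata)
}

#' @rdname IMMSDataset-class
#' @export
setMethod("featureTable", "IMMSDataset", function(object) object@features)

#' @rdname IMMSDataset-class
#' @export
setMethod("imsPlatform", "IMMSDataset", function(object) object@platform)

#' @rdname IMMSDataset-class
#' @export
setMethod("mobilityAxis", "IMMSDataset", function(object) object@mobilityAxis)

#' @rdname IMMSDataset-class
#' @export
setMethod("quadWindow", "IMMSDataset", function(object) object@quadWindow)

setMethod("show", "IMMSDataset", function(object) {
  f <- object@features
  cat(sprintf("IMMSDataset: %d features (%s, %s axis)\n",
              nrow(f), object@platform, object@mobilityAxis))
  if (nrow(f)) {
    cat(sprintf("  m/z %.2f .. %.2f, mobility %.4g .. %.4g\n",
                min(f$mz), max(f$mz), min(f$mobility), max(f$mobility)))
  }
  if (length(object@quadWindow))
    cat(sprintf("  quadrupole selection: %.2f +/- %.2f Th\n",
                object@quadWindow[1], object@quadWindow[2]))
})

## Default mobility histogram bin widths per axis: finer than the
## narrowest peak separation the assignment must resolve.
.defaultBinWidth <- function(mobilityAxis) {
  if (mobilityAxis == "inverse_reduced_mobility") 0.001 else 0.05
}

#' Read / write the feature-table interchange format
#'
#' The interchange format is a TSV with a `#key=value` metadata preamble
#' and columns `mz`, `mobility`, `intensity`. Recognised metadata keys:
#' `platform`, `mobility_axis`, `quad_center`, `quad_halfwidth`; unknown
#' keys are preserved in `metadata`. Round trips are bit-exact.
#'
#' @param path File path.
#' @return `readFeatureTable()`: an [IMMSDataset-class].
#' @export
readFeatureTable <- function(path) {
  lines <- readLines(path)
  isMeta <- grepl("^#", lines)
  headerAt <- which(!isMeta)[1]
  if (is.na(headerAt)) stop("no header line found in ", path)
  meta <- list()
  for (i in which(isMeta & seq_along(lines) < headerAt)) {
    kv <- sub("^#", "", lines[i])
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) stop(sprintf("line %d: metadata line without '=': %s", i, lines[i]))
    meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  tab <- utils::read.delim(text = lines[headerAt:length(lines)],
                           check.names = FALSE)
  for (col in c("mz", "mobility", "intensity")) {
    if (!col %in% names(tab))
      stop(sprintf("missing required column '%s' (header at line %d)", col, headerAt))
    if (!is.numeric(tab[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tab[[col]]))))[1]
      stop(sprintf("non-numeric value in column '%s' at line %d",
                   col, headerAt + bad))
    }
  }
  platform <- meta$platform %||% "TIMS"
  if (!platform %in% c("TIMS", "TWIMS"))
    stop("unknown platform metadata value: ", platform)
  axis <- meta$mobility_axis %||%
    (if (platform == "TIMS") "inverse_reduced_mobility" else "drift_time")
  if (!axis %in% c("inverse_reduced_mobility", "drift_time"))
    stop("unknown mobility_axis metadata value: ", axis)
  qw <- numeric()
  if (!is.null(meta$quad_center) && !is.null(meta$quad_halfwidth))
    qw <- c(as.numeric(meta$quad_center), as.numeric(meta$quad_halfwidth))
  extra <- meta[setdiff(names(meta),
                        c("platform", "mobility_axis", "quad_center",
                          "quad_halfwidth"))]
  IMMSDataset(tab[, c("mz", "mobility", "intensity")], platform = platform,
              mobilityAxis = axis, quadWindow = qw, metadata = extra)
}

#' @rdname readFeatureTable
#' @param dataset An [IMMSDataset-class].
#' @return `writeFeatureTable()`: `path`, invisibly.
#' @export
writeFeatureTable <- function(dataset, path) {
  stopifnot(is(dataset, "IMMSDataset"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#platform=%s", dataset@platform), con)
  writeLines(sprintf("#mobility_axis=%s", dataset@mobilityAxis), con)
  if (length(dataset@quadWindow)) {
    writeLines(sprintf("#quad_center=%.10g", dataset@quadWindow[1]), con)
    writeLines(sprintf("#quad_halfwidth=%.10g", dataset@quadWindow[2]), con)
  }
  for (k in names(dataset@metadata))
    writeLines(sprintf("#%s=%s", k, dataset@metadata[[k]]), con)
  f <- dataset@features
  writeLines("mz\tmobility\tintensity", con)
  if (nrow(f))
    writeLines(sprintf("%.17g\t%.17g\t%.17g", f$mz, f$mobility, f$intensity), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract an ion mobility spectrum (EIM)
#'
#' Histograms, on a regular mobility grid, the intensities of all
#' features whose m/z falls inside the selection. The selection is
#' either a window (`center` +/- `halfwidth`) or the full isotopic
#' distribution of a species (an [IsotopeEnvelope-class]): in envelope
#' mode a feature is selected when it lies within `envelopeTol` of any
#' envelope peak, which keeps adjacent isobaric envelopes at high charge
#' from cross-contaminating the spectrum.
#'
#' @param dataset An [IMMSDataset-class].
#' @param center,halfwidth Window-mode selection (Th). `halfwidth` may
#'   be length 2 (lower, upper) for an asymmetric window.
#' @param envelope Envelope-mode selection; overrides center/halfwidth.
#' @param binWidth Mobility grid step; defaults to 0.001 V s/cm^2 (TIMS)
#'   or 0.05 ms (TWIMS).
#' @param envelopeTol Per-peak m/z half-window in envelope mode (Th).
#' @return A [MobilitySpectrum-class]. An empty selection yields an
#'   all-zero spectrum with `provenance$empty = TRUE` and a warning.
#' @export
extractEIM <- function(dataset, center = NULL, halfwidth = NULL,
                       envelope = NULL, binWidth = NULL, envelopeTol = 0.05) {
  stopifnot(is(dataset, "IMMSDataset"))
  f <- dataset@features
  if (is.null(binWidth)) binWidth <- .defaultBinWidth(dataset@mobilityAxis)
  if (!is.null(envelope)) {
    stopifnot(is(envelope, "IsotopeEnvelope"))
    sel <- rowSums(abs(outer(f$mz, envelope@mz, `-`)) <= envelopeTol) > 0
    prov <- list(mode = "envelope", mz = range(envelope@mz),
                 charge = envelope@charge, tol = envelopeTol)
  } else {
    stopifnot(!is.null(center), !is.null(halfwidth))
    if (length(halfwidth) == 1L) halfwidth <- c(halfwidth, halfwidth)
    sel <- f$mz >= center - halfwidth[1] & f$mz <= center + halfwidth[2]
    prov <- list(mode = "window", center = center, halfwidth = halfwidth)
  }
  mobRange <- if (nrow(f)) range(f$mobility) else c(0, 1)
  ## bin centers on multiples of binWidth (features are assigned to the
  ## nearest center, avoiding edge ambiguity for on-grid data)
  c0 <- floor(mobRange[1] / binWidth) * binWidth
  centers <- seq(c0, ceiling(mobRange[2] / binWidth) * binWidth,
                 by = binWidth)
  if (length(centers) < 2L) centers <- c(centers, centers + binWidth)
  if (!any(sel)) {
    warning("selection matched no features; returning empty spectrum")
    prov$empty <- TRUE
    return(new("MobilitySpectrum", axis = centers,
               intensity = numeric(length(centers)), provenance = prov))
  }
  idx <- as.integer(round((f$mobility[sel] - c0) / binWidth)) + 1L
  idx[idx < 1L] <- 1L
  idx[idx > length(centers)] <- length(centers)
  intensity <- numeric(length(centers))
  agg <- tapply(f$intensity[sel], idx, sum)
  intensity[as.integer(names(agg))] <- as.numeric(agg)
  prov$empty <- FALSE
  new("MobilitySpectrum", axis = centers, intensity = intensity,
      provenance = prov)
}

#' @rdname MobilitySpectrum-class
#' @export
setMethod("spectrumAxis", "MobilitySpectrum", function(object) object@axis)

#' @rdname MobilitySpectrum-class
#' @export
setMethod("spectrumIntensity", "MobilitySpectrum", function(object) object@intensity)

setMethod("show", "MobilitySpectrum", function(object) {
  cat(sprintf("MobilitySpectrum: %d bins", length(object@axis)))
  if (length(object@axis))
    cat(sprintf(", axis %.4g .. %.4g", min(object@axis), max(object@axis)))
  cat(sprintf(", max intensity %.4g\n", max(0, object@intensity)))
})

#' Extract the mass spectrum inside a mobility window
#'
#' The mobility-gated mass spectrum: intensities of features whose
#' mobility lies inside `window`, aggregated per m/z and sorted. The
#' returned table is suitable for isotope-spacing reading with
#' [inferNZ()]. A `multiComponent` attribute flags windows whose peak
#' spacings indicate a superposition of envelopes at different charge
#' states.
#'
#' @param dataset An [IMMSDataset-class].
#' @param window Length-2 numeric mobility window (axis units).
#' @param minHeightFraction Peaks below this fraction of the base peak
#'   are ignored for the multi-component spacing check.
#' @return data.frame with columns `mz`, `intensity`; attribute
#'   `multiComponent` (logical).
#' @export
extractMsAtMobility <- function(dataset, window, minHeightFraction = 0.1) {
  stopifnot(is(dataset, "IMMSDataset"), length(window) == 2L)
  window <- sort(window)
  f <- dataset@features
  sel <- f$mobility >= window[1] & f$mobility <= window[2]
  f <- f[sel, , drop = FALSE]
  if (nrow(f) == 0L) {
    out <- data.frame(mz = numeric(), intensity = numeric())
    attr(out, "multiComponent") <- FALSE
    return(out)
  }
  agg <- tapply(f$intensity, f$mz, sum)
  out <- data.frame(mz = as.numeric(names(agg)), intensity = as.numeric(agg))
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL

  ## multi-component check: distinct implied charges among big peaks
  big <- out[out$intensity >= minHeightFraction * max(out$intensity), , drop = FALSE]
  multi <- FALSE
  if (nrow(big) > 2L) {
    d <- diff(big$mz)
    d <- d[d < 1.2 & d > 0.05]              # plausible isotopologue gaps
    if (length(d) > 1L) {
      zImplied <- round(ISOTOPE_SPACING / d)
      multi <- length(unique(zImplied[zImplied >= 1 & zImplied <= 12])) > 1L
    }
  }
  attr(out, "multiComponent") <- multi
  out
}

#' Savitzky-Golay smoothing of a mobility spectrum
#'
#' Applies a Savitzky-Golay filter (local least-squares polynomial
#' smoothing) to the spectrum intensities. Polynomials up to the filter
#' order are reproduced exactly.
#'
#' @param spectrum A [MobilitySpectrum-class].
#' @param windowLength Odd filter length, greater than `polyorder`.
#' @param polyorder Polynomial order.
#' @return A smoothed [MobilitySpectrum-class] (same axis; negative
#'   filter ringing is clipped at zero).
#' @export
smoothSpectrum <- function(spectrum, windowLength = 11L, polyorder = 3L) {
  stopifnot(is(spectrum, "MobilitySpectrum"))
  if (windowLength %% 2 == 0) stop("windowLength must be odd")
  if (windowLength <= polyorder) stop("windowLength must exceed polyorder")
  if (windowLength > length(spectrum@axis))
    stop("windowLength exceeds spectrum length")
  y <- signal::sgolayfilt(spectrum@intensity, p = polyorder, n = windowLength)
  y[y < 0] <- 0
  new("MobilitySpectrum", axis = spectrum@axis, intensity = y,
      provenance = c(spectrum@provenance,
                     list(smoothed = c(windowLength, polyorder))))
}

#' Detect mobility peaks
#'
#' Finds local maxima above `minHeightFraction` of the base peak (and
#' above an optional absolute floor), suppresses maxima closer than
#' `minSeparation` to a taller one, and refines each apex by a 3-point
#' parabolic interpolation. FWHM is measured by linear interpolation of
#' the half-height crossings.
#'
#' @param spectrum A [MobilitySpectrum-class].
#' @param minHeightFraction Minimum height relative to the spectrum
#'   maximum.
#' @param minSeparation Minimum apex separation (axis units).
#' @param minHeight Absolute intensity floor (default 0).
#' @param minProminence Minimum topographic prominence as a fraction of
#'   the peak height: a candidate must rise by at least this fraction
#'   above the deepest valley separating it from the nearest taller
#'   retained peak. Suppresses noise bumps on the flanks of larger
#'   peaks (default 0: keep all local maxima).
#' @return data.frame with columns `apex`, `height`, `fwhm`, ordered by
#'   decreasing height. All-zero spectra yield an empty table.
#' @export
detectPeaks <- function(spectrum, minHeightFraction = 0.05,
                        minSeparation = 0, minHeight = 0,
                        minProminence = 0) {
  stopifnot(is(spectrum, "MobilitySpectrum"))
  x <- spectrum@axis
  y <- spectrum@intensity
  empty <- data.frame(apex = numeric(), height = numeric(), fwhm = numeric())
  if (length(y) < 3L || max(y) <= 0) return(empty)
  thr <- max(minHeightFraction * max(y), minHeight)
  n <- length(y)
  isMax <- y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]
  cand <- which(isMax) + 1L
  cand <- cand[y[cand] > thr]
  if (!length(cand)) return(empty)
  cand <- cand[order(y[cand], decreasing = TRUE)]
  kept <- integer()
  for (i in cand) {
    if (length(kept) && any(abs(x[i] - x[kept]) < minSeparation)) next
    if (minProminence > 0 && length(kept)) {
      ## valley to the nearest taller retained peak on each side
      left <- kept[kept < i]
      right <- kept[kept > i]
      valley <- -Inf
      if (length(left))
        valley <- max(valley, min(y[max(left):i]))
      if (length(right))
        valley <- max(valley, min(y[i:min(right)]))
      if (is.finite(valley) && (y[i] - valley) < minProminence * y[i]) next
    }
    kept <- c(kept, i)
  }
  bin <- if (length(x) > 1L) x[2] - x[1] else 1
  res <- lapply(kept, function(i) {
    apex <- x[i]
    h <- y[i]
    if (i > 1L && i < n) {
      denom <- y[i - 1] - 2 * y[i] + y[i + 1]
      if (denom < 0) {
        dx <- 0.5 * (y[i - 1] - y[i + 1]) / denom
        dx <- max(-0.5, min(0.5, dx))
        apex <- x[i] + dx * bin
        h <- y[i] - 0.25 * (y[i - 1] - y[i + 1]) * dx
      }
    }
    half <- h / 2
    lo <- i
    while (lo > 1L && y[lo] > half) lo <- lo - 1L
    xl <- if (y[lo] <= half && lo < i)
      x[lo] + (half - y[lo]) / (y[lo + 1] - y[lo]) * bin else x[1]
    hi <- i
    while (hi < n && y[hi] > half) hi <- hi + 1L
    xr <- if (y[hi] <= half && hi > i)
      x[hi] - (half - y[hi]) / (y[hi - 1] - y[hi]) * bin else x[n]
    c(apex = apex, height = h, fwhm = xr - xl)
  })
  out <- as.data.frame(do.call(rbind, res))
  rownames(out) <- NULL
  out
}
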