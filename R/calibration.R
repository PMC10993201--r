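#' Fit a TIMS mobility calibration
#'
#' Matches observed calibrant positions to a reference table by m/z and
#' builds a piecewise-linear monotone map from the raw mobility axis to
#' calibrated inverse reduced mobility 1/K0. The map reproduces the
#' reference 1/K0 exactly at the anchors and interpolates linearly
#' between them (clamped outside the anchor range).
#'
#' @param observed data.frame with columns `raw` (raw axis position) and
#'   `mz` of the measured calibrant ions.
#' @param reference data.frame with columns `mz` and `invK0` (reference
#'   inverse reduced mobilities, V s/cm^2), e.g. the Agilent ESI Tuning
#'   Mix table.
#' @param mzTol Calibrant matching tolerance (Th).
#' @return A [TimsCalibration-class].
#' @export
fitTimsCalibration <- function(observed, reference, mzTol = 0.5) {
  stopifnot(all(c("raw", "mz") %in% names(observed)),
            all(c("mz", "invK0") %in% names(reference)))
  reference <- reference[order(reference$mz), , drop = FALSE]
  if (any(diff(reference$invK0) <= 0))
    stop("reference invK0 must increase strictly with m/z")
  m <- lapply(seq_len(nrow(observed)), function(i) {
    j <- which.min(abs(reference$mz - observed$mz[i]))
    if (abs(reference$mz[j] - observed$mz[i]) <= mzTol)
      data.frame(raw = observed$raw[i], mz = reference$mz[j],
                 invK0 = reference$invK0[j])
  })
  anchors <- do.call(rbind, m)
  if (is.null(anchors) || nrow(anchors) < 2L)
    stop("fewer than 2 calibrant points matched the reference table")
  anchors <- anchors[order(anchors$raw), , drop = FALSE]
  if (any(diff(anchors$invK0) <= 0))
    stop("matched calibrant sequence is not monotone in raw position")
  rownames(anchors) <- NULL
  new("TimsCalibration", anchors = anchors)
}

#' @rdname fitTimsCalibration
#' @param cal A [TimsCalibration-class].
#' @param raw Raw axis positions to calibrate.
#' @return `applyTimsCalibration()`: calibrated 1/K0 values.
#' @export
applyTimsCalibration <- function(cal, raw) {
  stopifnot(is(cal, "TimsCalibration"))
  stats::approx(cal@anchors$raw, cal@anchors$invK0, xout = raw,
                rule = 2)$y
}

setMethod("show", "TimsCalibration", function(object) {
  a <- object@anchors
  cat(sprintf("TimsCalibration: %d anchors, 1/K0 %.3f .. %.3f V s/cm^2\n",
              nrow(a), min(a$invK0), max(a$invK0)))
})

#' Convert inverse reduced mobility to collision cross section
#'
#' Mason-Schamp relation for reduced mobility: the CCS is proportional
#' to z * (1/K0) / sqrt(mu * T), with mu the ion-gas reduced mass. The
#' constant bundle uses the standard gas number density (the reduced
#' mobility convention) with T defaulting to 273.15 K; since vendor
#' conventions differ in T, the temperature is overridable -- relative
#' comparisons are unaffected by that choice.
#'
#' @param invK0 Inverse reduced mobility (V s/cm^2).
#' @param z Charge state.
#' @param ionMass Ion mass (Da).
#' @param gasMass Drift gas mass (Da), default N2.
#' @param temperature Gas temperature (K).
#' @return CCS in Angstrom^2.
#' @export
mobilityToCcs <- function(invK0, z, ionMass, gasMass = N2_MASS,
                          temperature = 273.15) {
  stopifnot(all(invK0 > 0), all(z > 0), all(ionMass > 0),
            gasMass > 0, temperature > 0)
  mu <- ionMass * gasMass / (ionMass + gasMass) * .ATOMIC_MASS_UNIT
  3 * z * .ELEMENTARY_CHARGE / (16 * .LOSCHMIDT) *
    sqrt(2 * pi / (mu * .BOLTZMANN * temperature)) *
    invK0 * 1e4 * 1e20
}

#' Fit a TWIMS CCS calibration
#'
#' Standard travelling-wave power-law calibration: drift times are
#' corrected for the mass-dependent ToF transit delay
#' (dt' = dt - edc * sqrt(mz) / 1000), reference CCS values are reduced
#' to CCS' = CCS * sqrt(mu) / z, and ln(CCS') is regressed linearly on
#' ln(dt').
#'
#' @param calibrants data.frame with columns `mz`, `z`, `ccs_ref`
#'   (reference drift-tube CCS in N2, Angstrom^2) and `dt` (measured
#'   drift time, ms).
#' @param edc Instrument EDC delay coefficient.
#' @param gasMass Drift gas mass (Da).
#' @return A [TwimsCalibration-class].
#' @export
fitTwimsCalibration <- function(calibrants, edc = 1.35, gasMass = N2_MASS) {
  need <- c("mz", "z", "ccs_ref", "dt")
  stopifnot(all(need %in% names(calibrants)))
  if (nrow(calibrants) < 3L) stop("at least 3 calibrants required")
  cal <- calibrants
  cal$dt_corr <- cal$dt - edc * sqrt(cal$mz) / 1000
  if (any(cal$dt_corr <= 0)) {
    bad <- which(cal$dt_corr <= 0)[1]
    stop(sprintf("calibrant %d (m/z %.1f) has non-positive corrected drift time",
                 bad, cal$mz[bad]))
  }
  ionMass <- cal$z * (cal$mz - PROTON_MASS)
  mu <- ionMass * gasMass / (ionMass + gasMass)
  cal$ccs_corr <- cal$ccs_ref * sqrt(mu) / cal$z
  fit <- stats::lm(log(ccs_corr) ~ log(dt_corr), data = cal)
  cal$fitted <- exp(stats::fitted(fit)) * cal$z / sqrt(mu)
  y <- log(cal$ccs_corr)
  r2 <- 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
  new("TwimsCalibration",
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      edc = edc, r2 = r2, calibrants = cal, gasMass = gasMass)
}

setMethod("show", "TwimsCalibration", function(object) {
  cat(sprintf("TwimsCalibration: ln(CCS') = %.4f ln(dt') + %.4f (R^2 = %.6f, %d calibrants)\n",
              object@slope, object@intercept, object@r2,
              nrow(object@calibrants)))
})

#' Convert a TWIMS drift time to CCS
#'
#' Inverse of the [fitTwimsCalibration()] construction:
#' CCS = exp(slope * ln(dt') + intercept) * z / sqrt(mu).
#'
#' @param dt Measured drift time (ms).
#' @param cal A [TwimsCalibration-class].
#' @param z Charge state.
#' @param ionMass Ion mass (Da).
#' @param mz Optional m/z for the EDC correction; defaults to
#'   (ionMass + z * m_H+) / z.
#' @return CCS in Angstrom^2.
#' @export
twimsCcs <- function(dt, cal, z, ionMass, mz = NULL) {
  stopifnot(is(cal, "TwimsCalibration"))
  if (is.null(mz)) mz <- (ionMass + z * PROTON_MASS) / z
  dtc <- dt - cal@edc * sqrt(mz) / 1000
  if (any(dtc <= 0)) stop("non-positive corrected drift time")
  mu <- ionMass * cal@gasMass / (ionMass + cal@gasMass)
  exp(cal@slope * log(dtc) + cal@intercept) * z / sqrt(mu)
}

#' Compare CCS values measured on two platforms
#'
#' Matches species on exact (n, z) pairs and reports per-species
#' relative differences 100 * |a - b| / mean(a, b), their mean and
#' maximum, a least-squares linear fit of b against a with R^2, and
#' which platform reads systematically larger.
#'
#' @param a,b data.frames with columns `n`, `z`, `ccs` (and optionally
#'   `platform` used for labelling).
#' @param labels Character(2) platform labels for the report.
#' @return A list of class `ccsComparison`: `table` (per-species),
#'   `meanRelDiff`, `maxRelDiff`, `r2`, `slope`, `intercept`,
#'   `nOverlap`, `larger` (label of the platform with larger CCS more
#'   often, or `"tie"`). With no overlapping species, `nOverlap = 0` and
#'   the statistics are `NA`.
#' @export
comparePlatforms <- function(a, b, labels = c("A", "B")) {
  need <- c("n", "z", "ccs")
  stopifnot(all(need %in% names(a)), all(need %in% names(b)))
  m <- merge(a[need], b[need], by = c("n", "z"), suffixes = c("_a", "_b"))
  if (nrow(m) == 0L) {
    out <- list(table = m, meanRelDiff = NA_real_, maxRelDiff = NA_real_,
                r2 = NA_real_, slope = NA_real_, intercept = NA_real_,
                nOverlap = 0L, larger = NA_character_, labels = labels)
    class(out) <- "ccsComparison"
    return(out)
  }
  m <- m[order(m$n, m$z), , drop = FALSE]
  m$relDiff <- 100 * abs(m$ccs_a - m$ccs_b) / ((m$ccs_a + m$ccs_b) / 2)
  if (nrow(m) >= 2L && stats::sd(m$ccs_a) > 0) {
    fit <- stats::lm(ccs_b ~ ccs_a, data = m)
    r2 <- 1 - sum(stats::resid(fit)^2) /
      sum((m$ccs_b - mean(m$ccs_b))^2)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
  } else {
    r2 <- slope <- intercept <- NA_real_
  }
  nB <- sum(m$ccs_b > m$ccs_a)
  nA <- sum(m$ccs_a > m$ccs_b)
  larger <- if (nA > nB) labels[1] else if (nB > nA) labels[2] else "tie"
  out <- list(table = m, meanRelDiff = mean(m$relDiff),
              maxRelDiff = max(m$relDiff), r2 = r2, slope = slope,
              intercept = intercept, nOverlap = nrow(m), larger = larger,
              labels = labels)
  class(out) <- "ccsComparison"
  out
}

#' @export
print.ccsComparison <- function(x, ...) {
  if (x$nOverlap == 0L) {
    cat("ccsComparison: no overlapping (n, z) species\n")
    return(invisible(x))
  }
  cat(sprintf("ccsComparison: %d overlapping species (%s vs %s)\n",
              x$nOverlap, x$labels[1], x$labels[2]))
  cat(sprintf("  mean relative difference: %.2f%%  (max %.2f%%)\n",
              x$meanRelDiff, x$maxRelDiff))
  if (!is.na(x$r2))
    cat(sprintf("  linear fit: slope %.4f, R^2 = %.6f\n", x$slope, x$r2))
  cat(sprintf("  larger CCS more often on: %s\n", x$larger))
  invisible(x)
}
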