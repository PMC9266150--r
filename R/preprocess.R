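#' @include spectra-ops.R
NULL

#' Standard normal variate transformation
#'
#' Centers and scales each spectrum to mean 0 and unit sample standard
#' deviation (divisor n-1), removing per-sample multiplicative scatter and
#' baseline offset. Metadata (diameters, SSC, groups) pass through.
#'
#' @param set a [SpectraSet-class]; every spectrum needs at least two
#'   distinct intensity values.
#' @return The transformed [SpectraSet-class].
#' @export
snv <- function(set) {
  stopifnot(is(set, "SpectraSet"))
  x <- intensities(set)
  m <- rowMeans(x)
  s <- apply(x, 1L, sd)
  bad <- which(s == 0 | !is.finite(s))
  if (length(bad))
    .stopf("constant spectrum (zero variance) for sample '%s'",
           sampleIds(set)[bad[1]])
  setIntensities(set, (x - m) / s)
}

#' Multiplicative scatter correction
#'
#' Regresses each spectrum on a reference spectrum by ordinary least squares
#' (`x ~ a + b * reference`) and returns `(x - a) / b`, so every corrected
#' spectrum has slope 1 and intercept 0 against the reference. By convention
#' the reference is the mean spectrum of the calibration set, and the same
#' reference is reused to transform prediction samples.
#'
#' @param set a [SpectraSet-class].
#' @param reference a [Spectrum-class] aligned to `set`'s grid, or `NULL` to
#'   use the mean spectrum of `set` itself.
#' @return The corrected [SpectraSet-class].
#' @export
msc <- function(set, reference = NULL) {
  stopifnot(is(set, "SpectraSet"))
  if (is.null(reference)) reference <- meanSpectrum(set)
  stopifnot(is(reference, "Spectrum"))
  .checkAligned(wavelengths(set), wavelengths(reference))
  r <- spectrumValues(reference)
  if (sd(r) == 0) .stopf("MSC reference spectrum is constant")
  x <- intensities(set)
  rc <- r - mean(r)
  b <- as.vector(x %*% rc) / sum(rc^2)     # OLS slope of x on r, per row
  bad <- which(abs(b) < 1e-12)
  if (length(bad))
    .stopf("degenerate MSC fit (|slope| < 1e-12) for sample '%s'",
           sampleIds(set)[bad[1]])
  a <- rowMeans(x) - b * mean(r)
  setIntensities(set, (x - a) / b)
}

#' Savitzky-Golay smoothing
#'
#' Convolves each spectrum with the Savitzky-Golay least-squares polynomial
#' kernel; exact on polynomials up to the chosen order, so band positions are
#' preserved while white noise is attenuated. Requires a uniform wavelength
#' grid. Edge points are handled by fitting the polynomial over the first and
#' last full window (no padding).
#'
#' @param set a [SpectraSet-class] on a uniform grid.
#' @param window odd window length in points (default 11).
#' @param polyorder polynomial order, `0 <= polyorder < window` (default 2).
#' @return The smoothed [SpectraSet-class].
#' @export
sgSmooth <- function(set, window = 11L, polyorder = 2L) {
  stopifnot(is(set, "SpectraSet"))
  window <- as.integer(window)
  polyorder <- as.integer(polyorder)
  if (window < 3L || window %% 2L == 0L)
    .stopf("Savitzky-Golay window must be an odd integer >= 3 (got %d)", window)
  if (window > nWavelengths(set))
    .stopf("Savitzky-Golay window (%d) exceeds the number of wavelengths (%d)",
           window, nWavelengths(set))
  if (polyorder < 0L || polyorder >= window)
    .stopf("polynomial order must satisfy 0 <= order < window")
  w <- wavelengths(set)
  if (length(w) > 2) {
    dw <- diff(w)
    if (max(dw) - min(dw) > 1e-8 * mean(dw))
      .stopf("Savitzky-Golay smoothing requires a uniform wavelength grid")
  }
  x <- intensities(set)
  out <- t(apply(x, 1L, signal::sgolayfilt, p = polyorder, n = window))
  setIntensities(set, out)
}

#' Apply a named pretreatment
#'
#' Dispatcher over the pretreatments compared in the pipeline: `"original"`
#' (identity), `"snv"`, `"msc"` and `"sg"` (Savitzky-Golay smoothing).
#'
#' @param set a [SpectraSet-class].
#' @param method one of `"original"`, `"snv"`, `"msc"`, `"sg"`.
#' @param reference optional MSC reference [Spectrum-class] (see [msc()]).
#' @param window,polyorder Savitzky-Golay parameters (see [sgSmooth()]).
#' @return The pretreated [SpectraSet-class].
#' @export
preprocessSpectra <- function(set,
                              method = c("original", "snv", "msc", "sg"),
                              reference = NULL, window = 11L, polyorder = 2L) {
  method <- match.arg(method)
  switch(method,
         original = set,
         snv = snv(set),
         msc = msc(set, reference),
         sg = sgSmooth(set, window, polyorder))
}

.checkAligned <- function(w1, w2, what = "wavelength grids") {
  if (length(w1) != length(w2) || any(abs(w1 - w2) > 1e-9))
    .stopf("%s are not aligned", what)
  invisible(TRUE)
}
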