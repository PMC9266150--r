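#' @include spectra-ops.R
NULL

#' Estimate the average extinction coefficient of a cohort
#'
#' Under Beer-Lambert attenuation, `I = I0 * exp(-u_e * d)`, the
#' log-intensity gap between a sample and a reference spectrum divided by
#' their diameter gap estimates the extinction coefficient at every
#' wavelength. This function averages the per-sample quotients
#' `(ln I_R - ln I_i) / (d_R - d_i)` over all samples whose diameter differs
#' from the reference by at least `minGap` mm, and returns
#' `u_e = -mean(quotients)` — positive when intensity decays with diameter.
#'
#' By default the reference is the mean spectrum and mean diameter of a named
#' size group (conventionally the medium group, whose calibration performs
#' best); both can be overridden explicitly.
#'
#' @param set a [SpectraSet-class] with strictly positive intensities.
#' @param reference a [Spectrum-class] aligned to `set`, or `NULL` to use the
#'   mean spectrum of `referenceGroup`.
#' @param referenceDiameter reference diameter d_R in mm, or `NULL` to use
#'   the mean diameter of `referenceGroup`.
#' @param minGap samples with `|d_R - d_i| < minGap` (mm) are excluded from
#'   the average (the quotient's denominator is near zero there); default 1.
#' @param referenceGroup group tag whose mean spectrum and mean diameter
#'   supply the reference when `reference`/`referenceDiameter` are `NULL`.
#' @param diameterMode `"per-sample"` uses each sample's own diameter as
#'   `d_i`; `"group-mean"` substitutes the mean diameter of the sample's
#'   group.
#' @param scalarExtinction if `TRUE`, collapse the per-wavelength extinction
#'   curve to its wavelength-average (a single scalar replicated across the
#'   grid).
#' @return A [CorrectionModel-class].
#' @seealso [applyCorrection()], [diameterAttenuationFit()]
#' @examples
#' s <- SpectraSet("a", 700, matrix(100), diameters = 70, ssc = 13)
#' ref <- Spectrum(700, 100 * exp(-0.5))
#' m <- estimateExtinction(s, ref, referenceDiameter = 80)
#' extinction(m)  # 0.05 per mm
#' @export
estimateExtinction <- function(set, reference = NULL, referenceDiameter = NULL,
                               minGap = 1.0, referenceGroup = NULL,
                               diameterMode = c("per-sample", "group-mean"),
                               scalarExtinction = FALSE) {
  stopifnot(is(set, "SpectraSet"))
  diameterMode <- match.arg(diameterMode)
  if (is.null(reference) || is.null(referenceDiameter)) {
    if (is.null(referenceGroup))
      .stopf("supply either a reference spectrum and diameter, or referenceGroup")
    refSet <- subsetGroup(set, referenceGroup)
    if (is.null(reference)) reference <- meanSpectrum(refSet)
    if (is.null(referenceDiameter)) referenceDiameter <- mean(diameters(refSet))
  }
  stopifnot(is(reference, "Spectrum"))
  .checkAligned(wavelengths(set), wavelengths(reference))
  refVals <- spectrumValues(reference)
  if (any(refVals <= 0)) .stopf("reference spectrum has non-positive values")
  .checkPositive(set)

  d <- diameters(set)
  if (diameterMode == "group-mean") {
    if (!length(groupLabels(set)))
      .stopf("diameterMode 'group-mean' needs group tags")
    d <- ave(d, groupLabels(set))
  }
  gap <- referenceDiameter - d
  use <- which(abs(gap) >= minGap)
  if (!length(use))
    .stopf("no sample has a diameter gap of at least %g mm to the reference",
           minGap)
  lnRef <- log(refVals)
  lnI <- log(intensities(set)[use, , drop = FALSE])
  # quotient rows: (ln I_R - ln I_i) / (d_R - d_i)
  q <- sweep(-lnI, 2L, lnRef, "+") / gap[use]
  ue <- -colMeans(q)
  if (scalarExtinction) ue <- rep(mean(ue), length(ue))
  new("CorrectionModel", referenceSpectrum = reference,
      referenceDiameter = as.numeric(referenceDiameter), extinction = ue,
      nUsed = length(use),
      excludedIds = sampleIds(set)[setdiff(seq_along(d), use)])
}

#' Transform spectra to the reference diameter
#'
#' Rescales every spectrum to what it would have been at the reference
#' diameter: `I* = I * exp(-u_e * (d_R - d_i))`, elementwise over
#' wavelengths. Samples at the reference diameter are returned unchanged;
#' with a positive extinction curve, smaller fruit are attenuated and larger
#' fruit amplified, shrinking the between-size-group spacing of the spectra.
#' Diameters and SSC pass through; outputs stay strictly positive.
#'
#' @param set a [SpectraSet-class] with strictly positive intensities, on
#'   the model's wavelength grid.
#' @param model a [CorrectionModel-class].
#' @return The corrected [SpectraSet-class].
#' @export
applyCorrection <- function(set, model) {
  stopifnot(is(set, "SpectraSet"), is(model, "CorrectionModel"))
  .checkAligned(wavelengths(set), wavelengths(model))
  .checkPositive(set)
  gap <- referenceDiameter(model) - diameters(set)
  # exp(-u_e (d_R - d_i) + ln I) computed as I * exp(-u_e * gap); the factor
  # is exactly 1 when gap or u_e is zero, so identity cases are bit-exact
  factor <- exp(-outer(gap, extinction(model)))
  setIntensities(set, intensities(set) * factor)
}

#' Log-intensity vs diameter regression at one wavelength
#'
#' Diagnostic for whether a cohort follows Beer-Lambert attenuation: fits
#' `ln(I) ~ d` by ordinary least squares at the grid point nearest the
#' requested wavelength. The slope estimates `-u_e`, the intercept
#' `ln(I_0)`, and r-squared measures how well the log-linear law holds.
#'
#' @param set a [SpectraSet-class] with at least 3 samples and positive
#'   intensities at the chosen wavelength.
#' @param wavelength requested wavelength, nm.
#' @return A list with `slope` (1/mm), `intercept`, `r_squared`, and
#'   `wavelength` (the grid point actually used).
#' @export
diameterAttenuationFit <- function(set, wavelength) {
  stopifnot(is(set, "SpectraSet"))
  if (nSamples(set) < 3)
    .stopf("attenuation fit needs at least 3 samples (got %d)", nSamples(set))
  j <- which.min(abs(wavelengths(set) - wavelength))
  y <- intensities(set)[, j]
  if (any(y <= 0))
    .stopf("non-positive intensity at %g nm", wavelengths(set)[j])
  d <- diameters(set)
  if (sd(d) == 0)
    .stopf("all samples share one diameter; the attenuation slope is undefined")
  ly <- log(y)
  fit <- lm(ly ~ d)
  r2 <- 1 - sum(fit$residuals^2) / sum((ly - mean(ly))^2)
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r_squared = r2, wavelength = wavelengths(set)[j])
}

#' Serialize / restore a correction model
#'
#' The model is written as a JSON sidecar (reference diameter, wavelength
#' grid, extinction curve, reference spectrum values, provenance counts) so
#' a model fitted on one cohort can correct another.
#'
#' @param model a [CorrectionModel-class].
#' @param path output path.
#' @return `path` invisibly (`writeCorrectionModel`); the restored
#'   [CorrectionModel-class] (`readCorrectionModel`).
#' @export
writeCorrectionModel <- function(model, path) {
  stopifnot(is(model, "CorrectionModel"))
  obj <- list(reference_diameter_mm = referenceDiameter(model),
              n_used = model@nUsed,
              excluded_ids = model@excludedIds,
              wavelengths_nm = wavelengths(model),
              extinction_per_mm = extinction(model),
              reference_spectrum = spectrumValues(referenceSpectrum(model)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCorrectionModel
#' @export
readCorrectionModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("CorrectionModel",
      referenceSpectrum = Spectrum(obj$wavelengths_nm, obj$reference_spectrum),
      referenceDiameter = obj$reference_diameter_mm,
      extinction = as.numeric(obj$extinction_per_mm),
      nUsed = as.integer(obj$n_used),
      excludedIds = as.character(obj$excluded_ids))
}

.checkPositive <- function(set) {
  x <- intensities(set)
  bad <- which(x <= 0, arr.ind = TRUE)
  if (nrow(bad))
    .stopf("non-positive intensity for sample '%s' at %g nm",
           sampleIds(set)[bad[1, 1]], wavelengths(set)[bad[1, 2]])
  invisible(TRUE)
}
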