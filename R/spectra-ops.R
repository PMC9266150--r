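#' @include AllClasses.R
NULL

#' Restrict a spectra set to a wavelength window
#'
#' Keeps exactly the grid wavelengths w with `lo <= w <= hi` (closed
#' interval); sample metadata pass through unchanged. Typical use is clipping
#' to the effective range where the detector signal carries information,
#' e.g. 350-850 nm for visible/NIR fruit transmission.
#'
#' @param set a [SpectraSet-class].
#' @param lo,hi window bounds in nm, `lo <= hi`.
#' @return The restricted [SpectraSet-class].
#' @examples
#' s <- SpectraSet("a", c(300, 400, 850, 900), matrix(1:4, 1), 80, 13)
#' wavelengths(restrictWavelengths(s, 350, 850))  # 400 850
#' @export
restrictWavelengths <- function(set, lo, hi) {
  stopifnot(is(set, "SpectraSet"))
  if (!is.numeric(lo) || !is.numeric(hi) || lo > hi)
    .stopf("invalid wavelength window: need lo <= hi")
  keep <- which(wavelengths(set) >= lo & wavelengths(set) <= hi)
  if (!length(keep))
    .stopf("no wavelength falls inside [%g, %g] nm", lo, hi)
  set[, keep]
}

#' Mean spectrum of a set
#'
#' Per-wavelength arithmetic mean over all samples; the reference spectrum
#' of a size group is the mean spectrum of that group.
#'
#' @param set a non-empty [SpectraSet-class].
#' @return A [Spectrum-class].
#' @export
meanSpectrum <- function(set) {
  stopifnot(is(set, "SpectraSet"))
  if (nSamples(set) < 1) .stopf("cannot take the mean spectrum of an empty set")
  Spectrum(wavelengths(set), colMeans(intensities(set)))
}

#' Subset a spectra set by group tag
#'
#' @param set a [SpectraSet-class] with group tags.
#' @param group a group label present in the set.
#' @return The [SpectraSet-class] of that group's samples.
#' @export
subsetGroup <- function(set, group) {
  stopifnot(is(set, "SpectraSet"))
  if (!length(groupLabels(set))) .stopf("spectra set carries no group tags")
  idx <- which(groupLabels(set) == group)
  if (!length(idx)) .stopf("no samples in group '%s'", group)
  set[idx, ]
}

#' Replace the intensity matrix of a set
#'
#' Internal-style helper used by the pretreatments and the size correction:
#' returns a copy of `set` with new intensities and untouched metadata.
#'
#' @param set a [SpectraSet-class].
#' @param intensities replacement matrix of identical shape.
#' @return A [SpectraSet-class].
#' @export
setIntensities <- function(set, intensities) {
  stopifnot(is(set, "SpectraSet"))
  SpectraSet(sampleIds(set), wavelengths(set), intensities,
             diameters(set), ssc(set), groupLabels(set))
}
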