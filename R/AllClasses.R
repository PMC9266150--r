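#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------- Spectrum --

#' A single spectrum on a wavelength grid
#'
#' Holds one vector of values aligned to a strictly increasing wavelength grid
#' (nm). Used for reference spectra (the mean spectrum of a fruit-size group)
#' and for ground-truth curves from the synthetic generator.
#'
#' @slot wavelengths strictly increasing numeric vector, nm.
#' @slot values numeric vector aligned to `wavelengths`.
#'
#' @exportClass Spectrum
setClass("Spectrum",
  representation(wavelengths = "numeric", values = "numeric"))

setValidity("Spectrum", function(object) {
  w <- object@wavelengths
  v <- object@values
  if (length(w) != length(v))
    return("wavelengths and values must have equal length")
  if (length(w) && any(!is.finite(w)))
    return("wavelengths must be finite")
  if (length(w) > 1 && any(diff(w) <= 0))
    return("wavelengths must be strictly increasing")
  if (length(v) && any(!is.finite(v)))
    return("values must be finite")
  TRUE
})

#' Construct a Spectrum
#'
#' @param wavelengths strictly increasing numeric vector, nm.
#' @param values numeric vector aligned to `wavelengths`.
#' @return A [Spectrum-class] object.
#' @examples
#' Spectrum(c(500, 600, 700), c(1, 2, 3))
#' @export
Spectrum <- function(wavelengths, values) {
  new("Spectrum", wavelengths = as.numeric(wavelengths),
      values = as.numeric(values))
}

#' @describeIn Spectrum-class wavelength grid (nm)
#' @param x a `Spectrum`
#' @export
setMethod("wavelengths", "Spectrum", function(x) x@wavelengths)

#' @describeIn Spectrum-class spectrum values
#' @export
setMethod("spectrumValues", "Spectrum", function(x) x@values)

setMethod("show", "Spectrum", function(object) {
  n <- length(object@wavelengths)
  cat(sprintf("Spectrum: %d points", n))
  if (n)
    cat(sprintf(", %g-%g nm", object@wavelengths[1], object@wavelengths[n]))
  cat("\n")
})

# -------------------------------------------------------------- SpectraSet --

#' A labelled collection of fruit transmission spectra
#'
#' The central container: an `n_samples x n_wavelengths` intensity matrix
#' (arbitrary detector counts) with per-sample metadata — fruit equatorial
#' diameter (mm), soluble solids content (degrees Brix) and an optional
#' size-group tag (e.g. `"65-75"`).
#'
#' @slot sampleIds character sample identifiers.
#' @slot wavelengths strictly increasing numeric grid, nm.
#' @slot intensities numeric matrix, samples in rows, wavelengths in columns.
#' @slot diameters positive numeric vector, mm.
#' @slot ssc numeric vector, degrees Brix.
#' @slot group character vector of group tags (may contain `NA`), or length 0
#'   when the cohort carries no grouping.
#'
#' @seealso [readSpectra()], [restrictWavelengths()], [meanSpectrum()]
#' @exportClass SpectraSet
setClass("SpectraSet",
  representation(sampleIds = "character", wavelengths = "numeric",
                 intensities = "matrix", diameters = "numeric",
                 ssc = "numeric", group = "character"))

setValidity("SpectraSet", function(object) {
  n <- length(object@sampleIds)
  p <- length(object@wavelengths)
  if (p > 1 && any(diff(object@wavelengths) <= 0))
    return("wavelengths must be strictly increasing with no duplicates")
  if (nrow(object@intensities) != n)
    return("intensities row count must equal the number of sample ids")
  if (ncol(object@intensities) != p)
    return("intensities column count must equal the number of wavelengths")
  if (length(object@diameters) != n)
    return("diameters length must equal the number of samples")
  if (length(object@ssc) != n)
    return("ssc length must equal the number of samples")
  if (n && any(!is.finite(object@diameters) | object@diameters <= 0))
    return("all diameters must be finite and > 0")
  if (n && any(!is.finite(object@intensities)))
    return("all intensities must be finite")
  if (length(object@group) && length(object@group) != n)
    return("group must be empty or have one tag per sample")
  TRUE
})

#' Construct a SpectraSet
#'
#' @param sampleIds character identifiers, one per sample.
#' @param wavelengths strictly increasing numeric grid, nm.
#' @param intensities numeric matrix (`length(sampleIds)` rows,
#'   `length(wavelengths)` columns).
#' @param diameters positive numeric vector, mm.
#' @param ssc numeric vector, degrees Brix.
#' @param group optional character vector of size-group tags.
#' @return A [SpectraSet-class] object.
#' @examples
#' s <- SpectraSet(c("a", "b"), c(500, 600, 700),
#'                 matrix(1:6, nrow = 2, byrow = TRUE),
#'                 diameters = c(70, 80), ssc = c(12, 13))
#' @export
SpectraSet <- function(sampleIds, wavelengths, intensities, diameters, ssc,
                       group = character(0)) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  dimnames(intensities) <- NULL
  new("SpectraSet", sampleIds = as.character(sampleIds),
      wavelengths = as.numeric(wavelengths), intensities = intensities,
      diameters = as.numeric(diameters), ssc = as.numeric(ssc),
      group = as.character(group))
}

#' @describeIn SpectraSet-class sample identifiers
#' @param x a `SpectraSet`
#' @export
setMethod("sampleIds", "SpectraSet", function(x) x@sampleIds)

#' @describeIn SpectraSet-class wavelength grid (nm)
#' @export
setMethod("wavelengths", "SpectraSet", function(x) x@wavelengths)

#' @describeIn SpectraSet-class intensity matrix (samples x wavelengths)
#' @export
setMethod("intensities", "SpectraSet", function(x) x@intensities)

#' @describeIn SpectraSet-class fruit diameters (mm)
#' @export
setMethod("diameters", "SpectraSet", function(x) x@diameters)

#' @describeIn SpectraSet-class soluble solids content (degrees Brix)
#' @export
setMethod("ssc", "SpectraSet", function(x) x@ssc)

#' @describeIn SpectraSet-class size-group tags (length 0 when untagged)
#' @export
setMethod("groupLabels", "SpectraSet", function(x) x@group)

#' @describeIn SpectraSet-class number of samples
#' @export
setMethod("nSamples", "SpectraSet", function(x) length(x@sampleIds))

#' @describeIn SpectraSet-class number of wavelengths
#' @export
setMethod("nWavelengths", "SpectraSet", function(x) length(x@wavelengths))

#' @describeIn SpectraSet-class subset samples (`i`) and/or wavelengths (`j`)
#' @param i sample index (integer, logical or sample-id character).
#' @param j wavelength index (integer or logical over grid positions).
#' @param ... ignored.
#' @param drop ignored; a `SpectraSet` is always returned.
#' @export
setMethod("[", "SpectraSet", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nSamples(x))
  if (is.character(i)) i <- match(i, x@sampleIds)
  if (anyNA(i)) .stopf("unknown sample id in subset")
  if (missing(j)) j <- seq_len(nWavelengths(x))
  grp <- if (length(x@group)) x@group[i] else character(0)
  SpectraSet(x@sampleIds[i], x@wavelengths[j],
             x@intensities[i, j, drop = FALSE],
             x@diameters[i], x@ssc[i], grp)
})

setMethod("show", "SpectraSet", function(object) {
  p <- nWavelengths(object)
  cat(sprintf("SpectraSet: %d samples x %d wavelengths",
              nSamples(object), p))
  if (p)
    cat(sprintf(" (%g-%g nm)", object@wavelengths[1], object@wavelengths[p]))
  cat("\n")
  if (length(object@group)) {
    tab <- table(object@group, useNA = "no")
    cat("  groups: ",
        paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
              collapse = ", "), "\n", sep = "")
  }
  if (nSamples(object)) {
    cat(sprintf("  diameter: %.1f-%.1f mm; SSC: %.1f-%.1f Brix\n",
                min(object@diameters), max(object@diameters),
                min(object@ssc), max(object@ssc)))
  }
})

# ---------------------------------------------------------- CorrectionModel --

#' A fitted fruit-size correction model
#'
#' Stores the reference spectrum and reference diameter together with the
#' average per-wavelength extinction coefficient (1/mm) estimated from the
#' log-intensity/diameter quotients of the contributing samples.
#'
#' @slot referenceSpectrum a [Spectrum-class], the reference intensity curve.
#' @slot referenceDiameter positive reference diameter, mm.
#' @slot extinction per-wavelength extinction coefficient, 1/mm, aligned to
#'   the reference spectrum's grid.
#' @slot nUsed number of samples that contributed to the average.
#' @slot excludedIds ids of samples skipped for a near-zero diameter gap.
#'
#' @seealso [estimateExtinction()], [applyCorrection()]
#' @exportClass CorrectionModel
setClass("CorrectionModel",
  representation(referenceSpectrum = "Spectrum", referenceDiameter = "numeric",
                 extinction = "numeric", nUsed = "integer",
                 excludedIds = "character"))

setValidity("CorrectionModel", function(object) {
  if (length(object@referenceDiameter) != 1 ||
      !is.finite(object@referenceDiameter) || object@referenceDiameter <= 0)
    return("referenceDiameter must be a single positive number")
  if (length(object@extinction) != length(object@referenceSpectrum@wavelengths))
    return("extinction must be aligned to the reference spectrum wavelengths")
  if (any(!is.finite(object@extinction)))
    return("extinction coefficients must be finite")
  if (length(object@nUsed) != 1 || object@nUsed < 1L)
    return("nUsed must be a single count >= 1")
  TRUE
})

#' @describeIn CorrectionModel-class per-wavelength extinction coefficient (1/mm)
#' @param x a `CorrectionModel`
#' @export
setMethod("extinction", "CorrectionModel", function(x) x@extinction)

#' @describeIn CorrectionModel-class reference diameter (mm)
#' @export
setMethod("referenceDiameter", "CorrectionModel", function(x) x@referenceDiameter)

#' @describeIn CorrectionModel-class reference spectrum
#' @export
setMethod("referenceSpectrum", "CorrectionModel", function(x) x@referenceSpectrum)

#' @describeIn CorrectionModel-class wavelength grid of the model
#' @export
setMethod("wavelengths", "CorrectionModel",
          function(x) x@referenceSpectrum@wavelengths)

setMethod("show", "CorrectionModel", function(object) {
  cat(sprintf("CorrectionModel: d_R = %.2f mm, %d wavelengths\n",
              object@referenceDiameter, length(object@extinction)))
  cat(sprintf("  extinction: %.4g-%.4g /mm (mean %.4g)\n",
              min(object@extinction), max(object@extinction),
              mean(object@extinction)))
  cat(sprintf("  estimated from %d samples (%d excluded for small gap)\n",
              object@nUsed, length(object@excludedIds)))
})

# ------------------------------------------------------------- SplitIndices --

#' Calibration/prediction partition of a cohort
#'
#' @slot calibration integer indices of the calibration samples.
#' @slot prediction integer indices of the remaining (prediction) samples.
#'
#' @seealso [kennardStone()]
#' @exportClass SplitIndices
setClass("SplitIndices",
  representation(calibration = "integer", prediction = "integer"))

setValidity("SplitIndices", function(object) {
  if (length(intersect(object@calibration, object@prediction)))
    return("calibration and prediction indices must be disjoint")
  if (anyDuplicated(object@calibration) || anyDuplicated(object@prediction))
    return("indices must be unique")
  TRUE
})

#' @describeIn SplitIndices-class calibration-sample indices
#' @param x a `SplitIndices`
#' @export
setMethod("calibrationIndices", "SplitIndices", function(x) x@calibration)

#' @describeIn SplitIndices-class prediction-sample indices
#' @export
setMethod("predictionIndices", "SplitIndices", function(x) x@prediction)

setMethod("show", "SplitIndices", function(object) {
  cat(sprintf("SplitIndices: %d calibration / %d prediction\n",
              length(object@calibration), length(object@prediction)))
})

# ----------------------------------------------------------------- PLSModel --

#' A fitted PLS1 regression model
#'
#' NIPALS partial least squares regression of a single response (SSC) on a
#' spectral matrix, with mean-centering of predictors and response. The
#' regression vector `b` acts on centered predictors; predictions are
#' `(X - xMean) %*% b + yMean`.
#'
#' @slot nLv number of latent variables retained.
#' @slot xMean,yMean centering parameters.
#' @slot weights p x nLv matrix of NIPALS weight vectors (unit norm).
#' @slot xLoadings p x nLv matrix of X-loadings.
#' @slot yLoadings length-nLv vector of response loadings.
#' @slot coefficients regression vector on centered X, one entry per
#'   wavelength.
#' @slot projection p x nLv matrix `W (P'W)^{-1}` mapping centered X to
#'   scores; used for truncated-component predictions.
#' @slot residuals training residuals.
#'
#' @seealso [fitPLS()], [selectLatentVariables()]
#' @exportClass PLSModel
setClass("PLSModel",
  representation(nLv = "integer", xMean = "numeric", yMean = "numeric",
                 weights = "matrix", xLoadings = "matrix",
                 yLoadings = "numeric", coefficients = "numeric",
                 projection = "matrix", residuals = "numeric"))

setValidity("PLSModel", function(object) {
  if (object@nLv < 1L) return("nLv must be >= 1")
  p <- length(object@xMean)
  if (length(object@coefficients) != p)
    return("coefficients must have one entry per predictor")
  if (ncol(object@weights) != object@nLv)
    return("weights must have nLv columns")
  TRUE
})

#' @describeIn PLSModel-class number of latent variables
#' @param x a `PLSModel`
#' @export
setMethod("nLatent", "PLSModel", function(x) x@nLv)

#' @describeIn PLSModel-class regression vector on centered predictors
#' @param object a `PLSModel`
#' @param ... ignored
#' @export
setMethod("coef", "PLSModel", function(object, ...) object@coefficients)

setMethod("show", "PLSModel", function(object) {
  cat(sprintf("PLSModel: %d latent variables, %d predictors\n",
              object@nLv, length(object@xMean)))
  cat(sprintf("  training RMSE (n-1): %.4g\n",
              sqrt(sum(object@residuals^2) /
                   max(1, length(object@residuals) - 1))))
})
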