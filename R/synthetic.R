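#' @include spectra-ops.R
NULL

.gauss <- function(wl, center, width) exp(-0.5 * ((wl - center) / width)^2)

# Halogen-lamp-like smooth source/detector envelope, detector counts
.defaultSourceIntensity <- function(wl) {
  1.2e6 * .gauss(wl, 720, 160) + 3e4
}

# Baseline tissue extinction (1/mm): transmission maxima (weak absorption)
# near 645/710/810 nm and absorption bands near 675 (chlorophyll),
# 758 (O-H) and 830 (N-H) nm
.defaultBaseExtinction <- function(wl) {
  0.085 +
    0.012 * .gauss(wl, 675, 8) +
    0.008 * .gauss(wl, 758, 10) +
    0.005 * .gauss(wl, 830, 8) -
    0.010 * .gauss(wl, 645, 9) -
    0.010 * .gauss(wl, 710, 11) -
    0.006 * .gauss(wl, 810, 10)
}

# SSC-dependent extinction, 1/(mm * Brix), concentrated at the sugar-related
# O-H / N-H bands
.defaultSscCoupling <- function(wl) {
  2.2e-4 * .gauss(wl, 758, 12) +
    1.5e-4 * .gauss(wl, 830, 10) +
    0.8e-4 * .gauss(wl, 675, 10)
}

.defaultGroups <- function() {
  data.frame(label = c("65-75", "75-85", "85-95"),
             lo = c(65, 75, 85), hi = c(75, 85, 95),
             sscMean = c(13.8, 13.2, 13.3),
             sscSd = c(1.62, 1.60, 1.73),
             sscMin = c(9.8, 8.3, 10.9),
             sscMax = c(17.2, 17.2, 15.3),
             stringsAsFactors = FALSE)
}

#' Configuration for the synthetic cohort generator
#'
#' Describes a simulated fruit cohort: three diameter groups (defaults
#' 65-75, 75-85 and 85-95 mm, 160 fruit each) with group-specific SSC
#' distributions, a smooth positive source-intensity envelope, a baseline
#' tissue extinction curve with absorption structure near 645, 675, 710,
#' 758, 810 and 830 nm, an SSC-dependent extinction term concentrated at
#' the sugar-related bands, and multiplicative log-normal detector noise.
#' Spectra follow `I = I0(w) * exp(-(uBase(w) + k(w) * SSC) * d) * exp(eps)`.
#'
#' `sourceIntensity`, `baseExtinction` and `sscCoupling` accept a function
#' of wavelength, a vector on the grid, or a single number; they are stored
#' evaluated on the grid.
#'
#' @param nPerGroup fruit per diameter group (default 160).
#' @param wavelengths the grid, nm (default 350-850 nm in 1-nm steps).
#' @param groups data frame with columns `label`, `lo`, `hi` (mm),
#'   `sscMean`, `sscSd`, `sscMin`, `sscMax` (degrees Brix).
#' @param sourceIntensity source envelope `I0(w)` (counts), positive.
#' @param baseExtinction baseline extinction `uBase(w)`, 1/mm, positive.
#' @param sscCoupling SSC coupling `k(w)`, 1/(mm*Brix), non-negative.
#' @param noiseSd standard deviation of the additive log-domain noise
#'   (default 0.01, i.e. ~1% multiplicative intensity noise).
#' @param seed integer RNG seed; cohorts are bit-reproducible from it.
#' @return A list of class `"SyntheticConfig"`.
#' @seealso [generateCohort()]
#' @export
syntheticConfig <- function(nPerGroup = 160L,
                            wavelengths = seq(350, 850, by = 1),
                            groups = .defaultGroups(),
                            sourceIntensity = NULL,
                            baseExtinction = NULL,
                            sscCoupling = NULL,
                            noiseSd = 0.01,
                            seed = 1L) {
  wl <- as.numeric(wavelengths)
  if (any(diff(wl) <= 0)) .stopf("wavelength grid must be strictly increasing")
  evalCurve <- function(x, default, name) {
    v <- if (is.null(x)) default(wl)
         else if (is.function(x)) x(wl)
         else if (length(x) == 1L) rep(as.numeric(x), length(wl))
         else as.numeric(x)
    if (length(v) != length(wl))
      .stopf("%s must evaluate to one value per wavelength", name)
    v
  }
  i0 <- evalCurve(sourceIntensity, .defaultSourceIntensity, "sourceIntensity")
  ub <- evalCurve(baseExtinction, .defaultBaseExtinction, "baseExtinction")
  k <- evalCurve(sscCoupling, .defaultSscCoupling, "sscCoupling")
  if (any(i0 <= 0)) .stopf("sourceIntensity must be positive everywhere")
  if (any(ub < 0)) .stopf("baseExtinction must be non-negative")
  if (any(k < 0)) .stopf("sscCoupling must be non-negative")
  if (noiseSd < 0) .stopf("noiseSd must be >= 0")
  need <- c("label", "lo", "hi", "sscMean", "sscSd", "sscMin", "sscMax")
  if (!all(need %in% names(groups)))
    .stopf("groups must have columns %s", paste(need, collapse = ", "))
  if (any(groups$lo >= groups$hi)) .stopf("group diameter ranges must have lo < hi")
  if (nrow(groups) > 1 && any(groups$hi[-nrow(groups)] > groups$lo[-1]))
    .stopf("group diameter ranges must be ordered and non-overlapping")
  structure(list(nPerGroup = as.integer(nPerGroup), wavelengths = wl,
                 groups = groups, sourceIntensity = i0, baseExtinction = ub,
                 sscCoupling = k, noiseSd = noiseSd, seed = as.integer(seed)),
            class = "SyntheticConfig")
}

#' Generate a synthetic fruit cohort with ground truth
#'
#' Draws, per group, diameters uniformly on the group range and SSC from a
#' normal distribution truncated to the group's min/max, then builds each
#' spectrum by Beer-Lambert attenuation of the source envelope with the
#' sample's extinction curve `uBase(w) + k(w) * SSC`, and multiplies by
#' log-normal noise. Fully reproducible from `config$seed`.
#'
#' @param config a [syntheticConfig()] object.
#' @return A list with `set` (the [SpectraSet-class]) and `truth`, a list
#'   holding the noiseless intensity matrix, the per-sample true extinction
#'   matrix, the per-sample diameters and SSC, and the config itself.
#' @seealso [trueSpectrumAt()], [groupMeansTable()]
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed)
  g <- config$groups
  nG <- nrow(g)
  n <- config$nPerGroup * nG
  wl <- config$wavelengths
  d <- numeric(0); s <- numeric(0); grp <- character(0); ids <- character(0)
  for (i in seq_len(nG)) {
    d <- c(d, runif(config$nPerGroup, g$lo[i], g$hi[i]))
    s <- c(s, .rtruncnorm(config$nPerGroup, g$sscMean[i], g$sscSd[i],
                          g$sscMin[i], g$sscMax[i]))
    grp <- c(grp, rep(g$label[i], config$nPerGroup))
    ids <- c(ids, sprintf("%s_%03d", g$label[i], seq_len(config$nPerGroup)))
  }
  # per-sample extinction curves, n x p
  ext <- matrix(config$baseExtinction, n, length(wl), byrow = TRUE) +
    outer(s, config$sscCoupling)
  lnClean <- matrix(log(config$sourceIntensity), n, length(wl), byrow = TRUE) -
    ext * d
  clean <- exp(lnClean)
  noisy <- if (config$noiseSd > 0)
    clean * exp(matrix(rnorm(n * length(wl), 0, config$noiseSd), n))
  else clean
  set <- SpectraSet(ids, wl, noisy, d, s, grp)
  truth <- list(diameters = d, ssc = s, group = grp, noiseless = clean,
                extinction = ext, config = config)
  list(set = set, truth = truth)
}

# truncated normal by rejection; degenerate sd collapses to the mean
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * (n - length(out)), mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Ground-truth spectrum at a given diameter and SSC
#'
#' Evaluates the generator's noiseless law
#' `I0(w) * exp(-(uBase(w) + k(w) * ssc) * diameter)` — e.g. the exact
#' spectrum of a reference-diameter fruit, independent of any finite sample.
#'
#' @param config a [syntheticConfig()] object (also accepts the `truth`
#'   element returned by [generateCohort()]).
#' @param diameter fruit diameter, mm.
#' @param sscValue soluble solids content, degrees Brix (irrelevant when the
#'   config has zero SSC coupling).
#' @return A [Spectrum-class].
#' @export
trueSpectrumAt <- function(config, diameter, sscValue = 0) {
  if (!inherits(config, "SyntheticConfig") && !is.null(config$config))
    config <- config$config
  stopifnot(inherits(config, "SyntheticConfig"))
  u <- config$baseExtinction + config$sscCoupling * sscValue
  Spectrum(config$wavelengths, config$sourceIntensity * exp(-u * diameter))
}

#' Per-group SSC summary table
#'
#' Descriptive statistics of SSC per size group in the conventional order:
#' group, n, max, min, mean, standard deviation. Samples without a group tag
#' are omitted with a warning.
#'
#' @param set a [SpectraSet-class] with group tags.
#' @return A data frame with columns `group`, `n`, `max`, `min`, `mean`, `sd`.
#' @export
groupMeansTable <- function(set) {
  stopifnot(is(set, "SpectraSet"))
  grp <- groupLabels(set)
  if (!length(grp)) .stopf("spectra set carries no group tags")
  if (anyNA(grp)) {
    .warnf("%d samples without a group tag were omitted", sum(is.na(grp)))
    keep <- !is.na(grp)
    set <- set[keep, ]
    grp <- grp[keep]
  }
  sscVals <- split(ssc(set), grp)
  do.call(rbind, lapply(names(sscVals), function(gname) {
    v <- sscVals[[gname]]
    data.frame(group = gname, n = length(v), max = max(v), min = min(v),
               mean = mean(v), sd = if (length(v) > 1) sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
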