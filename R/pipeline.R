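#' @include size-correction.R kennard-stone.R pls.R preprocess.R
NULL

#' Describe an end-to-end evaluation experiment
#'
#' Collects everything one run of the pipeline needs: the cohort, the
#' evaluation cells to compute, the pretreatments to compare, the reference
#' size group for the correction, and the numerical knobs. Three kinds of
#' cells are available:
#'
#' * `"per-group"` — one model per size group, split `nCal`/rest by
#'   Kennard-Stone, evaluated on its own prediction set, for every
#'   pretreatment requested;
#' * `"mixed"` — one model on the concatenation of all per-group
#'   calibration sets, evaluated on the concatenated prediction sets;
#' * `"cross-size"` — the reference group's calibration set predicts each
#'   *other* group in full, once without and once with size correction
#'   (the extinction model is fitted on the reference group's calibration
#'   subset only, then applied everywhere).
#'
#' @param set the cohort, a [SpectraSet-class] with group tags.
#' @param referenceGroup the size group whose calibration set anchors the
#'   correction and the cross-size cells (default `"75-85"`).
#' @param cells subset of `c("per-group", "mixed", "cross-size")`.
#' @param pretreatments pretreatments for the per-group/mixed cells (any of
#'   `"original"`, `"snv"`, `"msc"`, `"sg"`).
#' @param crossPretreatment single pretreatment for the cross-size cells
#'   (default `"original"`).
#' @param nCalPerGroup calibration samples per group (default 120).
#' @param wavelengthRange effective range in nm, closed interval (default
#'   `c(350, 850)`).
#' @param lvMax largest latent-variable count searched (default 20).
#' @param folds cross-validation folds for LV selection (default 10).
#' @param minGap minimum diameter gap for extinction estimation, mm.
#' @param sgWindow,sgPolyorder Savitzky-Golay parameters.
#' @param rmseDivisor `"n_minus_1"` (default) or `"n"`.
#' @return A list of class `"ExperimentPlan"`.
#' @seealso [runExperiment()]
#' @export
experimentPlan <- function(set, referenceGroup = "75-85",
                           cells = c("per-group", "mixed", "cross-size"),
                           pretreatments = "original",
                           crossPretreatment = "original",
                           nCalPerGroup = 120L,
                           wavelengthRange = c(350, 850),
                           lvMax = 20L, folds = 10L, minGap = 1.0,
                           sgWindow = 11L, sgPolyorder = 2L,
                           rmseDivisor = "n_minus_1") {
  stopifnot(is(set, "SpectraSet"))
  cells <- match.arg(cells, several.ok = TRUE)
  pretreatments <- match.arg(pretreatments,
                             c("original", "snv", "msc", "sg"),
                             several.ok = TRUE)
  crossPretreatment <- match.arg(crossPretreatment,
                                 c("original", "snv", "msc", "sg"))
  if (!length(groupLabels(set)))
    .stopf("the cohort must carry group tags")
  if (!referenceGroup %in% groupLabels(set))
    .stopf("reference group '%s' is not present in the cohort", referenceGroup)
  structure(list(set = set, referenceGroup = referenceGroup, cells = cells,
                 pretreatments = pretreatments,
                 crossPretreatment = crossPretreatment,
                 nCalPerGroup = as.integer(nCalPerGroup),
                 wavelengthRange = wavelengthRange,
                 lvMax = as.integer(lvMax), folds = as.integer(folds),
                 minGap = minGap, sgWindow = as.integer(sgWindow),
                 sgPolyorder = as.integer(sgPolyorder),
                 rmseDivisor = rmseDivisor),
            class = "ExperimentPlan")
}

#' Run an evaluation experiment
#'
#' Executes the plan: restricts wavelengths, splits each group by
#' Kennard-Stone on the raw restricted intensities, optionally fits and
#' applies the size correction (cross-size cells), pretreats, selects the
#' latent-variable count by cross-validation on the calibration set, fits
#' PLS and evaluates Rc/RMSEC on calibration and Rp/RMSEP on the designated
#' prediction cohort.
#'
#' @param plan an [experimentPlan()] object.
#' @param resultsPath optional path; when given, the report is also written
#'   as CSV.
#' @return A data frame with one row per evaluation cell: `cell`,
#'   `calibration_set`, `prediction_set`, `pretreatment`, `corrected`,
#'   `n_cal`, `n_pred`, `n_lv`, `r_c`, `rmsec`, `r_p`, `rmsep`,
#'   `r_squared_alt`.
#' @seealso [compareCorrection()]
#' @export
runExperiment <- function(plan, resultsPath = NULL) {
  stopifnot(inherits(plan, "ExperimentPlan"))
  set <- restrictWavelengths(plan$set, plan$wavelengthRange[1],
                             plan$wavelengthRange[2])
  groups <- unique(groupLabels(set))
  groupSets <- lapply(groups, subsetGroup, set = set)
  names(groupSets) <- groups
  splits <- lapply(groupSets, function(gs)
    kennardStone(gs, min(plan$nCalPerGroup, nSamples(gs) - 1L)))
  rows <- list()

  evalCell <- function(cell, calSet, predSet, pretreatment, corrected) {
    ref <- if (pretreatment == "msc") meanSpectrum(calSet) else NULL
    calP <- preprocessSpectra(calSet, pretreatment, reference = ref,
                              window = plan$sgWindow,
                              polyorder = plan$sgPolyorder)
    predP <- preprocessSpectra(predSet, pretreatment, reference = ref,
                               window = plan$sgWindow,
                               polyorder = plan$sgPolyorder)
    Xc <- intensities(calP); yc <- ssc(calP)
    nlv <- suppressWarnings(
      selectLatentVariables(Xc, yc, plan$lvMax, plan$folds))
    fit <- suppressWarnings(fitPLS(Xc, yc, nlv))
    yhatC <- predict(fit, Xc)
    yhatP <- predict(fit, intensities(predP))
    yp <- ssc(predP)
    data.frame(cell = cell$name, calibration_set = cell$cal,
               prediction_set = cell$pred, pretreatment = pretreatment,
               corrected = corrected, n_cal = length(yc), n_pred = length(yp),
               n_lv = as.integer(nlv),
               r_c = correlationMetric(yc, yhatC),
               rmsec = rmseMetric(yc, yhatC, plan$rmseDivisor),
               r_p = correlationMetric(yp, yhatP),
               rmsep = rmseMetric(yp, yhatP, plan$rmseDivisor),
               r_squared_alt = correlationMetric(yp, yhatP, "printed"),
               stringsAsFactors = FALSE)
  }

  if ("per-group" %in% plan$cells) {
    for (g in groups) {
      sp <- splits[[g]]
      for (pt in plan$pretreatments) {
        rows[[length(rows) + 1L]] <- evalCell(
          list(name = "per-group", cal = g, pred = g),
          groupSets[[g]][calibrationIndices(sp), ],
          groupSets[[g]][predictionIndices(sp), ], pt, FALSE)
      }
    }
  }

  if ("mixed" %in% plan$cells) {
    calAll <- do.call(.rbindSets, lapply(groups, function(g)
      groupSets[[g]][calibrationIndices(splits[[g]]), ]))
    predAll <- do.call(.rbindSets, lapply(groups, function(g)
      groupSets[[g]][predictionIndices(splits[[g]]), ]))
    for (pt in plan$pretreatments) {
      rows[[length(rows) + 1L]] <- evalCell(
        list(name = "mixed", cal = "all", pred = "all"),
        calAll, predAll, pt, FALSE)
    }
  }

  if ("cross-size" %in% plan$cells) {
    rg <- plan$referenceGroup
    refCal <- groupSets[[rg]][calibrationIndices(splits[[rg]]), ]
    # average over every calibration sample of every size group: the wide
    # diameter gaps of the outer groups stabilize the quotients (only
    # spectra and diameters enter; no SSC labels are used)
    calUnion <- do.call(.rbindSets, lapply(groups, function(g)
      groupSets[[g]][calibrationIndices(splits[[g]]), ]))
    corr <- estimateExtinction(calUnion, reference = meanSpectrum(refCal),
                               referenceDiameter = mean(diameters(refCal)),
                               minGap = plan$minGap)
    others <- setdiff(groups, rg)
    for (g in others) {
      target <- groupSets[[g]]
      for (corrected in c(FALSE, TRUE)) {
        calUse <- if (corrected) applyCorrection(refCal, corr) else refCal
        predUse <- if (corrected) applyCorrection(target, corr) else target
        rows[[length(rows) + 1L]] <- evalCell(
          list(name = "cross-size", cal = rg, pred = g),
          calUse, predUse, plan$crossPretreatment, corrected)
      }
    }
  }

  report <- do.call(rbind, rows)
  if (!is.null(resultsPath)) write.csv(report, resultsPath, row.names = FALSE)
  report
}

# concatenate SpectraSets sharing one wavelength grid
.rbindSets <- function(...) {
  sets <- list(...)
  wl <- wavelengths(sets[[1]])
  for (s in sets[-1]) .checkAligned(wl, wavelengths(s))
  SpectraSet(unlist(lapply(sets, sampleIds)), wl,
             do.call(rbind, lapply(sets, intensities)),
             unlist(lapply(sets, diameters)), unlist(lapply(sets, ssc)),
             unlist(lapply(sets, groupLabels)))
}

#' Effect of the size correction on cross-size cells
#'
#' Pairs corrected and uncorrected cross-size rows of a [runExperiment()]
#' report (matched on calibration set, prediction set and pretreatment) and
#' returns the per-cell changes in prediction correlation and RMSEP, with a
#' flag marking cells where the correction improved both metrics.
#'
#' @param report a data frame from [runExperiment()].
#' @return A data frame with `calibration_set`, `prediction_set`,
#'   `pretreatment`, `delta_r_p` (corrected minus uncorrected),
#'   `delta_rmsep`, and `improved`.
#' @export
compareCorrection <- function(report) {
  cs <- report[report$cell == "cross-size", , drop = FALSE]
  if (!nrow(cs)) .stopf("report contains no cross-size cells")
  key <- interaction(cs$calibration_set, cs$prediction_set, cs$pretreatment,
                     drop = TRUE)
  out <- lapply(levels(key), function(k) {
    pair <- cs[key == k, , drop = FALSE]
    on <- pair[pair$corrected, , drop = FALSE]
    off <- pair[!pair$corrected, , drop = FALSE]
    if (nrow(on) != 1L || nrow(off) != 1L)
      .stopf("cross-size cell '%s' lacks a matched corrected/uncorrected pair", k)
    data.frame(calibration_set = off$calibration_set,
               prediction_set = off$prediction_set,
               pretreatment = off$pretreatment,
               delta_r_p = on$r_p - off$r_p,
               delta_rmsep = on$rmsep - off$rmsep,
               improved = on$r_p > off$r_p && on$rmsep < off$rmsep,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
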