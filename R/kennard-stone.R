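#' @include AllClasses.R
NULL

#' Kennard-Stone calibration/prediction split
#'
#' Deterministic max-min selection of a representative calibration subset:
#' the two mutually most-distant samples (Euclidean distance over intensity
#' rows) seed the calibration set, then the sample maximizing its minimum
#' distance to the already-selected set is added until `nCal` samples are
#' chosen. The remainder forms the prediction set. Ties are broken by the
#' smallest sample index, so identical input always yields an identical
#' split.
#'
#' @param x a [SpectraSet-class] (distances over its intensity matrix) or a
#'   numeric matrix with samples in rows.
#' @param nCal number of calibration samples, `2 <= nCal <= n`.
#' @return A [SplitIndices-class]; indices are sorted ascending.
#' @examples
#' pos <- matrix(0:9, ncol = 1)
#' calibrationIndices(kennardStone(pos, 2))  # 1 10  (the extreme pair)
#' @export
kennardStone <- function(x, nCal) {
  if (is(x, "SpectraSet")) x <- intensities(x)
  x <- as.matrix(x)
  n <- nrow(x)
  nCal <- as.integer(nCal)
  if (nCal < 2L || nCal > n)
    .stopf("nCal must satisfy 2 <= nCal <= %d (got %d)", n, nCal)
  dm <- as.matrix(dist(x))
  # seed: lexicographically smallest pair attaining the maximum distance
  best <- which(dm == max(dm), arr.ind = TRUE)
  best <- best[best[, 1] < best[, 2], , drop = FALSE]
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
  sel <- c(best[1, 1], best[1, 2])
  minDist <- pmin(dm[, sel[1]], dm[, sel[2]])
  minDist[sel] <- -Inf
  while (length(sel) < nCal) {
    nxt <- which.max(minDist)          # first (smallest-index) maximizer
    sel <- c(sel, nxt)
    minDist <- pmin(minDist, dm[, nxt])
    minDist[nxt] <- -Inf
  }
  new("SplitIndices", calibration = sort(as.integer(sel)),
      prediction = setdiff(seq_len(n), as.integer(sel)))
}

#' Persist a split for audit
#'
#' Writes a two-column CSV (`sample_id`, `role`) recording which samples went
#' to calibration and which to prediction.
#'
#' @param split a [SplitIndices-class].
#' @param set the [SpectraSet-class] the split indexes into.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSplit <- function(split, set, path) {
  stopifnot(is(split, "SplitIndices"), is(set, "SpectraSet"))
  ids <- sampleIds(set)
  df <- rbind(
    data.frame(sample_id = ids[calibrationIndices(split)], role = "calibration"),
    data.frame(sample_id = ids[predictionIndices(split)], role = "prediction"))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
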