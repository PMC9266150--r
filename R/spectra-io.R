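#' @include AllClasses.R
NULL

.META_COLS <- c("id", "diameter_mm", "ssc_brix")

#' Read a wide-format spectra CSV
#'
#' Expects a header row with the mandatory columns `id`, `diameter_mm`,
#' `ssc_brix`, an optional `group` column, and one numeric column per
#' wavelength (plain numbers in nm, '.' decimal separator). Wavelength
#' columns may appear in any order; they are sorted ascending and the
#' intensity columns permuted consistently.
#'
#' @param path path to a CSV file.
#' @return A [SpectraSet-class].
#' @seealso [writeSpectra()]
#' @export
readSpectra <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in .META_COLS)
    if (!col %in% names(df))
      .stopf("spectra file is missing mandatory column '%s'", col)
  hasGroup <- "group" %in% names(df)
  # keep duplicates so repeated wavelength columns are caught below
  wlCols <- names(df)[!names(df) %in% c(.META_COLS, "group")]
  wl <- suppressWarnings(as.numeric(wlCols))
  if (anyNA(wl))
    .stopf("non-numeric wavelength column header: '%s'", wlCols[which(is.na(wl))[1]])
  if (anyDuplicated(wl))
    .stopf("duplicate wavelength column: %g nm", wl[duplicated(wl)][1])
  if (nrow(df) > 0) {
    for (col in c("diameter_mm", "ssc_brix", wlCols)) {
      if (!is.numeric(df[[col]])) {
        bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
        .stopf("non-numeric value in column '%s', row %d", col, bad)
      }
    }
  }
  ord <- order(wl)
  intens <- as.matrix(df[, wlCols[ord], drop = FALSE])
  storage.mode(intens) <- "double"
  SpectraSet(sampleIds = as.character(df$id), wavelengths = wl[ord],
             intensities = intens, diameters = df$diameter_mm,
             ssc = df$ssc_brix,
             group = if (hasGroup) as.character(df$group) else character(0))
}

#' Write a SpectraSet to a wide-format CSV
#'
#' Numbers are written at full double precision (15 significant digits), so
#' a write/read round trip reproduces the set to text precision. A `group`
#' column is emitted only when the set carries group tags.
#'
#' @param set a [SpectraSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSpectra <- function(set, path) {
  stopifnot(is(set, "SpectraSet"))
  df <- data.frame(id = sampleIds(set), diameter_mm = diameters(set),
                   ssc_brix = ssc(set), check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (length(groupLabels(set))) df$group <- groupLabels(set)
  intens <- intensities(set)
  colnames(intens) <- as.character(wavelengths(set))
  df <- cbind(df, as.data.frame(intens, check.names = FALSE))
  ok <- tryCatch({
    write.csv(df, path, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) .stopf("cannot write spectra file '%s': %s",
                          path, conditionMessage(ok))
  invisible(path)
}
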