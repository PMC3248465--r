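#' Read and validate a sample sheet
#'
#' The sample sheet assigns every fish to its phenotype and treatment:
#' tab-separated with header `fish_id`, `sex` (F/M/unknown), `temperature`
#' (LT/HT), `treatment` (none/E2), `tissue` (gonad/brain), `family`.
#'
#' @param path path to the TSV file.
#' @return a validated data.frame.
#' @export
readSampleSheet <- function(path) {
  # colClasses guards against "F" being parsed as FALSE
  sheet <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                             colClasses = "character")
  validateSampleSheet(sheet)
}

#' @rdname readSampleSheet
#' @param sheet a data.frame to validate in place.
#' @export
validateSampleSheet <- function(sheet) {
  need <- c("fish_id", "sex", "temperature", "treatment", "tissue", "family")
  miss <- setdiff(need, names(sheet))
  if (length(miss)) {
    stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(sheet$fish_id)) stop("fish_id values must be unique")
  ok <- list(sex = c("F", "M", "unknown"), temperature = c("LT", "HT"),
             treatment = c("none", "E2"), tissue = c("gonad", "brain"))
  for (col in names(ok)) {
    bad <- setdiff(unique(sheet[[col]]), ok[[col]])
    if (length(bad)) {
      stop(sprintf("invalid %s value(s): %s", col, paste(bad, collapse = ", ")))
    }
  }
  sheet
}

#' Treatment-class label for each fish
#'
#' Combines the grouping factors into the class labels used throughout the
#' study (default sex then temperature: FLT, FHT, MLT, MHT).
#'
#' @param sheet a sample sheet data.frame.
#' @param classBy character vector of sample-sheet columns.
#' @return character vector of class labels, one per row of `sheet`.
#' @export
classLabels <- function(sheet, classBy = c("sex", "temperature")) {
  do.call(paste0, sheet[classBy])
}

#' @rdname readSampleSheet
#' @export
writeSampleSheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
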