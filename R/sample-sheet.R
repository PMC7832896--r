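#' Read and validate a sample sheet
#'
#' The sample sheet maps each sequenced individual to its inline P1 barcode
#' and phenotypic sex. Format: TSV with header `sample_id<TAB>barcode<TAB>sex`,
#' sex coded `M`/`F`. Validation enforces the properties the demultiplexer
#' relies on: unique sample ids, equal-length unique barcodes that are
#' mutually at least 2 mismatches apart (so 1-mismatch barcode rescue can
#' never be ambiguous against an exact match).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `sample_id`, `barcode`, `sex`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", comment.char = "#")
  validate_sample_sheet(df)
}

#' Write a sample sheet
#' @param sheet Data.frame with columns `sample_id`, `barcode`, `sex`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  validate_sample_sheet(sheet)
  utils::write.table(sheet[, c("sample_id", "barcode", "sex")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a sample sheet
#'
#' @param sheet Data.frame with columns `sample_id`, `barcode`, `sex`.
#' @return The validated sheet (invisibly usable in pipelines).
#' @export
validate_sample_sheet <- function(sheet) {
  req <- c("sample_id", "barcode", "sex")
  if (!all(req %in% names(sheet))) {
    stop("sample sheet must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicate sample_id in sample sheet")
  }
  if (anyDuplicated(sheet$barcode)) {
    stop("duplicate barcode in sample sheet")
  }
  if (!all(sheet$sex %in% c("M", "F"))) {
    stop("sex must be 'M' or 'F'")
  }
  if (length(unique(nchar(sheet$barcode))) != 1L) {
    stop("all barcodes must have the same length")
  }
  if (!all(grepl("^[ACGT]+$", sheet$barcode))) {
    stop("barcodes must be A/C/G/T strings")
  }
  if (nrow(sheet) >= 2L) {
    d <- hamming_matrix(sheet$barcode)
    if (min(d[upper.tri(d)]) < 2L) {
      stop("barcodes must be mutually >= 2 mismatches apart")
    }
  }
  if (length(unique(sheet$sex)) < 2L) {
    warning("sample sheet contains a single sex; ",
            "sex-marker stages require both sexes")
  }
  sheet
}
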