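#' Read a FASTQ file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that returns plain
#' character vectors, which is the working representation used throughout the
#' pipeline (reads are short, uniform-length tags). Gzipped input is handled
#' transparently. A malformed record triggers a hard error naming the
#' 1-based record index at which the file first deviates from the 4-line
#' FASTQ layout.
#'
#' @param path Path to a FASTQ file (optionally `.gz`).
#' @return A data.frame with columns `id`, `seq`, `qual` (one row per read).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) {
    stop("FASTQ file not found: ", path)
  }
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq",
                                 with.qualities = TRUE),
    error = function(e) {
      idx <- locate_malformed_fastq(path)
      if (!is.na(idx)) {
        stop("malformed FASTQ record at record index ", idx, " in ", path,
             call. = FALSE)
      }
      stop("failed to read FASTQ ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  data.frame(
    id = as.character(names(x)),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' @noRd
#' Diagnostic pass over a FASTQ file: returns the 1-based index of the first
#' structurally invalid record, or NA if the 4-line structure looks sound.
locate_malformed_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n_rec <- ceiling(length(lines) / 4)
  for (i in seq_len(n_rec)) {
    block <- lines[(4L * (i - 1L) + 1L):min(4L * i, length(lines))]
    if (length(block) < 4L ||
        !startsWith(block[1L], "@") ||
        !startsWith(block[3L], "+") ||
        nchar(block[2L]) != nchar(block[4L])) {
      return(i)
    }
  }
  NA_integer_
}

#' Write a FASTQ file
#'
#' @param reads A data.frame with columns `id`, `seq`, `qual` as produced by
#'   [read_fastq()].
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(is.data.frame(reads), all(c("id", "seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    stop("sequence/quality length mismatch in reads to be written")
  }
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}
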