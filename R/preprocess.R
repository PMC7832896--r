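#' Demultiplex inline-barcoded RADseq reads
#'
#' Assigns each read to the unique sample whose barcode is within
#' `allow_barcode_mismatch` of the read prefix (1-mismatch rescue by
#' default, mirroring common RADseq demultiplexer behaviour); an ambiguous
#' prefix (two barcodes within tolerance) drops the read rather than risking
#' misassignment. The restriction-site remnant immediately after the barcode
#' must match `overhang` exactly — the enzyme cut site is the locus anchor,
#' so no mismatch is tolerated there (set `check_overhang = FALSE` for
#' pre-cleaned input). Retained reads are emitted with the barcode removed
#' and the overhang kept, trimmed to a uniform length, and optionally passed
#' through the sliding-window quality filter so that the report accounts for
#' every input read.
#'
#' @param reads Path(s) to FASTQ file(s) (the pooled sequencer output).
#' @param sheet Sample sheet data.frame (see [read_sample_sheet()]).
#' @param overhang Expected restriction-site remnant (default SbfI
#'   `TGCAGG`).
#' @param allow_barcode_mismatch Maximum Hamming distance for barcode
#'   rescue.
#' @param check_overhang Require the exact overhang after the barcode.
#' @param trim_length Uniform post-barcode read length to emit; default the
#'   shortest retained read.
#' @param qual_window,qual_threshold Sliding-window quality filter settings
#'   applied to assigned reads (see [quality_filter()]); set
#'   `qual_threshold = 0` to disable.
#' @param out_dir Directory for per-sample FASTQ output.
#' @param gzip Write gzipped per-sample FASTQ.
#' @return An object of class `demux_report`: list with `per_sample` (a
#'   data.frame of sample_id, sex, n_retained, file), `dropped` (named
#'   counts: unknown_barcode, ambiguous_barcode, missing_site, low_quality),
#'   `n_input`, `trim_length`, and `files` (named by sample id).
#' @export
demultiplex <- function(reads, sheet, overhang = "TGCAGG",
                        allow_barcode_mismatch = 1, check_overhang = TRUE,
                        trim_length = NULL, qual_window = 15,
                        qual_threshold = 10, out_dir, gzip = FALSE) {
  sheet <- validate_sample_sheet(sheet)
  if (nchar(overhang) == 0L && check_overhang) {
    stop("overhang must be nonempty when check_overhang = TRUE")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  rd <- do.call(rbind, lapply(reads, read_fastq))
  n_input <- nrow(rd)
  bl <- nchar(sheet$barcode[1L])
  oh_len <- nchar(overhang)

  dropped <- c(unknown_barcode = 0L, ambiguous_barcode = 0L,
               missing_site = 0L, low_quality = 0L)
  assign_idx <- rep(NA_integer_, n_input)
  if (n_input > 0L) {
    prefix <- substr(rd$seq, 1L, bl)
    assign_idx <- match(prefix, sheet$barcode)
    if (allow_barcode_mismatch > 0L) {
      miss <- which(is.na(assign_idx))
      if (length(miss) > 0L) {
        uniq <- unique(prefix[miss])
        bmat <- seq_matrix(sheet$barcode)
        resolved <- vapply(uniq, function(pf) {
          if (nchar(pf) != bl) return(NA_integer_)
          hits <- which(hamming_to(bmat, pf) <= allow_barcode_mismatch)
          if (length(hits) == 1L) hits else if (length(hits) > 1L) -1L else
            NA_integer_
        }, integer(1))
        assign_idx[miss] <- resolved[match(prefix[miss], uniq)]
      }
    }
    dropped["ambiguous_barcode"] <- sum(assign_idx == -1L, na.rm = TRUE)
    dropped["unknown_barcode"] <- sum(is.na(assign_idx))
    assign_idx[!is.na(assign_idx) & assign_idx == -1L] <- NA_integer_
  }

  keep <- !is.na(assign_idx)
  if (check_overhang && any(keep)) {
    site <- substr(rd$seq, bl + 1L, bl + oh_len)
    bad_site <- keep & site != overhang
    dropped["missing_site"] <- sum(bad_site)
    keep <- keep & !bad_site
  }

  # barcode removal + uniform trim
  rd$seq <- substr(rd$seq, bl + 1L, nchar(rd$seq))
  rd$qual <- substr(rd$qual, bl + 1L, nchar(rd$qual))
  if (any(keep)) {
    tl <- trim_length %||% min(nchar(rd$seq[keep]))
    short <- keep & nchar(rd$seq) < tl
    dropped["missing_site"] <- dropped["missing_site"] + sum(short)
    keep <- keep & !short
    rd$seq <- substr(rd$seq, 1L, tl)
    rd$qual <- substr(rd$qual, 1L, tl)
  } else {
    tl <- trim_length %||% 0L
  }

  if (qual_threshold > 0 && any(keep)) {
    ok <- rep(TRUE, n_input)
    ok[keep] <- quality_keep(rd$qual[keep], window = qual_window,
                             threshold = qual_threshold)
    dropped["low_quality"] <- sum(keep & !ok)
    keep <- keep & ok
  }

  files <- character(0)
  per <- sheet[, c("sample_id", "sex")]
  per$n_retained <- 0L
  for (j in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[j]
    sel <- which(keep & assign_idx == j)
    f <- file.path(out_dir, paste0(sid, ".fq", if (gzip) ".gz" else ""))
    write_fastq(rd[sel, , drop = FALSE], f)
    files[sid] <- f
    per$n_retained[j] <- length(sel)
  }
  per$file <- unname(files[per$sample_id])

  rep <- structure(list(
    per_sample = per, dropped = dropped, n_input = n_input,
    trim_length = tl, files = files
  ), class = "demux_report")
  stopifnot(sum(rep$per_sample$n_retained) + sum(rep$dropped) == n_input)
  rep
}

#' @export
print.demux_report <- function(x, ...) {
  cat("Demultiplexing report: ", x$n_input, " input reads, ",
      sum(x$per_sample$n_retained), " retained (trim length ",
      x$trim_length, ")\n", sep = "")
  cat("  dropped:", paste(names(x$dropped), x$dropped, sep = "=",
                          collapse = ", "), "\n")
  print(x$per_sample[, c("sample_id", "sex", "n_retained")], row.names = FALSE)
  invisible(x)
}

#' Write a demultiplexing report as TSV
#' @param report A `demux_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_demux_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  stamp_header(con, c(list(n_input = report$n_input,
                           trim_length = report$trim_length),
                      as.list(report$dropped)))
  utils::write.table(report$per_sample[, c("sample_id", "sex", "n_retained")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
#' Keep vector for the sliding-window quality rule: a read fails if any
#' window of `window` bases has mean phred below `threshold`. Windows longer
#' than the read fall back to the whole-read mean.
quality_keep <- function(quals, window = 15, threshold = 10) {
  n <- length(quals)
  if (n == 0L) return(logical(0))
  if (window < 1L) stop("window must be >= 1")
  qm <- phred_matrix(quals)
  len <- nrow(qm)
  w <- min(as.integer(window), len)
  s <- .colSums(qm[seq_len(w), , drop = FALSE], w, n)
  min_sum <- s
  if (len > w) {
    for (j in seq_len(len - w)) {
      s <- s - qm[j, ] + qm[j + w, ]
      min_sum <- pmin(min_sum, s)
    }
  }
  (min_sum / w) >= threshold
}

#' Sliding-window quality filter for a FASTQ file
#'
#' Drops any read containing a window of `window` bases whose mean phred
#' quality falls below `threshold`; retained reads pass through unmodified.
#'
#' @param input FASTQ path.
#' @param output Output FASTQ path; `NULL` returns the filtered reads
#'   without writing.
#' @param window Window width in bases.
#' @param threshold Minimum acceptable mean phred within any window.
#' @return List with `n_kept`, `n_dropped`, and `path` (or `reads` when
#'   `output` is `NULL`).
#' @export
quality_filter <- function(input, output = NULL, window = 15, threshold = 10) {
  rd <- read_fastq(input)
  if (any(nchar(rd$seq) != nchar(rd$qual))) {
    stop("sequence/quality length mismatch in ", input)
  }
  keep <- if (nrow(rd) == 0L) logical(0) else
    quality_keep(rd$qual, window, threshold)
  out <- rd[keep, , drop = FALSE]
  res <- list(n_kept = nrow(out), n_dropped = nrow(rd) - nrow(out))
  if (is.null(output)) {
    res$reads <- out
  } else {
    write_fastq(out, output)
    res$path <- output
  }
  res
}
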