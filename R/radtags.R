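#' Call depth-supported RAD tags for one individual
#'
#' A RAD tag is a distinct read sequence observed at least `min_depth` times
#' in one individual's demultiplexed reads. Sequences below the depth
#' threshold are discarded — that discard is exactly what the downstream
#' raw-read confirmation step guards against, since a locus sequenced at low
#' depth in one sex can masquerade as absent there.
#'
#' @param reads FASTQ path or character vector of (uniform-length)
#'   post-demultiplex read sequences.
#' @param sample_id Individual the reads belong to.
#' @param min_depth Minimum exact-copy count for a tag.
#' @return A data.frame of RAD tags: `sample_id`, `sequence`, `depth`,
#'   ordered by depth descending then sequence.
#' @export
call_tags <- function(reads, sample_id, min_depth = 5) {
  if (min_depth < 1) stop("min_depth must be >= 1")
  seqs <- if (is.character(reads) && length(reads) == 1L &&
              file.exists(reads)) {
    read_fastq(reads)$seq
  } else {
    as.character(reads)
  }
  if (length(seqs) == 0L) {
    warning("no reads for sample ", sample_id)
    return(data.frame(sample_id = character(0), sequence = character(0),
                      depth = integer(0), stringsAsFactors = FALSE))
  }
  if (length(unique(nchar(seqs))) != 1L) {
    stop("reads for sample ", sample_id, " are not uniform length; ",
         "demultiplex/trim first")
  }
  tab <- table(seqs)
  tab <- tab[tab >= min_depth]
  out <- data.frame(sample_id = rep(sample_id, length(tab)),
                    sequence = names(tab),
                    depth = as.integer(tab),
                    stringsAsFactors = FALSE)
  out[order(-out$depth, out$sequence), , drop = FALSE]
}

#' Cluster RAD tags from all individuals into candidate loci
#'
#' Single-linkage clustering of the distinct tag sequences under Hamming
#' distance at most `max_allele_mismatch`; every connected component is one
#' candidate locus and each distinct sequence within it one allele. Fixed
#' tag length and the shared restriction-site anchor make positional
#' (Hamming) comparison exact, so no alignment is needed. Loci violating
#' the two-alleles rule — more than two alleles overall, or more than two in
#' any single individual — are flagged `excluded` with a reason and are
#' omitted from downstream presence matrices, but retained in the output
#' for auditability.
#'
#' @param tags Data.frame of RAD tags across individuals (rbind of
#'   [call_tags()] outputs).
#' @param max_allele_mismatch Maximum Hamming distance joining two alleles
#'   of one locus.
#' @return An object of class `rad_loci`: list with
#'   `loci` (locus_id, n_alleles, n_carriers, excluded, reason),
#'   `alleles` (locus_id, allele, sequence),
#'   `occupancy` (locus_id, sample_id, n_alleles, depth), and the
#'   clustering parameters.
#' @export
cluster_loci <- function(tags, max_allele_mismatch = 3) {
  stopifnot(is.data.frame(tags),
            all(c("sample_id", "sequence", "depth") %in% names(tags)))
  if (nrow(tags) == 0L) {
    stop("no tags to cluster")
  }
  if (length(unique(nchar(tags$sequence))) != 1L) {
    stop("tag sequences have mixed lengths; all samples must be trimmed ",
         "to the same length")
  }
  seqs <- sort(unique(tags$sequence))
  comp <- hamming_components(seqs, max_allele_mismatch)

  # deterministic locus ids in order of each component's first (lexicographic)
  # member
  first_seq <- vapply(split(seqs, comp), `[`, "", 1L)
  ord <- order(first_seq)
  relabel <- integer(length(ord))
  relabel[as.integer(names(first_seq))[ord]] <- seq_along(ord)
  comp <- relabel[comp]
  locus_of_seq <- stats::setNames(sprintf("C%05d", comp), seqs)

  alleles <- data.frame(locus_id = unname(locus_of_seq), sequence = seqs,
                        stringsAsFactors = FALSE)
  alleles <- alleles[order(alleles$locus_id, alleles$sequence), , drop = FALSE]
  alleles$allele <- stats::ave(seq_len(nrow(alleles)), alleles$locus_id,
                               FUN = seq_along)

  tg <- tags
  tg$locus_id <- locus_of_seq[tg$sequence]
  occ <- stats::aggregate(
    cbind(n_alleles = rep(1L, nrow(tg)), depth = tg$depth),
    by = list(locus_id = tg$locus_id, sample_id = tg$sample_id), FUN = sum)
  occ <- occ[order(occ$locus_id, occ$sample_id), , drop = FALSE]

  n_alleles <- table(alleles$locus_id)
  n_carriers <- table(unique(occ[, c("locus_id", "sample_id")])$locus_id)
  max_ind_alleles <- tapply(occ$n_alleles, occ$locus_id, max)

  ids <- sort(unique(alleles$locus_id))
  loci <- data.frame(
    locus_id = ids,
    n_alleles = as.integer(n_alleles[ids]),
    n_carriers = as.integer(n_carriers[ids]),
    stringsAsFactors = FALSE
  )
  too_many <- loci$n_alleles > 2L
  too_many_ind <- as.integer(max_ind_alleles[ids]) > 2L
  loci$excluded <- too_many | too_many_ind
  loci$reason <- ifelse(too_many, ">2 alleles",
                        ifelse(too_many_ind, ">2 alleles in an individual",
                               ""))
  rownames(loci) <- NULL

  structure(list(
    loci = loci,
    alleles = alleles[, c("locus_id", "allele", "sequence")],
    occupancy = occ[, c("locus_id", "sample_id", "n_alleles", "depth")],
    max_allele_mismatch = max_allele_mismatch
  ), class = "rad_loci")
}

#' @noRd
#' Connected components of the <= max_mismatch Hamming graph via union-find.
hamming_components <- function(seqs, max_mismatch) {
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1L) {
    m <- seq_matrix(seqs)
    for (i in seq_len(n - 1L)) {
      rest <- (i + 1L):n
      d <- colSums(m[, rest, drop = FALSE] != m[, i])
      for (j in rest[d <= max_mismatch]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}

#' @export
print.rad_loci <- function(x, ...) {
  cat("Candidate RAD loci: ", nrow(x$loci), " (",
      sum(!x$loci$excluded), " retained with <=2 alleles, ",
      sum(x$loci$excluded), " excluded)\n", sep = "")
  cat("  max_allele_mismatch:", x$max_allele_mismatch, "\n")
  invisible(x)
}

#' @export
summary.rad_loci <- function(object, ...) {
  keep <- object$loci[!object$loci$excluded, ]
  out <- list(
    n_loci = nrow(object$loci),
    n_retained = nrow(keep),
    n_excluded = sum(object$loci$excluded),
    allele_counts = table(keep$n_alleles)
  )
  class(out) <- "summary.rad_loci"
  out
}

#' @export
print.summary.rad_loci <- function(x, ...) {
  cat("Loci:", x$n_loci, "total,", x$n_retained, "retained,",
      x$n_excluded, "excluded\n")
  cat("Alleles per retained locus:\n")
  print(x$allele_counts)
  invisible(x)
}

#' Presence/absence matrix over non-excluded loci
#'
#' @param loci A `rad_loci` object.
#' @param sheet Sample sheet; column order of the matrix follows sheet
#'   order. Every sample seen in the loci must be present in the sheet.
#' @return A logical matrix (loci x individuals) with locus ids as rownames
#'   and sample ids as colnames; the per-column sex vector is attached as
#'   attribute `"sex"`.
#' @export
presence_matrix <- function(loci, sheet) {
  stopifnot(inherits(loci, "rad_loci"))
  sheet <- validate_sample_sheet(sheet)
  unknown <- setdiff(unique(loci$occupancy$sample_id), sheet$sample_id)
  if (length(unknown) > 0L) {
    stop("samples present in loci but missing from sheet: ",
         paste(unknown, collapse = ", "))
  }
  keep_ids <- loci$loci$locus_id[!loci$loci$excluded]
  m <- matrix(FALSE, nrow = length(keep_ids), ncol = nrow(sheet),
              dimnames = list(keep_ids, sheet$sample_id))
  occ <- loci$occupancy[loci$occupancy$locus_id %in% keep_ids, , drop = FALSE]
  m[cbind(occ$locus_id, occ$sample_id)] <- TRUE
  attr(m, "sex") <- stats::setNames(sheet$sex, sheet$sample_id)
  m
}

#' Write loci as FASTA (alleles) plus a presence-matrix TSV
#'
#' Allele records are named `<locus_id>_allele<k>`. Both files carry a
#' parameter stamp in `#` header lines so every downstream count is
#' auditable.
#'
#' @param loci A `rad_loci` object.
#' @param matrix Presence matrix from [presence_matrix()].
#' @param fasta_path,matrix_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_loci <- function(loci, matrix, fasta_path, matrix_path) {
  al <- loci$alleles
  x <- Biostrings::DNAStringSet(al$sequence)
  names(x) <- sprintf("%s_allele%d", al$locus_id, al$allele)
  Biostrings::writeXStringSet(x, fasta_path)

  con <- file(matrix_path, "w")
  on.exit(close(con))
  stamp_header(con, list(max_allele_mismatch = loci$max_allele_mismatch,
                         n_loci_retained = nrow(matrix)))
  df <- data.frame(locus_id = rownames(matrix),
                   ifelse(matrix, 1L, 0L), check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta_path, matrix = matrix_path))
}
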