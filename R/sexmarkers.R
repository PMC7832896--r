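#' Identify putative sex-specific markers from a presence matrix
#'
#' A locus is putatively MALE-specific when it is present in at least
#' `min_carriers` males and in zero females, and symmetrically for
#' FEMALE-specific. Absence in the other sex is absolute (zero carriers):
#' the tolerance for sequencing noise is supplied later by the raw-read
#' confirmation step, not here. Male-specific markers indicate an XX/XY
#' system (Y-linked sequence), female-specific markers a ZZ/ZW system
#' (W-linked sequence).
#'
#' @param matrix Logical presence matrix (loci x individuals) from
#'   [presence_matrix()].
#' @param sex Sex vector (`"M"`/`"F"`) aligned with the matrix columns;
#'   defaults to the matrix's `"sex"` attribute.
#' @param min_carriers Minimum carriers in the specific sex; default
#'   `ceiling(n_sex / 2)` evaluated per sex.
#' @return An object of class `sex_markers`: data.frame with `locus_id`,
#'   `specificity` (`"MALE"`/`"FEMALE"`), `n_carriers`, sorted by
#'   `n_carriers` descending then `locus_id`; `confirmed` is `NA` until
#'   [confirm_markers()] runs.
#' @export
find_putative <- function(matrix, sex = attr(matrix, "sex"),
                          min_carriers = NULL) {
  if (is.null(sex)) stop("a sex vector is required")
  sex <- as.character(sex)
  if (length(sex) != ncol(matrix)) {
    stop("sex vector length does not match matrix columns")
  }
  if (!all(sex %in% c("M", "F"))) stop("sex must be 'M' or 'F'")
  if (length(unique(sex)) < 2L) {
    stop("both sexes must be represented to call sex-specific markers")
  }
  n_m <- sum(sex == "M")
  n_f <- sum(sex == "F")
  minc_m <- as.integer(min_carriers %||% ceiling(n_m / 2))
  minc_f <- as.integer(min_carriers %||% ceiling(n_f / 2))

  cm <- rowSums(matrix[, sex == "M", drop = FALSE])
  cf <- rowSums(matrix[, sex == "F", drop = FALSE])
  male_spec <- cf == 0L & cm >= minc_m
  female_spec <- cm == 0L & cf >= minc_f

  out <- rbind(
    data.frame(locus_id = rownames(matrix)[male_spec],
               specificity = rep("MALE", sum(male_spec)),
               n_carriers = as.integer(cm[male_spec]),
               stringsAsFactors = FALSE),
    data.frame(locus_id = rownames(matrix)[female_spec],
               specificity = rep("FEMALE", sum(female_spec)),
               n_carriers = as.integer(cf[female_spec]),
               stringsAsFactors = FALSE)
  )
  out <- out[order(-out$n_carriers, out$locus_id), , drop = FALSE]
  rownames(out) <- NULL
  out$confirmed <- rep(NA, nrow(out))
  attr(out, "min_carriers") <- c(MALE = minc_m, FEMALE = minc_f)
  class(out) <- c("sex_markers", "data.frame")
  out
}

#' Confirm putative sex-specific markers against opposite-sex raw reads
#'
#' The decisive false-positive filter: a putative marker is confirmed only
#' if none of its allele sequences occurs (within `max_mismatches` over the
#' full tag length) among the *raw* post-demultiplex reads — i.e. reads
#' before any depth threshold — of every individual of the opposite sex.
#' A locus sequenced below the tag-calling depth threshold in one sex looks
#' absent there in the presence matrix, but its reads are still in the raw
#' files, so this search eliminates exactly those artefacts. Reads and tags
#' share the restriction-site anchor, so the comparison is positional
#' (Hamming over the full length), not a local alignment. Both alleles of a
#' two-allele marker are searched: either allele appearing in the opposite
#' sex disqualifies sex-linkage.
#'
#' @param markers A `sex_markers` object from [find_putative()].
#' @param loci The `rad_loci` object the markers came from (supplies allele
#'   sequences).
#' @param read_files Named character vector of post-demultiplex FASTQ paths,
#'   one per sample id (the demux output, *not* the depth-filtered tags).
#'   A missing file for any opposite-sex sample is a hard error — silently
#'   skipping it would inflate confirmation.
#' @param sheet Sample sheet (supplies each sample's sex).
#' @param max_mismatches Hamming tolerance of the read search (default 0 =
#'   exact).
#' @return The `sex_markers` object with `confirmed` set and, for
#'   disconfirmed markers, a `disconfirming_evidence` list-column of
#'   data.frames (`sample_id`, `n_reads`, `allele`).
#' @export
confirm_markers <- function(markers, loci, read_files, sheet,
                            max_mismatches = 0) {
  stopifnot(inherits(markers, "sex_markers"), inherits(loci, "rad_loci"))
  sheet <- validate_sample_sheet(sheet)
  markers$confirmed <- logical(nrow(markers))
  markers$disconfirming_evidence <- vector("list", nrow(markers))
  if (nrow(markers) == 0L) return(markers)

  opp_of <- c(MALE = "F", FEMALE = "M")
  needed_sexes <- unique(opp_of[markers$specificity])
  reads_by_sex <- list()
  for (sx in needed_sexes) {
    ids <- sheet$sample_id[sheet$sex == sx]
    paths <- read_files[ids]
    missing <- ids[is.na(paths) |
                     !file.exists(ifelse(is.na(paths), "", paths))]
    if (length(missing) > 0L) {
      stop("missing raw read file(s) for opposite-sex sample(s): ",
           paste(missing, collapse = ", "))
    }
    # unique sequence x sample counts, to search once per distinct read
    tabs <- lapply(ids, function(sid) {
      tab <- table(read_fastq(read_files[[sid]])$seq)
      data.frame(sample_id = rep(sid, length(tab)),
                 sequence = names(tab), n_reads = as.integer(tab),
                 stringsAsFactors = FALSE)
    })
    reads_by_sex[[sx]] <- do.call(rbind, tabs)
  }

  allele_seqs <- split(loci$alleles$sequence, loci$alleles$locus_id)
  for (i in seq_len(nrow(markers))) {
    lid <- markers$locus_id[i]
    seqs <- allele_seqs[[lid]]
    if (is.null(seqs)) stop("marker locus ", lid, " not found in loci")
    opp <- reads_by_sex[[opp_of[[markers$specificity[i]]]]]
    ev <- list()
    for (k in seq_along(seqs)) {
      hit <- if (max_mismatches == 0) {
        opp$sequence == seqs[k]
      } else {
        same_len <- nchar(opp$sequence) == nchar(seqs[k])
        h <- rep(FALSE, nrow(opp))
        if (any(same_len)) {
          m <- seq_matrix(opp$sequence[same_len])
          h[same_len] <- hamming_to(m, seqs[k]) <= max_mismatches
        }
        h
      }
      if (any(hit)) {
        e <- opp[hit, c("sample_id", "n_reads"), drop = FALSE]
        e <- stats::aggregate(n_reads ~ sample_id, e, sum)
        e$allele <- k
        ev[[length(ev) + 1L]] <- e
      }
    }
    if (length(ev) > 0L) {
      markers$confirmed[i] <- FALSE
      markers$disconfirming_evidence[[i]] <- do.call(rbind, ev)
    } else {
      markers$confirmed[i] <- TRUE
    }
  }
  attr(markers, "max_mismatches") <- max_mismatches
  markers
}

#' @export
print.sex_markers <- function(x, ...) {
  n_put <- nrow(x)
  cat("Sex-specific markers: ", n_put, " putative", sep = "")
  if (n_put > 0L && !all(is.na(x$confirmed))) {
    cat(", ", sum(x$confirmed), " confirmed", sep = "")
  }
  cat("\n")
  for (sp in c("MALE", "FEMALE")) {
    sel <- x$specificity == sp
    if (!any(sel)) next
    cat("  ", sp, "-specific: ", sum(sel), sep = "")
    if (!all(is.na(x$confirmed))) {
      cat(" (", sum(x$confirmed[sel]), " confirmed)", sep = "")
    }
    cat("\n")
  }
  invisible(x)
}

#' Infer the heterogamety system from confirmed markers
#'
#' Confirmed male-specific markers with zero female-specific markers imply
#' an XX/XY system (the male-limited sequence is Y-linked); the symmetric
#' pattern implies ZZ/ZW. Anything else — both positive or both below
#' `min_markers` — is UNRESOLVED.
#'
#' @param markers A confirmed `sex_markers` object.
#' @param min_markers Minimum confirmed markers required to call a system.
#' @return An object of class `system_call`: list with `system`
#'   (`"XY"`/`"ZW"`/`"UNRESOLVED"`), `n_male_specific_confirmed`,
#'   `n_female_specific_confirmed`, `min_markers`.
#' @export
call_system <- function(markers, min_markers = 1) {
  stopifnot(inherits(markers, "sex_markers"))
  if (any(is.na(markers$confirmed))) {
    stop("markers must be confirmed (run confirm_markers()) before ",
         "calling a system")
  }
  n_male <- sum(markers$specificity == "MALE" & markers$confirmed)
  n_female <- sum(markers$specificity == "FEMALE" & markers$confirmed)
  system <- if (n_male >= min_markers && n_female == 0L) {
    "XY"
  } else if (n_female >= min_markers && n_male == 0L) {
    "ZW"
  } else {
    "UNRESOLVED"
  }
  structure(list(system = system,
                 n_male_specific_confirmed = n_male,
                 n_female_specific_confirmed = n_female,
                 min_markers = as.integer(min_markers)),
            class = "system_call")
}

#' @export
print.system_call <- function(x, ...) {
  cat("Sex chromosome system call: ", x$system, "\n", sep = "")
  cat("  confirmed male-specific markers:  ",
      x$n_male_specific_confirmed, "\n", sep = "")
  cat("  confirmed female-specific markers: ",
      x$n_female_specific_confirmed, "\n", sep = "")
  invisible(x)
}

#' Write putative/confirmed marker tables and the confirmed-marker FASTA
#'
#' `confirmed.fasta` (records `<locus_id>_allele<k>`) is the input to the
#' downstream two-step BLAST synteny stage.
#'
#' @param markers A confirmed `sex_markers` object.
#' @param loci The matching `rad_loci` object.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_markers <- function(markers, loci, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  put_path <- file.path(dir, "putative.tsv")
  conf_path <- file.path(dir, "confirmed.tsv")
  fa_path <- file.path(dir, "confirmed.fasta")

  base <- as.data.frame(markers)[, c("locus_id", "specificity", "n_carriers")]
  utils::write.table(cbind(base, confirmed = markers$confirmed), put_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  conf <- base[which(markers$confirmed), , drop = FALSE]
  utils::write.table(conf, conf_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  al <- loci$alleles[loci$alleles$locus_id %in% conf$locus_id, , drop = FALSE]
  x <- Biostrings::DNAStringSet(al$sequence)
  names(x) <- sprintf("%s_allele%d", al$locus_id, al$allele)
  Biostrings::writeXStringSet(x, fa_path)
  invisible(c(putative = put_path, confirmed = conf_path, fasta = fa_path))
}
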