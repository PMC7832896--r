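#' Parameters for the synthetic RADseq simulator
#'
#' Bundles and validates every knob of [simulate_rad_dataset()]. The defaults
#' describe a single-enzyme (SbfI) RADseq library of 150-bp-class forward
#' reads: a 6-base inline barcode, the 6-base `TGCAGG` SbfI remnant, and a
#' 140-base tag.
#'
#' @param n_males,n_females Number of individuals of each sex (at least one
#'   individual in total).
#' @param system Sex chromosome system to simulate: `"XY"`, `"ZW"`, or
#'   `"NONE"` (no sex-linked sequence at all).
#' @param n_autosomal_loci Number of autosomal loci carried by every
#'   individual.
#' @param n_sexlimited_loci Number of loci present only in the heterogametic
#'   sex (Y-hemizygous under XY, W-specific under ZW). Must be 0 when
#'   `system = "NONE"`.
#' @param n_gametolog_pairs Number of loci with a diverged gametolog pair:
#'   both sexes carry allele 1; the heterogametic sex additionally carries
#'   allele 2 at `allele_div` divergence. Must be 0 when `system = "NONE"`.
#' @param tag_length Length of the tag downstream of the enzyme overhang.
#' @param barcode_length Inline barcode length.
#' @param overhang Restriction-site remnant retained at the 5' end of every
#'   insert (default the SbfI remnant `TGCAGG`).
#' @param mean_depth Poisson mean of per-tag read depth.
#' @param error_rate Per-base substitution probability applied downstream of
#'   the barcode.
#' @param dropout_rate Per-individual, per-locus probability that the locus
#'   yields no reads at all in that individual (allelic dropout).
#' @param allele_div Per-base divergence between gametolog alleles; applied
#'   as exactly `round(allele_div * tag_length)` substitutions in the tag
#'   (never in the overhang), so locus-clustering behaviour at a given
#'   parameter set is deterministic.
#' @param seed Integer seed; identical parameters and seed give byte-identical
#'   output files.
#' @param n_planted_fp Number of planted false-positive autosomal loci:
#'   sequenced at a fixed low depth (`planted_fp_depth`) in one sex and at
#'   `mean_depth` in the other, so that the depth threshold of tag calling
#'   makes them look sex-specific while the raw reads disprove it. Used to
#'   exercise the confirmation step.
#' @param planted_fp_depth Fixed read depth of a planted locus in the
#'   low-depth sex.
#' @param planted_fp_low_sex Which sex gets the low depth (`"F"` makes the
#'   planted loci masquerade as male-specific).
#' @param lowq_read_rate Fraction of reads corrupted with a 15-base window of
#'   phred-2 qualities, to exercise the sliding-window quality filter.
#' @return An object of class `sim_params` (a validated named list).
#' @export
sim_params <- function(n_males = 9, n_females = 9,
                       system = c("XY", "ZW", "NONE"),
                       n_autosomal_loci = 100,
                       n_sexlimited_loci = 0,
                       n_gametolog_pairs = 0,
                       tag_length = 140, barcode_length = 6,
                       overhang = "TGCAGG",
                       mean_depth = 20, error_rate = 0.001,
                       dropout_rate = 0.02, allele_div = 0.05,
                       seed = 1,
                       n_planted_fp = 0, planted_fp_depth = 2,
                       planted_fp_low_sex = "F",
                       lowq_read_rate = 0) {
  system <- match.arg(system)
  p <- list(
    n_males = as.integer(n_males), n_females = as.integer(n_females),
    system = system,
    n_autosomal_loci = as.integer(n_autosomal_loci),
    n_sexlimited_loci = as.integer(n_sexlimited_loci),
    n_gametolog_pairs = as.integer(n_gametolog_pairs),
    tag_length = as.integer(tag_length),
    barcode_length = as.integer(barcode_length),
    overhang = toupper(overhang),
    mean_depth = mean_depth, error_rate = error_rate,
    dropout_rate = dropout_rate, allele_div = allele_div,
    seed = as.integer(seed),
    n_planted_fp = as.integer(n_planted_fp),
    planted_fp_depth = as.integer(planted_fp_depth),
    planted_fp_low_sex = planted_fp_low_sex,
    lowq_read_rate = lowq_read_rate
  )
  counts <- c("n_males", "n_females", "n_autosomal_loci",
              "n_sexlimited_loci", "n_gametolog_pairs", "tag_length",
              "barcode_length", "n_planted_fp", "planted_fp_depth")
  for (nm in counts) {
    if (is.na(p[[nm]]) || p[[nm]] < 0L) stop(nm, " must be a count >= 0")
  }
  rates <- c("error_rate", "dropout_rate", "allele_div", "lowq_read_rate")
  for (nm in rates) {
    if (!is.numeric(p[[nm]]) || p[[nm]] < 0 || p[[nm]] > 1) {
      stop(nm, " must be in [0, 1]")
    }
  }
  if (p$n_males == 0L && p$n_females == 0L) {
    stop("at least one individual is required (n_males = n_females = 0)")
  }
  if (p$mean_depth < 0) stop("mean_depth must be >= 0")
  if (!grepl("^[ACGT]+$", p$overhang)) stop("overhang must be an A/C/G/T string")
  if (!p$planted_fp_low_sex %in% c("M", "F")) {
    stop("planted_fp_low_sex must be 'M' or 'F'")
  }
  if (p$system == "NONE" &&
      (p$n_sexlimited_loci > 0L || p$n_gametolog_pairs > 0L)) {
    stop("system 'NONE' requires n_sexlimited_loci = 0 and ",
         "n_gametolog_pairs = 0")
  }
  structure(p, class = "sim_params")
}

#' @noRd
#' Random A/C/G/T strings of length `len`, pairwise Hamming distance at least
#' `min_dist`, by rejection. At desk scale random tags are essentially never
#' rejected (expected distance ~ 0.75 * len).
random_seqs <- function(n, len, min_dist) {
  out <- character(0)
  mat <- NULL
  tries <- 0L
  while (length(out) < n) {
    cand <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
    if (is.null(mat) || all(hamming_to(mat, cand) >= min_dist)) {
      out <- c(out, cand)
      mat <- cbind(mat, as.integer(charToRaw(cand)))
    }
    tries <- tries + 1L
    if (tries > 100L * n + 1000L) {
      stop("could not generate ", n, " sequences of length ", len,
           " at minimum distance ", min_dist)
    }
  }
  out
}

#' Simulate a RADseq dataset with known sex chromosome architecture
#'
#' Writes, under `dir`: per-individual barcoded FASTQ files
#' (`reads/<sample_id>.fq`), a pooled FASTQ (`raw_reads.fq`, the
#' concatenation in sample-sheet order, i.e. what the sequencer would hand
#' to the demultiplexer), the sample sheet (`samples.tsv`) and the ground
#' truth table (`truth.tsv`). Every read is
#' `barcode + overhang + tag`; substitution errors are applied downstream of
#' the barcode; per-tag depth is Poisson; allelic dropout zeroes a locus for
#' an individual. Sex-limited loci yield reads only in the heterogametic sex.
#'
#' @param params A [sim_params()] object.
#' @param dir Output directory (created if missing).
#' @param gzip Write gzipped FASTQ files.
#' @return An object of class `rad_sim`: list with `params`, `sheet`,
#'   `truth`, `dir`, `sample_files` (named by sample id), `pooled_file`,
#'   `truth_file`, `sheet_file`, `planted_fp_ids`.
#' @export
simulate_rad_dataset <- function(params, dir, gzip = FALSE) {
  stopifnot(inherits(params, "sim_params"))
  dir.create(file.path(dir, "reads"), recursive = TRUE, showWarnings = FALSE)
  with_seed(params$seed, simulate_rad_dataset_impl(params, dir, gzip))
}

#' @noRd
simulate_rad_dataset_impl <- function(params, dir, gzip) {
  p <- params
  het_sex <- switch(p$system, XY = "M", ZW = "F", NONE = NA_character_)
  sheet <- data.frame(
    sample_id = c(sprintf("M%02d", seq_len(p$n_males)),
                  sprintf("F%02d", seq_len(p$n_females))),
    sex = c(rep("M", p$n_males), rep("F", p$n_females)),
    stringsAsFactors = FALSE
  )
  sheet$barcode <- random_seqs(nrow(sheet), p$barcode_length, min_dist = 3L)
  sheet <- sheet[, c("sample_id", "barcode", "sex")]

  n_base <- p$n_autosomal_loci + p$n_sexlimited_loci + p$n_gametolog_pairs +
    p$n_planted_fp
  tags <- if (n_base > 0L) {
    random_seqs(n_base, p$tag_length, min_dist = 10L)
  } else character(0)

  male_ids <- sheet$sample_id[sheet$sex == "M"]
  female_ids <- sheet$sample_id[sheet$sex == "F"]
  all_ids <- sheet$sample_id
  het_ids <- if (is.na(het_sex)) character(0) else {
    if (het_sex == "M") male_ids else female_ids
  }

  # One row per allele: locus_id, class, allele, tag, carriers (list).
  alleles <- list()
  locus_counter <- 0L
  next_locus <- function() {
    locus_counter <<- locus_counter + 1L
    sprintf("L%04d", locus_counter)
  }
  t_i <- 0L
  for (i in seq_len(p$n_autosomal_loci)) {
    t_i <- t_i + 1L
    alleles[[length(alleles) + 1L]] <- list(
      locus_id = next_locus(), class = "AUTOSOMAL", allele = 1L,
      tag = tags[t_i], carriers = all_ids, planted = FALSE)
  }
  for (i in seq_len(p$n_sexlimited_loci)) {
    t_i <- t_i + 1L
    alleles[[length(alleles) + 1L]] <- list(
      locus_id = next_locus(), class = "SEXLIMITED", allele = 1L,
      tag = tags[t_i], carriers = het_ids, planted = FALSE)
  }
  n_div <- as.integer(round(p$allele_div * p$tag_length))
  for (i in seq_len(p$n_gametolog_pairs)) {
    t_i <- t_i + 1L
    lid <- next_locus()
    shared <- tags[t_i]
    diverged <- mutate_positions(shared, n_div, 1L, p$tag_length)
    alleles[[length(alleles) + 1L]] <- list(
      locus_id = lid, class = "GAMETOLOG_SHARED", allele = 1L,
      tag = shared, carriers = all_ids, planted = FALSE)
    alleles[[length(alleles) + 1L]] <- list(
      locus_id = lid, class = "GAMETOLOG_SEXLIMITED", allele = 2L,
      tag = diverged, carriers = het_ids, planted = FALSE)
  }
  planted_ids <- character(0)
  for (i in seq_len(p$n_planted_fp)) {
    t_i <- t_i + 1L
    lid <- next_locus()
    planted_ids <- c(planted_ids, lid)
    alleles[[length(alleles) + 1L]] <- list(
      locus_id = lid, class = "AUTOSOMAL", allele = 1L,
      tag = tags[t_i], carriers = all_ids, planted = TRUE)
  }

  truth <- data.frame(
    locus_id = vapply(alleles, `[[`, "", "locus_id"),
    class = vapply(alleles, `[[`, "", "class"),
    allele = vapply(alleles, `[[`, 0L, "allele"),
    sequence = paste0(p$overhang, vapply(alleles, `[[`, "", "tag")),
    carriers = vapply(alleles, function(a) paste(a$carriers, collapse = ","),
                      ""),
    stringsAsFactors = FALSE
  )

  read_len <- p$barcode_length + nchar(p$overhang) + p$tag_length
  base_qual <- strrep("I", read_len)
  sample_files <- character(0)
  pooled <- vector("list", nrow(sheet))

  for (j in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[j]
    sex <- sheet$sex[j]
    bc <- sheet$barcode[j]
    # allele rows this individual carries
    carried <- which(vapply(alleles, function(a) sid %in% a$carriers, TRUE))
    depths <- integer(length(carried))
    if (length(carried) > 0L) {
      planted <- vapply(alleles[carried], `[[`, TRUE, "planted")
      # dropout is drawn once per locus (not per allele) for this individual
      loci_here <- vapply(alleles[carried], `[[`, "", "locus_id")
      uloc <- unique(loci_here[!planted])
      dropped <- uloc[stats::runif(length(uloc)) < p$dropout_rate]
      depths[!planted] <- stats::rpois(sum(!planted), p$mean_depth)
      depths[loci_here %in% dropped] <- 0L
      depths[planted] <- if (sex == p$planted_fp_low_sex) {
        p$planted_fp_depth
      } else {
        as.integer(round(p$mean_depth))
      }
    }
    tag_seqs <- vapply(alleles[carried], `[[`, "", "tag")
    seqs <- rep(paste0(bc, p$overhang, tag_seqs), depths)
    n_reads <- length(seqs)
    if (n_reads > 0L && p$error_rate > 0) {
      n_err <- stats::rbinom(n_reads, read_len - p$barcode_length,
                             p$error_rate)
      for (i in which(n_err > 0L)) {
        seqs[i] <- mutate_positions(seqs[i], n_err[i],
                                    p$barcode_length + 1L, read_len)
      }
    }
    quals <- rep(base_qual, n_reads)
    if (n_reads > 0L && p$lowq_read_rate > 0) {
      hit <- which(stats::runif(n_reads) < p$lowq_read_rate)
      for (i in hit) {
        w <- min(15L, read_len)
        start <- sample(read_len - w + 1L, 1L)
        substr(quals[i], start, start + w - 1L) <- strrep("#", w)
      }
    }
    reads <- data.frame(
      id = sprintf("%s_%06d", sid, seq_len(n_reads)),
      seq = seqs, qual = quals, stringsAsFactors = FALSE
    )
    f <- file.path(dir, "reads", paste0(sid, ".fq", if (gzip) ".gz" else ""))
    write_fastq(reads, f)
    sample_files[sid] <- f
    pooled[[j]] <- reads
  }

  pooled_file <- file.path(dir, paste0("raw_reads.fq", if (gzip) ".gz" else ""))
  write_fastq(do.call(rbind, pooled), pooled_file)
  sheet_file <- file.path(dir, "samples.tsv")
  write_sample_sheet(sheet, sheet_file)
  truth_file <- file.path(dir, "truth.tsv")
  write_truth(truth, truth_file)

  structure(list(
    params = p, sheet = sheet, truth = truth, dir = dir,
    sample_files = sample_files, pooled_file = pooled_file,
    sheet_file = sheet_file, truth_file = truth_file,
    planted_fp_ids = planted_ids
  ), class = "rad_sim")
}

#' @export
print.rad_sim <- function(x, ...) {
  p <- x$params
  cat("Synthetic RADseq dataset (", p$system, " system)\n", sep = "")
  cat("  individuals: ", p$n_males, " M + ", p$n_females, " F\n", sep = "")
  cat("  loci: ", p$n_autosomal_loci, " autosomal, ",
      p$n_sexlimited_loci, " sex-limited, ",
      p$n_gametolog_pairs, " gametolog pairs",
      if (p$n_planted_fp > 0) paste0(", ", p$n_planted_fp, " planted FP"),
      "\n", sep = "")
  cat("  directory: ", x$dir, "\n", sep = "")
  invisible(x)
}

#' Write a ground-truth table
#'
#' One row per allele: `locus_id`, `class` (AUTOSOMAL, SEXLIMITED,
#' GAMETOLOG_SHARED, GAMETOLOG_SEXLIMITED), `allele` index, post-barcode
#' `sequence` (overhang + tag), and the comma-separated `carriers`.
#'
#' @param truth Truth data.frame as in a `rad_sim` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  req <- c("locus_id", "class", "allele", "sequence", "carriers")
  if (!is.data.frame(truth) || !all(req %in% names(truth))) {
    stop("truth must be a data.frame with columns: ",
         paste(req, collapse = ", "))
  }
  if (nrow(truth) == 0L) stop("refusing to write an empty truth table")
  utils::write.table(truth[, req], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a ground-truth table written by [write_truth()]
#' @param path TSV path.
#' @return The truth data.frame.
#' @export
read_truth <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "integer",
                                         "character", "character"),
                          comment.char = "#")
  if (nrow(df) == 0L) stop("empty truth table: ", path)
  bad <- setdiff(df$class, c("AUTOSOMAL", "SEXLIMITED", "GAMETOLOG_SHARED",
                             "GAMETOLOG_SEXLIMITED"))
  if (length(bad) > 0L) {
    stop("unknown truth class: ", paste(bad, collapse = ", "))
  }
  df
}
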