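# Shared fixture builders (everything is generated in code at test time).

# Small, fast simulation settings for property-style tests.
tiny_params <- function(system = "XY", seed = 1, ...) {
  args <- list(
    n_males = 4, n_females = 4, system = system,
    n_autosomal_loci = 25,
    n_sexlimited_loci = if (system == "NONE") 0 else 4,
    n_gametolog_pairs = if (system == "NONE") 0 else 1,
    tag_length = 80, mean_depth = 10, seed = seed
  )
  do.call(sim_params, utils::modifyList(args, list(...)))
}

# Run the post-sequencing stages (demux -> tags -> loci -> matrix) on a
# simulated dataset; returns the pieces the sex-marker stage needs.
run_core_stages <- function(sim, min_depth = 5, max_allele_mismatch = 3) {
  demux <- demultiplex(sim$pooled_file, sim$sheet,
                       overhang = sim$params$overhang,
                       out_dir = file.path(sim$dir, "demux"))
  tags <- do.call(rbind, lapply(sim$sheet$sample_id, function(sid) {
    call_tags(demux$files[[sid]], sid, min_depth = min_depth)
  }))
  loci <- cluster_loci(tags, max_allele_mismatch = max_allele_mismatch)
  pres <- presence_matrix(loci, sim$sheet)
  list(demux = demux, tags = tags, loci = loci, pres = pres)
}

# Hand-built confirmed marker set for call_system tests.
make_markers <- function(n_male, n_female) {
  n <- n_male + n_female
  df <- data.frame(
    locus_id = sprintf("C%05d", seq_len(n)),
    specificity = c(rep("MALE", n_male), rep("FEMALE", n_female)),
    n_carriers = rep(5L, n),
    confirmed = rep(TRUE, n),
    stringsAsFactors = FALSE
  )
  class(df) <- c("sex_markers", "data.frame")
  df
}

# Two-sample sheet reused across demux and error-path tests.
sheet2 <- data.frame(
  sample_id = c("s1", "s2"),
  barcode = c("ACGTAA", "ACGGTT"),
  sex = c("M", "F"),
  stringsAsFactors = FALSE
)

# A minimal FASTQ on disk from sequences (constant high quality).
write_test_fastq <- function(seqs, path, ids = NULL) {
  reads <- data.frame(
    id = ids %||% sprintf("r%04d", seq_along(seqs)),
    seq = seqs,
    qual = strrep("I", nchar(seqs)),
    stringsAsFactors = FALSE
  )
  radsexmark::write_fastq(reads, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a
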