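#' Build and validate a pipeline configuration
#'
#' Every tunable of the pipeline stages lives in one validated list, and the
#' full configuration is stamped into `summary.json` so that every reported
#' count is auditable against the parameters that produced it. Unknown keys
#' are rejected (a typo must not silently fall back to a default).
#'
#' @param ... Named overrides of the defaults, or a single named list.
#'   Keys: `sim` (list of [sim_params()] arguments, or NULL to start from
#'   existing files), `reads` (pooled FASTQ path(s)), `sheet` (sample sheet
#'   path), `overhang`, `allow_barcode_mismatch`, `qual_window`,
#'   `qual_threshold`, `min_depth`, `max_allele_mismatch`, `min_carriers`
#'   (NULL = ceiling of half of the specific sex), `max_mismatches`,
#'   `min_markers`, `evalue_max`, `alpha`, `adjust`, `seed`, `synteny`
#'   (list with `m2t`, `t2g`, `annotation` paths, or NULL to skip the
#'   stage).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    sim = NULL, reads = NULL, sheet = NULL,
    overhang = "TGCAGG", allow_barcode_mismatch = 1L,
    qual_window = 15L, qual_threshold = 10,
    min_depth = 5L, max_allele_mismatch = 3L,
    min_carriers = NULL, max_mismatches = 0L, min_markers = 1L,
    evalue_max = 1e-10, alpha = 0.05, adjust = "none",
    seed = 1L, synteny = NULL
  )
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) && is.list(dots[[1L]])) {
    dots <- dots[[1L]]
  }
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, dots, keep.null = TRUE)

  if (is.null(cfg$sim) && (is.null(cfg$reads) || is.null(cfg$sheet))) {
    stop("config needs either 'sim' parameters or 'reads' + 'sheet' paths")
  }
  if (cfg$min_depth < 1) stop("min_depth must be >= 1")
  if (cfg$qual_window < 1) stop("qual_window must be >= 1")
  if (cfg$max_allele_mismatch < 0) stop("max_allele_mismatch must be >= 0")
  if (cfg$allow_barcode_mismatch < 0) {
    stop("allow_barcode_mismatch must be >= 0")
  }
  if (cfg$max_mismatches < 0) stop("max_mismatches must be >= 0")
  if (cfg$min_markers < 1) stop("min_markers must be >= 1")
  if (!is.null(cfg$min_carriers) && cfg$min_carriers < 1) {
    stop("min_carriers must be >= 1 (or NULL for the per-sex default)")
  }
  if (cfg$evalue_max <= 0) stop("evalue_max must be > 0")
  if (cfg$alpha <= 0 || cfg$alpha > 1) stop("alpha must be in (0, 1]")
  if (!cfg$adjust %in% c("none", "bonferroni")) {
    stop("adjust must be 'none' or 'bonferroni'")
  }
  if (!is.null(cfg$synteny)) {
    req <- c("m2t", "t2g", "annotation")
    if (!all(req %in% names(cfg$synteny))) {
      stop("synteny config needs keys: ", paste(req, collapse = ", "))
    }
  }
  if (!is.null(cfg$sim)) {
    if (is.null(cfg$sim$seed)) cfg$sim$seed <- cfg$seed
    cfg$sim <- as.list(do.call(sim_params, cfg$sim))  # validate early
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML path.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

#' Run the full sex-marker discovery pipeline
#'
#' Stages, in order: (optional) read simulation, demultiplexing + quality
#' filtering, per-individual RAD-tag calling, locus clustering with the
#' two-alleles filter, putative sex-marker identification, raw-read
#' confirmation, heterogamety system call, and (optional) synteny
#' enrichment. Intermediate artifacts land on disk under `out_dir`, and a
#' machine-readable `summary.json` records counts at each stage. Rerunning
#' with an identical configuration reproduces identical outputs.
#'
#' @param config A `pipeline_config` (or a list accepted by
#'   [pipeline_config()]).
#' @param out_dir Output directory.
#' @param quiet Suppress per-stage progress messages.
#' @return An object of class `rad_run`: list with `dir`, `config`, `sim`
#'   (if simulated), `demux`, `loci`, `presence`, `markers`, `system`,
#'   `enrichment` (if run), and `summary` (the list written as
#'   `summary.json`).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) {
    config <- pipeline_config(config)
  }
  cfg <- config
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[radsexmark] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed (outputs under ", out_dir,
           "): ", conditionMessage(e), call. = FALSE)
    })
  }
  summary <- list(config = config_stamp(cfg))

  sim <- NULL
  if (!is.null(cfg$sim)) {
    say("simulating reads")
    sim <- stage("simulate", {
      simulate_rad_dataset(do.call(sim_params, cfg$sim),
                           file.path(out_dir, "sim"))
    })
    reads <- sim$pooled_file
    sheet <- sim$sheet
    summary$simulate <- list(
      system = sim$params$system,
      n_individuals = nrow(sim$sheet),
      n_truth_loci = length(unique(sim$truth$locus_id)),
      n_reads = nrow(read_fastq(sim$pooled_file))
    )
  } else {
    reads <- cfg$reads
    sheet <- stage("read_sheet", read_sample_sheet(cfg$sheet))
  }

  say("demultiplexing")
  demux <- stage("demultiplex", {
    demultiplex(reads, sheet, overhang = cfg$overhang,
                allow_barcode_mismatch = cfg$allow_barcode_mismatch,
                qual_window = cfg$qual_window,
                qual_threshold = cfg$qual_threshold,
                out_dir = file.path(out_dir, "demux"))
  })
  write_demux_report(demux, file.path(out_dir, "demux_report.tsv"))
  summary$demultiplex <- list(
    n_input = demux$n_input,
    n_retained = sum(demux$per_sample$n_retained),
    dropped = as.list(demux$dropped)
  )

  say("calling RAD tags and clustering loci")
  tags <- stage("call_tags", {
    do.call(rbind, lapply(sheet$sample_id, function(sid) {
      call_tags(demux$files[[sid]], sid, min_depth = cfg$min_depth)
    }))
  })
  loci <- stage("cluster_loci", {
    cluster_loci(tags, max_allele_mismatch = cfg$max_allele_mismatch)
  })
  pres <- stage("presence_matrix", presence_matrix(loci, sheet))
  write_loci(loci, pres, file.path(out_dir, "loci.fasta"),
             file.path(out_dir, "presence_matrix.tsv"))
  summary$loci <- list(
    n_tags = nrow(tags),
    n_loci = nrow(loci$loci),
    n_retained = sum(!loci$loci$excluded),
    n_excluded = sum(loci$loci$excluded),
    min_depth = cfg$min_depth
  )

  say("identifying and confirming sex-specific markers")
  markers <- stage("find_putative", {
    find_putative(pres, min_carriers = cfg$min_carriers)
  })
  markers <- stage("confirm", {
    confirm_markers(markers, loci, demux$files, sheet,
                    max_mismatches = cfg$max_mismatches)
  })
  syscall <- stage("call_system", call_system(markers, cfg$min_markers))
  write_markers(markers, loci, out_dir)
  jsonlite::write_json(
    list(system = syscall$system,
         n_male_specific_confirmed = syscall$n_male_specific_confirmed,
         n_female_specific_confirmed = syscall$n_female_specific_confirmed),
    file.path(out_dir, "system_call.json"), auto_unbox = TRUE, pretty = TRUE)
  summary$sexmarkers <- list(
    n_putative = nrow(markers),
    n_putative_male = sum(markers$specificity == "MALE"),
    n_putative_female = sum(markers$specificity == "FEMALE"),
    n_confirmed = sum(markers$confirmed),
    n_confirmed_male = syscall$n_male_specific_confirmed,
    n_confirmed_female = syscall$n_female_specific_confirmed,
    system = syscall$system
  )

  enrichment <- NULL
  if (!is.null(cfg$synteny)) {
    say("synteny enrichment")
    enrichment <- stage("synteny", {
      annot <- read_annotation(cfg$synteny$annotation)
      chains <- resolve_hits(cfg$synteny$m2t, cfg$synteny$t2g,
                             evalue_max = cfg$evalue_max,
                             annotation = annot)
      enrichment_table(chains, annot, alpha = cfg$alpha,
                       adjust = cfg$adjust)
    })
    write_enrichment(enrichment, file.path(out_dir, "enrichment.tsv"))
    summary$synteny <- list(
      n_unique_genes = attr(enrichment, "n_genes"),
      top_chromosome = attr(enrichment, "top"),
      top_p = as.data.frame(enrichment)$p[1L],
      top_significant = attr(enrichment, "top_significant")
    )
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  structure(list(dir = out_dir, config = cfg, sim = sim, demux = demux,
                 loci = loci, presence = pres, markers = markers,
                 system = syscall, enrichment = enrichment,
                 summary = summary),
            class = "rad_run")
}

#' @noRd
#' Configuration as stamped into summary.json: scalar keys only, no
#' absolute paths (so reruns into different directories are byte-identical).
config_stamp <- function(cfg) {
  keep <- c("overhang", "allow_barcode_mismatch", "qual_window",
            "qual_threshold", "min_depth", "max_allele_mismatch",
            "min_carriers", "max_mismatches", "min_markers", "evalue_max",
            "alpha", "adjust", "seed")
  stamp <- cfg[keep]
  stamp$min_carriers <- cfg$min_carriers %||% "auto"
  if (!is.null(cfg$sim)) {
    stamp$sim <- cfg$sim[setdiff(names(cfg$sim), character(0))]
  }
  stamp
}

#' @export
print.rad_run <- function(x, ...) {
  cat("radsexmark pipeline run:", x$dir, "\n")
  s <- x$summary
  if (!is.null(s$simulate)) {
    cat("  simulated:", s$simulate$n_reads, "reads,",
        s$simulate$n_truth_loci, "truth loci (system",
        s$simulate$system, ")\n")
  }
  cat("  demux: ", s$demultiplex$n_retained, "/", s$demultiplex$n_input,
      " reads retained\n", sep = "")
  cat("  loci: ", s$loci$n_retained, " retained (",
      s$loci$n_excluded, " excluded)\n", sep = "")
  cat("  markers: ", s$sexmarkers$n_putative, " putative, ",
      s$sexmarkers$n_confirmed, " confirmed (",
      s$sexmarkers$n_confirmed_male, " male-specific, ",
      s$sexmarkers$n_confirmed_female, " female-specific)\n", sep = "")
  cat("  system call:", s$sexmarkers$system, "\n")
  if (!is.null(s$synteny)) {
    cat("  synteny top chromosome:", s$synteny$top_chromosome,
        "(p =", format(s$synteny$top_p), ")\n")
  }
  invisible(x)
}

#' Evaluate a pipeline run against the simulator's ground truth
#'
#' Confirmed markers are matched to truth loci by allele sequence (cluster
#' ids and truth ids are independent namespaces). Sensitivity is the
#' fraction of truly sex-limited (SEXLIMITED) loci recovered as confirmed
#' markers of the correct specificity; specificity is the fraction of
#' autosomal truth loci *not* reported as confirmed sex-specific.
#' Gametolog-derived sex-limited alleles are genuinely sex-linked, so
#' recovering them counts neither for nor against these two rates.
#'
#' @param run A `rad_run` object (must include marker results).
#' @param truth Truth data.frame or path to a `truth.tsv`; defaults to the
#'   run's own simulation.
#' @return List with `sensitivity`, `specificity`, `system_correct`,
#'   `n_sexlimited`, `n_recovered`, `n_autosomal`, `n_false_positive`,
#'   `false_positive_loci`.
#' @export
evaluate_run <- function(run, truth = NULL) {
  stopifnot(inherits(run, "rad_run"))
  if (is.null(truth)) {
    if (is.null(run$sim)) stop("no truth table: supply 'truth'")
    truth <- run$sim$truth
  } else if (is.character(truth)) {
    truth <- read_truth(truth)
  }
  run_seqs <- run$loci$alleles$sequence
  if (!any(truth$sequence %in% run_seqs)) {
    stop("truth table does not match this run: no truth sequence appears ",
         "among the called alleles")
  }

  het_sex <- if (!is.null(run$sim)) {
    switch(run$sim$params$system, XY = "MALE", ZW = "FEMALE",
           NONE = NA_character_)
  } else NA_character_

  conf <- as.data.frame(run$markers)
  conf <- conf[which(conf$confirmed), , drop = FALSE]
  allele_seqs <- split(run$loci$alleles$sequence, run$loci$alleles$locus_id)
  conf_seqs_by_spec <- lapply(c(MALE = "MALE", FEMALE = "FEMALE"),
    function(sp) {
      unlist(allele_seqs[conf$locus_id[conf$specificity == sp]],
             use.names = FALSE)
    })

  sl <- truth[truth$class == "SEXLIMITED", , drop = FALSE]
  n_sl <- length(unique(sl$locus_id))
  recovered <- if (n_sl > 0L && !is.na(het_sex)) {
    hit <- sl$sequence %in% conf_seqs_by_spec[[het_sex]]
    length(unique(sl$locus_id[hit]))
  } else 0L

  auto <- truth[truth$class == "AUTOSOMAL", , drop = FALSE]
  n_auto <- length(unique(auto$locus_id))
  all_conf_seqs <- unlist(conf_seqs_by_spec, use.names = FALSE)
  fp_loci <- unique(auto$locus_id[auto$sequence %in% all_conf_seqs])

  truth_system <- if (!is.null(run$sim)) run$sim$params$system else NA
  list(
    sensitivity = if (n_sl > 0L) recovered / n_sl else NA_real_,
    specificity = if (n_auto > 0L) 1 - length(fp_loci) / n_auto else
      NA_real_,
    system_correct = if (!is.na(truth_system)) {
      identical(run$system$system, truth_system) ||
        (truth_system == "NONE" && run$system$system == "UNRESOLVED")
    } else NA,
    n_sexlimited = n_sl,
    n_recovered = recovered,
    n_autosomal = n_auto,
    n_false_positive = length(fp_loci),
    false_positive_loci = fp_loci
  )
}
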