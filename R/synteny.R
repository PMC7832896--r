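#' Read a 12-column BLAST tabular file (outfmt 6 layout)
#'
#' Columns: qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend,
#' sstart, send, evalue, bitscore. BLAST is consumed, never invoked — the
#' synteny stage's contract starts at tabular files, which keeps it hermetic
#' with respect to external database versions. A row with the wrong field
#' count is a hard error naming the line.
#'
#' @param path TSV path (comment lines starting `#` allowed).
#' @return Data.frame with the 12 standard columns.
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) stop("BLAST tabular file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  content <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[content], "\t", fixed = TRUE))
  if (any(nf != 12L)) {
    bad <- which(content)[which(nf != 12L)[1L]]
    stop("malformed BLAST tabular row at line ", bad, " of ", path,
         " (expected 12 tab-separated fields, found ",
         nf[which(nf != 12L)[1L]], ")")
  }
  df <- utils::read.table(
    path, sep = "\t", comment.char = "#", stringsAsFactors = FALSE,
    col.names = c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore"),
    colClasses = c("character", "character", "numeric", "integer",
                   "integer", "integer", "integer", "integer", "integer",
                   "integer", "numeric", "numeric")
  )
  df
}

#' @noRd
#' Best hit per query: lowest e-value, ties broken by higher bitscore then
#' lexicographic subject id.
best_hit_per_query <- function(hits) {
  ord <- order(hits$qseqid, hits$evalue, -hits$bitscore, hits$sseqid)
  h <- hits[ord, , drop = FALSE]
  h[!duplicated(h$qseqid), , drop = FALSE]
}

#' Chain two-step BLAST hits: marker -> transcript -> gene
#'
#' For each sex-specific marker, keeps its best transcript hit and chains it
#' to that transcript's best gene hit; chains failing `evalue_max` at either
#' step are dropped. Using a transcriptome of a related species as an
#' intermediary lets short RAD markers reach an annotated reference genome
#' that is too diverged for direct nucleotide BLAST.
#'
#' @param markers_vs_transcripts,transcripts_vs_genes BLAST tabular paths or
#'   data.frames from [read_blast_tab()].
#' @param evalue_max Maximum e-value accepted at each step.
#' @param annotation Optional [read_annotation()] object with a gene map, to
#'   attach each gene's chromosome.
#' @return Data.frame of hit chains: `marker_id`, `transcript_id`,
#'   `gene_id`, `chromosome` (NA without a gene map), `evalue_m2t`,
#'   `evalue_t2g`; one row per marker. Distinct markers may share a gene;
#'   the unique-gene collapse happens in [enrichment_table()].
#' @export
resolve_hits <- function(markers_vs_transcripts, transcripts_vs_genes,
                         evalue_max = 1e-10, annotation = NULL) {
  m2t <- if (is.character(markers_vs_transcripts)) {
    read_blast_tab(markers_vs_transcripts)
  } else markers_vs_transcripts
  t2g <- if (is.character(transcripts_vs_genes)) {
    read_blast_tab(transcripts_vs_genes)
  } else transcripts_vs_genes

  m2t <- m2t[m2t$evalue <= evalue_max, , drop = FALSE]
  t2g <- t2g[t2g$evalue <= evalue_max, , drop = FALSE]
  best_m <- best_hit_per_query(m2t)
  best_t <- best_hit_per_query(t2g)

  idx <- match(best_m$sseqid, best_t$qseqid)
  keep <- !is.na(idx)
  chains <- data.frame(
    marker_id = best_m$qseqid[keep],
    transcript_id = best_m$sseqid[keep],
    gene_id = best_t$sseqid[idx[keep]],
    chromosome = NA_character_,
    evalue_m2t = best_m$evalue[keep],
    evalue_t2g = best_t$evalue[idx[keep]],
    stringsAsFactors = FALSE
  )
  chains <- chains[order(chains$marker_id), , drop = FALSE]
  rownames(chains) <- NULL
  if (!is.null(annotation)) {
    stopifnot(inherits(annotation, "annotation_table"))
    if (is.null(annotation$gene_map)) {
      stop("annotation has no per-gene chromosome map; supply the ",
           "gene_id<TAB>chromosome form")
    }
    chains$chromosome <- unname(annotation$gene_map[chains$gene_id])
  }
  chains
}

#' Read a per-chromosome gene annotation table
#'
#' Two accepted TSV forms: `chromosome<TAB>gene_count` (counts only) or
#' `gene_id<TAB>chromosome` (per-gene map, from which counts are tallied).
#' The second form additionally enables chromosome lookup for BLAST-hit
#' genes.
#'
#' @param path TSV path (optional header; `#` comments allowed).
#' @return An object of class `annotation_table`: list with `counts` (named
#'   integer vector per chromosome), `N` (total annotated genes), and
#'   `gene_map` (named chromosome vector per gene, or NULL for the counts
#'   form).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) != 2L) stop("annotation must have exactly 2 columns")
  # optional header
  hdr <- tolower(unlist(df[1L, ]))
  if (any(hdr %in% c("chromosome", "gene_id", "gene_count", "chrom"))) {
    df <- df[-1L, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("empty annotation table: ", path)
  if (all(grepl("^[0-9]+$", df[[2L]]))) {
    counts <- stats::setNames(as.integer(df[[2L]]), df[[1L]])
    if (anyDuplicated(names(counts))) {
      stop("duplicate chromosome in annotation counts")
    }
    gene_map <- NULL
  } else {
    if (anyDuplicated(df[[1L]])) stop("duplicate gene_id in annotation")
    gene_map <- stats::setNames(df[[2L]], df[[1L]])
    tab <- table(gene_map)
    counts <- stats::setNames(as.integer(tab), names(tab))
  }
  if (any(counts < 0L)) stop("annotation gene counts must be >= 0")
  N <- sum(counts)
  if (N <= 0L) stop("annotation must contain at least one gene")
  structure(list(counts = counts, N = N, gene_map = gene_map),
            class = "annotation_table")
}

#' Hypergeometric upper-tail probability P(X >= k)
#'
#' Exact upper tail of the hypergeometric distribution: the probability of
#' observing at least `k` category members among `n` draws without
#' replacement from a population of `N` containing `K` category members.
#' Computed in log space from exact log-binomial coefficients
#' (log-factorials) with a log-sum-exp reduction, so extreme tails (p well
#' below 1e-20) keep full relative precision. `k = 0` gives 1;
#' `k > min(K, n)` gives 0.
#'
#' @param k Observed category count (vectorised).
#' @param N Population size.
#' @param K Category size in the population.
#' @param n Number of draws.
#' @return `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#' @export
hypergeom_sf <- function(k, N, K, n) {
  if (length(N) != 1L || length(K) != 1L || length(n) != 1L) {
    stop("N, K, n must be scalars")
  }
  if (is.na(N) || is.na(K) || is.na(n) || N < 0 || K < 0 || K > N ||
      n < 0 || n > N) {
    stop("require 0 <= K <= N and 0 <= n <= N")
  }
  if (any(is.na(k)) || any(k < 0)) stop("require k >= 0")
  vapply(k, function(ki) {
    hi <- min(K, n)
    if (ki <= 0) return(1)
    if (ki > hi) return(0)
    i <- ki:hi
    lg <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
    m <- max(lg)
    min(exp(m) * sum(exp(lg - m)), 1)
  }, numeric(1))
}

#' Per-chromosome enrichment of BLAST-hit genes
#'
#' Tests, for every chromosome of the annotation, whether the sex-specific
#' markers hit more genes there than expected if hits fell proportionally
#' to each chromosome's annotated gene count. Genes hit by several markers
#' count once (the draws are genes, not markers). For chromosome with `K`
#' of the `N` annotated genes and `k` of the `n` unique hit genes observed:
#' expected = `n * K / N` and p = `P(X >= k)` under
#' Hypergeometric(N, K, n) — the one-sided "more genes than expected"
#' question.
#'
#' @param chains Hit-chain data.frame from [resolve_hits()]; `chromosome`
#'   must be resolvable (from the chains or the annotation's gene map).
#' @param annotation An `annotation_table`.
#' @param alpha Significance level for the top call.
#' @param adjust Multiple-testing rule across chromosomes: `"none"`
#'   (raw p-values) or `"bonferroni"`.
#' @return An object of class `synteny_enrichment`: data.frame with one row
#'   per chromosome (`chromosome`, `observed`, `expected`, `p`, `p_adj`,
#'   `significant`), sorted by p ascending then chromosome; attributes
#'   `n_genes`, `N`, `top` (lowest-p chromosome) and `top_significant`.
#' @export
enrichment_table <- function(chains, annotation, alpha = 0.05,
                             adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(annotation, "annotation_table"))
  if (nrow(chains) == 0L) stop("no hit chains; need at least one gene")
  chrom <- chains$chromosome
  if (any(is.na(chrom))) {
    if (is.null(annotation$gene_map)) {
      stop("chains carry no chromosome and annotation has no gene map")
    }
    chrom <- unname(annotation$gene_map[chains$gene_id])
  }
  genes <- chains$gene_id
  first <- !duplicated(genes)
  genes <- genes[first]
  chrom <- chrom[first]
  if (any(is.na(chrom))) {
    stop("gene(s) missing from annotation: ",
         paste(genes[is.na(chrom)], collapse = ", "))
  }
  unknown <- setdiff(unique(chrom), names(annotation$counts))
  if (length(unknown) > 0L) {
    stop("gene(s) on chromosome(s) absent from annotation: ",
         paste(unknown, collapse = ", "))
  }
  n <- length(genes)
  N <- annotation$N
  if (n > N) stop("more unique hit genes than annotated genes")

  chroms <- names(annotation$counts)
  obs <- as.integer(table(factor(chrom, levels = chroms)))
  K <- as.integer(annotation$counts)
  tab <- data.frame(
    chromosome = chroms,
    observed = obs,
    expected = n * K / N,
    p = mapply(function(k, Kc) hypergeom_sf(k, N, Kc, n), obs, K),
    stringsAsFactors = FALSE
  )
  tab$p_adj <- if (adjust == "bonferroni") {
    pmin(tab$p * nrow(tab), 1)
  } else {
    tab$p
  }
  tab$significant <- tab$p_adj < alpha
  tab <- tab[order(tab$p, tab$chromosome), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("synteny_enrichment", "data.frame"),
            n_genes = n, N = N, alpha = alpha, adjust = adjust,
            top = tab$chromosome[1L], top_significant = tab$significant[1L])
}

#' @export
print.synteny_enrichment <- function(x, ...) {
  cat("Synteny enrichment over ", attr(x, "n_genes"),
      " unique genes (annotation: ", attr(x, "N"), " genes on ",
      nrow(x), " chromosomes)\n", sep = "")
  cat("  top chromosome: ", attr(x, "top"),
      if (attr(x, "top_significant")) " (significant at alpha=" else
        " (not significant at alpha=",
      attr(x, "alpha"), ")\n", sep = "")
  df <- as.data.frame(x)
  df$expected <- round(df$expected, 3)
  df$p <- signif(df$p, 4)
  df$p_adj <- signif(df$p_adj, 4)
  print(utils::head(df, 10), row.names = FALSE)
  if (nrow(df) > 10L) cat("  ... and", nrow(df) - 10L, "more chromosomes\n")
  invisible(x)
}

#' Bar-plot of observed versus expected genes per chromosome
#'
#' @param x A `synteny_enrichment` object.
#' @param n_chrom Show the first `n_chrom` chromosomes in annotation order.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the matrix plotted.
#' @export
plot.synteny_enrichment <- function(x, n_chrom = nrow(x), ...) {
  df <- as.data.frame(x)
  df <- df[order(df$chromosome), , drop = FALSE]
  df <- utils::head(df, n_chrom)
  m <- rbind(observed = df$observed, expected = df$expected)
  colnames(m) <- df$chromosome
  graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                    col = c("black", "grey70"),
                    ylab = "genes with BLAST hit", las = 2, ...)
  invisible(m)
}

#' Write the enrichment table (with observed/expected bar-plot data)
#' @param enrichment A `synteny_enrichment` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(enrichment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  stamp_header(con, list(n_genes = attr(enrichment, "n_genes"),
                         N = attr(enrichment, "N"),
                         alpha = attr(enrichment, "alpha"),
                         adjust = attr(enrichment, "adjust"),
                         top = attr(enrichment, "top")))
  utils::write.table(as.data.frame(enrichment), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
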