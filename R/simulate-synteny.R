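#' Simulate two-step BLAST hit tables and an annotation (synthetic fixture)
#'
#' Builds a fully synthetic input set for the synteny stage: an annotation
#' of `n_chromosomes` chromosomes with `genes_per_chr` genes each
#' (gene_id -> chromosome form), plus marker->transcript and
#' transcript->gene BLAST tabular files in which `n_on_target` of the
#' `n_genes` unique hit genes lie on `target_chr` and the remainder are
#' spread one per other chromosome. Optionally some genes are hit by two
#' markers (`n_redundant_markers`), exercising the unique-gene collapse.
#' All identifiers are synthetic; e-values/bitscores are fixed well inside
#' any sensible threshold.
#'
#' @param dir Output directory.
#' @param n_genes Unique genes hit.
#' @param n_on_target How many of them lie on the target chromosome.
#' @param n_chromosomes Chromosomes in the annotation.
#' @param genes_per_chr Annotated genes per chromosome (so the target holds
#'   `1 / n_chromosomes` of the annotation when uniform).
#' @param target_chr Index (1-based) of the target chromosome.
#' @param n_redundant_markers Extra markers that re-hit already-hit genes.
#' @return List of paths: `m2t`, `t2g`, `annotation`, plus `target` (the
#'   target chromosome name).
#' @export
simulate_synteny_hits <- function(dir, n_genes = 38, n_on_target = 19,
                                  n_chromosomes = 38, genes_per_chr = 20,
                                  target_chr = 10,
                                  n_redundant_markers = 0) {
  if (n_on_target > n_genes) stop("n_on_target must be <= n_genes")
  if (n_genes - n_on_target > n_chromosomes - 1L) {
    stop("too many off-target genes for one-per-chromosome placement")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  chroms <- sprintf("chr%02d", seq_len(n_chromosomes))
  target <- chroms[target_chr]

  gene_id <- sprintf("gene_%s_%03d",
                     rep(chroms, each = genes_per_chr),
                     rep(seq_len(genes_per_chr), n_chromosomes))
  gene_chrom <- rep(chroms, each = genes_per_chr)
  annot_path <- file.path(dir, "annotation.tsv")
  utils::write.table(
    data.frame(gene_id = gene_id, chromosome = gene_chrom),
    annot_path, sep = "\t", quote = FALSE, row.names = FALSE)

  on_target <- gene_id[gene_chrom == target][seq_len(n_on_target)]
  other_chroms <- setdiff(chroms, target)[seq_len(n_genes - n_on_target)]
  off_target <- gene_id[match(other_chroms, gene_chrom)]
  hit_genes <- c(on_target, off_target)

  markers <- sprintf("marker%03d", seq_len(n_genes + n_redundant_markers))
  transcripts <- sprintf("transcript%03d",
                         seq_len(n_genes + n_redundant_markers))
  gene_of_marker <- c(hit_genes,
                      hit_genes[seq_len(n_redundant_markers)])

  blast_row <- function(q, s, evalue, bitscore) {
    data.frame(qseqid = q, sseqid = s, pident = 98.0, length = 140L,
               mismatch = 2L, gapopen = 0L, qstart = 1L, qend = 140L,
               sstart = 1L, send = 140L, evalue = evalue,
               bitscore = bitscore, stringsAsFactors = FALSE)
  }
  m2t <- blast_row(markers, transcripts, 1e-40, 250)
  t2g <- blast_row(transcripts, gene_of_marker, 1e-30, 200)

  m2t_path <- file.path(dir, "markers_vs_transcripts.tsv")
  t2g_path <- file.path(dir, "transcripts_vs_genes.tsv")
  utils::write.table(m2t, m2t_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(t2g, t2g_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  list(m2t = m2t_path, t2g = t2g_path, annotation = annot_path,
       target = target)
}
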