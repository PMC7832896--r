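test_that("hypergeometric upper tail matches exhaustive draw enumeration on the worked case", {
  # all C(10,4) = 210 draws from a population of 10 with 3 marked items
  expect_equal(draw_enum_sf(2, 10, 3, 4), 1 / 3)
  expect_equal(hypergeom_sf(2, 10, 3, 4), 1 / 3)
  expect_equal(hypergeom_sf(0, 10, 3, 4), 1)
  expect_equal(hypergeom_sf(4, 10, 3, 4), 0)  # k > K
})

test_that("hypergeometric tail handles edge cases and rejects bad input", {
  expect_equal(hypergeom_sf(5, 20, 20, 5), 1)   # K = N: certain event
  expect_equal(hypergeom_sf(3, 20, 5, 0), 0)    # no draws
  expect_equal(hypergeom_sf(0, 20, 5, 0), 1)
  expect_error(hypergeom_sf(1, 10, 11, 4), "K <= N")
  expect_error(hypergeom_sf(1, 10, 3, 11), "n <= N")
  expect_error(hypergeom_sf(-1, 10, 3, 4), "k >= 0")
})

test_that("hypergeometric tail agrees with the distribution's survival function and is monotone", {
  set.seed(4)
  for (rep in 1:40) {
    N <- sample(2:80, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    ks <- 0:(min(K, n) + 1L)
    mine <- hypergeom_sf(ks, N, K, n)
    ref <- stats::phyper(ks - 1, K, N - K, n, lower.tail = FALSE)
    expect_equal(mine, ref, tolerance = 1e-12)
    expect_true(all(diff(mine) <= 1e-15))
    # pmf recovered from tail differences sums to one over the support
    pmf <- mine[-length(mine)] - mine[-1]
    expect_equal(sum(pmf), 1 - mine[length(mine)], tolerance = 1e-12)
  }
})

test_that("BLAST tabular parsing is strict about the 12-column layout", {
  dir <- withr::local_tempdir()
  good <- file.path(dir, "good.tsv")
  writeLines(c(
    "# comment",
    paste(c("m1", "t1", "98.5", "140", "2", "0", "1", "140", "1", "140",
            "1e-30", "250"), collapse = "\t")), good)
  df <- read_blast_tab(good)
  expect_equal(nrow(df), 1L)
  expect_equal(df$evalue, 1e-30)
  expect_equal(df$qseqid, "m1")
  bad <- file.path(dir, "bad.tsv")
  writeLines(c(
    paste(rep("x", 12), collapse = "\t"),
    paste(rep("y", 11), collapse = "\t")), bad)
  expect_error(read_blast_tab(bad), "line 2")
})

test_that("hit chaining keeps the best transcript, drops weak chains, and collapses shared genes", {
  dir <- withr::local_tempdir()
  row <- function(q, s, e, b) {
    paste(c(q, s, "98", "140", "2", "0", "1", "140", "1", "140",
            format(e), format(b)), collapse = "\t")
  }
  m2t <- file.path(dir, "m2t.tsv")
  t2g <- file.path(dir, "t2g.tsv")
  writeLines(c(
    row("m1", "tGOOD", 1e-30, 200), row("m1", "tBAD", 1e-5, 100),
    row("m2", "tWEAK", 1e-30, 200),
    row("m3", "tSHARED", 1e-25, 180), row("m4", "tSHARED2", 1e-25, 180),
    row("m5", "tTIE", 1e-20, 150)), m2t)
  writeLines(c(
    row("tGOOD", "geneA", 1e-20, 150),
    row("tWEAK", "geneB", 1e-3, 50),        # fails evalue_max
    row("tSHARED", "geneC", 1e-22, 160),
    row("tSHARED2", "geneC", 1e-21, 155),   # same gene via another transcript
    row("tTIE", "geneD", 1e-15, 120), row("tTIE", "geneE", 1e-15, 120)),
    t2g)
  chains <- resolve_hits(m2t, t2g, evalue_max = 1e-10)
  expect_setequal(chains$marker_id, c("m1", "m3", "m4", "m5"))
  expect_equal(chains$transcript_id[chains$marker_id == "m1"], "tGOOD")
  expect_equal(chains$gene_id[chains$marker_id == "m1"], "geneA")
  # equal e-value and bitscore: lexicographic subject id wins
  expect_equal(chains$gene_id[chains$marker_id == "m5"], "geneD")
  # two markers on geneC collapse to one unique gene at enrichment
  ann <- file.path(dir, "ann.tsv")
  writeLines(c("gene_id\tchromosome", "geneA\tc1", "geneC\tc1",
               "geneD\tc2", paste0("geneX", 1:7, "\tc2")), ann)
  annot <- read_annotation(ann)
  e <- enrichment_table(chains, annot)
  expect_equal(attr(e, "n_genes"), 3L)
  expect_equal(sum(e$observed), 3L)
})

test_that("annotation tables load in both accepted forms", {
  dir <- withr::local_tempdir()
  counts <- file.path(dir, "counts.tsv")
  writeLines(c("chromosome\tgene_count", "c1\t10", "c2\t90"), counts)
  a1 <- read_annotation(counts)
  expect_equal(a1$N, 100L)
  expect_equal(unname(a1$counts["c1"]), 10L)
  expect_null(a1$gene_map)
  genes <- file.path(dir, "genes.tsv")
  writeLines(c("g1\tc1", "g2\tc1", "g3\tc2"), genes)
  a2 <- read_annotation(genes)
  expect_equal(a2$N, 3L)
  expect_equal(unname(a2$gene_map["g3"]), "c2")
  expect_error(read_annotation(file.path(dir, "nope.tsv")))
})

test_that("enrichment rows carry proportional expectations and exact tail p-values", {
  dir <- withr::local_tempdir()
  counts <- file.path(dir, "counts.tsv")
  writeLines(c("c1\t10", "c2\t90"), counts)
  annot <- read_annotation(counts)
  chains <- data.frame(
    gene_id = sprintf("g%02d", 1:20),
    chromosome = rep(c("c1", "c2"), c(2, 18)),
    stringsAsFactors = FALSE
  )
  e <- enrichment_table(chains, annot)
  expect_equal(e$expected[e$chromosome == "c1"], 2)
  expect_equal(sum(e$expected), 20, tolerance = 1e-9)
  expect_equal(sum(e$observed), 20L)

  # worked tail value: annotation {c1: 3, c2: 7}, n = 4 draws, k(c1) = 2
  writeLines(c("c1\t3", "c2\t7"), counts)
  annot2 <- read_annotation(counts)
  chains2 <- data.frame(gene_id = sprintf("g%d", 1:4),
                        chromosome = c("c1", "c1", "c2", "c2"))
  e2 <- enrichment_table(chains2, annot2)
  expect_equal(e2$p[e2$chromosome == "c1"], draw_enum_sf(2, 10, 3, 4))
  expect_equal(e2$p[e2$chromosome == "c1"], 1 / 3)

  # every gene on the only chromosome: the certain event, p = 1
  writeLines("c1\t50", counts)
  chains3 <- data.frame(gene_id = sprintf("g%d", 1:5), chromosome = "c1")
  e3 <- enrichment_table(chains3, read_annotation(counts))
  expect_equal(e3$p, 1)

  # a gene on an unannotated chromosome is a hard error
  chains4 <- data.frame(gene_id = "g1", chromosome = "cX")
  expect_error(enrichment_table(chains4, annot), "absent from annotation")

  # bonferroni adjustment scales p across chromosomes
  e5 <- enrichment_table(chains2, annot2, adjust = "bonferroni")
  expect_equal(e5$p_adj, pmin(e5$p * 2, 1))
})

test_that("normalisation: expected counts always sum to the number of unique genes", {
  set.seed(9)
  for (rep in 1:10) {
    n_chr <- sample(3:12, 1)
    counts <- sample(5:40, n_chr, replace = TRUE)
    dir <- withr::local_tempdir()
    f <- file.path(dir, "ann.tsv")
    writeLines(sprintf("chr%d\t%d", seq_len(n_chr), counts), f)
    annot <- read_annotation(f)
    n <- sample(2:15, 1)
    chains <- data.frame(
      gene_id = sprintf("g%d", seq_len(n)),
      chromosome = sample(sprintf("chr%d", seq_len(n_chr)), n,
                          replace = TRUE, prob = counts))
    e <- enrichment_table(chains, annot)
    expect_equal(sum(e$expected), n, tolerance = 1e-9)
    expect_true(all(e$p >= 0 & e$p <= 1))
  }
})
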