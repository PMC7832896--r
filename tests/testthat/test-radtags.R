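test_that("tag calling applies the exact-copy depth threshold", {
  s1 <- strrep("A", 30)
  s2 <- paste0(strrep("A", 29), "C")
  t1 <- call_tags(rep(s1, 6), "x", min_depth = 5)
  expect_equal(nrow(t1), 1L)
  expect_equal(t1$depth, 6L)
  expect_equal(nrow(call_tags(rep(s1, 4), "x", min_depth = 5)), 0L)
  t2 <- call_tags(c(rep(s1, 6), rep(s2, 5)), "x", min_depth = 5)
  expect_equal(nrow(t2), 2L)
  expect_setequal(t2$sequence, c(s1, s2))
  expect_warning(out <- call_tags(character(0), "x"), "no reads")
  expect_equal(nrow(out), 0L)
  expect_error(call_tags(c("AAA", "AAAA"), "x", min_depth = 1),
               "uniform length")
})

test_that("near-identical alleles cluster into one locus; distant sequences stay apart", {
  base <- strrep("ACGT", 10)
  near <- paste0(substr(base, 1, 39), "A")      # 1 mismatch
  far <- paste0(strrep("TTTTT", 8))             # >> 3 mismatches
  tags <- do.call(rbind, lapply(sprintf("i%02d", 1:10), function(sid) {
    data.frame(sample_id = sid, sequence = c(base, near), depth = 6L)
  }))
  tags <- rbind(tags, data.frame(sample_id = "i01", sequence = far,
                                 depth = 6L))
  loci <- cluster_loci(tags, max_allele_mismatch = 3)
  expect_equal(nrow(loci$loci), 2L)
  two <- loci$loci[loci$loci$n_alleles == 2L, ]
  expect_equal(two$n_carriers, 10L)
  expect_false(any(loci$loci$excluded))
  xs <- c("A", "A", "A", "A", "C", "C", "C", "G", "G", "T")
  ys <- c("A", "C", "G", "T", "A", "C", "G", "A", "C", "A")
  sheet <- data.frame(sample_id = sprintf("i%02d", 1:10),
                      barcode = paste0(strrep(xs, 3), strrep(ys, 3)),
                      sex = rep(c("M", "F"), 5))
  m <- presence_matrix(loci, sheet)
  expect_equal(unname(rowSums(m)),
               loci$loci$n_carriers[match(rownames(m),
                                          loci$loci$locus_id)])
  expect_true(all(m[two$locus_id, ]))
})

test_that("loci with more than two alleles are flagged excluded and left out of the matrix", {
  base <- strrep("GATTACA", 5)
  v1 <- sub("^G", "A", base)
  v2 <- sub("^GA", "AT", base)
  tags <- data.frame(sample_id = "only",
                     sequence = c(base, v1, v2), depth = 8L)
  loci <- cluster_loci(tags, max_allele_mismatch = 3)
  expect_equal(nrow(loci$loci), 1L)
  expect_true(loci$loci$excluded)
  expect_match(loci$loci$reason, ">2 alleles")
  sheet <- data.frame(sample_id = "only", barcode = "ACGTAC", sex = "M")
  expect_warning(m <- presence_matrix(loci, sheet), "single sex")
  expect_equal(nrow(m), 0L)
})

test_that("mixed-length tags and unknown samples are hard errors", {
  tags <- data.frame(sample_id = c("a", "a"),
                     sequence = c("AAAA", "AAAAA"), depth = 5L)
  expect_error(cluster_loci(tags), "mixed lengths")
  tags2 <- data.frame(sample_id = "ghost", sequence = strrep("A", 20),
                      depth = 5L)
  loci <- cluster_loci(tags2)
  expect_error(presence_matrix(loci, sheet2), "missing from sheet")
})

test_that("single-linkage clustering matches brute-force transitive closure", {
  for (seed in 1:5) {
    set.seed(seed)
    # seed sequences plus mutated satellites produce nontrivial components
    n_seed <- 8
    len <- 30
    seeds <- replicate(n_seed, paste(sample(c("A", "C", "G", "T"), len,
                                            TRUE), collapse = ""))
    seqs <- unique(unlist(lapply(seeds, function(s) {
      sat <- replicate(3, {
        chars <- strsplit(s, "")[[1]]
        pos <- sample(len, sample(1:4, 1))
        chars[pos] <- sample(c("A", "C", "G", "T"), length(pos), TRUE)
        paste(chars, collapse = "")
      })
      c(s, sat)
    })))
    tags <- data.frame(sample_id = "z", sequence = seqs, depth = 5L)
    loci <- cluster_loci(tags, max_allele_mismatch = 3)
    got <- split(loci$alleles$sequence, loci$alleles$locus_id)
    want <- split(sort(seqs), brute_components(sort(seqs), 3))
    norm <- function(g) unname(lapply(g, sort)[order(vapply(g, min, ""))])
    expect_identical(norm(got), norm(want))
  }
})

test_that("noise-free synthetic data yields one locus per truth locus, with gametolog merge/split set by divergence", {
  # divergence 2 bases (<= max mismatch): pair clusters as one 2-allele locus
  p_merge <- sim_params(n_males = 3, n_females = 3, system = "ZW",
                        n_autosomal_loci = 10, n_sexlimited_loci = 3,
                        n_gametolog_pairs = 2, tag_length = 80,
                        allele_div = 0.025, error_rate = 0,
                        dropout_rate = 0, seed = 41)
  sim <- simulate_rad_dataset(p_merge, withr::local_tempdir())
  st <- run_core_stages(sim)
  expect_equal(nrow(st$loci$loci), 10 + 3 + 2)
  expect_false(any(st$loci$loci$excluded))
  expect_equal(sum(st$loci$loci$n_alleles == 2L), 2L)

  # divergence 8 bases (> max mismatch): each pair splits into two loci
  p_split <- sim_params(n_males = 3, n_females = 3, system = "ZW",
                        n_autosomal_loci = 10, n_sexlimited_loci = 3,
                        n_gametolog_pairs = 2, tag_length = 80,
                        allele_div = 0.1, error_rate = 0,
                        dropout_rate = 0, seed = 41)
  sim2 <- simulate_rad_dataset(p_split, withr::local_tempdir())
  st2 <- run_core_stages(sim2)
  expect_equal(nrow(st2$loci$loci), 10 + 3 + 2 * 2)
  expect_true(all(st2$loci$loci$n_alleles == 1L))
})
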