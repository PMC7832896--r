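# presence matrix fixture: 18 individuals (9 M, 9 F), hand-set patterns
pres_fixture <- function() {
  ids <- c(sprintf("M%02d", 1:9), sprintf("F%02d", 1:9))
  sex <- stats::setNames(rep(c("M", "F"), each = 9), ids)
  m <- matrix(FALSE, nrow = 4, ncol = 18,
              dimnames = list(c("C00001", "C00002", "C00003", "C00004"),
                              ids))
  m["C00001", 1:9] <- TRUE                 # all males, no females
  m["C00002", c(1:9, 10)] <- TRUE          # all males + one female
  m["C00003", ] <- TRUE                    # everyone
  m["C00004", 10:18] <- TRUE               # all females
  attr(m, "sex") <- sex
  m
}

test_that("putative markers require presence in one sex and absolute absence in the other", {
  m <- pres_fixture()
  put <- find_putative(m)
  expect_equal(nrow(put), 2L)
  expect_setequal(put$locus_id, c("C00001", "C00004"))
  expect_equal(put$specificity[put$locus_id == "C00001"], "MALE")
  expect_equal(put$specificity[put$locus_id == "C00004"], "FEMALE")
  expect_false("C00002" %in% put$locus_id)  # one opposite-sex carrier kills it
  expect_false("C00003" %in% put$locus_id)
  expect_true(all(is.na(put$confirmed)))
  # min_carriers: demand all 9, a 5-carrier locus disappears
  m2 <- m
  m2["C00001", 6:9] <- FALSE
  put2 <- find_putative(m2, min_carriers = 9)
  expect_false("C00001" %in% put2$locus_id)
  put3 <- find_putative(m2)  # default ceil(9/2) = 5 keeps it
  expect_true("C00001" %in% put3$locus_id)
})

test_that("output ordering is carriers-descending then locus id, and single-sex input errors", {
  m <- pres_fixture()
  m["C00002", 10] <- FALSE  # now male-specific with 9 carriers
  m["C00001", 6:9] <- FALSE # 5 carriers
  put <- find_putative(m)
  expect_identical(put$locus_id, c("C00002", "C00004", "C00001"))
  expect_identical(put$n_carriers, c(9L, 9L, 5L))
  expect_error(find_putative(m[, 1:9, drop = FALSE],
                             sex = rep("M", 9)), "both sexes")
})

test_that("no locus can be both male- and female-specific", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 30
    m <- matrix(stats::runif(n * 8) < 0.5, nrow = n,
                dimnames = list(sprintf("C%05d", 1:n),
                                c(sprintf("M%d", 1:4), sprintf("F%d", 1:4))))
    put <- find_putative(m, sex = rep(c("M", "F"), each = 4),
                         min_carriers = 1)
    expect_equal(anyDuplicated(put$locus_id), 0L)
  }
})

test_that("confirmation rejects markers whose sequence occurs in opposite-sex raw reads", {
  dir <- withr::local_tempdir()
  tagA <- strrep("ACGGT", 8)  # the 'sex-specific' tag under test
  tagB <- strrep("TGCAA", 8)  # a genuinely female-limited tag
  filler <- strrep("GGACT", 8)
  # tags: both seen at depth >= 5 only in females
  tags <- rbind(
    data.frame(sample_id = "F01", sequence = c(tagA, tagB), depth = 8L),
    data.frame(sample_id = "F02", sequence = c(tagA, tagB), depth = 7L),
    data.frame(sample_id = "M01", sequence = filler, depth = 9L),
    data.frame(sample_id = "M02", sequence = filler, depth = 9L)
  )
  loci <- cluster_loci(tags)
  sheet <- data.frame(sample_id = c("F01", "F02", "M01", "M02"),
                      barcode = c("AAAAAA", "CCCCCC", "GGGGGG", "TTTTTT"),
                      sex = c("F", "F", "M", "M"))
  pres <- presence_matrix(loci, sheet)
  put <- find_putative(pres, min_carriers = 1)
  # tagA + tagB female-specific, plus the male-only filler locus
  expect_equal(nrow(put), 3L)

  # male raw reads: M01 contains tagA twice (below any depth threshold)
  files <- c(
    F01 = write_test_fastq(rep(c(tagA, tagB), c(8, 8)),
                           file.path(dir, "F01.fq")),
    F02 = write_test_fastq(rep(c(tagA, tagB), c(7, 7)),
                           file.path(dir, "F02.fq")),
    M01 = write_test_fastq(c(rep(filler, 9), tagA, tagA),
                           file.path(dir, "M01.fq")),
    M02 = write_test_fastq(rep(filler, 9), file.path(dir, "M02.fq"))
  )
  conf <- confirm_markers(put, loci, files, sheet)
  tagA_locus <- loci$alleles$locus_id[loci$alleles$sequence == tagA]
  tagB_locus <- loci$alleles$locus_id[loci$alleles$sequence == tagB]
  expect_false(conf$confirmed[conf$locus_id == tagA_locus])
  expect_true(conf$confirmed[conf$locus_id == tagB_locus])
  ev <- conf$disconfirming_evidence[[which(conf$locus_id == tagA_locus)]]
  expect_equal(ev$sample_id, "M01")
  expect_equal(ev$n_reads, 2L)
  # disconfirmed markers always carry evidence; confirmed never do
  expect_null(conf$disconfirming_evidence[[which(conf$locus_id ==
                                                   tagB_locus)]])

  # a missing opposite-sex read file is a hard error, not a silent skip
  expect_error(confirm_markers(put, loci, files[c("F01", "F02", "M01")],
                               sheet), "missing raw read file")

  # with a 1-mismatch tolerance, a near-miss read also disqualifies
  near <- paste0(substr(tagB, 1, 39), "T")
  files["M02"] <- write_test_fastq(c(rep(filler, 9), near),
                                   file.path(dir, "M02b.fq"))
  conf2 <- confirm_markers(put, loci, files, sheet, max_mismatches = 1)
  expect_false(conf2$confirmed[conf2$locus_id == tagB_locus])
})

test_that("system calls follow confirmed marker counts", {
  xy <- call_system(make_markers(166, 0))
  expect_equal(xy$system, "XY")
  expect_equal(xy$n_male_specific_confirmed, 166L)
  zw <- call_system(make_markers(0, 646))
  expect_equal(zw$system, "ZW")
  expect_equal(call_system(make_markers(0, 0))$system, "UNRESOLVED")
  expect_equal(call_system(make_markers(3, 2))$system, "UNRESOLVED")
  expect_equal(call_system(make_markers(1, 0), min_markers = 2)$system,
               "UNRESOLVED")
  unconf <- make_markers(1, 0)
  unconf$confirmed <- NA
  expect_error(call_system(unconf), "confirmed")
})

test_that("shuffling sex labels on a system-free simulation yields no confirmed markers", {
  n_hits <- 0L
  for (seed in 1:20) {
    sim <- simulate_rad_dataset(
      tiny_params("NONE", seed = seed, n_autosomal_loci = 20),
      withr::local_tempdir())
    sheet <- sim$sheet
    set.seed(1000L + seed)
    sheet$sex <- sample(sheet$sex)  # random permutation of labels
    st <- run_core_stages(list(pooled_file = sim$pooled_file, sheet = sheet,
                               params = sim$params, dir = sim$dir))
    put <- find_putative(st$pres)
    conf <- confirm_markers(put, st$loci, st$demux$files, sheet)
    n_hits <- n_hits + sum(conf$confirmed)
  }
  expect_equal(n_hits, 0L)
})
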