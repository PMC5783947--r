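apt32 <- atp_dna_construct()

test_that("closed-form counts agree with brute-force enumeration sizes", {
  for (L in c(4L, 10L, 17L, 32L)) {
    for (X in seq_len(L)) {
      for (Y in X:L) {
        expect_identical(count_perfect_match(L, X, Y),
                         brute_pm_count(L, X, Y))
        expect_identical(count_single_mismatch(L, X, Y),
                         brute_mm_count(L, X, Y))
      }
    }
  }
  # printed specializations agree with the general form
  expect_identical(count_perfect_match(10, 1, 10), 55L)
  expect_identical(count_perfect_match(5, 5, 5), 1L)
  expect_identical(count_single_mismatch(4, 1, 1), 4L)
  expect_error(count_perfect_match(10, 5, 3), class = "acekit_violation_error")
  expect_error(count_single_mismatch(10, 0, 3),
               class = "acekit_violation_error")
})

test_that("enumeration covers every window exactly once and matches counts", {
  d7 <- enumerate_perfect_match(apt32, 7, 7)
  expect_equal(nrow(d7), 26)
  expect_false(anyDuplicated(d7$ace_id) > 0)
  full <- enumerate_perfect_match(apt32, 32, 32)
  expect_equal(nrow(full), 1)
  expect_equal(full$start5, -5L)
  d <- enumerate_perfect_match(apt32, 7, 12)
  expect_equal(nrow(d), count_perfect_match(32, 7, 12))
  expect_error(enumerate_perfect_match(apt32, 7, 40),
               class = "acekit_violation_error")

  mm <- enumerate_single_mismatch(apt32, c(12, 15))
  expect_equal(nrow(mm), count_single_mismatch(32, 12, 12) +
                 count_single_mismatch(32, 15, 15))
  expect_false(anyDuplicated(mm$ace_id) > 0)
  # every mismatch position lies inside its window
  i0 <- ifelse(mm$start5 > 0, mm$start5 + 5L, mm$start5 + 6L)
  mi <- ifelse(mm$mismatch_pos > 0, mm$mismatch_pos + 5L, mm$mismatch_pos + 6L)
  expect_true(all(mi >= i0 & mi <= i0 + mm$length - 1L))
})

test_that("probe sequences are reverse complements with spacer and linker", {
  toy <- aptamer_construct("t", "ACGT")
  d <- data.frame(aptamer_id = "t", ace_id = "x", start5 = 1L, length = 4L,
                  mismatch_pos = NA_integer_, degenerate = FALSE,
                  spacer3_len = 2L, linker5_len = 0L)
  expect_equal(probe_sequence(d, toy), "ACGTTT") # ACGT is self-complementary
  rna <- toy_rna()
  d2 <- data.frame(aptamer_id = "toyRNA", ace_id = "y", start5 = 3L,
                   length = 4L, mismatch_pos = NA_integer_,
                   degenerate = FALSE, spacer3_len = 0L, linker5_len = 0L)
  # window GGAU CC.. -> coords 3..6 = AUCC -> revcomp (DNA) = GGAT
  expect_equal(probe_sequence(d2, rna), "GGAT")
  d3 <- d2; d3$start5 <- 1L # window GGAU -> ATCC
  expect_equal(probe_sequence(d3, rna), "ATCC")
  d4 <- d; d4$linker5_len <- 3L
  expect_equal(probe_sequence(d4, toy), "TTTACGTTT")
  bad <- d; bad$length <- 9L
  expect_error(probe_sequence(bad, toy), class = "acekit_violation_error")
})

test_that("every mismatched probe differs from its perfect match at exactly one position", {
  mm <- enumerate_single_mismatch(apt32, 12)
  pm <- mm; pm$mismatch_pos <- NA_integer_
  p_mm <- probe_sequence(mm, apt32)
  p_pm <- probe_sequence(pm, apt32)
  ndiff <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, p_mm, p_pm)
  expect_true(all(ndiff == ifelse(mm$degenerate, 0L, 1L)))
  # the A-substitution rule never has fixed points on a pure-ACGT aptamer
  expect_false(any(mm$degenerate))
  # perfect-match probes equal the Biostrings reverse complement of their
  # window (independent oracle), so they are complementary at every position
  idx <- c(1L, 50L, 200L)
  for (r in idx) {
    i0 <- pm$start5[r] + ifelse(pm$start5[r] > 0, 5L, 6L)
    win <- substr(apt32$sequence, i0, i0 + pm$length[r] - 1L)
    oracle <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(win)))
    expect_equal(substr(p_pm[r], 1, pm$length[r]), oracle)
  }
})

test_that("the paper-style mismatch carries A opposite an aptamer G", {
  d <- parse_name("5'_4T:12:6G", apt32)
  expect_equal(aptamer_base(apt32, 6L), "G")
  probe <- probe_sequence(d, apt32)
  # probe position opposite coordinate 6 in window 4..15: (15 - 6) + 1 = 10
  expect_equal(substr(probe, 10, 10), "A")
})

test_that("names format and parse as mutual inverses, both anchors", {
  d <- parse_name("3'_11G:11", apt32)
  expect_equal(d$start5, 1L)
  expect_equal(d$length, 11L)
  expect_equal(format_name(d, apt32, "5p"), "5'_1A:11")
  expect_equal(format_name(d, apt32, "3p"), "3'_11G:11")

  neg <- parse_name("5'_-5C:9", apt32)
  expect_equal(neg$start5, -5L)
  expect_equal(neg$length, 9L)

  # unicode primes and Q-labelled solution names are accepted
  expect_equal(parse_name("5ʹQ_-2T:9", apt32)$start5, -2L)

  # round trip over a whole enumerated family, both anchors
  fam <- rbind(enumerate_perfect_match(apt32, 7, 10),
               enumerate_single_mismatch(apt32, 9))
  for (anchor in c("5p", "3p")) {
    back <- parse_name(format_name(fam, apt32, anchor), apt32)
    expect_equal(back$start5, fam$start5)
    expect_equal(back$length, fam$length)
    expect_equal(back$mismatch_pos, fam$mismatch_pos)
  }
  # 3' anchor arithmetic skips coordinate 0
  p <- parse_name("5'_-5C:15", apt32)
  expect_equal(format_name(p, apt32, "3p"), "3'_10A:15")

  expect_error(parse_name("5'_1X:11", apt32)) # malformed base letter
  expect_error(parse_name("5'_1G:11", apt32),
               class = "acekit_violation_error") # base disagreement
  expect_error(parse_name("gibberish", apt32),
               class = "acekit_violation_error")
})

test_that("layouts are seeded, identical across sub-arrays, capacity-checked", {
  d <- enumerate_perfect_match(apt32, 7, 12)
  l1 <- assign_layout(d, 6, 5, seed = 3)
  l2 <- assign_layout(d, 6, 5, seed = 3)
  expect_identical(l1$positions, l2$positions)
  l3 <- assign_layout(d, 6, 5, seed = 4)
  expect_false(identical(l1$positions$grid_row, l3$positions$grid_row))
  # identical multiset of placements regardless of seed
  expect_identical(table(l1$positions$ace_id), table(l3$positions$ace_id))
  # identical layout replicated across sub-arrays
  p <- l1$positions
  sa1 <- p[p$subarray_id == "sa1", c("ace_id", "replicate", "grid_row",
                                     "grid_col")]
  sa6 <- p[p$subarray_id == "sa6", c("ace_id", "replicate", "grid_row",
                                     "grid_col")]
  expect_equal(sa1, sa6, ignore_attr = TRUE)
  expect_equal(sum(p$subarray_id == "sa1"), nrow(d) * 5)

  # 1400 ACEs x 5 replicates exactly fill a 7000-spot sub-array
  d1400 <- enumerate_single_mismatch(atp_dna_construct(), c(12, 15))
  d1400 <- d1400[seq_len(1400), ]
  lay <- assign_layout(d1400, 6, 5, seed = 1, grid_dim = c(70, 100))
  expect_equal(sum(lay$positions$subarray_id == "sa1"), 7000)
  expect_error(assign_layout(d1400, 6, 6, seed = 1, grid_dim = c(70, 100)),
               class = "acekit_violation_error")
})

test_that("probe manifest and FASTA round-trip through Biostrings", {
  d <- enumerate_perfect_match(apt32, 30, 32)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  man <- write_probe_manifest(d, apt32, tsv)
  expect_true(file.exists(sub("tsv$", "fasta", tsv)))
  fa <- Biostrings::readDNAStringSet(sub("tsv$", "fasta", tsv))
  expect_equal(length(fa), nrow(d))
  expect_equal(unname(as.character(fa[man$ace_name_5p[1]])),
               man$probe_sequence[1])
})
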