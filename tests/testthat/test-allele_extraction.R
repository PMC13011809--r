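test_that("an embedded TGRS is delineated exactly, in either orientation", {
  set.seed(51)
  tg <- rand_dna(1200)
  contig <- paste0(rand_dna(500), tg, rand_dna(500))
  b <- delineate_boundaries(contig, tg)
  expect_true(b$ok)
  expect_equal(c(b$start, b$end), c(501, 1700))
  expect_equal(b$orientation, "+")
  expect_equal(b$identity, 1)

  brc <- delineate_boundaries(oracle_revcomp(contig), tg)
  expect_true(brc$ok)
  expect_equal(brc$orientation, "-")
  expect_equal(c(brc$start, brc$end), c(501, 1700))
})

test_that("boundaries survive scattered mismatches in the contig", {
  set.seed(52)
  tg <- rand_dna(1500)
  mutated <- tg
  for (p in sample(100:1400, 5)) {
    substr(mutated, p, p) <-
      sample(setdiff(c("A", "C", "G", "T"), substr(mutated, p, p)), 1)
  }
  contig <- paste0(rand_dna(300), mutated, rand_dna(300))
  b <- delineate_boundaries(contig, tg)
  expect_true(b$ok)
  expect_equal(c(b$start, b$end), c(301, 1800))
})

test_that("an unrelated contig fails delineation", {
  set.seed(53)
  b <- delineate_boundaries(rand_dna(2000), rand_dna(1500))
  expect_false(b$ok)
})

test_that("alleles carry requested flanks, clipped to the contig", {
  set.seed(54)
  tg <- rand_dna(1000)
  left <- rand_dna(700); right <- rand_dna(2500)
  contig <- paste0(left, tg, right)
  locus <- genephase:::phased_locus("g1", contig, "primary", NA_character_,
                                    10L)
  al <- extract_alleles(locus, tg, flanks = c(0, 2000))
  a0 <- al[al$flank == 0, ]
  expect_equal(a0$sequence, tg)
  expect_equal(a0$label, "H")
  a2k <- al[al$flank == 2000, ]
  expect_equal(a2k$left_flank, 700)   # clipped: only 700 bp available
  expect_equal(a2k$right_flank, 2000)
  expect_equal(nchar(a2k$sequence), 700 + 1000 + 2000)
  # nested tiers: the 0-flank allele sits inside the 2 kbp tier
  expect_match(a2k$sequence, a0$sequence, fixed = TRUE)
})

test_that("homozygous AAS-2K length is gene span plus 4 kbp when flanks
          are available", {
  set.seed(55)
  tg <- rand_dna(1200)
  contig <- paste0(rand_dna(2300), tg, rand_dna(2300))
  locus <- genephase:::phased_locus("g2", contig, "primary", NA_character_,
                                    8L)
  al <- extract_alleles(locus, tg, flanks = c(0, 2000))
  expect_equal(nchar(al$sequence[al$flank == 2000]), 1200 + 4000)
})

test_that("every allele is a contiguous subsequence of its source contig", {
  set.seed(56)
  tg <- rand_dna(900)
  c1 <- paste0(rand_dna(400), tg, rand_dna(400))
  tg_mut <- tg
  substr(tg_mut, 450, 450) <- if (substr(tg, 450, 450) == "A") "C" else "A"
  c2 <- paste0(rand_dna(350), tg_mut, rand_dna(350))
  locus <- genephase:::phased_locus("g3", c(c1, c2), "primary",
                                    NA_character_, 20L)
  al <- extract_alleles(locus, tg, flanks = c(0, 200))
  for (i in seq_len(nrow(al))) {
    src <- locus$contigs[[al$contig_index[i]]]
    expect_true(grepl(al$sequence[i], src, fixed = TRUE) ||
                  grepl(al$sequence[i], oracle_revcomp(src), fixed = TRUE))
  }
})

test_that("h1/h2 labelling is deterministic under the ordering rule", {
  set.seed(57)
  tg <- rand_dna(800)
  tg_ins <- paste0(substr(tg, 1, 400), rand_dna(50), substr(tg, 401, 800))
  c_short <- paste0(rand_dna(100), tg, rand_dna(100))
  c_long <- paste0(rand_dna(100), tg_ins, rand_dna(100))
  locus_ab <- genephase:::phased_locus("g4", c(c_short, c_long), "primary",
                                       NA_character_, 12L)
  locus_ba <- genephase:::phased_locus("g4", c(c_long, c_short), "primary",
                                       NA_character_, 12L)
  al_ab <- extract_alleles(locus_ab, tg, flanks = 0)
  al_ba <- extract_alleles(locus_ba, tg, flanks = 0)
  # shorter gene interval is always h1, regardless of contig order
  expect_equal(al_ab$sequence[al_ab$label == "h1"],
               al_ba$sequence[al_ba$label == "h1"])
  expect_equal(nchar(al_ab$sequence[al_ab$label == "h1"]), 800)
  expect_equal(nchar(al_ab$sequence[al_ab$label == "h2"]), 850)
})

test_that("reverse-complemented contigs are normalized to TGRS-forward", {
  set.seed(58)
  tg <- rand_dna(1000)
  contig <- paste0(rand_dna(200), tg, rand_dna(200))
  fwd <- genephase:::phased_locus("g5", contig, "primary", NA_character_, 9L)
  rev <- genephase:::phased_locus("g5", oracle_revcomp(contig), "primary",
                                  NA_character_, 9L)
  expect_equal(extract_alleles(fwd, tg, flanks = 0)$sequence,
               extract_alleles(rev, tg, flanks = 0)$sequence)
})

test_that("failed delineation on all contigs marks allele-extraction
          failure", {
  set.seed(59)
  locus <- genephase:::phased_locus("g6", rand_dna(1500), "primary",
                                    NA_character_, 5L)
  al <- extract_alleles(locus, rand_dna(1200), flanks = 0)
  expect_equal(nrow(al), 0L)
  expect_equal(attr(al, "failure_stage"), "allele_extraction")
})
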