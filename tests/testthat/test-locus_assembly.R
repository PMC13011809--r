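test_that("two haplotypes differing by SNPs assemble into two true contigs", {
  loc <- make_locus_reads(len = 2000, n_snps = 3, reads_per_hap = 15,
                          seed = 41)
  ctg <- builtin_assemble(loc$reads, loc$tgrs, seed = 1)
  expect_length(ctg, 2L)
  expect_setequal(ctg, c(loc$h1, loc$h2))
})

test_that("a single distinguishing SNP at 10x per haplotype is recovered", {
  loc <- make_locus_reads(len = 2000, n_snps = 1, reads_per_hap = 10,
                          seed = 42)
  ctg <- builtin_assemble(loc$reads, loc$tgrs, seed = 1)
  expect_setequal(ctg, c(loc$h1, loc$h2))
})

test_that("identical haplotypes collapse to a single consensus contig", {
  loc <- make_locus_reads(len = 1500, n_snps = 0, reads_per_hap = 10,
                          seed = 43)
  ctg <- builtin_assemble(loc$reads, loc$tgrs, seed = 1)
  expect_length(ctg, 1L)
  expect_identical(ctg, loc$h1)
})

test_that("scattered read errors are out-voted by the consensus", {
  loc <- make_locus_reads(len = 2000, n_snps = 0, reads_per_hap = 6,
                          sub_rate = 0.002, seed = 44)
  ctg <- builtin_assemble(loc$reads, loc$tgrs, seed = 1)
  expect_length(ctg, 1L)
  expect_identical(ctg, loc$h1)
})

test_that("assembly is deterministic under a fixed seed", {
  loc <- make_locus_reads(len = 1200, n_snps = 2, reads_per_hap = 8,
                          sub_rate = 0.003, seed = 45)
  expect_identical(builtin_assemble(loc$reads, loc$tgrs, seed = 9),
                   builtin_assemble(loc$reads, loc$tgrs, seed = 9))
})

test_that("assemble_locus maps contig counts to zygosity calls", {
  loc <- make_locus_reads(len = 1500, n_snps = 3, reads_per_hap = 12,
                          seed = 46)
  rs <- list(gene_id = "gX", n_selected = length(loc$reads),
             reads = data.frame(read_id = paste0("r", seq_along(loc$reads)),
                                sequence = loc$reads,
                                S = 300L, E = 300L + 1500L - 1L,
                                s = 0L, e = 1499L,
                                stringsAsFactors = FALSE))
  class(rs) <- "locus_read_set"
  het <- assemble_locus(rs, loc$tgrs, seed = 1, window_flank = 400L)
  expect_equal(het$zygosity, "heterozygous")
  expect_length(het$contigs, 2L)
  expect_equal(het$assembler_used, "primary")

  rs_homo <- rs
  rs_homo$reads <- rs$reads[1:12, ]  # one haplotype only
  rs_homo$n_selected <- 12L
  homo <- assemble_locus(rs_homo, loc$tgrs, seed = 1, window_flank = 400L)
  expect_equal(homo$zygosity, "homozygous")
  expect_length(homo$contigs, 1L)
})

test_that("an empty read set fails at the read-selection stage", {
  res <- assemble_locus(NULL, "ACGT")
  expect_equal(res$zygosity, "failed")
  expect_equal(res$failure_stage, "read_selection")
  expect_equal(res$assembler_used, "none")
})

test_that("fallback is invoked iff the primary yields zero contigs", {
  loc <- make_locus_reads(len = 1000, n_snps = 0, reads_per_hap = 5,
                          seed = 47)
  rs <- list(gene_id = "gY", n_selected = length(loc$reads),
             reads = data.frame(read_id = paste0("r", seq_along(loc$reads)),
                                sequence = loc$reads,
                                S = 300L, E = 1299L, s = 0L, e = 999L,
                                stringsAsFactors = FALSE))
  class(rs) <- "locus_read_set"
  dud <- structure(list(name = "dud", kind = "builtin",
                        fn = function(reads, tgrs, seed, ...) character(0)),
                   class = "assembler_backend")
  res <- assemble_locus(rs, loc$tgrs, primary = dud, seed = 1,
                        window_flank = 400L)
  expect_equal(res$assembler_used, "fallback")
  expect_equal(res$zygosity, "homozygous")

  many <- structure(list(name = "many", kind = "builtin",
                         fn = function(reads, tgrs, seed, ...)
                           c("ACGT", "ACGA", "ACGC")),
                    class = "assembler_backend")
  res2 <- assemble_locus(rs, loc$tgrs, primary = many, seed = 1,
                         window_flank = 400L)
  expect_equal(res2$zygosity, "failed")
  expect_equal(res2$failure_stage, "assembly")
  res3 <- assemble_locus(rs, loc$tgrs, primary = many, seed = 1,
                         window_flank = 400L, keep_two_longest = TRUE)
  expect_equal(res3$zygosity, "heterozygous")
  res4 <- assemble_locus(rs, loc$tgrs, primary = many,
                         fallback = "consensus", seed = 1,
                         window_flank = 400L, fallback_on_excess = TRUE)
  expect_equal(res4$assembler_used, "fallback")
  expect_equal(res4$zygosity, "homozygous")
})

test_that("external assembler backends follow the FASTA-in/FASTA-out
          contract and missing binaries are skipped gracefully", {
  script <- withr::local_tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh", "cp \"$1\" \"$2\""), script)
  Sys.chmod(script, "0755")
  be <- assembler_backend("copycat", cmd = script)
  expect_equal(be$kind, "external")
  out <- be$fn(c("ACGTACGT", "ACGTACGT"), NULL, seed = 1)
  expect_equal(out, c("ACGTACGT", "ACGTACGT"))

  gone <- assembler_backend("ghost", cmd = "no_such_assembler_binary")
  expect_message(res <- gone$fn(c("ACGT"), NULL, seed = 1), "skipped")
  expect_length(res, 0L)
})
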