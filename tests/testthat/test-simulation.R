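test_that("zero variant rates give identical haplotypes and alleles", {
  m0 <- variant_model("custom", snp_rate = 0, sv_rate = 0,
                      sv_probs = rep(1 / 9, 9))
  sim <- simulate_diploid(n_genes = 5, model = m0, seed = 71)
  expect_identical(sim$hap_a, sim$hap_b)
  expect_identical(sim$allele_a, sim$allele_b)
  expect_equal(nrow(sim$variant_log), 0L)
})

test_that("gene lengths stay in the 1,000-5,000 bp range and ids are
          shared across haplotypes", {
  sim <- simulate_diploid(n_genes = 40, model = variant_model("low"),
                          seed = 72)
  lens <- nchar(sim$allele_a)
  expect_true(all(lens >= 1000 & lens <= 5000))
  expect_identical(names(sim$allele_a), names(sim$allele_b))
})

test_that("variant placement matches the per-kbp rate (binomial check)", {
  sim <- simulate_diploid(n_genes = 150, model = variant_model("low"),
                          seed = 73)
  L <- nchar(sim$hap_a)
  n_snp <- sum(sim$variant_log$type == "snp")
  ci <- qpois(c(0.005, 0.995), L * 1.5 / 1000)
  expect_gte(n_snp, ci[1])
  expect_lte(n_snp, ci[2])
  n_sv <- sum(sim$variant_log$type != "snp")
  ci_sv <- qpois(c(0.005, 0.995), L * 0.1 / 1000)
  expect_gte(n_sv, ci_sv[1])
  expect_lte(n_sv, ci_sv[2])
})

test_that("SV sizes follow the size-class distribution (chi-square GoF)", {
  m <- variant_model("high")
  sim <- simulate_diploid(n_genes = 120, model = m, seed = 74)
  svs <- sim$variant_log[sim$variant_log$type != "snp", ]
  expect_gt(nrow(svs), 1000)
  cls <- cut(svs$size, breaks = c(0, genephase:::SV_SIZE_CLASSES[, "hi"]),
             labels = FALSE)
  obs <- tabulate(cls, nbins = 9)
  # pool the rare upper classes so expected counts stay above ~5
  keep <- m$sv_probs * nrow(svs) >= 5
  obs_p <- c(obs[keep], sum(obs[!keep]))
  p_p <- c(m$sv_probs[keep], sum(m$sv_probs[!keep]))
  gof <- suppressWarnings(chisq.test(obs_p, p = p_p))
  expect_gt(gof$p.value, 0.01)
})

test_that("the annotation liftover reproduces truth alleles verbatim", {
  sim <- simulate_diploid(n_genes = 25, model = variant_model("high"),
                          seed = 75)
  for (i in seq_len(nrow(sim$genes))) {
    expect_identical(substr(sim$hap_b, sim$genes$b_start[i],
                            sim$genes$b_end[i]),
                     sim$allele_b[[sim$genes$gene_id[i]]])
  }
})

test_that("loci without gene-body variants are truth-homozygous, at the
          rate the variant model implies", {
  sim <- simulate_diploid(n_genes = 400, model = variant_model("low"),
                          seed = 76)
  n_homo <- sum(sim$allele_a == sim$allele_b)
  # ~3.2% of loci expected homozygous under the low model (averaging
  # exp(-rate * len) over gene lengths); allow a generous binomial band
  expect_gt(n_homo, qbinom(0.005, 400, 0.032))
  expect_lt(n_homo, qbinom(0.995, 400, 0.032))
  in_gene <- sim$variant_log[sim$variant_log$gene_overlap, ]
  hit <- unique(findInterval(in_gene$position, sim$genes$a_start))
  expect_true(all(sim$allele_a[-hit] == sim$allele_b[-hit]))
})

test_that("read lengths respect the truncated-normal clip range", {
  sim <- simulate_diploid(n_genes = 3, model = variant_model("low"),
                          seed = 77)
  reads <- simulate_reads(sim, coverage = 5, seed = 77)
  expect_true(all(nchar(reads) >= 10000 & nchar(reads) <= 30000))
})

test_that("error-free reads are exact substrings at their declared
          coordinates", {
  sim <- simulate_diploid(n_genes = 3, model = variant_model("low"),
                          seed = 78)
  reads <- simulate_reads(sim, coverage = 3, sub_rate = 0, ins_rate = 0,
                          del_rate = 0, seed = 78)
  meta <- do.call(rbind, strsplit(names(reads), "|", fixed = TRUE))
  coords <- do.call(rbind, strsplit(meta[, 3], "-", fixed = TRUE))
  for (i in seq_along(reads)) {
    hap <- if (meta[i, 2] == "a") sim$hap_a else sim$hap_b
    expect_identical(unname(reads[i]),
                     substr(hap, as.integer(coords[i, 1]),
                            as.integer(coords[i, 2])))
  }
})

test_that("read generation stops at the coverage target", {
  sim <- simulate_diploid(n_genes = 3, model = variant_model("low"),
                          seed = 79)
  reads <- simulate_reads(sim, coverage = 30, seed = 79)
  mean_len <- mean(c(nchar(sim$hap_a), nchar(sim$hap_b)))
  total <- sum(nchar(reads))
  expect_gte(total, 30 * mean_len)
  expect_lt(total, 30 * mean_len + 30000)
})

test_that("downsampling is seeded, tight, and a no-op when target exceeds
          supply", {
  sim <- simulate_diploid(n_genes = 3, model = variant_model("low"),
                          seed = 80)
  reads <- simulate_reads(sim, coverage = 42.9, seed = 80)
  gsize <- mean(c(nchar(sim$hap_a), nchar(sim$hap_b)))
  d1 <- downsample_reads(reads, 10, gsize, seed = 5)
  d2 <- downsample_reads(reads, 10, gsize, seed = 5)
  expect_identical(d1, d2)
  expect_gte(sum(nchar(d1)), 10 * gsize)
  expect_lt(sum(nchar(d1)), 10 * gsize + 30000)
  expect_warning(all_back <- downsample_reads(reads, 99, gsize, seed = 5),
                 "below target")
  expect_identical(all_back, reads)
})

test_that("coverage is total bases over genome size", {
  expect_equal(coverage_of(0), 0.0)
  expect_equal(coverage_of(360e6), 1.0)
  expect_equal(coverage_of(15444e6), 42.9)
  expect_error(coverage_of(100, 0), "positive")
})

test_that("the simulator is deterministic end to end", {
  s1 <- simulate_diploid(n_genes = 4, model = variant_model("high"),
                         seed = 81)
  s2 <- simulate_diploid(n_genes = 4, model = variant_model("high"),
                         seed = 81)
  expect_identical(s1$hap_b, s2$hap_b)
  expect_identical(simulate_reads(s1, coverage = 2, seed = 81),
                   simulate_reads(s2, coverage = 2, seed = 81))
})

test_that("simulated data round-trips through the on-disk layout", {
  sim <- simulate_diploid(n_genes = 4, model = variant_model("low"),
                          seed = 82)
  outdir <- withr::local_tempdir()
  write_diploid(sim, outdir)
  tg_b <- extract_tgrs(file.path(outdir, "hap_b.fasta"),
                       file.path(outdir, "genes_b.gff3"))
  expect_identical(unname(tg_b$seq), unname(sim$allele_b))
})
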