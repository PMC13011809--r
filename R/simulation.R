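# Diploid haplotype / HiFi read simulator: paired haplotypes under per-kbp
# SNP and SV rate models with a categorical SV size distribution, truth
# allele sets, truncated-normal read lengths, and seeded downsampling.

SV_SIZE_CLASSES <- cbind(lo = c(1, 11, 51, 101, 201, 501, 1001, 5001, 10001),
                         hi = c(10, 50, 100, 200, 500, 1000, 5000, 10000,
                                50000))

#' Define a variant model (SNP/SV rates and SV size distribution)
#'
#' Two named presets mirror low- and high-diversity plant genomes:
#' `"low"` (rice-like: 1.5 SNPs/kbp, 0.1 SVs/kbp) and `"high"`
#' (citrus-like: 17 SNPs/kbp, 1.8 SVs/kbp), each with its own size-class
#' probability vector over the nine SV size bins from 1-10 bp up to
#' 10,001-50,000 bp. Probability vectors are normalized to sum to 1.
#'
#' @param name `"low"`, `"high"`, or `"custom"`.
#' @param snp_rate,sv_rate Per-kbp rates (required for `"custom"`).
#' @param sv_probs Probability per SV size class (length 9).
#' @return Object of class `variant_model`.
#' @export
variant_model <- function(name = c("low", "high", "custom"),
                          snp_rate = NULL, sv_rate = NULL, sv_probs = NULL) {
  name <- match.arg(name)
  if (name == "low") {
    snp_rate <- 1.5; sv_rate <- 0.1
    sv_probs <- c(0.80, 0.15, 0.03, 0.01, 0.005, 0.003, 0.0015, 0.0004,
                  0.0001)
  } else if (name == "high") {
    snp_rate <- 17; sv_rate <- 1.8
    sv_probs <- c(0.69, 0.10, 0.06, 0.0275, 0.036, 0.03, 0.0365, 0.01,
                  0.0001)
  }
  stopifnot(is.numeric(snp_rate), snp_rate >= 0,
            is.numeric(sv_rate), sv_rate >= 0,
            length(sv_probs) == nrow(SV_SIZE_CLASSES), all(sv_probs >= 0))
  structure(list(name = name, snp_rate = snp_rate, sv_rate = sv_rate,
                 sv_probs = sv_probs / sum(sv_probs),
                 sv_size_classes = SV_SIZE_CLASSES),
            class = "variant_model")
}

#' Simulate a paired diploid (two haplotypes + truth allele sets)
#'
#' Haplotype A is laid out as alternating random intergenic spacers and gene
#' bodies (gene lengths uniform in `gene_len_range`, spacers uniform in
#' `spacer_len_range`, all genes on the forward strand of one chromosome).
#' Haplotype B is derived from A by placing SNPs and SVs genome-wide as
#' Poisson processes at the model's per-kbp rates; SV sizes are drawn from
#' the model's size-class distribution (uniform within a class), with a
#' 50/50 insertion/deletion mix and random insertion content. Deletions are
#' clipped at block boundaries. Gene coordinates are lifted exactly through
#' the indels, so extracting the B annotation from haplotype B reproduces
#' the truth B alleles verbatim. Loci with no variant inside the gene body
#' are truth-homozygous (identical A and B alleles).
#'
#' @param n_genes Number of gene loci (default 1000).
#' @param model A [variant_model()].
#' @param seed Integer seed (all randomness derives from it).
#' @param gene_len_range Gene body length range in bp (default 1000-5000).
#' @param spacer_len_range Intergenic spacer range in bp (default
#'   10000-30000, so a 10-30 kbp read can span a gene plus flanks).
#' @param min_snps_per_gene Force at least this many SNPs into every gene
#'   body (default 0 = pure Poisson; used by constructions that need every
#'   locus heterozygous).
#' @return Object of class `sim_diploid`: list with `hap_a`, `hap_b`
#'   (chromosome strings), `genes` (gene_id, a_start, a_end, b_start,
#'   b_end, strand), `allele_a`, `allele_b` (named truth gene sequences),
#'   `variant_log` (type, position on A, size, gene_overlap), `model`,
#'   `seed`.
#' @export
simulate_diploid <- function(n_genes = 1000L, model = variant_model("low"),
                             seed = 1L, gene_len_range = c(1000L, 5000L),
                             spacer_len_range = c(10000L, 30000L),
                             min_snps_per_gene = 0L) {
  stopifnot(n_genes >= 1L)
  set.seed(seed)
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  # Block layout: spacer, gene, spacer, gene, ..., spacer.
  n_blocks <- 2L * n_genes + 1L
  is_gene <- seq_len(n_blocks) %% 2L == 0L
  lens <- integer(n_blocks)
  lens[is_gene] <- sample(gene_len_range[1]:gene_len_range[2], n_genes,
                          replace = TRUE)
  lens[!is_gene] <- sample(spacer_len_range[1]:spacer_len_range[2],
                           n_genes + 1L, replace = TRUE)
  a_blocks <- character(n_blocks)
  b_blocks <- character(n_blocks)
  logs <- vector("list", n_blocks)
  offset_a <- 0L
  for (i in seq_len(n_blocks)) {
    a <- random_dna(lens[i])
    n_snp <- stats::rpois(1L, lens[i] * model$snp_rate / 1000)
    if (is_gene[i]) n_snp <- max(n_snp, min_snps_per_gene)
    n_sv <- stats::rpois(1L, lens[i] * model$sv_rate / 1000)
    ops <- draw_variants(lens[i], n_snp, n_sv, model)
    res <- apply_variants(a, ops)
    # Ops landing inside an earlier deletion are relocated (not dropped),
    # so realized variant counts follow the model's per-kbp rates.
    tries <- 0L
    while (nrow(res$dropped) > 0L && tries < 50L) {
      moved <- res$dropped
      moved$position <- sample.int(lens[i], nrow(moved))
      res <- apply_variants(a, rbind(res$log, moved))
      tries <- tries + 1L
    }
    a_blocks[i] <- a
    b_blocks[i] <- res$seq
    if (nrow(res$log)) {
      res$log$position <- res$log$position + offset_a
      res$log$gene_overlap <- is_gene[i]
      logs[[i]] <- res$log
    }
    offset_a <- offset_a + lens[i]
  }
  a_end <- cumsum(nchar(a_blocks))
  a_start <- a_end - nchar(a_blocks) + 1L
  b_end <- cumsum(nchar(b_blocks))
  b_start <- b_end - nchar(b_blocks) + 1L
  genes <- data.frame(gene_id = gene_ids,
                      a_start = a_start[is_gene], a_end = a_end[is_gene],
                      b_start = b_start[is_gene], b_end = b_end[is_gene],
                      strand = "+", stringsAsFactors = FALSE)
  vlog <- do.call(rbind, logs[!vapply(logs, is.null, TRUE)])
  if (is.null(vlog)) {
    vlog <- data.frame(type = character(), position = integer(),
                       size = integer(), gene_overlap = logical())
  }
  structure(list(
    hap_a = paste(a_blocks, collapse = ""),
    hap_b = paste(b_blocks, collapse = ""),
    genes = genes,
    allele_a = stats::setNames(a_blocks[is_gene], gene_ids),
    allele_b = stats::setNames(b_blocks[is_gene], gene_ids),
    variant_log = vlog, model = model, seed = seed
  ), class = "sim_diploid")
}

# Draw SNP/SV events for one block; positions sampled without replacement.
draw_variants <- function(len, n_snp, n_sv, model) {
  n <- n_snp + n_sv
  if (n == 0L || n >= len) {
    return(data.frame(type = character(), position = integer(),
                      size = integer(), stringsAsFactors = FALSE))
  }
  pos <- sample.int(len, n)
  type <- c(rep("snp", n_snp),
            sample(c("ins", "del"), n_sv, replace = TRUE))
  size <- rep(1L, n)
  if (n_sv > 0L) {
    cls <- sample.int(nrow(model$sv_size_classes), n_sv, replace = TRUE,
                      prob = model$sv_probs)
    size[n_snp + seq_len(n_sv)] <- as.integer(round(stats::runif(
      n_sv, model$sv_size_classes[cls, "lo"],
      model$sv_size_classes[cls, "hi"])))
  }
  data.frame(type = type, position = pos, size = size,
             stringsAsFactors = FALSE)
}

# Apply an edit list to a sequence. Ops carry positions on the input frame;
# they are applied left to right, ops shadowed by an earlier deletion are
# dropped, deletions are clipped at the sequence end. Returns the edited
# sequence and the realized op log.
apply_variants <- function(seq, ops) {
  if (nrow(ops) == 0L) {
    return(list(seq = seq, log = ops, dropped = ops))
  }
  ops <- ops[order(ops$position), , drop = FALSE]
  len <- nchar(seq)
  pieces <- character(2L * nrow(ops) + 1L)
  np <- 0L
  cur <- 1L
  realized <- logical(nrow(ops))
  for (i in seq_len(nrow(ops))) {
    p <- ops$position[i]
    if (p < cur) next  # shadowed by a previous deletion
    realized[i] <- TRUE
    if (ops$type[i] == "snp") {
      pieces[np + 1L] <- substr(seq, cur, p - 1L)
      pieces[np + 2L] <- sample(setdiff(BASES, substr(seq, p, p)), 1L)
      np <- np + 2L
      cur <- p + 1L
    } else if (ops$type[i] == "ins") {
      pieces[np + 1L] <- substr(seq, cur, p)
      pieces[np + 2L] <- random_dna(ops$size[i])
      np <- np + 2L
      cur <- p + 1L
    } else {  # del
      pieces[np + 1L] <- substr(seq, cur, p - 1L)
      np <- np + 1L
      cur <- min(p + ops$size[i], len + 1L)
    }
  }
  pieces[np + 1L] <- substr(seq, cur, len)
  list(seq = paste(pieces[seq_len(np + 1L)], collapse = ""),
       log = ops[realized, , drop = FALSE],
       dropped = ops[!realized, , drop = FALSE])
}

#' Simulate HiFi-like reads from a diploid
#'
#' Reads are drawn alternately from the two haplotypes with uniform start
#' positions and truncated-normal lengths (mean 21,000, sd 2,000, clipped to
#' 10,000-30,000 bp by default), with per-base substitution and 1-bp
#' insertion/deletion errors. Generation stops once total bases reach
#' `coverage` times the mean haplotype length. The true source haplotype and
#' coordinates are encoded in each read name (`read_<i>|<hap>|<start>-<end>`)
#' so downstream selection can be checked against truth.
#'
#' @param diploid A `sim_diploid`.
#' @param coverage Target total depth (x; both haplotypes combined).
#' @param length_mean,length_sd,length_min,length_max Read length model, bp.
#' @param sub_rate,ins_rate,del_rate Per-base error rates (defaults
#'   0.002/0.0005/0.0005, HiFi-like).
#' @param seed Integer seed.
#' @return Named character vector of reads.
#' @export
simulate_reads <- function(diploid, coverage, length_mean = 21000,
                           length_sd = 2000, length_min = 10000,
                           length_max = 30000, sub_rate = 0.002,
                           ins_rate = 0.0005, del_rate = 0.0005,
                           seed = 1L) {
  stopifnot(coverage > 0, length_min <= length_mean,
            length_mean <= length_max)
  haps <- c(a = diploid$hap_a, b = diploid$hap_b)
  if (any(nchar(haps) < length_min)) {
    stop("haplotype shorter than the minimum read length")
  }
  set.seed(seed)
  mean_len <- mean(nchar(haps))
  target <- coverage * mean_len
  reads <- character(0)
  total <- 0
  i <- 0L
  while (total < target) {
    i <- i + 1L
    hap <- c("a", "b")[(i %% 2L) + 1L]
    hseq <- haps[[hap]]
    rl <- min(rtrunc_norm(length_mean, length_sd, length_min, length_max),
              nchar(hseq))
    start <- sample.int(nchar(hseq) - rl + 1L, 1L)
    rseq <- substr(hseq, start, start + rl - 1L)
    if (sub_rate > 0 || ins_rate > 0 || del_rate > 0) {
      rseq <- add_read_errors(rseq, sub_rate, ins_rate, del_rate)
    }
    reads[sprintf("read_%d|%s|%d-%d", i, hap, start, start + rl - 1L)] <-
      rseq
    total <- total + nchar(rseq)
  }
  reads
}

# Truncated normal by rejection (the truncation window is wide, so
# rejection is cheap and exact).
rtrunc_norm <- function(mean, sd, lo, hi) {
  repeat {
    x <- stats::rnorm(1L, mean, sd)
    if (x >= lo && x <= hi) return(as.integer(round(x)))
  }
}

add_read_errors <- function(seq, sub_rate, ins_rate, del_rate) {
  len <- nchar(seq)
  n_sub <- stats::rbinom(1L, len, sub_rate)
  n_ins <- stats::rbinom(1L, len, ins_rate)
  n_del <- stats::rbinom(1L, len, del_rate)
  n <- n_sub + n_ins + n_del
  if (n == 0L) return(seq)
  ops <- data.frame(
    type = rep(c("snp", "ins", "del"), c(n_sub, n_ins, n_del)),
    position = sample.int(len, min(n, len)),
    size = 1L, stringsAsFactors = FALSE)[seq_len(min(n, len)), ]
  apply_variants(seq, ops)$seq
}

#' Seeded downsampling of a read set to a target coverage
#'
#' Reads are shuffled under the seed and taken until their cumulative bases
#' reach `target_coverage * genome_size`; identical seeds give identical
#' subsets. If the input holds fewer bases than the target, everything is
#' returned with a warning.
#'
#' @param reads Named character vector of reads.
#' @param target_coverage Target depth (x).
#' @param genome_size Genome size in bp used to define coverage.
#' @param seed Integer seed.
#' @return Named character vector (a subset of `reads`).
#' @export
downsample_reads <- function(reads, target_coverage, genome_size,
                             seed = 1L) {
  target <- target_coverage * genome_size
  lens <- nchar(reads)
  if (sum(lens) <= target) {
    if (sum(lens) < target) {
      warning("available coverage below target; returning all reads")
    }
    return(reads)
  }
  set.seed(seed)
  ord <- sample.int(length(reads))
  keep_n <- which(cumsum(lens[ord]) >= target)[1L]
  reads[sort(ord[seq_len(keep_n)])]
}

#' Coverage implied by a base count
#'
#' @param total_bases Total sequenced bases.
#' @param genome_size Genome size in bp (default 360 Mb, the citrus-scale
#'   convention used for per-cultivar coverage).
#' @return `total_bases / genome_size`.
#' @export
coverage_of <- function(total_bases, genome_size = 360e6) {
  if (genome_size <= 0) stop("genome_size must be positive")
  total_bases / genome_size
}

#' Write a simulated diploid to disk (FASTA + GFF3 + truth sets + log)
#'
#' Emits `hap_a.fasta`/`hap_b.fasta` (chromosomes `chrA`/`chrB`),
#' `genes_a.gff3`/`genes_b.gff3`, truth allele FASTAs
#' `allele_a.fasta`/`allele_b.fasta`, and `variant_log.tsv`.
#'
#' @param diploid A `sim_diploid`.
#' @param outdir Output directory.
#' @return Invisibly, the output directory.
#' @export
write_diploid <- function(diploid, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(c(chrA = diploid$hap_a), file.path(outdir, "hap_a.fasta"))
  write_fasta(c(chrB = diploid$hap_b), file.path(outdir, "hap_b.fasta"))
  write_fasta(diploid$allele_a, file.path(outdir, "allele_a.fasta"))
  write_fasta(diploid$allele_b, file.path(outdir, "allele_b.fasta"))
  g <- diploid$genes
  write_gff3(g$gene_id, "chrA", g$a_start, g$a_end, g$strand,
             file.path(outdir, "genes_a.gff3"))
  write_gff3(g$gene_id, "chrB", g$b_start, g$b_end, g$strand,
             file.path(outdir, "genes_b.gff3"))
  utils::write.table(diploid$variant_log,
                     file.path(outdir, "variant_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

write_gff3 <- function(ids, seqid, start, end, strand, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tgenephase\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     seqid, start, end, strand, ids))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.sim_diploid <- function(x, ...) {
  cat(sprintf(paste0("sim_diploid: %d genes, haplotypes %s/%s bp, ",
                     "%d variants (%s model), seed %d\n"),
              nrow(x$genes), format(nchar(x$hap_a), big.mark = ","),
              format(nchar(x$hap_b), big.mark = ","),
              nrow(x$variant_log), x$model$name, x$seed))
  invisible(x)
}
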