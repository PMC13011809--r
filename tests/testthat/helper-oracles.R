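# Independent oracles and small constructors used across the suite.

oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Literal transcription of the strand-specific spanning-read selection
# inequalities, evaluated one record at a time (the implementation under
# test is vectorised; this one is deliberately scalar and direct).
oracle_spanning <- function(L, S, E, strand, l, s, e, mapq,
                            min_mapq = 60, span_fraction = 0.95) {
  if (mapq < min_mapq) return(FALSE)
  common <- ((e + 1) - (s + 1) > l * span_fraction) && (L > l)
  if (strand == "+") {
    common && (S + 1 > s + 1) && (L - S > l - s)
  } else {
    Sp <- L - E - 1
    common && (Sp + 1 > s + 1) && (E + 1 > l - s)
  }
}

# Exact k-mer Jaccard by direct set construction (canonical k-mers built
# with a different mechanism than the implementation: per-k-mer loop with
# chartr-based reverse complement).
oracle_jaccard <- function(a, b, k = 21) {
  kmers <- function(seq) {
    n <- nchar(seq)
    out <- character(n - k + 1)
    for (i in seq_len(n - k + 1)) {
      f <- substr(seq, i, i + k - 1)
      r <- oracle_revcomp(f)
      out[i] <- if (f <= r) f else r
    }
    unique(out)
  }
  ka <- kmers(a); kb <- kmers(b)
  length(intersect(ka, kb)) / length(union(ka, kb))
}

# Levenshtein distance via alignment with unit costs (Biostrings route,
# independent of the utils::adist route used by tolerant_match).
oracle_edit_distance <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -1)
  -Biostrings::score(Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 1))
}

# Random alignment records exercising every boundary of the selection law.
random_alignment_records <- function(n, seed) {
  set.seed(seed)
  l <- sample(500:3000, n, replace = TRUE)
  L <- pmax(l + sample(-200:4000, n, replace = TRUE), 50L)
  S <- integer(n); E <- integer(n); s <- integer(n); e <- integer(n)
  for (i in seq_len(n)) {
    S[i] <- sample.int(L[i], 1) - 1L
    E[i] <- S[i] + sample.int(L[i] - S[i], 1) - 1L
    s[i] <- sample.int(l[i], 1) - 1L
    e[i] <- s[i] + sample.int(l[i] - s[i], 1) - 1L
  }
  data.frame(
    read_id = sprintf("r%d", seq_len(n)), L = L, S = S, E = E,
    strand = sample(c("+", "-"), n, replace = TRUE),
    gene_id = sprintf("g%d", sample.int(20, n, replace = TRUE)),
    l = l, s = s, e = e,
    mapq = sample(c(60L, 60L, 60L, 59L, sample(0:60, 1)), n,
                  replace = TRUE),
    stringsAsFactors = FALSE)
}

# A diploid locus built directly: haplotype windows differing at known SNP
# positions, plus reads copied from them (optionally with errors).
make_locus_reads <- function(len = 2000, n_snps = 3, reads_per_hap = 15,
                             flank = 300, sub_rate = 0, seed = 1) {
  set.seed(seed)
  h1 <- rand_dna(len + 2 * flank)
  h2 <- h1
  if (n_snps > 0) {
    pos <- sample((flank + 1):(flank + len), n_snps)
    for (p in pos) {
      old <- substr(h2, p, p)
      substr(h2, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    }
  }
  mutate <- function(x) {
    if (sub_rate == 0) return(x)
    v <- strsplit(x, "")[[1]]
    hit <- which(stats::runif(length(v)) < sub_rate)
    for (p in hit) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    paste(v, collapse = "")
  }
  reads <- c(vapply(seq_len(reads_per_hap), function(i) mutate(h1), ""),
             vapply(seq_len(reads_per_hap), function(i) mutate(h2), ""))
  list(h1 = h1, h2 = h2, tgrs = substr(h1, flank + 1, flank + len),
       gene_span_1 = substr(h1, flank + 1, flank + len),
       gene_span_2 = substr(h2, flank + 1, flank + len),
       reads = reads)
}
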