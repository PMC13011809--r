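# Step 6: per-locus summary records — zygosity, allele lengths, k-mer
# Jaccard between alleles, MinHash signatures — written as ASF CSV files.

#' Exact Jaccard similarity between the canonical k-mer sets of two sequences
#'
#' Canonical k-mers (the lexicographic minimum of a k-mer and its reverse
#' complement) make the measure strand-independent. Identical sequences give
#' exactly 1; disjoint k-mer contents give 0.
#'
#' @param a,b DNA sequences.
#' @param k k-mer size (default 21).
#' @return Jaccard coefficient in `[0, 1]`.
#' @export
kmer_jaccard <- function(a, b, k = 21L) {
  ka <- canonical_kmers(a, k)
  kb <- canonical_kmers(b, k)
  length(intersect(ka, kb)) / length(union(ka, kb))
}

canonical_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) stop(sprintf("sequence length %d < k = %d", n, k))
  starts <- seq_len(n - k + 1L)
  fwd <- substring(seq, starts, starts + k - 1L)
  rev <- substring(revcomp(seq), starts, starts + k - 1L)
  rev <- rev[length(rev):1L]  # rev[i] = revcomp of fwd[i]
  unique(pmin(fwd, rev))
}

# MinHash machinery. k-mers are reduced to integer fingerprints with a
# polynomial rolling hash over a prime field small enough that the
# permutation arithmetic (a*h + b mod p) stays exact in doubles.
MINHASH_P <- 67108859   # largest prime < 2^26
MINHASH_P2 <- 67108837  # second, independent fingerprint field

# Two independent polynomial fingerprints per k-mer; the first feeds the
# MinHash permutations, both feed the identity digest (a k-mer set collision
# must hit both fields at once, which is negligible at panel scale).
kmer_fingerprints <- function(kmers) {
  h1 <- numeric(length(kmers))
  h2 <- numeric(length(kmers))
  for (i in seq_len(max(nchar(kmers)))) {
    v <- match(substr(kmers, i, i), BASES) - 1L
    h1 <- (h1 * 5 + v) %% MINHASH_P
    h2 <- (h2 * 7 + v + 3) %% MINHASH_P2
  }
  list(h1 = h1, h2 = h2)
}

#' MinHash signature of a sequence's canonical k-mer set
#'
#' Computes `num_hashes` independent minimum hash values over the canonical
#' k-mer set under seeded universal-hash permutations, plus a fixed-length
#' hex digest folded over the full fingerprinted k-mer set (not only the
#' minima, so even a single-base difference perturbs it). Identical
#' sequences always give identical digests and non-identical alleles get
#' distinct ones (collisions are negligible at panel scale); the
#' per-permutation minima support alignment-free Jaccard estimation via
#' [minhash_jaccard()].
#'
#' @param seq DNA sequence (length >= `k`).
#' @param k k-mer size (default 21).
#' @param num_hashes Number of hash permutations (default 128).
#' @param hash_seed Seed fixing the permutation family (default 42; keep
#'   constant across runs that must be comparable).
#' @return Object of class `minhash`: list with `values` (numeric vector of
#'   length `num_hashes`), `digest` (16-char hex string), `k`, `num_hashes`,
#'   `hash_seed`.
#' @export
minhash_signature <- function(seq, k = 21L, num_hashes = 128L,
                              hash_seed = 42L) {
  km <- canonical_kmers(seq, k)
  fp <- kmer_fingerprints(km)
  perms <- minhash_perms(num_hashes, hash_seed)
  vals <- numeric(num_hashes)
  for (j in seq_len(num_hashes)) {
    vals[j] <- min((perms$a[j] * fp$h1 + perms$b[j]) %% MINHASH_P)
  }
  digest <- fold_digest(c(length(fp$h1), sort(fp$h1), sort(fp$h2), vals))
  structure(list(values = vals, digest = digest, k = k,
                 num_hashes = num_hashes, hash_seed = hash_seed),
            class = "minhash")
}

minhash_perms <- function(num_hashes, hash_seed) {
  set.seed(hash_seed)
  list(a = sample.int(MINHASH_P - 1L, num_hashes, replace = TRUE),
       b = sample.int(MINHASH_P, num_hashes, replace = TRUE) - 1L)
}

# Polynomial fold of the signature values into a fixed 16-char hex digest.
# Two independent prime-modulus accumulators; all arithmetic stays below
# 2^53 so the fold is exact in doubles.
fold_digest <- function(vals) {
  h1 <- 2166136261 %% 2147483629
  h2 <- 40389
  for (v in vals) {
    h1 <- (h1 * 131 + v + 17) %% 2147483629
    h2 <- (h2 * 31 + v) %% 4294967291
  }
  sprintf("%08x%08x", as.integer(h1), as.integer(h2 %% 2^31))
}

#' Estimate Jaccard similarity from two MinHash signatures
#'
#' The fraction of matching per-permutation minima is an unbiased estimator
#' of the k-mer Jaccard coefficient with standard error about
#' `1/sqrt(num_hashes)`.
#'
#' @param sig1,sig2 `minhash` objects with the same `k`, `num_hashes`, and
#'   `hash_seed`.
#' @return Estimated Jaccard coefficient.
#' @export
minhash_jaccard <- function(sig1, sig2) {
  stopifnot(sig1$k == sig2$k, sig1$num_hashes == sig2$num_hashes,
            sig1$hash_seed == sig2$hash_seed)
  mean(sig1$values == sig2$values)
}

#' @export
print.minhash <- function(x, ...) {
  cat(sprintf("minhash: k=%d, %d hashes, digest %s\n",
              x$k, x$num_hashes, x$digest))
  invisible(x)
}

#' Summarize one phased locus into an ASF record
#'
#' One row per locus: zygosity, read support, assembler provenance, allele
#' lengths, and for heterozygous loci the k-mer Jaccard between the two
#' alleles plus both MinHash digests. Homozygous loci carry a single length
#' and digest; Jaccard is left empty (it is defined between two alleles).
#'
#' @param alleles Allele data.frame from [extract_alleles()], all rows from
#'   one flank tier of one locus.
#' @param locus The corresponding `phased_locus`.
#' @param k,num_hashes,hash_seed Sketch parameters (see
#'   [minhash_signature()]).
#' @return One-row data.frame with columns `gene_id`, `zygosity`,
#'   `n_reads_selected`, `assembler_used`, `allele1_len`, `allele2_len`,
#'   `jaccard`, `minhash1`, `minhash2`.
#' @export
summarize_locus <- function(alleles, locus, k = 21L, num_hashes = 128L,
                            hash_seed = 42L) {
  base <- data.frame(gene_id = locus$gene_id, zygosity = locus$zygosity,
                     n_reads_selected = locus$n_reads,
                     assembler_used = locus$assembler_used,
                     allele1_len = NA_integer_, allele2_len = NA_integer_,
                     jaccard = NA_real_, minhash1 = NA_character_,
                     minhash2 = NA_character_, stringsAsFactors = FALSE)
  if (is.null(alleles) || nrow(alleles) == 0L) return(base)
  sq <- alleles$sequence[order(alleles$label)]
  base$allele1_len <- nchar(sq[1L])
  sketchable <- nchar(sq) >= k
  if (sketchable[1L]) {
    base$minhash1 <- minhash_signature(sq[1L], k, num_hashes, hash_seed)$digest
  }
  if (length(sq) == 2L) {
    base$allele2_len <- nchar(sq[2L])
    if (sketchable[2L]) {
      base$minhash2 <- minhash_signature(sq[2L], k, num_hashes,
                                         hash_seed)$digest
    }
    if (all(sketchable)) base$jaccard <- kmer_jaccard(sq[1L], sq[2L], k)
  }
  base
}

#' Write ASF summary files (CSV), one per flank tier
#'
#' Column order: gene_id, zygosity, n_reads_selected, assembler_used,
#' allele1_len, allele2_len, jaccard, minhash1, minhash2.
#'
#' @param summaries Data.frame of [summarize_locus()] rows with an extra
#'   `flank` column, or a single-tier data.frame.
#' @param outdir Output directory.
#' @param prefix File prefix (default `"ASF"`; tiers named like allele
#'   FASTAs: `ASF.csv`, `ASF-2K.csv`, `ASF-UD<n>.csv`).
#' @return Invisibly, written paths.
#' @export
write_asf <- function(summaries, outdir, prefix = "ASF") {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cols <- c("gene_id", "zygosity", "n_reads_selected", "assembler_used",
            "allele1_len", "allele2_len", "jaccard", "minhash1", "minhash2")
  flanks <- if ("flank" %in% names(summaries)) summaries$flank else 0
  paths <- character(0)
  for (fl in sort(unique(flanks))) {
    sub <- summaries[flanks == fl, cols, drop = FALSE]
    tag <- if (fl == 0) "" else if (fl == 2000) "-2K" else paste0("-UD", fl)
    path <- file.path(outdir, paste0(prefix, tag, ".csv"))
    utils::write.csv(sub, path, row.names = FALSE, quote = FALSE, na = "")
    paths <- c(paths, path)
  }
  invisible(paths)
}
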