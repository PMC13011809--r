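# Step 4: assemble each locus's spanning reads into 1 or 2 phased contigs
# and call zygosity. Two contigs indicate a heterozygous locus; a single
# contig denotes homozygosity.

#' Built-in diploid locus assembler (pileup consensus with read partitioning)
#'
#' A self-contained assembler for reads that each span the whole locus, so a
#' column-wise pileup is a valid coordinate frame (no overlap-layout graph is
#' needed). The reads are multiple-aligned (mafft), candidate heterozygous
#' sites are the pileup columns whose second-most-frequent symbol (base or
#' gap) reaches both `min_alt_fraction` of the column depth and
#' `min_alt_support` reads, reads are partitioned into two groups by
#' average-linkage clustering on their site-allele vectors, and each group is
#' collapsed to a column-majority consensus. One contig is emitted when there
#' are no candidate sites (or the partition is degenerate or both consensi
#' are identical), two otherwise.
#'
#' @param reads Character vector of read sequences, all oriented the same
#'   way and each spanning the locus.
#' @param tgrs TGRS sequence for the locus (used only for sanity/reporting;
#'   the pileup frame comes from the reads themselves).
#' @param min_alt_fraction Minimum minor-symbol fraction for a candidate
#'   heterozygous site (default 0.2, tolerant of HiFi-scale error).
#' @param min_alt_support Minimum minor-symbol read count (default 3).
#' @param seed Integer seed controlling read subsampling.
#' @param max_reads Reads above this count are subsampled (seeded) before the
#'   multiple alignment (default 60).
#' @return Character vector of 0, 1 or 2 contigs.
#' @export
builtin_assemble <- function(reads, tgrs = NULL, min_alt_fraction = 0.2,
                             min_alt_support = 3, seed = 1L,
                             max_reads = 60L) {
  reads <- reads[nzchar(reads)]
  if (length(reads) == 0L) return(character(0))
  if (length(reads) == 1L) return(unname(reads))
  if (length(reads) > max_reads) {
    set.seed(seed)
    reads <- reads[sort(sample.int(length(reads), max_reads))]
  }
  M <- pileup_matrix(reads)
  if (is.null(M)) return(character(0))
  st <- pileup_column_stats(M)
  sites <- which(st$alt_count >= min_alt_support &
                 st$alt_frac >= min_alt_fraction)
  if (length(sites) == 0L) {
    return(consensus_from_pileup(M))
  }
  groups <- partition_reads(M[, sites, drop = FALSE], seed = seed)
  if (min(tabulate(groups, 2L)) < 2L) {
    return(consensus_from_pileup(M))
  }
  c1 <- consensus_from_pileup(M[groups == 1L, , drop = FALSE])
  c2 <- consensus_from_pileup(M[groups == 2L, , drop = FALSE])
  ctg <- unique(c(c1, c2))
  ctg[nzchar(ctg)]
}

#' Plain consensus assembler (always one contig)
#'
#' Collapses all reads to a single column-majority consensus without
#' heterozygous-site partitioning. Used as the default fallback backend.
#'
#' @inheritParams builtin_assemble
#' @return Character vector with a single contig (or empty).
#' @export
consensus_assemble <- function(reads, tgrs = NULL, seed = 1L,
                               max_reads = 60L) {
  reads <- reads[nzchar(reads)]
  if (length(reads) == 0L) return(character(0))
  if (length(reads) == 1L) return(unname(reads))
  if (length(reads) > max_reads) {
    set.seed(seed)
    reads <- reads[sort(sample.int(length(reads), max_reads))]
  }
  M <- pileup_matrix(reads)
  if (is.null(M)) return(character(0))
  consensus_from_pileup(M)
}

# Multiple-align reads with mafft and return a character matrix
# (rows = reads, cols = alignment columns). Leading/trailing gaps of each
# row (ragged window ends, not deletions) are masked to NA.
pileup_matrix <- function(reads) {
  mafft <- require_binary("mafft")
  tmp_in <- tempfile("msa_", fileext = ".fasta")
  tmp_out <- tempfile("msa_", fileext = ".aln")
  on.exit(unlink(c(tmp_in, tmp_out)))
  write_fasta(stats::setNames(reads, paste0("r", seq_along(reads))), tmp_in)
  status <- system2(mafft, c("--retree", "1", "--maxiterate", "0",
                             "--quiet", tmp_in),
                    stdout = tmp_out, stderr = FALSE)
  if (!identical(status, 0L)) return(NULL)
  aln <- read_seqs(tmp_out)
  if (length(aln) != length(reads)) return(NULL)
  M <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  for (i in seq_len(nrow(M))) {
    nongap <- which(M[i, ] != "-")
    if (length(nongap) == 0L) { M[i, ] <- NA_character_; next }
    lo <- nongap[1L]; hi <- nongap[length(nongap)]
    if (lo > 1L) M[i, seq_len(lo - 1L)] <- NA_character_
    if (hi < ncol(M)) M[i, seq(hi + 1L, ncol(M))] <- NA_character_
  }
  M
}

SYMBOLS <- c("A", "C", "G", "T", "-")

# Per-column symbol counts, depth, and minor-symbol support/fraction.
pileup_column_stats <- function(M) {
  counts <- vapply(SYMBOLS, function(s) colSums(M == s, na.rm = TRUE),
                   numeric(ncol(M)))
  if (ncol(M) == 1L) counts <- matrix(counts, nrow = 1L,
                                      dimnames = list(NULL, SYMBOLS))
  depth <- rowSums(counts)
  top <- max.col(counts, ties.method = "first")
  tmp <- counts
  tmp[cbind(seq_len(nrow(tmp)), top)] <- -1
  alt_count <- pmax(tmp[, 1L], tmp[, 2L], tmp[, 3L], tmp[, 4L], tmp[, 5L])
  alt_frac <- ifelse(depth > 0, alt_count / depth, 0)
  list(depth = depth, alt_count = alt_count, alt_frac = alt_frac)
}

# Cluster reads into two groups on their site-allele vectors
# (average-linkage on pairwise mismatch fraction; NA-tolerant).
partition_reads <- function(sites, seed = 1L) {
  n <- nrow(sites)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      both <- !is.na(sites[i, ]) & !is.na(sites[j, ])
      d[i, j] <- d[j, i] <- if (any(both)) {
        mean(sites[i, both] != sites[j, both])
      } else 0.5
    }
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  stats::cutree(hc, k = 2L)
}

consensus_from_pileup <- function(M) {
  counts <- vapply(SYMBOLS, function(s) colSums(M == s, na.rm = TRUE),
                   numeric(ncol(M)))
  if (ncol(M) == 1L) counts <- matrix(counts, nrow = 1L)
  depth <- rowSums(counts)
  # max.col with ties.method = "first" resolves ties in fixed symbol order
  # (bases win over the gap symbol).
  pick <- SYMBOLS[max.col(counts, ties.method = "first")]
  paste(pick[depth > 0 & pick != "-"], collapse = "")
}

#' Define an assembler backend
#'
#' Backends follow one contract: reads in, contigs out, deterministic given
#' a seed. Built-ins are `"pileup"` ([builtin_assemble()]) and
#' `"consensus"` ([consensus_assemble()]). External assemblers (e.g. hifiasm
#' or Flye adapters) are wrapped as a command that is invoked as
#' `cmd <reads.fasta> <contigs.fasta>`; a missing binary makes the backend
#' unavailable (skipped with a note), never a load-time failure.
#'
#' @param name Backend name: `"pileup"`, `"consensus"`, or a label for an
#'   external command.
#' @param cmd For external backends, the command to invoke.
#' @return An `assembler_backend` object (list with `name`, `kind`, `fn`).
#' @export
assembler_backend <- function(name, cmd = NULL) {
  if (inherits(name, "assembler_backend")) return(name)
  if (is.null(cmd)) {
    fn <- switch(name,
      pileup = function(reads, tgrs, seed, ...)
        builtin_assemble(reads, tgrs, seed = seed, ...),
      consensus = function(reads, tgrs, seed, ...)
        consensus_assemble(reads, tgrs, seed = seed),
      stop(sprintf("unknown built-in assembler backend '%s'", name))
    )
    return(structure(list(name = name, kind = "builtin", fn = fn),
                     class = "assembler_backend"))
  }
  fn <- function(reads, tgrs, seed, ...) {
    if (!nzchar(Sys.which(strsplit(cmd, "\\s+")[[1]][1]))) {
      message(sprintf("external assembler '%s' not on PATH; skipped", name))
      return(character(0))
    }
    tmp_in <- tempfile("asm_", fileext = ".fasta")
    tmp_out <- tempfile("asm_", fileext = ".fasta")
    on.exit(unlink(c(tmp_in, tmp_out)))
    write_fasta(stats::setNames(reads, paste0("r", seq_along(reads))),
                tmp_in)
    parts <- strsplit(cmd, "\\s+")[[1]]
    status <- system2(parts[1], c(parts[-1], tmp_in, tmp_out),
                      stdout = FALSE, stderr = FALSE)
    if (!identical(status, 0L) || !file.exists(tmp_out)) return(character(0))
    unname(read_seqs(tmp_out))
  }
  structure(list(name = name, kind = "external", fn = fn),
            class = "assembler_backend")
}

#' Assemble one locus into phased contigs and call zygosity
#'
#' Runs the primary assembler on the locus's spanning reads (trimmed to a
#' window of the TGRS match plus `window_flank` bp on each side); the
#' fallback assembler is invoked iff the primary yields zero contigs (and,
#' when `fallback_on_excess`, also on more than two). The final contig count
#' is mapped to zygosity: 2 = heterozygous, 1 = homozygous, anything else =
#' failed (unless `keep_two_longest`, which retains the two longest contigs).
#'
#' @param read_set A `locus_read_set` (see [locus_read_sets()]), or `NULL` /
#'   empty for a locus with no selected reads.
#' @param tgrs_seq TGRS sequence for the locus.
#' @param primary,fallback Assembler backends (names or
#'   [assembler_backend()] objects).
#' @param seed Integer seed.
#' @param window_flank Extra bp kept on each side of the TGRS match when
#'   trimming reads for assembly (default 2500, enough for +/-2 kbp allele
#'   flanks).
#' @param fallback_on_excess Also fall back when the primary emits >2
#'   contigs (default FALSE).
#' @param keep_two_longest Keep the two longest contigs instead of failing
#'   when >2 are produced (default FALSE).
#' @param ... Passed to the backend (e.g. `min_alt_fraction`).
#' @return A `phased_locus`: list with `gene_id`, `contigs` (the phased
#'   contigs), `zygosity` (`"heterozygous"`, `"homozygous"`, `"failed"`),
#'   `assembler_used` (`"primary"`, `"fallback"`, `"none"`), `n_reads`,
#'   and `failure_stage` (`NA` or one of `"read_selection"`, `"assembly"`).
#' @export
assemble_locus <- function(read_set, tgrs_seq, primary = "pileup",
                           fallback = "consensus", seed = 1L,
                           window_flank = 2500L, fallback_on_excess = FALSE,
                           keep_two_longest = FALSE, ...) {
  gid <- if (is.null(read_set)) NA_character_ else read_set$gene_id
  if (is.null(read_set) || read_set$n_selected == 0L) {
    return(phased_locus(gid, character(0), "none", "read_selection", 0L))
  }
  rd <- read_set$reads
  lo <- pmax(1L, rd$S + 1L - window_flank)
  hi <- pmin(nchar(rd$sequence), rd$E + 1L + window_flank)
  windows <- substr(rd$sequence, lo, hi)

  primary <- assembler_backend(primary)
  fallback <- assembler_backend(fallback)
  contigs <- primary$fn(windows, tgrs_seq, seed = seed, ...)
  used <- "primary"
  need_fb <- length(contigs) == 0L ||
    (fallback_on_excess && length(contigs) > 2L)
  if (need_fb) {
    contigs <- fallback$fn(windows, tgrs_seq, seed = seed)
    used <- "fallback"
  }
  if (length(contigs) > 2L && keep_two_longest) {
    contigs <- contigs[order(-nchar(contigs))][1:2]
  }
  if (!length(contigs) %in% c(1L, 2L)) {
    return(phased_locus(gid, character(0), "none", "assembly",
                        read_set$n_selected))
  }
  phased_locus(gid, contigs, used, NA_character_, read_set$n_selected)
}

phased_locus <- function(gene_id, contigs, assembler_used, failure_stage,
                         n_reads) {
  zyg <- if (length(contigs) == 2L) "heterozygous" else
    if (length(contigs) == 1L) "homozygous" else "failed"
  structure(list(gene_id = gene_id, contigs = contigs, zygosity = zyg,
                 assembler_used = assembler_used,
                 failure_stage = failure_stage, n_reads = n_reads),
            class = "phased_locus")
}

#' @export
print.phased_locus <- function(x, ...) {
  cat(sprintf("phased_locus %s: %s (%d contig(s), %d reads, %s)\n",
              x$gene_id, x$zygosity, length(x$contigs), x$n_reads,
              x$assembler_used))
  invisible(x)
}
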