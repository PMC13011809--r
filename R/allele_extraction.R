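# Step 5: align each phased contig back to its TGRS, delineate the gene
# boundaries, and emit allele sequences with 0 / +-2 kbp / user-defined
# flanks (AAS, AAS-2K, AAS-UD).

#' Delineate gene boundaries on a contig by aligning the TGRS back to it
#'
#' The TGRS is aligned against the contig in both orientations
#' (global-on-pattern / local-on-subject, so the whole TGRS is placed within
#' the contig) and the better-scoring orientation defines the gene interval.
#' Scoring: match 1, mismatch -2, gap open -4, gap extend -1 (configurable).
#' The fraction of TGRS bases matched is reported; below `min_tgrs_cov` the
#' locus fails at the allele-extraction stage.
#'
#' @param contig Contig sequence.
#' @param tgrs_seq TGRS sequence.
#' @param min_tgrs_cov Minimum fraction of TGRS bases matched (default 0.5).
#' @param match,mismatch,gap_open,gap_extend Alignment scores.
#' @return List with `start`, `end` (1-based inclusive gene interval on the
#'   contig, in the *reported* orientation), `orientation` (`"+"` or `"-"`),
#'   `identity` (matched TGRS fraction), and `ok` (logical). For a `"-"` hit
#'   the interval refers to the reverse-complemented contig.
#' @export
delineate_boundaries <- function(contig, tgrs_seq, min_tgrs_cov = 0.5,
                                 match = 1, mismatch = -2, gap_open = 4,
                                 gap_extend = 1) {
  stopifnot(nzchar(contig), nzchar(tgrs_seq))
  l <- nchar(tgrs_seq)
  # Fast path: an exact embedded copy of the TGRS needs no alignment.
  hit <- regexpr(tgrs_seq, contig, fixed = TRUE)
  if (hit > 0L) {
    return(list(start = as.integer(hit), end = as.integer(hit) + l - 1L,
                orientation = "+", identity = 1, ok = TRUE))
  }
  rc <- revcomp(contig)
  hit <- regexpr(tgrs_seq, rc, fixed = TRUE)
  if (hit > 0L) {
    return(list(start = as.integer(hit), end = as.integer(hit) + l - 1L,
                orientation = "-", identity = 1, ok = TRUE))
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  score_one <- function(subj) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = tgrs_seq, subject = subj, type = "global-local",
      substitutionMatrix = mat, gapOpening = gap_open,
      gapExtension = gap_extend)
    list(identity = Biostrings::nmatch(aln) / l,
         start = Biostrings::start(Biostrings::subject(aln)),
         end = Biostrings::end(Biostrings::subject(aln)),
         score = Biostrings::score(aln))
  }
  fwd <- score_one(contig)
  # A confident forward hit cannot be beaten by the reverse orientation;
  # only compute the reverse alignment when the forward one is weak.
  if (fwd$identity >= 0.9) {
    best <- fwd; orient <- "+"
  } else {
    rev <- score_one(revcomp(contig))
    if (rev$score > fwd$score) { best <- rev; orient <- "-" }
    else { best <- fwd; orient <- "+" }
  }
  list(start = best$start, end = best$end, orientation = orient,
       identity = best$identity, ok = best$identity >= min_tgrs_cov)
}

#' Extract allele sequences from a phased locus
#'
#' Each contig of a phased locus yields one allele per requested flank: the
#' TGRS-delineated gene interval extended by up to `flank` bp on each side
#' (clipped to the available contig sequence; the obtained flank widths are
#' recorded). All alleles are normalized to TGRS-forward orientation.
#' Heterozygous alleles are labelled `h1`/`h2` after sorting the pair by
#' (length, then lexicographic) — biological phase is unknowable without
#' pedigree, so the ordering is a reproducibility convention; a homozygous
#' allele is labelled `H`.
#'
#' @param locus A `phased_locus` from [assemble_locus()].
#' @param tgrs_seq TGRS sequence for the locus.
#' @param flanks Integer vector of requested flank widths in bp
#'   (default `c(0, 2000)` — the AAS and AAS-2K tiers).
#' @param min_tgrs_cov Passed to [delineate_boundaries()].
#' @return A data.frame with one row per contig x flank: `gene_id`, `label`
#'   (`h1`/`h2`/`H`), `flank` (requested bp), `left_flank`, `right_flank`
#'   (obtained bp), `contig_index`, `sequence`; or an empty data.frame with attribute
#'   `failure_stage = "allele_extraction"` when delineation fails for every
#'   contig. Contigs failing delineation individually are dropped.
#' @export
extract_alleles <- function(locus, tgrs_seq, flanks = c(0, 2000),
                            min_tgrs_cov = 0.5) {
  if (locus$zygosity == "failed" || length(locus$contigs) == 0L) {
    return(failed_extraction())
  }
  placed <- list()
  for (i in seq_along(locus$contigs)) {
    ctg <- locus$contigs[[i]]
    b <- delineate_boundaries(ctg, tgrs_seq, min_tgrs_cov = min_tgrs_cov)
    if (!b$ok) next
    if (b$orientation == "-") ctg <- revcomp(ctg)
    placed[[length(placed) + 1L]] <- list(contig = ctg, start = b$start,
                                          end = b$end, index = i)
  }
  if (length(placed) == 0L) return(failed_extraction())
  # Deterministic h1/h2 ordering: by gene-interval length, then sequence.
  if (length(placed) == 2L) {
    key <- vapply(placed, function(p)
      sprintf("%012d|%s", p$end - p$start + 1L,
              substr(p$contig, p$start, p$end)), "")
    placed <- placed[order(key)]
    labels <- c("h1", "h2")
  } else {
    labels <- "H"
  }
  rows <- list()
  for (j in seq_along(placed)) {
    p <- placed[[j]]
    clen <- nchar(p$contig)
    for (fl in flanks) {
      left <- min(fl, p$start - 1L)
      right <- min(fl, clen - p$end)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = locus$gene_id, label = labels[j], flank = fl,
        left_flank = left, right_flank = right, contig_index = p$index,
        sequence = substr(p$contig, p$start - left, p$end + right),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Empty result marking an allele-extraction-stage failure.
failed_extraction <- function() {
  structure(data.frame(), failure_stage = "allele_extraction")
}

#' Write allele sequences as FASTA, one file per flank tier
#'
#' Record ids follow `{gene_id}|{label}|flank={n}`; sequences are
#' TGRS-forward and bit-identical across runs.
#'
#' @param alleles Allele data.frame from [extract_alleles()] (rows from many
#'   loci may be concatenated).
#' @param outdir Output directory.
#' @param prefix File name prefix (default `"AAS"`); flank tiers are written
#'   as `<prefix>.fasta` (flank 0), `<prefix>-2K.fasta` (flank 2000) and
#'   `<prefix>-UD<flank>.fasta` otherwise.
#' @return Invisibly, the written paths.
#' @export
write_alleles <- function(alleles, outdir, prefix = "AAS") {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (fl in sort(unique(alleles$flank))) {
    sub <- alleles[alleles$flank == fl, , drop = FALSE]
    tag <- if (fl == 0) "" else if (fl == 2000) "-2K" else paste0("-UD", fl)
    path <- file.path(outdir, paste0(prefix, tag, ".fasta"))
    ids <- sprintf("%s|%s|flank=%d", sub$gene_id, sub$label, sub$flank)
    write_fasta(stats::setNames(sub$sequence, ids), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
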