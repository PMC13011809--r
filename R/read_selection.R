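# Steps 2-3: map query reads to each TGRS and keep only reads that fully
# span the locus, using the strand-specific selection inequalities.

#' Parse a PAF alignment file into read-to-TGRS alignment records
#'
#' Reads minimap2-style PAF (12+ tab-separated columns). End coordinates in
#' PAF are 0-based half-open; they are converted to the 0-based *inclusive*
#' convention used by the selection arithmetic (`E = qend - 1`,
#' `e = tend - 1`). Records flagged secondary (`tp:A:S`) are dropped.
#'
#' @param path Path to a PAF file.
#' @param tgrs Optional `tgrs_set`; alignments to unknown gene ids are then
#'   dropped with a warning giving the count.
#' @return A data.frame of alignments with columns `read_id`, `L` (read
#'   length), `S`, `E` (0-based inclusive match coords on the read),
#'   `strand`, `gene_id`, `l` (TGRS length), `s`, `e` (0-based inclusive
#'   match coords on the TGRS), `mapq`.
#' @export
read_paf <- function(path, tgrs = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_alignments())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) < 12L)
  if (length(bad)) {
    stop(sprintf("malformed PAF line %d: fewer than 12 columns", bad[1L]))
  }
  secondary <- vapply(fields, function(f) any(f == "tp:A:S"), logical(1))
  fields <- fields[!secondary]
  if (length(fields) == 0L) return(empty_alignments())
  m <- do.call(rbind, lapply(fields, `[`, 1:12))
  aln <- data.frame(
    read_id = m[, 1],
    L = as.integer(m[, 2]),
    S = as.integer(m[, 3]),
    E = as.integer(m[, 4]) - 1L,
    strand = m[, 5],
    gene_id = m[, 6],
    l = as.integer(m[, 7]),
    s = as.integer(m[, 8]),
    e = as.integer(m[, 9]) - 1L,
    mapq = as.integer(m[, 12]),
    stringsAsFactors = FALSE
  )
  validate_alignments(aln)
  if (!is.null(tgrs)) {
    unknown <- !aln$gene_id %in% tgrs$info$gene_id
    if (any(unknown)) {
      warning(sprintf("dropped %d alignment(s) to unknown gene ids",
                      sum(unknown)))
      aln <- aln[!unknown, , drop = FALSE]
    }
  }
  aln
}

empty_alignments <- function() {
  data.frame(read_id = character(), L = integer(), S = integer(),
             E = integer(), strand = character(), gene_id = character(),
             l = integer(), s = integer(), e = integer(), mapq = integer(),
             stringsAsFactors = FALSE)
}

validate_alignments <- function(aln) {
  ok <- aln$S >= 0L & aln$S <= aln$E & aln$E < aln$L &
    aln$s >= 0L & aln$s <= aln$e & aln$e < aln$l &
    aln$mapq >= 0L & aln$mapq <= 60L & aln$strand %in% c("+", "-")
  if (any(!ok)) {
    stop(sprintf("invalid alignment record for read '%s' on gene '%s'",
                 aln$read_id[!ok][1L], aln$gene_id[!ok][1L]))
  }
  invisible(aln)
}

#' Map reads against a TGRS collection with minimap2
#'
#' Runs the minimap2 binary (preset `map-hifi`, secondary alignments
#' suppressed) with the TGRS collection as the target and returns the primary
#' alignments as a validated record set. Any aligner producing PAF can stand
#' in by supplying its output to [read_paf()] instead.
#'
#' @param reads Named character vector of read sequences, or a FASTA/FASTQ
#'   path.
#' @param tgrs A `tgrs_set` from [extract_tgrs()].
#' @param preset minimap2 preset (default `"map-hifi"`).
#' @param extra_args Additional minimap2 arguments.
#' @return Alignment data.frame as from [read_paf()].
#' @export
align_reads <- function(reads, tgrs, preset = "map-hifi",
                        extra_args = character()) {
  mm2 <- require_binary("minimap2")
  tmpdir <- tempfile("mm2_")
  dir.create(tmpdir)
  on.exit(unlink(tmpdir, recursive = TRUE))
  ref_fa <- file.path(tmpdir, "tgrs.fasta")
  write_fasta(tgrs$seq, ref_fa)
  reads_path <- if (is.character(reads) && length(reads) == 1L &&
                    file.exists(reads)) reads else {
    p <- file.path(tmpdir, "reads.fasta")
    write_fasta(reads, p)
    p
  }
  paf <- file.path(tmpdir, "aln.paf")
  status <- system2(mm2, c("-x", preset, "--secondary=no", "-t", "1",
                           extra_args, ref_fa, reads_path),
                    stdout = paf, stderr = FALSE)
  if (!identical(status, 0L)) stop("minimap2 failed with status ", status)
  read_paf(paf, tgrs = tgrs)
}

#' Select reads that fully span each TGRS
#'
#' Applies the strand-specific spanning criteria: a read is retained at a
#' locus only if its alignment covers more than `span_fraction` of the TGRS,
#' the read is longer than the TGRS, and the read overhangs the TGRS on both
#' sides — i.e. its 5' end lies upstream of the TGRS start and its 3' end
#' downstream of the TGRS end. With 0-based inclusive coordinates (`L` read
#' length, `l` TGRS length, `S`/`E` match start/end on the read, `s`/`e` on
#' the TGRS, `S' = L - E - 1` the inverted read start):
#'
#' * `+` strand: `(e+1)-(s+1) > l*span_fraction`, `L > l`, `S+1 > s+1`,
#'   `L-S > l-s`;
#' * `-` strand: `(e+1)-(s+1) > l*span_fraction`, `L > l`, `S'+1 > s+1`,
#'   `E+1 > l-s`.
#'
#' Only alignments with `mapq >= min_mapq` are considered. A read passing at
#' several loci is retained at each.
#'
#' @param alignments Alignment data.frame (see [read_paf()]).
#' @param min_mapq Minimum mapping quality (default 60).
#' @param span_fraction Minimum fraction of the TGRS covered (default 0.95).
#' @return The input with logical column `keep` and character column
#'   `failed_condition` (`""` for kept rows; the first failing condition
#'   among `mapq`, `span`, `read_length`, `upstream_overhang`,
#'   `downstream_overhang` otherwise).
#' @export
select_spanning_reads <- function(alignments, min_mapq = 60,
                                  span_fraction = 0.95) {
  aln <- alignments
  n <- nrow(aln)
  if (n == 0L) {
    aln$keep <- logical(0)
    aln$failed_condition <- character(0)
    return(aln)
  }
  Sp <- aln$L - aln$E - 1L  # inverted read start for '-' strand
  span_ok <- (aln$e + 1) - (aln$s + 1) > aln$l * span_fraction
  len_ok <- aln$L > aln$l
  up_ok <- ifelse(aln$strand == "+", aln$S + 1 > aln$s + 1, Sp + 1 > aln$s + 1)
  down_ok <- ifelse(aln$strand == "+", aln$L - aln$S > aln$l - aln$s,
                    aln$E + 1 > aln$l - aln$s)
  mapq_ok <- aln$mapq >= min_mapq
  aln$keep <- mapq_ok & span_ok & len_ok & up_ok & down_ok
  fc <- character(n)
  fc[!down_ok] <- "downstream_overhang"
  fc[!up_ok] <- "upstream_overhang"
  fc[!len_ok] <- "read_length"
  fc[!span_ok] <- "span"
  fc[!mapq_ok] <- "mapq"
  fc[aln$keep] <- ""
  aln$failed_condition <- fc
  aln
}

#' Build per-locus spanning-read sets
#'
#' Groups the kept alignments by gene and attaches the read sequences,
#' oriented to TGRS-forward (minus-strand reads are reverse-complemented and
#' their match coordinates mirrored). When one read passes at a locus with
#' several primary/supplementary records, the highest-mapq (then longest
#' span) record is kept.
#'
#' @param selection Output of [select_spanning_reads()].
#' @param reads Named character vector of read sequences (or FASTA/FASTQ
#'   path).
#' @return Named list of `locus_read_set` objects: each a list with
#'   `gene_id`, `n_selected`, and `reads` — a data.frame of `read_id`,
#'   `sequence` (TGRS-forward), `S`, `E` (0-based inclusive TGRS match
#'   interval on the oriented read), `s`, `e`.
#' @export
locus_read_sets <- function(selection, reads) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_seqs(reads)
  }
  kept <- selection[selection$keep, , drop = FALSE]
  out <- list()
  for (gid in unique(kept$gene_id)) {
    g <- kept[kept$gene_id == gid, , drop = FALSE]
    g <- g[order(-g$mapq, -(g$e - g$s)), , drop = FALSE]
    g <- g[!duplicated(g$read_id), , drop = FALSE]
    seqs <- unname(reads[g$read_id])
    S <- g$S; E <- g$E
    neg <- g$strand == "-"
    if (any(neg)) {
      seqs[neg] <- revcomp(seqs[neg])
      S2 <- g$L[neg] - g$E[neg] - 1L
      E2 <- g$L[neg] - g$S[neg] - 1L
      S[neg] <- S2
      E[neg] <- E2
    }
    out[[gid]] <- structure(list(
      gene_id = gid,
      n_selected = nrow(g),
      reads = data.frame(read_id = g$read_id, sequence = seqs,
                         S = S, E = E, s = g$s, e = g$e,
                         stringsAsFactors = FALSE)
    ), class = "locus_read_set")
  }
  out
}
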