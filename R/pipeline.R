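# Pipeline orchestration: chain TGRS extraction, mapping, spanning-read
# selection, locus assembly, allele extraction and summarisation, with
# per-stage failure accounting and a reproducibility manifest.

#' Phase all loci of a TGRS collection from a read set
#'
#' The in-memory pipeline core: maps reads to every TGRS, selects spanning
#' reads, assembles each locus, extracts alleles at the requested flank
#' tiers, and summarises. Per-locus failures never abort the run; each
#' failed locus records the stage it failed at (`mapping` — no alignment to
#' the locus at all; `read_selection` — alignments but no spanning read;
#' `assembly`; `allele_extraction`).
#'
#' @param tgrs A `tgrs_set`.
#' @param reads Named character vector of reads, or FASTA/FASTQ path.
#' @param min_mapq,span_fraction Spanning-read selection thresholds (see
#'   [select_spanning_reads()]).
#' @param flanks Flank tiers in bp for allele extraction (default
#'   `c(0, 2000)`).
#' @param primary,fallback Assembler backends (see [assembler_backend()]).
#' @param seed Master seed; per-locus seeds are derived deterministically
#'   from it and the gene id.
#' @param min_alt_fraction,min_alt_support Built-in assembler site
#'   thresholds.
#' @param window_flank Assembly window margin beyond the TGRS match
#'   (default `max(flanks) + 500`).
#' @param ... Passed to [assemble_locus()].
#' @return List with `loci` (named list of `phased_locus`), `alleles`
#'   (data.frame over all loci and flank tiers), `summaries` (ASF rows with
#'   a `flank` column), `failures` (gene_id, failure_stage), `selection`
#'   (the per-alignment selection log), and `counts` (n_loci, n_output,
#'   n_het, n_homo, n_failed, per-stage failure counts, n_fallback, and
#'   n_multilocus_reads — reads retained at more than one locus).
#' @export
phase_loci <- function(tgrs, reads, min_mapq = 60, span_fraction = 0.95,
                       flanks = c(0, 2000), primary = "pileup",
                       fallback = "consensus", seed = 1L,
                       min_alt_fraction = 0.2, min_alt_support = 3,
                       window_flank = NULL, ...) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_seqs(reads)
  }
  if (is.null(window_flank)) window_flank <- max(flanks) + 500L
  aln <- align_reads(reads, tgrs)
  sel <- select_spanning_reads(aln, min_mapq = min_mapq,
                               span_fraction = span_fraction)
  sets <- locus_read_sets(sel, reads)
  mapped_genes <- unique(aln$gene_id)

  loci <- list()
  allele_rows <- list()
  summary_rows <- list()
  fail_rows <- list()
  for (gid in tgrs$info$gene_id) {
    tg <- tgrs$seq[[gid]]
    locus <- assemble_locus(sets[[gid]], tg, primary = primary,
                            fallback = fallback,
                            seed = derive_seed(seed, gid),
                            window_flank = window_flank,
                            min_alt_fraction = min_alt_fraction,
                            min_alt_support = min_alt_support, ...)
    locus$gene_id <- gid
    stage <- locus$failure_stage
    alleles <- NULL
    if (locus$zygosity != "failed") {
      alleles <- extract_alleles(locus, tg, flanks = flanks)
      if (is.null(alleles) || nrow(alleles) == 0L) {
        stage <- "allele_extraction"
        locus$zygosity <- "failed"
        alleles <- NULL
      }
    }
    if (!is.na(stage) && stage == "read_selection" &&
        !gid %in% mapped_genes) {
      stage <- "mapping"
    }
    locus$failure_stage <- stage
    loci[[gid]] <- locus
    if (!is.null(alleles)) allele_rows[[gid]] <- alleles
    if (!is.na(stage)) {
      fail_rows[[gid]] <- data.frame(gene_id = gid, failure_stage = stage,
                                     stringsAsFactors = FALSE)
    }
    for (fl in flanks) {
      sub <- if (is.null(alleles)) NULL else
        alleles[alleles$flank == fl, , drop = FALSE]
      row <- summarize_locus(sub, locus)
      row$flank <- fl
      summary_rows[[paste(gid, fl)]] <- row
    }
  }
  summaries <- do.call(rbind, summary_rows)
  rownames(summaries) <- NULL
  failures <- if (length(fail_rows)) do.call(rbind, fail_rows) else
    data.frame(gene_id = character(), failure_stage = character())
  rownames(failures) <- NULL
  zyg <- vapply(loci, function(x) x$zygosity, "")
  counts <- list(
    n_loci = length(loci),
    n_output = sum(zyg != "failed"),
    n_het = sum(zyg == "heterozygous"),
    n_homo = sum(zyg == "homozygous"),
    n_failed = sum(zyg == "failed"),
    failures_by_stage = table(factor(failures$failure_stage,
      levels = c("mapping", "read_selection", "assembly",
                 "allele_extraction"))),
    n_fallback = sum(vapply(loci, function(x)
      x$zygosity != "failed" && identical(x$assembler_used, "fallback"),
      TRUE)),
    n_multilocus_reads = sum(table(sel$read_id[sel$keep]) > 1L)
  )
  alleles_df <- if (length(allele_rows)) {
    out <- do.call(rbind, allele_rows)
    rownames(out) <- NULL
    out
  } else NULL
  list(loci = loci, alleles = alleles_df, summaries = summaries,
       failures = failures, counts = counts, selection = sel)
}

#' Run the full phasing pipeline from files to an output directory
#'
#' Executes all six stages — TGRS extraction, read mapping, spanning-read
#' selection, locus assembly, allele extraction, summarisation — and writes:
#' phased contigs (`APC.fasta`, records `{gene_id}.ctg1`/`.ctg2`), allele
#' FASTAs per flank tier (`AAS.fasta`, `AAS-2K.fasta`, `AAS-UD<n>.fasta`),
#' summary CSVs (`ASF*.csv`), a per-stage failure table
#' (`failures.tsv`), the selection log (`selection_log.tsv`), and a JSON
#' run manifest (package version, configuration and its hash, seed,
#' counts). Outputs are bit-identical across reruns with the same inputs,
#' configuration and seed.
#'
#' @param genome Reference genome FASTA path (or named character vector).
#' @param annotation GFF3 path (or annotation data.frame).
#' @param reads FASTA/FASTQ path (or named character vector).
#' @param outdir Output directory; `NULL` for an in-memory run only.
#' @param feature_type GFF3 feature type for TGRS extraction.
#' @param flanks Flank tiers in bp (default `c(0, 2000)`).
#' @param seed Master seed.
#' @param ... Passed to [phase_loci()].
#' @return Invisibly, the [phase_loci()] result list with an added
#'   `manifest` element.
#' @export
run_pipeline <- function(genome, annotation, reads, outdir = NULL,
                         feature_type = "gene", flanks = c(0, 2000),
                         seed = 1L, ...) {
  tgrs <- extract_tgrs(genome, annotation, feature_type = feature_type)
  res <- phase_loci(tgrs, reads, flanks = flanks, seed = seed, ...)
  cfg <- list(feature_type = feature_type, flanks = flanks, seed = seed,
              extra = list(...))
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE)
  manifest <- list(
    package = "genephase",
    version = as.character(utils::packageVersion("genephase")),
    config = cfg,
    config_hash = fold_digest(utf8ToInt(cfg_json)),
    seed = seed,
    counts = res$counts[c("n_loci", "n_output", "n_het", "n_homo",
                          "n_failed", "n_fallback")],
    failures_by_stage = as.list(res$counts$failures_by_stage)
  )
  res$manifest <- manifest
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    apc <- unlist(lapply(res$loci, function(x) {
      if (length(x$contigs) == 0L) return(NULL)
      stats::setNames(x$contigs, paste0(x$gene_id, ".ctg",
                                        seq_along(x$contigs)))
    }))
    if (length(apc)) write_fasta(apc, file.path(outdir, "APC.fasta"))
    if (!is.null(res$alleles)) write_alleles(res$alleles, outdir)
    write_asf(res$summaries, outdir)
    utils::write.table(res$failures, file.path(outdir, "failures.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sel_log <- res$selection[, c("gene_id", "read_id", "strand", "keep",
                                 "failed_condition")]
    utils::write.table(sel_log, file.path(outdir, "selection_log.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(res)
}

# TGRS set for a simulated diploid, using haplotype A as the reference.
#' Build the TGRS set of a simulated diploid (A haplotype as reference)
#'
#' @param diploid A `sim_diploid`.
#' @return A `tgrs_set` over the simulated genes.
#' @export
tgrs_from_sim <- function(diploid) {
  ann <- data.frame(gene_id = diploid$genes$gene_id, seq_id = "chrA",
                    start = diploid$genes$a_start,
                    end = diploid$genes$a_end,
                    strand = diploid$genes$strand, stringsAsFactors = FALSE)
  extract_tgrs(c(chrA = diploid$hap_a), ann)
}
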