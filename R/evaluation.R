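# Verification of reconstructed alleles against simulated truth, coverage
# sweeps, and the cultivar summary-table statistics.

#' Perfect-match verification of reconstructed alleles against truth
#'
#' An output allele matches a truth allele iff the sequences are identical
#' (orientation is already normalized by allele extraction; comparison uses
#' the 0-flank allele tier against the truth gene sequences). Per locus:
#' `match_a` / `match_b` flag whether any output equals the A-side / B-side
#' truth allele; `both_match` is true when a heterozygous output pair covers
#' both truth alleles, or when a homozygous output matches at a
#' truth-homozygous locus (identical A and B truth alleles).
#'
#' @param alleles Allele data.frame (0-flank rows; e.g.
#'   `result$alleles[result$alleles$flank == 0, ]`).
#' @param truth_a,truth_b Named character vectors of truth allele sequences
#'   sharing the same gene ids.
#' @return Object of class `evaluation_report`: list with `per_locus` (one
#'   row per truth locus: gene_id, output_count, zygosity, match_a,
#'   match_b, both_match) and `aggregates` (n_loci, n_output, n_het,
#'   n_homo, n_no_output, pct_match_a, pct_match_b, n_both_match,
#'   pct_both_match, n_both_match_het, pct_both_match_het — the
#'   heterozygous-pairs-only joint rate — and n_no_match).
#' @export
perfect_match_eval <- function(alleles, truth_a, truth_b) {
  if (!setequal(names(truth_a), names(truth_b))) {
    stop("truth allele sets do not share the same gene ids")
  }
  gids <- names(truth_a)
  truth_b <- truth_b[gids]
  per <- data.frame(gene_id = gids, output_count = 0L,
                    zygosity = "none", match_a = FALSE, match_b = FALSE,
                    both_match = FALSE, stringsAsFactors = FALSE)
  if (!is.null(alleles) && nrow(alleles)) {
    alleles <- alleles[alleles$gene_id %in% gids, , drop = FALSE]
    split_seq <- split(alleles$sequence, alleles$gene_id)
    for (i in seq_along(gids)) {
      out <- split_seq[[gids[i]]]
      if (is.null(out)) next
      ta <- truth_a[[gids[i]]]; tb <- truth_b[[gids[i]]]
      per$output_count[i] <- length(out)
      per$zygosity[i] <- if (length(out) == 2L) "heterozygous" else
        "homozygous"
      per$match_a[i] <- any(out == ta)
      per$match_b[i] <- any(out == tb)
      per$both_match[i] <- if (length(out) == 2L) {
        (out[1] == ta && out[2] == tb) || (out[1] == tb && out[2] == ta)
      } else {
        ta == tb && out[1] == ta
      }
    }
  }
  agg <- list(
    n_loci = nrow(per),
    n_output = sum(per$output_count > 0L),
    n_het = sum(per$zygosity == "heterozygous"),
    n_homo = sum(per$zygosity == "homozygous"),
    n_no_output = sum(per$output_count == 0L),
    pct_match_a = 100 * mean(per$match_a),
    pct_match_b = 100 * mean(per$match_b),
    n_both_match = sum(per$both_match),
    pct_both_match = 100 * mean(per$both_match),
    n_both_match_het = sum(per$both_match & per$zygosity == "heterozygous"),
    pct_both_match_het = 100 * mean(per$both_match &
                                      per$zygosity == "heterozygous"),
    n_no_match = sum(per$output_count > 0L & !per$match_a & !per$match_b)
  )
  structure(list(per_locus = per, aggregates = agg),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  a <- x$aggregates
  cat(sprintf("evaluation_report: %d loci, %d with output (%d het / %d homo)\n",
              a$n_loci, a$n_output, a$n_het, a$n_homo))
  cat(sprintf("  perfect match A: %.1f%%  B: %.1f%%  both: %.1f%% (%d loci)\n",
              a$pct_match_a, a$pct_match_b, a$pct_both_match,
              a$n_both_match))
  cat(sprintf("  no match: %d  no output: %d\n", a$n_no_match,
              a$n_no_output))
  invisible(x)
}

#' Tolerance-based sequence match (one error per kbp)
#'
#' Two sequences match if their Levenshtein edit distance does not exceed
#' `ceil(max(length)/1000 * tol_per_kbp)` — the one-error-per-kbp criterion
#' consistent with HiFi read accuracy of 99.5-99.9%.
#'
#' @param a,b DNA sequences.
#' @param tol_per_kbp Allowed errors per kbp (default 1).
#' @return Logical.
#' @export
tolerant_match <- function(a, b, tol_per_kbp = 1.0) {
  stopifnot(nzchar(a), nzchar(b))
  allowed <- ceiling(max(nchar(a), nchar(b)) / 1000 * tol_per_kbp)
  d <- utils::adist(a, b)[1, 1]
  d <= allowed
}

#' Coverage sweep: run the locus-phasing pipeline at several read depths
#'
#' Simulates one read pool at the highest requested coverage, downsamples it
#' (seeded) to each target, runs the full per-locus pipeline against the
#' A-haplotype reference, and tabulates output counts by zygosity and source
#' assembler.
#'
#' @param diploid A `sim_diploid`.
#' @param coverages Numeric vector of target depths (x).
#' @param seed Integer seed.
#' @param read_params Named list passed to [simulate_reads()] (error rates,
#'   length model).
#' @param ... Passed to [phase_loci()] (selection/assembly parameters).
#' @return Data.frame with one row per coverage: `coverage`, `n_output`,
#'   `n_het`, `n_homo`, `n_primary`, `n_fallback`.
#' @export
coverage_sweep <- function(diploid, coverages, seed = 1L,
                           read_params = list(), ...) {
  tgrs <- tgrs_from_sim(diploid)
  pool <- do.call(simulate_reads,
                  c(list(diploid = diploid, coverage = max(coverages),
                         seed = seed), read_params))
  genome_size <- mean(c(nchar(diploid$hap_a), nchar(diploid$hap_b)))
  rows <- lapply(sort(coverages), function(cv) {
    reads <- downsample_reads(pool, cv, genome_size, seed = seed)
    res <- phase_loci(tgrs, reads, seed = seed, flanks = 0, ...)
    s <- res$summaries[res$summaries$flank == 0, , drop = FALSE]
    ok <- s$zygosity %in% c("heterozygous", "homozygous")
    data.frame(coverage = cv,
               n_output = sum(ok),
               n_het = sum(s$zygosity == "heterozygous"),
               n_homo = sum(s$zygosity == "homozygous"),
               n_primary = sum(ok & s$assembler_used == "primary"),
               n_fallback = sum(ok & s$assembler_used == "fallback"))
  })
  do.call(rbind, rows)
}

#' Summary statistics over a per-cultivar phasing record table
#'
#' Computes the cross-cultivar mean output count, mean success rate,
#' output-count standard deviation (population and sample forms), and the
#' Pearson correlation between success rate and sequencing coverage.
#'
#' @param records Data.frame with columns `n_output`, `ratio_pct`,
#'   `coverage` (see [cultivar_table()] for the bundled 18-cultivar
#'   citrus fixture).
#' @return List: `mean_output`, `mean_ratio`, `sd_output_pop`,
#'   `sd_output_sample`, `pearson_r`.
#' @export
table1_stats <- function(records) {
  if (is.null(records) || nrow(records) == 0L) stop("empty record table")
  n <- nrow(records)
  list(mean_output = mean(records$n_output),
       mean_ratio = mean(records$ratio_pct),
       sd_output_pop = stats::sd(records$n_output) * sqrt((n - 1) / n),
       sd_output_sample = stats::sd(records$n_output),
       pearson_r = stats::cor(records$ratio_pct, records$coverage))
}

#' Bundled per-cultivar phasing summary table (18 citrus cultivars)
#'
#' Per-cultivar output counts, success rates (% of 1,409 target genes),
#' zygosity counts, heterozygosity, and sequencing coverage (total bases /
#' 360 Mb) for 18 citrus cultivars phased against a Satsuma mandarin
#' reference.
#'
#' @return Data.frame with columns `name`, `n_output`, `ratio_pct`,
#'   `n_het`, `n_homo`, `heterozygosity`, `coverage`.
#' @export
cultivar_table <- function() {
  path <- system.file("extdata", "cultivar_summary.csv",
                      package = "genephase", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
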