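# Internal helpers shared across modules.

#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement pairwiseAlignment nmatch subject start end
#' @importFrom stats runif rnorm rpois hclust cutree as.dist setNames
#' @importFrom utils adist
NULL

BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

#' Read sequences from FASTA or FASTQ as a named character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that returns plain
#' uppercase character strings named by the first whitespace-delimited token
#' of each record header.
#'
#' @param path Path to a FASTA or FASTQ file (format auto-detected from the
#'   first character).
#' @return Named character vector of sequences.
#' @export
read_seqs <- function(path) {
  first <- readChar(path, 1L)
  fmt <- if (identical(first, "@")) "fastq" else "fasta"
  ss <- Biostrings::readDNAStringSet(path, format = fmt)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

write_fasta <- function(seqs, path, width = 80L) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

write_fastq <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  qual <- vapply(nchar(seqs), function(n) strrep("I", n), "")
  writeLines(paste0("@", names(seqs), "\n", seqs, "\n+\n", qual), con)
  invisible(path)
}

# Deterministic 31-bit per-item seed derived from a master seed and a label.
derive_seed <- function(seed, label) {
  h <- 0
  for (v in utf8ToInt(paste0(label))) h <- (h * 131 + v) %% 2147483647
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

require_binary <- function(bin) {
  path <- Sys.which(bin)
  if (!nzchar(path)) {
    stop(sprintf("required external tool '%s' not found on PATH", bin),
         call. = FALSE)
  }
  unname(path)
}
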