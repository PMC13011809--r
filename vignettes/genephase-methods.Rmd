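---
title: "genephase: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{genephase: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, the
assumptions behind each stage, the parameters that matter, and the design
choices that were genuinely open. Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The phasing model

`genephase` treats each annotated gene as an independent diploid locus. A
locus is anchored by its **TGRS** — the reference subsequence spanning the
full genomic gene interval (introns and UTRs included; exon structure is
deliberately ignored, since the object of interest is the complete allele
sequence). Minus-strand genes are reverse-complemented at extraction so
every TGRS reads 5'→3' in gene orientation; a single orientation
convention is what makes downstream allele normalization and cross-run
bit-identity possible. Whether to flip minus-strand loci at all was an
open choice — mapping would work either way — and we flip, because it
gives every output FASTA one interpretable orientation.

### Spanning-read selection

Reads are mapped to the TGRS collection (minimap2, `map-hifi` preset,
secondary alignments suppressed) and filtered by the strand-specific
spanning law described in the README: mapping quality ≥ 60, alignment
covering > 95% of the TGRS, read longer than the TGRS, and overhangs on
both sides. Three conventions are fixed here:

* End coordinates are 0-based *inclusive*; PAF half-open ends are
  converted on input (`E = qend − 1`, `e = tend − 1`). The selection
  arithmetic's "+1" terms assume exactly this.
* Only primary records are considered — the law assumes one `(S, E)` per
  read. A read split by a large structural difference therefore fails
  selection at that locus, which is the intended behaviour: such a read
  does not span.
* The mapping-quality filter is applied before multi-locus assignment; a
  read passing at several loci is retained at each (paralog resolution is
  deferred to assembly). "Coverage" in the selection stage means exactly
  the span conditions — no additional depth filter is applied.

### The built-in locus assembler

Because every selected read spans the entire locus, no overlap-layout
graph is needed: a column-wise pileup is a complete coordinate frame. The
built-in assembler:

1. trims each read to its TGRS match plus a window margin (default
   `max(flank requests) + 500` bp, so contigs retain enough sequence for
   the flank tiers);
2. multiple-aligns the windows (mafft, fastest progressive mode; the
   alignment is deterministic for a given input);
3. masks each row's leading/trailing gap runs (ragged window ends, not
   deletions) and marks **candidate heterozygous sites**: columns whose
   second-most-frequent symbol — base or gap, so indels are sites too —
   has fraction ≥ `min_alt_fraction` (0.2) and count ≥ `min_alt_support`
   (3);
4. partitions reads by average-linkage clustering on their site-allele
   vectors (pairwise mismatch fraction, NA-tolerant), cut into two groups;
5. emits one column-majority consensus per group, dropping gap-majority
   columns; ties resolve in the fixed order A, C, G, T, gap, so bases beat
   gaps and runs are reproducible without randomness.

One contig is emitted when there are no candidate sites, when a partition
is degenerate (a group smaller than two reads), or when both group
consensi are identical — this is the collapse that turns
truth-homozygous loci into single-contig homozygous calls. Two contigs
call heterozygosity. More than two cannot arise from the built-in
assembler, but external backends may produce them; by default that is an
assembly failure (the diploid model defines only one or two), with
options to keep the two longest or to trigger the fallback instead.

`min_alt_fraction = 0.2` with `min_alt_support = 3` is chosen for
HiFi-scale error (≈Q20+, i.e. per-base error well under 1%): a true
heterozygous site at balanced coverage sits near fraction 0.5, while
error pileups at 0.2–0.5% per base essentially never reach 20% of a
column at support ≥ 3. Loci with more than `max_reads = 60` spanning
reads are subsampled (seeded) before alignment; at the 10–60× coverages
of interest this cap rarely binds.

Assembler provenance is recorded per locus, and the fraction of loci
resolved by the fallback is part of the coverage-sweep output, because
which backend produces output is itself coverage- and diversity-dependent.

### Allele extraction

Each contig is aligned back to its TGRS (whole-TGRS-in-contig alignment,
match 1, mismatch −2, gap open −4, gap extend −1 — ordinary DNA scoring;
nothing downstream is sensitive to modest changes). The aligned extent
defines the gene interval, so allele lengths may legitimately differ from
*l* when indels fall inside the gene. An exact embedded TGRS copy is
detected by substring search first, which short-circuits most
reference-side contigs. If fewer than half the TGRS bases align
(`min_tgrs_cov = 0.5`), the locus fails at the allele-extraction stage.
Alleles are emitted per flank request — 0 bp (AAS), ±2 kbp (AAS-2K),
user-defined (AAS-UD) — clipped to the available contig sequence, with
obtained flank widths recorded rather than failing the locus; clipping
was an open choice the data format now documents. Heterozygous alleles
are labelled `h1`/`h2` by (gene-interval length, then lexicographic)
order: biological phase is unknowable without pedigree information, and a
deterministic convention makes repeated runs bit-identical. Homozygous
output is labelled `H`.

### Sketch summaries

Per-locus summaries record zygosity, read support, assembler provenance,
allele lengths, the exact Jaccard coefficient between the two alleles'
canonical k-mer sets (k = 21 — the standard sketching size, long enough
that random 21-mers essentially never repeat at gene scale), and a
MinHash record per allele: 128 seeded universal-hash permutations over
26-bit k-mer fingerprints (the field size keeps `a·h + b mod p` exact in
doubles), serialized as a 16-character hex digest. The digest is folded
over the *full* fingerprinted k-mer set (under two independent
fingerprint hashes), not just the 128 minima: the minima estimate
similarity, but one SNP only perturbs ~k of thousands of k-mers and can
leave every minimum unchanged, so a digest meant to certify identity must
see the whole set. The permutation seed (42) is a constant of the format:
digests are only comparable across runs because it never varies.

## The simulator

The simulator generates the conditions under which the method is
characterised, so its defaults are fixed and not tuned per experiment:

* **Genome layout.** Alternating random gene bodies (uniform
  1,000–5,000 bp) and intergenic spacers (uniform 10–30 kbp), all genes
  forward-strand on one chromosome. The spacer range is a design choice:
  reads of 10–30 kbp must be able to span one gene plus flanks but should
  rarely span two loci.
* **Variant models.** Haplotype B derives from A with SNPs and SVs placed
  as Poisson processes at per-kbp rates: the low model (rice-like,
  1.5 SNPs/kbp, 0.1 SVs/kbp) and the high model (citrus-like, 17
  SNPs/kbp, 1.8 SVs/kbp), each with its nine-bin SV size distribution
  from 1–10 bp to 10–50 kbp. The high model's published class
  percentages total 99.01%; the vector is normalized to sum to one. SV
  sizes are uniform within a bin; SVs are insertions or deletions with
  equal probability (the class of SV was unspecified; inversions and
  translocations are out of scope), insertion content random. Variants
  landing inside an earlier deletion are relocated rather than dropped,
  so realized counts follow the nominal rates; deletions are clipped at
  block boundaries, so a spacer deletion never silently truncates a gene.
* **Truth and liftover.** Gene coordinates are lifted exactly through the
  indels; extracting the B annotation from haplotype B reproduces the
  truth B alleles verbatim (tested as a round-trip). Loci with no variant
  in the gene body are truth-homozygous; under the low model at 1,000
  genes the expected fraction, averaging `exp(−1.6ℓ/1000)` over gene
  lengths, is ≈3.2% — a few dozen loci.
* **Reads.** Lengths are truncated-normal (mean 21,000, sd 2,000, clipped
  to 10,000–30,000 bp), starts uniform, haplotypes alternating, stopping
  when total bases reach coverage × mean haplotype length. Default error
  rates are substitution 0.002 with 1-bp insertions and deletions at
  0.0005 each — a HiFi-like ≥Q20 profile. The quality-score *model* of a
  real instrument (position- or context-dependent error) is not
  emulated; errors are i.i.d. True source coordinates ride along in read
  names so selection can be audited against truth.
* **Downsampling.** A seeded shuffle taking reads until the base target
  is met, mirroring standard coverage-titration practice.

What passing simulated tests does **not** show: performance on real reads
with structured error, on genomes with paralogy or repeats around target
genes, or on annotations whose gene models are wrong. The simulation
validates the algorithmic core, not instrument realism.

## Evaluation conventions

* **Success** at a locus means one (homozygous) or two (heterozygous)
  allele sequences were produced.
* **Perfect match** is exact sequence identity of the 0-flank allele with
  a truth allele after orientation normalization. `both_match` holds when
  a heterozygous pair covers both truth alleles, or when a homozygous
  output matches at a truth-homozygous locus — the accounting treats a
  correct single allele at an identical-allele locus as fully correct.
* **Tolerant match** allows `ceil(max(length)/1000)` edits per the
  one-error-per-kbp convention; the ceiling (a 4,528-bp pair allows 5
  edits) is our resolution of an unstated rounding.
* The bundled 18-cultivar summary table is a versioned CSV fixture;
  `table1_stats()` computes its cross-cultivar mean output, mean success
  rate, both population- and sample-form SDs (which form the published
  table used was unstated, so both are reported; the population form
  matches), and the Pearson correlation of success rate with coverage.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at sizes chosen to make
each property measurable on a single CPU in minutes: 100-locus error-free
end-to-end identity checks, 200-locus panels at 30× for the
perfect-match-rate comparisons, 1,000-gene simulations for
goodness-of-fit of the variant models, 8-seed paired comparisons of 10×
vs 30× heterozygous output for the allele-dropout direction, and a
500-allele panel for sketch identity. Master seeds derive per-locus seeds
deterministically from the gene id, so any locus can be re-run in
isolation and whole-run outputs are bit-identical under a fixed seed.

## Known limitations

* Diploid only; more than two haplotypes per locus is out of scope.
* Paralogs are not disambiguated at selection time: a read spanning two
  near-identical loci is retained at both, and resolution relies on
  assembly separating the copies.
* The built-in assembler presumes spanning reads; it cannot join a locus
  from partial overlaps, so loci longer than the read length fail by
  construction (by design — the method targets gene-scale loci).
* Structural variants on the non-reference haplotype can break spanning
  alignment of that haplotype's reads, producing allele dropout at high
  variant densities; this is measured, not hidden, by the evaluation
  module.
* Digest-based allele identity is content-hash identity: distinct
  sequences sharing an identical canonical k-mer set (e.g. exact
  repeats longer than the sequence difference) would collide; at
  gene-panel scale this is negligible.
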