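---
title: "How a reference transcriptome changes spliced read mapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How a reference transcriptome changes spliced read mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

splicemapr studies a single experimental contrast: the same read set
aligned *with* a reference transcriptome (transcript sequences built from a
gene annotation, hits projected back to the genome) and *without* one
(de-novo seed–extend splice discovery on the bare genome), each under a
unique-reporting or multiple-reporting policy. This vignette documents the
models behind each stage, the parameters that matter, what the simulation
does and does not capture, and the numerical conventions, so that the
outputs can be read critically.

## The comparison model

Both runs produce one primary alignment per read (or an unmapped record).
Every read mapped by the guided run is then classified by
`compare_runs()`:

* **IDENTICAL** — the annotation-free run reports the same chromosome,
  strand, and the same ordered list of genomic blocks. Comparison is
  block-wise, not CIGAR-string-wise, so `10M20M` and `30M` spell the same
  placement; NM and other tags are ignored because the question is *where*
  the read went, not how it was scored.
* **ALTERNATIVE** — mapped, but to a different region or with different
  splice sites. A strand flip alone counts as ALTERNATIVE by default
  (`strand_matters = FALSE` relaxes this; the choice is exposed because
  either convention is defensible for an unstranded library).
* **UNMAPPED** — lost without the annotation.

Reads the guided run itself fails to map are counted
(`attr(x, "n_a_unmapped")`) but never categorized, and so are reads mapped
only in the annotation-free run (`n_b_only`): the three categories
partition exactly the guided-run mapped set, which is the denominator for
every percentage the package prints.

Junction statistics always come from the guided run's placement: a read is
a *junction read* if its alignment has two or more blocks (an `N` gap in
the CIGAR), its *exon span* is the block count, and its *MOE* is
`min(first block, last block)` — for a two-block alignment of an L-base
read this is `min(OL, OR)` with range 1..⌊L/2⌋ (1..37 at L = 75). MOE is
generalized to `min(first, last)` for 3+-block alignments so the profile
is total, but the MOE histograms are restricted to two-exon junction
reads, where the quantity has its clean interpretation.

## The toy aligners

Both aligners are substitution-only (`k_mismatch`, default 2): no indels,
no soft clips, no quality weighting. The phenomena under study — junction
loss, anchor-limited splice discovery, pseudogene capture, multi-mapping —
do not require gaps, and a gapless scorer keeps every stage checkable
against brute-force enumeration (the test suite does exactly that).

**Guided**: every placement of the read, in both orientations, on every
spliced transcript sequence with at most `k_mismatch` substitutions is
found by a seeded-and-verified search, projected to the genome through the
exon structure (M blocks, N introns), and duplicate genomic placements
collapsed — two isoforms supporting the same placement are one candidate.
Reads with no transcriptome hit at all fall back to the genome-only
aligner. Score: fewest mismatches, then fewer splices.

**Genome-only**: stage 1 enumerates contiguous placements exactly as
above. Stage 2 places the read's `min_anchor`-base (default 8) prefix and
suffix exactly; every prefix/suffix pair on one chromosome and strand
whose implied gap lies in `intron_range` (default 40–50,000) yields a
two-block M–N–M candidate, with the interior split chosen to minimize
substitutions. One intron per read is a deliberate structural limit: reads
spanning three or more exons are recoverable only through the annotation,
which turns the "multi-exon reads need prior knowledge" observation into a
property of the model rather than a statistical accident.

Scoring is total and documented: mismatches, then contiguous before
spliced, then smallest intron, then leftmost coordinate, then chromosome
name. *Unique* mode reports a read only when exactly one distinct genomic
placement attains the best score, otherwise it is dropped with the tie
count recorded (`n_locations`, written as `NH:i`); *multiple* mode reports
all tied-best placements up to `max_locations` (default 2000).

Two artifacts of this idealization are worth knowing when reading
ALTERNATIVE counts. First, because stage-2 anchors are short exact seeds,
a read with sequencing errors in its terminal `min_anchor` bases can
"repair" them by relocating that anchor across a spurious intron (nm
counts only substitutions outside the anchors), and a small-MOE junction
read can pair a chance anchor hit with a real one into a chimeric
two-block placement. Real spliced aligners suppress both with gap
penalties and splice-motif (GT–AG) models, which this package deliberately
omits to keep the candidate class enumerable; the consequence is a
somewhat larger, broader-MOE ALTERNATIVE category than motif-aware tools
would produce. Second, with no motif anchoring, a junction whose flanking
bases happen to repeat at the intron boundary admits several equally good
splits; the aligner resolves the tie deterministically (smallest left
block), so such reads surface as ALTERNATIVE-with-shifted-splice-sites —
the same ambiguity that annotation resolves in real data.

## The simulator and what it stands for

`sim_config()` fixes the study conditions; `make_genome()` and
`simulate_reads()` are deterministic given the seed (every stage derives a
stage-salted substream, so changing `n_reads` never changes the genome).

* **Reads**: 75 bp single-end, sampled uniformly along transcripts with
  transcript choice weighted by spliced length — the uniform-coverage
  ideal of an unstranded library. Per-base substitution probability
  `error_rate = 0.005`, a typical Illumina substitution load; constant
  quality strings, since nothing downstream reads qualities. Reads carry
  the transcript's strand; the aligners handle reverse complements, so
  unstranded behaviour is exercised without doubling the truth
  bookkeeping.
* **Genes**: 30 genes of 2–8 exons, exons 50–300 bp, introns 60–2,000 bp,
  intergenic spacers 500–1,500 bp, random strand — compact human-like
  structure scaled so the whole genome stays near 200 kb and a 20,000-read
  study runs in seconds. With L = 75 and uniform sampling, the truth MOE
  of two-exon junction reads is discrete-uniform on 1..37, which the test
  suite verifies by a goodness-of-fit test.
* **Confounders**: an intronless copy of one parent gene's mRNA with
  exactly `retrocopy_mutations = 2` substitutions, inserted intergenically
  and *left out of the annotation* — a processed pseudogene without a gene
  model. Two mutations equals the aligner's mismatch budget, so capture of
  the parent's reads by the copy is expressed rather than guaranteed per
  read. A byte-identical second copy of another gene's locus, both copies
  annotated, makes unique-mode counts for that pair exactly zero. And one
  gene carries a 6 bp internal exon, unbridgeable by an 8-base-anchor
  de-novo search.

What the simulator does **not** model: expression heterogeneity (all
transcripts at length-proportional abundance), indels and quality-profiled
errors, paired ends, alternative isoforms per gene, GC or positional
coverage bias, and genome-scale repeat structure. Trends measured here —
junction enrichment among moved/lost reads, span-dependent recovery decay,
the MOE split between categories, count dominance of the guided run — are
mechanistic consequences that carry over to real data; the *magnitudes*
(category percentages, gene counts) are properties of these synthetic
conditions and should not be read as estimates for any real tissue.

## Quantification conventions

`count_genes()` implements intersection-strict assignment: a read counts
for a gene only if every block lies within the exons of at least one of
the gene's transcripts and no other gene qualifies; union mode (any-block
overlap, still unambiguous) is available for contrast. Counting ignores
strand, matching an unstranded protocol. Fold changes use
`log2((n1 + 0.5) / (n2 + 0.5))` after scaling all four count vectors to a
common total; the 0.5 pseudocount and total-count normalization are the
package's own convention (simple, symmetric, and antisymmetric under
sample swap — a property the tests check), not an attempt to reproduce
any particular quantifier. Discordance flags are strict inequalities at
|Δlog2FC| > 2 and > 3.3.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere inside the package; 1-based
  conventions exist only at the GTF and SAM boundaries.
* CIGAR vocabulary is M/I/D/N/S with X and `=` normalised to M on input;
  alignments may not begin or end with N.
* `n_reads = 0` runs the whole pipeline to empty-but-well-formed outputs
  with a warning; genes with zero guided-run counts are excluded from
  reduction denominators rather than producing infinities.
* All randomness flows from one integer seed through stage-named
  substreams; two runs with identical configuration produce byte-identical
  output tables.

## Problem sizes

The shipped configuration — 30 genes, ~220 kb genome, 20,000 reads per
sample, two samples, three alignment runs — was chosen so a full pipeline
completes in roughly half a minute on a single core while keeping ≥ 6,000
junction reads in the comparison, enough that the category fractions and
MOE histograms are stable to a percentage point or two across seeds. The
test suite uses the same machinery at smaller sizes plus hand-built
fixtures whose expected alignments are derivable by brute force.
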