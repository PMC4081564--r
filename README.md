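# splicemapr

**splicemapr** is a desk-scale laboratory for a question every RNA-Seq
analyst has to answer: *how much does the reference transcriptome you hand
your aligner change where your reads end up — and what does that do to
gene-level results?*

Short junction reads (reads spanning an exon–exon boundary) are the hard
part of spliced alignment. Aligners that consult a transcript annotation
can place a junction read even when its overlap with one of the flanking
exons is a handful of bases; annotation-free (de-novo) spliced alignment
must anchor both sides of the candidate intron in the genome and fails
exactly where guidance helps most. The effect is confounded by processed
pseudogenes (intronless retrotransposed copies of mRNAs that soak up
junction reads as contiguous matches), identical gene duplications
(uniquely mapping reads become multi-reads genome-wide), and exons shorter
than the read length.

splicemapr makes the whole phenomenon reproducible on a laptop:

1. **Simulate** a compact genome carrying those confounders plus
   ground-truth-labelled 75 bp reads (`make_genome()`, `simulate_reads()`).
2. **Align** the reads twice with fully specified toy aligners: a
   transcriptome-guided aligner that projects transcript hits to genomic
   spliced alignments (`align_guided()`), and a genome-only seed–extend
   spliced aligner (`align_genome_only()`), each in *unique* or *multiple*
   reporting mode.
3. **Compare** the runs per read (`compare_runs()`): every read mapped in
   the guided run is **Identical** (same chromosome, strand and block
   list), **Alternative** (mapped elsewhere or with different splice
   sites) or **Unmapped** in the annotation-free run. Junction statistics
   come from the CIGAR block structure: *exon span* (number of M blocks
   separated by N gaps) and **MOE**, the minimum overlap with an exon,

   ```
   MOE = min(OL, OR)
   ```

   the smaller of a junction read's overlaps with its two flanking exons
   (for a 75 bp read, 1 ≤ MOE ≤ 37).
4. **Quantify** the downstream impact: intersection-strict per-gene counts
   under both runs (`count_genes()`), the list of genes losing ≥ 20 % of
   their counts without annotation (`reduction_report()`), and
   between-sample log2 fold-change concordance with |Δlog2FC| > 2 and
   > 3.3 discordance flags (`fc_concordance()`).

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` methods for the result objects, and `autoplot()` for the
category, MOE-histogram, exon-span and concordance figures. Plain-text
FASTA/GTF/FASTQ/SAM readers and writers round out the toolbox.

## Worked example

```r
library(splicemapr)

b <- run_pipeline(file.path(tempdir(), "demo"),
                  sim = sim_config(seed = 1), quiet = TRUE)
summarize_comparison(b$comparison)
```

```
Run comparison (19189 guided-run-mapped reads, 6652 junction reads)

# A tibble: 3 × 5
  category        n   pct n_junction junction_fraction
  <fct>       <int> <dbl>      <int>             <dbl>
1 IDENTICAL   14772 77.0        3168             0.214
2 ALTERNATIVE  3190 16.6        2714             0.851
3 UNMAPPED    1227  6.39        770             0.628
```

Reading the table: of the 19,189 reads the guided run maps, 77 % land
identically without the annotation, 16.6 % move, 6.4 % are lost — and the
moved/lost categories are dominated by junction reads (85 % and 63 %
junction, versus 35 % overall). The per-gene fallout:

```r
head(reduction_report(b$counts$s1_a, b$counts$s1_b), 5)
```

```
# A tibble: 5 × 4
  gene_id count_a count_b reduction_pct
  <chr>     <int>   <int>         <dbl>
1 G001       1061     132          87.6
2 G015        871     584          33.0
3 G030        240     166          30.8
4 G018        326     233          28.5
5 G005        706     505          28.5
```

`G001` is the gene whose mRNA has an unannotated retrotransposed copy in
the simulated genome: without the annotation its junction reads map
contiguously to the pseudogene and its exonic reads become ambiguous, so
its count collapses by 88 %. `G030` carries a 6 bp internal exon that only
the guided aligner can bridge. `autoplot(b$comparison, type = "moe")`
shows the companion picture: identically recovered junction reads all have
MOE ≥ 8 (the de-novo anchor length), while the alternative category is
dominated by MOE 1–3.

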