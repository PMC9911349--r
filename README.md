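# lncexport

Quantitative tools for the nuclear-export boundary that separates long
non-coding RNAs from mRNAs — the boundary a de novo gene must cross when it
originates from a lncRNA locus.

lncRNAs and mRNAs share transcript anatomy but differ sharply in where they
end up: lncRNAs stay in the nucleus, mRNAs are exported. Two cis-acting
levers control the crossing: **U1 snRNP recognition sites** retained in
exonic sequence (which anchor a transcript in the nucleus) and **splicing
efficiency** (which removes intronic U1 sites and licenses export). This
package implements, as one tested pipeline, the statistics used to study
that boundary:

* **N/C ratio** — per-gene nuclear/cytoplasmic expression from
  fractionation RNA-seq: `log2((FPKM_nuc + 0.1)/(FPKM_cyt + 0.1))`, with
  the weak-expression filter (total FPKM < 0.2) and z-score normalization
  for cross-dataset comparison.
* **PSI / ISOR** — per-intron per cent spliced in and the gene-level
  isoform spliced-out ratio, `ISOR = sum(intron_len * PSI) / exonic_len`,
  with an independent full-length-read estimator.
* **Maximum-entropy site models** — U1/5'-splice 9-mer scorers (order-1
  closed form or order-2 iterative proportional fitting), strong-site
  densities per kb, and variant delta-scores with strengthen/weaken calls.
* **Sequence classifier** — a convolutional network (11-nt first-layer
  filters, count-sensitive pooling, Rcpp backend) that classifies nuclear-
  vs cytosol-enriched transcripts from sequence and extracts the motifs its
  first layer learned as position-frequency matrices.
* **CRISPR mutation effects** — allele-resolved Fisher exact tests of
  export shift (nuclear odds ratio of mutant vs reference allele) and
  splicing shift (with the |ΔPSI| > 5% rule), BH correction, the top-50%
  |ΔU1| filter, and the splicing/export concordance summary.
* **Selection tests** — pN/pS with equal-rate site counting,
  derived-allele-frequency spectra with bootstrap errors, and a
  Monte-Carlo skewness test for an excess of rare derived alleles.
* **Co-expression conservation** — cross-species conservation of
  co-expression partner sets from two-population expression panels.
* **Synthetic data** — generators for every input above (FASTA/GTF/VCF/TSV
  writable) with known ground truth, so the whole pipeline runs and is
  tested end to end with no external downloads.

## Worked example

Simulate a 100-gene genome in two classes (coding-like and lncRNA-like),
generate fractionation counts, and compute N/C ratios and ISOR:

```r
library(lncexport)

cfg <- sim_config(n_genes = 100, seed = 1)
sim <- simulate_genome(cfg)
fr  <- simulate_fraction_counts(sim$models, sim$truth, cfg)

nc <- nc_ratio(data.frame(
  gene_id  = fr$counts$gene_id,
  fpkm_nuc = compute_fpkm(fr$counts$reads_nuc, fr$counts$exonic_length,
                          sum(fr$counts$reads_nuc)),
  fpkm_cyt = compute_fpkm(fr$counts$reads_cyt, fr$counts$exonic_length,
                          sum(fr$counts$reads_cyt))))
iso <- compute_isor(fr$junctions, exonic_length(sim$models))

bt <- sim$truth$genes$biotype[match(nc$gene_id, sim$truth$genes$gene_id)]
round(tapply(nc$nc_ratio, bt, median, na.rm = TRUE), 2)
#> coding lncRNA
#>  -1.32   1.78
round(tapply(iso$isor, bt, median), 2)
#> coding lncRNA
#>   0.79   0.39
```

lncRNA-like genes sit ~3 log2 units above coding-like genes in the N/C
distribution (nucleus-retained) and splice out about half as much of their
length — the two directional signatures of the export boundary.

Testing one mutation's effect on export from allele-resolved fraction
counts (reads carrying the mutant or reference allele in each fraction):

```r
counts <- data.frame(mutation_id = "mut1",
                     n_mut_nuc = 330L, n_ref_nuc = 118L,
                     n_mut_cyt = 633L, n_ref_cyt = 875L)
test_export_shift(counts)[, c("mutation_id", "odds_ratio", "q_bh",
                              "export_call")]
#>   mutation_id odds_ratio     q_bh      export_call
#> 1        mut1       3.87 8.71e-33 decreased_export
```

The mutant allele's nuclear odds are 3.9-fold the reference allele's, so
this mutation retains its transcript in the nucleus (decreased export).

`run_pipeline(cfg, outdir)` chains the stages (genome → counts → N/C →
ISOR → U1 scan → mutation tests → selection tests) and writes TSV/VCF/GTF
outputs plus a JSON manifest with md5 sums; reruns with the same config are
byte-identical.

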