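# methexpress

Tissue-comparative analysis of whole-genome bisulfite-sequencing (WGBS)
methylomes and RNA-seq transcriptomes, for plant epigenomics studies that
ask how DNA methylation differs between organs and micro-dissected tissues
(e.g. root vascular vs nonvascular tissue) and how those differences relate
to gene expression. The package consumes count-level data — per-cytosine
methylation count tables, gene models, gene-level read counts — and is
driven end to end by a synthetic-data generator with known ground truth, so
every stage is testable without any external download.

## What it computes

* **Methylated-cytosine calls.** Replicates are pooled per cytosine; an
  unmethylated spike-in estimates the bisulfite non-conversion rate
  *p* (typically 0.01–0.33%); each cytosine with pooled depth *n* ≥ 4 is
  tested with the exact binomial upper tail *B(x ≥ k; n, p)* and called
  methylated at Benjamini–Hochberg FDR ≤ 0.01 (all contexts jointly).
* **Weighted methylation levels** (Σk/Σn, coverage-weighted), replicate
  status correlations, and PCA on the samples × sites 0/1 methylation-state
  matrix restricted to sites ≥ 4× in every replicate of every sample.
* **Metagene profiles**: 100 × 20-bp windows over each 2-kb flank and 100
  bins over the exon-concatenated gene body, fraction of methylated marks
  per covered cytosine, averaged across genes; expression-quartile
  stratification by RPKM; Kruskal–Wallis + Tukey tests on per-bin averages.
* **DMRs**: 100-bp windows at 50-bp steps, all contexts pooled, cytosines
  ≥ 4× in both samples, two-sided Fisher exact test on read counts for
  windows with ≥ 15 cytosines, concatenation of adjacent windows at
  p < 0.001, and the 30/70 rule (weighted level < 30% in one sample and
  > 70% in the other); ±1-kb gene association; per-gene one-tailed binomial
  hypermethylation tests (N ≥ 20 cytosines, BH ≤ 0.05); k-means DMR
  clustering.
* **Expression**: CPM/RPKM, expressed-gene filter (CPM ≥ 3 in every
  replicate), a negative-binomial exact test for differential expression
  (median-ratio normalisation, common dispersion, BH ≤ 0.05),
  vascular-style enrichment filtering (> 1.2-fold above all contrast
  classes at q ≤ 0.001), and pairwise-slope coexpression (Pearson r of
  tissue-pair RPKM slopes, coexpressed at r ≥ 0.9 — provably identical to
  plain Pearson on the tissue-mean profiles).
* **Enrichment**: hypergeometric GO over-representation with Bonferroni
  correction (< 0.05) and one-sided Fisher tests for transcription-factor
  family enrichment.

## Worked example

Simulate a two-tissue study with one planted DMR, run the full pipeline,
and look at the results:

```r
library(methexpress)

cfg <- list(
  tissues = c("vascular", "nonvascular"), n_replicates = 3,
  contrast = c("vascular", "nonvascular"), seed = 42,
  n_chrom = 1, chrom_length = 120000, n_genes = 20,
  planted_dmrs = tibble::tibble(chrom = "chr1", start = 30000, end = 30300,
                                tissue_high = "vascular",
                                rate_high = 0.9, rate_low = 0.05))
res <- run_pipeline(cfg, "pipeline_out")

res$error_rate
#> [1] 0.001883771
res$dmrs[, c("chrom", "start", "end", "level_a", "level_b", "direction")]
#> # A tibble: 1 × 6
#>   chrom start   end level_a level_b direction
#>   <chr> <int> <int>   <dbl>   <dbl> <chr>
#> 1 chr1  29950 30300   0.828   0.101 hyper_a
```

The spike-in recovers the simulated 0.2% non-conversion rate, and the
planted 300-bp region hypermethylated in vascular tissue (true rates 0.9 vs
0.05) is recovered within one 50-bp window of its planted coordinates with
weighted levels 83% vs 10% — a DMR under the 30/70 rule, hyper in the first
contrast sample (`hyper_a`). `pipeline_out/` holds the DMR BED, per-sample call tables,
metagene profiles, PCA coordinates, DE table and a reproducibility manifest
(seed, parameters, parameter hash); re-running with the same config is
byte-identical.

Individual stages compose with pipes, e.g.:

```r
sim <- simulate_methylome(genome, genes, methylome_truth(), "root", 3, seed = 1)
calls <- sim$tables |> merge_replicates() |> call_methylation(error_rate = 0.002)
```

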