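---
title: "Models and methods behind methexpress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methexpress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`methexpress` implements a tissue-comparative analysis of whole-genome
bisulfite-sequencing (WGBS) methylomes alongside RNA-seq transcriptomes: it
calls methylated cytosines, profiles methylation over genes, detects
differentially methylated regions (DMRs), relates methylation to expression
quartiles, tests differential expression and coexpression, and runs
over-representation statistics. This vignette explains each model, the
parameters that matter, and the design decisions taken where more than one
reading was defensible. Every empirical claim here is one the package's own
test suite or acceptance script computes.

## The binomial site caller

Bisulfite treatment converts unmethylated cytosines to uracil (sequenced as
T) while methylated cytosines stay C, so the methylated-read fraction at a
cytosine estimates its methylation. Conversion is imperfect: a fully
unmethylated spike-in sequence is carried through the library, and its
apparent methylation

$$\hat p \;=\; \frac{\sum_i k_i}{\sum_i n_i} \quad (\text{spike-in sites } i)$$

estimates the non-conversion (error) rate. Typical values in sorghum-scale
WGBS libraries run 0.01–0.33%; `estimate_error_rate()` warns outside that
band and floors the estimate at $10^{-4}$ (the low end of the band) so that
a spuriously clean spike-in cannot degenerate the test.

Replicate count tables are pooled additively (`merge_replicates()`), and
each cytosine with pooled depth $n \ge 4$ is tested with the exact upper
binomial tail

$$P(X \ge k) \;=\; \sum_{x \ge k} \binom{n}{x}\, p^x (1-p)^{n-x},$$

where $k$ is the methylated-read count and $p$ the spike-in error rate.
Benjamini–Hochberg correction is applied per sample across **all three
contexts jointly** (CG, CHG, CHH), and a site is called methylated at
$q \le 0.01$. Sites below 4x are flagged `uncallable` and never enter the
test family. Per-strand cytosines are separate test units; symmetric CG
pairs are not pooled across strands — the conservative reading where the
source procedure is silent.

## Contexts, weighted levels, replicate QC and PCA

`annotate_contexts()` classifies every cytosine on both strands by its own
5'→3' triplet (CG; CHG; CHH with H ∈ {A,C,T}). Triplets containing N are
skipped; a cytosine within 2 bp of a chromosome end whose context cannot be
completed falls back to the broadest class consistent with the visible
bases.

Regional methylation is always the *weighted* level $\sum k_i / \sum n_i$ —
total methylated reads over total reads — not the mean of per-site
fractions; the two differ whenever coverage varies across sites, and the
test suite asserts the algebraic identity between the weighted level and
the coverage-weighted mean of fractions.

Replicate agreement is quantified two ways: a Pearson correlation of binary
methylation status over sites callable in both replicates
(`replicate_correlation()`), and a PCA on the samples-by-sites 0/1 status
matrix (`methylation_pca()`), restricted to sites covered at ≥4x in every
replicate of every sample so the matrix has no missing entries. PCA uses
status, not levels, and fixes the sign of each component (largest-magnitude
loading positive) so coordinates are reproducible run to run.

## Metagene profiles

`bin_gene()` builds the metagene coordinate: 100 fixed 20-bp windows over
the 2,000 bp upstream of the gene start, 100 bins partitioning the
exon-concatenated gene body into pieces whose lengths differ by at most
1 bp, and 100 20-bp windows downstream — all oriented 5'→3' in the gene's
own direction. Genes with under 100 bp of exon cannot host 100 body bins
and are skipped. Per gene and bin, the profile counts binomially-called
methylated marks over covered (≥4x) cytosines of the context; the per-bin
profile value is the unweighted mean over genes in which the bin has at
least one covered cytosine (gene-weighted averaging; the alternative
cytosine-weighted reading would let long, high-coverage genes dominate).

Group differences (expression quartiles 1–4 by RPKM, or tissues) are tested
per region with a Kruskal–Wallis test on the per-bin averages followed by
Tukey HSD for pairwise contrasts. The flank regions natively have 100 bins;
an aggregated 50-bin (40-bp) view is available (`bins50 = TRUE`) for the
variant of the procedure described over 50 upstream/downstream bins, and
the native 100-bin view is the default. Bins along a gene are
autocorrelated, so these p-values are anticonservative and should be read
comparatively rather than absolutely.

Quartile grouping uses the 25/50/75 percentiles of RPKM among expressed
genes; a gene tying a breakpoint goes to the lower group, so a degenerate
all-equal sample collapses into group 1 rather than splitting arbitrarily.

## DMR detection

Candidate windows of 100 bp, stepped by 50 bp and fully contained in the
chromosome, pool all three contexts. A cytosine contributes only when
covered ≥4x in **both** samples, and a window is tested only with ≥15 such
cytosines. The test is a two-sided Fisher exact test on summed read counts
(methylated vs unmethylated by sample) — read-level counts preserve depth
information, whereas per-cytosine binary counts would discard it. Windows
at p < 0.001 (strictly) whose intervals touch or overlap are concatenated;
merged regions are classified as DMRs when one sample's weighted level is
strictly below 30% and the other's strictly above 70%.

One subtlety required a choice. A window that merely *straddles* a sharp
DMR boundary is usually Fisher-significant (half its cytosines differ
dramatically), yet its own level is intermediate; merging such windows
drags flanking background into the region and dilutes the region's weighted
level — for a 300-bp region at 0.9 vs 0.05 the expected diluted level is
≈0.69, just under the 70% bar, which would cost roughly half of all true
regions. `detect_dmrs()` therefore applies the 30/70 rule twice: per tested
window before concatenation, and again on the merged region. The
window-level screen keeps region boundaries tight (recovered regions
coincide with the planted intervals in the test suite) without changing
what qualifies as a DMR.

DMRs associate with every gene whose span extended by 1,000 bp on each side
intersects them, recording overlap vs 5'/3' flank strand-aware. Per-gene
hypermethylation uses a one-tailed binomial test per context — $N$ callable
cytosines in the gene span (genes with $N < 20$ excluded), $K$ methylated
calls, and the genome-wide fraction of callable cytosines called methylated
as the background $P$ — with BH correction at $q \le 0.05$. K-means (fixed
seed, 25 restarts, user-chosen $k$, default 4) clusters DMRs on their
per-sample levels; a plain mean silhouette on Euclidean distances reports
separation.

## Expression analysis

CPM is $c \cdot 10^6 / L$ and RPKM $c \cdot 10^9 / (L \cdot \ell)$ for
count $c$, library size $L$ (column sum) and gene length $\ell$ in bp. A
gene is *expressed* in a tissue when CPM ≥ 3 (inclusive) in every
replicate.

Differential expression is a deliberately transparent negative-binomial
exact test: median-of-ratios size factors; one common dispersion estimated
by the aggregated moment equation $\sum_g (s_g^2 - \bar\mu_g) / \sum_g
\bar\mu_g^2$ within groups (aggregating before dividing avoids the strong
downward bias of per-gene moment ratios at $n = 3$); then, per gene, an
exact conditional test on the normalised group sums, using the fact that a
sum of $r$ i.i.d. NB$(\mu, \phi)$ variables is NB$(r\mu, \phi/r)$: all
splits of the observed total no more probable than the observed split
contribute to the p-value. BH-FDR at 0.05 defines differential expression,
with direction labelled by the sign of the log fold-change (the
"positive log fold-change" phrasing is a direction label, not a one-sided
test — both directions are reported). This is not a re-implementation of
edgeR's empirical-Bayes tagwise machinery; edgeR serves as an independent
cross-check in the test suite, where the two testers rank genes nearly
identically (rank correlation > 0.95) and call substantially the same
genes.

Tissue enrichment filtering keeps a gene when some focal class exceeds
**every** contrast class by strictly more than 1.2-fold at $q \le 0.001$.

Coexpression against a reference gene correlates *pairwise tissue slopes*:
for every ordered pair of distinct tissue classes the difference in
replicate-averaged RPKM is taken, and the Pearson correlation of the two
genes' slope vectors is computed. Because each pair enters with both signs
the slope vectors are mean-zero, and the statistic collapses exactly to the
plain Pearson correlation of the tissue-mean vectors — an identity the test
suite verifies to $10^{-12}$ on 1,000 random profiles. (Had the slopes been
taken in one direction per pair only, the identity would fail; the
symmetric construction is the one consistent with "all combinations" of
lines between tissue values.) Genes with $r \ge 0.9$ are coexpressed.

## Over-representation statistics

GO-term enrichment is the one-sided hypergeometric (Fisher) upper tail per
term with at least one study hit, Bonferroni-corrected over tested terms,
enriched at corrected $p < 0.05$ (strict). The population universe defaults
to all annotated genes. Annotations are used as given — parent-term
propagation through the GO graph is out of scope. Transcription-factor
family enrichment is the analogous one-sided Fisher test of family members
among focal (e.g. vascular-expressed) genes against the genome-wide focal
fraction. Both tests are checked against log-choose enumeration oracles to
$10^{-10}$.

## The synthetic-data generator

Every stage is testable without external data because `simulate_methylome()`
and `simulate_expression()` generate studies with known truth:

* **Genome**: i.i.d. bases at a target GC fraction (default 0.44,
  grass-like), plus an extra fully unmethylated `spikein` chromosome whose
  observed methylated fraction estimates the error rate.
* **Methylome**: each cytosine receives a regional rate (per-context
  baselines, default CG 0.75 > CHG 0.45 > CHH 0.05, the plant ordering;
  optionally a CG gene-body multiplier inside exons) and a **single true
  binary state shared by all tissues and replicates**. Tissue differences
  enter only where planted: DMR intervals re-draw the state per tissue at
  `rate_high` (> 0.7) or `rate_low` (< 0.3), so truth is recoverable under
  the 30/70 rule, and an optional `flip_fraction` flips a random site subset
  per additional tissue to emulate broad tissue differences for PCA
  scenarios. Replicates then differ *only* by read sampling: Poisson
  coverage (default mean 8, in the study-like 4–12x band) and binomial
  reads with success probability $1-\text{err}$ at methylated and
  $\text{err}$ at unmethylated sites (default err = 0.002, mid spike-in
  range). Simulation is site-level, not read-level, because the pipeline
  consumes count tables. An earlier design that drew states independently
  per tissue was rejected: it makes every window differ between tissues at
  a few percent of sites, which is not a null background.
* **Expression**: NB counts around tissue-mean profiles. DE is planted
  multiplicatively ($2^{\text{lfc}}$ in the up-tissue). Coexpression-module
  members are built from the reference profile with orthogonalised noise so
  the planted tissue-profile correlation equals the target (default 0.95)
  exactly before count noise; the reference's log-profile is standardised
  (spread 1.2) so its tissue contrast is guaranteed. The unplanted
  background is rebalanced so each tissue's total expression is equal —
  otherwise library-size normalisation compositionally distorts the planted
  correlations (we measured planted 0.95 dropping to ≈0.89 without the
  balancing).

Two noise regimes are used deliberately: dispersion 0.05 for DE power and
null-calibration scenarios, and 0.01 for coexpression and replicate-QC
scenarios — the latter matches the high end of replicate $r^2$ (≈0.98 on
FPKM) that motivates treating replicates as near-pure sampling noise.

What the generator does **not** emulate: read-level artefacts (mapping,
PCR duplicates), transposable-element and centromeric methylation
structure, chromosome-scale methylation gradients, batch effects, and
gene-length biases in expression. Passing tests therefore demonstrate
correctness of the statistical machinery under the stated model, not
robustness to those real-data phenomena.

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open; on-disk count tables are
  1-based. The conversion is confined to the readers/writers and checked by
  round-trip tests.
* Window Fisher p-values sum hypergeometric probabilities `<= observed *
  (1 + 1e-7)`; the tolerance guards against floating-point ties, and the
  implementation is checked against enumeration to $10^{-10}$.
* `binomial_tail(0, n, p) = 1` exactly; `p` must lie strictly inside (0,1),
  with the $10^{-4}$ floor supplying a valid value when a spike-in is
  perfectly clean.
* Empty selections (weighted level of an empty region, correlation of
  constant status vectors, constant expression profiles) signal a typed
  condition (`methexpress_undefined`) rather than returning NaN.
* K-means on identical feature rows warns and returns one cluster;
  silhouette is undefined at $k = 1$.
* All simulation entry points take a seed and are byte-reproducible; the
  pipeline manifest records the seed and a parameter hash.

## Problem sizes

The test suite and acceptance script run, among others: $10^5$ sites for
caller calibration; a 2-Mb genome with 50 planted 300-bp DMRs at 10x for
DMR recovery; 300 genes on a 1.5-Mb genome for metagene fidelity; 2,000
genes for DE null calibration and 1,000 for power; 200 genes across five
tissue classes for coexpression. These sizes keep every run modest on a
single CPU while leaving the statistical assertions well-powered; they are
scaled-down analogues of the study design (4 sample classes x 3
replicates, genome-wide methylomes), not reproductions of its genome-scale
datasets.

## Known limitations

* The DE test uses a single common dispersion; genes with atypical
  dispersion are mis-calibrated relative to tagwise empirical-Bayes
  methods.
* Tukey HSD on metagene bins treats autocorrelated bins as independent
  observations (inherited from the procedure it mirrors).
* Hypermethylation counts cytosines over the gene span, not exons only;
  with intron-rich genes the two differ.
* The window-level 30/70 screen in `detect_dmrs()` is required for sharp
  planted boundaries; real DMR edges are softer and would be less affected.
* GO enrichment does not propagate annotations up the ontology graph.
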