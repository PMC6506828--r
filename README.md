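# chialink

Pol II ChIA-PET loop calling and SOX2 enhancer-expression co-association
analysis, in R.

SOX2 loss in neural stem cells (NSCs) collapses much of the RNA polymerase
II-mediated long-range chromatin connectivity between gene promoters and
distal enhancers, and the genes wired to SOX2-bound enhancers are the ones
that lose expression. `chialink` implements the full analysis chain behind
that observation, for anyone working with ChIA-PET-style interaction data,
enhancer chromatin marks and WT/mutant expression tables:

* **Loop calling** — paired-end tags (PETs) are linker-filtered,
  deduplicated (2-bp joint tolerance), classified (self-ligation ≤ 8 kb /
  intra- / inter-chromosomal) and clustered by single linkage with both ends
  within 1 kb. A cluster with `c` member PETs, anchor tag counts `n_a`,
  `n_b` and sequencing depth `T` is scored with the hypergeometric tail
  `p = P(X ≥ c)`, `X ~ Hypergeom(T, n_a, n_b)`, adjusted by
  Benjamini–Hochberg; significant loops satisfy `c ≥ 3` (in-situ dialect),
  `q < 0.05`, `p < 0.05`. A tag re-pairing simulation estimates the
  coincidence noise level.
* **Anchor annotation** — promoter (±2.5 kb of a TSS) > gene body >
  intergenic priority at 1-bp overlap; interactions typed P-P / P-nonP /
  nonP-nonP; Pol II support on both anchors; SOX2 occupancy of the distal
  anchor defines a SOX2-bound promoter–enhancer (P-E) loop.
* **Mark layer** — peak standardization to ≥ 2 kb, promoter/distal split at
  1 kb, active (H3K27ac⁺ H3K4me1⁺) vs poised (H3K4me1⁺ only) enhancer
  states, 200-bp Poisson bin binarization (`p < 1e-4`), chi-square WT/MUT
  differential bins, and random-sampling interval enrichment with a
  mappability/blacklist mask (1,000 matched random sets, add-one empirical
  p).
* **Expression link** — log2 TPM fold ratios, limma-moderated differential
  q-values, expression groups (group 1: fold > 1.5 and q < 0.05; group 2:
  q < 0.2; group 3: rest; eligibility TPM > 5), exact Wilcoxon paired
  signed-rank tests.
* **Co-association** — for gene sets of sizes `n` (expression group) and `m`
  (interaction category) with `k` genes in common out of `N`, the signed
  score `s = −log10 p` if `k > nm/N` else `+log10 p` from a two-sided Fisher
  exact test; `|s| > 2` is significant.

A synthetic-data generator (`simulate_dataset()`) plants a genome, loops,
peak sets and WT/MUT expression with known ground truth, so the entire
pipeline is testable end to end without any deposited sequencing data.

## Worked example

Simulate a WT-like NSC world in which genes connected to SOX2-bound
enhancers are downregulated to 15% in MUT, then run every stage:

```r
library(chialink)

run <- run_pipeline(pipeline_config(seed = 5, n_genes = 1600, n_chroms = 4,
                                    chrom_length = 2e7, n_loops = 300,
                                    n_background_pets = 15000))
print(run)
#> pipeline run (seed 5)
#>   PETs: 18629 total, 18629 unique (self 3000 / intra 12629 / inter 3000)
#>   loops: 309 clusters, 300 significant (23755 per million intra PETs)
#>   nodes: 560 (367 promoter); types P-P 138 / P-nonP 131 / nonP-nonP 31

subset(run$coassoc, group == "group1")
#>  group      category  k  n   m    N        p  score
#> group1            pe 45 47 123 1558 4.29e-51 50.368
#> group1       sox2_pe 45 47  45 1558 5.31e-85 84.275
#> group1    nonsox2_pe  0 47  78 1558 1.68e-01 -0.775
#> group1            pp  5 47 254 1558 4.20e-01 -0.376
#> group1 sox2_promoter  7 47 164 1558 3.30e-01  0.481
```

Reading the output: of 1,558 eligible genes (TPM > 5), 47 land in group 1
(significant expression decrease in MUT), and 45 of them are genes whose
promoter loops to a SOX2-bound enhancer — a co-association score of 84
(`−log10 p`), overwhelmingly significant, while genes looped to enhancers
*without* SOX2 show no association (score −0.78, within the ±2 band). This
is the planted structure: downregulation was applied exactly to
SOX2-bound-enhancer-connected genes, and the pipeline recovers it.

Individual stages are available as plain functions (`call_loops()`,
`annotate_interactions()`, `summarize_connectivity()`,
`empirical_enrichment()`, `differential_qvalues()`,
`coassociation_matrix()`, ...). A thin command-line wrapper lives at
`inst/cli/chialink.R`. The methods vignette
(`vignettes/chialink-methods.Rmd`) documents the models, parameter choices
and limitations.

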