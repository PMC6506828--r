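---
title: "Methods: loop calling, anchor annotation and co-association scoring"
author: "chialink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: loop calling, anchor annotation and co-association scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chialink)
```

## The problem

SOX2 is required for the self-renewal of neural stem cells (NSCs), and its
loss reshapes the three-dimensional regulatory wiring of the genome: RNA
polymerase II (Pol II)-mediated chromatin loops connecting gene promoters to
distal enhancers are lost, and the genes they serve are downregulated.
`chialink` implements the computational chain needed to quantify that claim
from ChIA-PET (chromatin interaction analysis with paired-end tags), ChIP-seq
and RNA-seq style inputs:

1. call significant chromatin interactions from PET tag pairs;
2. annotate interaction anchors against a gene model and type each
   interaction as promoter-promoter (P-P), promoter-distal (P-nonP, i.e.
   putative promoter-enhancer) or distal-distal (nonP-nonP);
3. classify enhancer chromatin states from H3K27ac and H3K4me1 occupancy and
   measure SOX2 enrichment in them by masked random sampling;
4. group genes by expression change between wild-type (WT) and Sox2-deleted
   (MUT) cells;
5. score the co-association between expression groups and interaction
   categories with a signed Fisher statistic.

Because the deposited sequencing data are not required, a synthetic-data
generator with planted ground truth stands in for them; every stage is
exercised and verified against that truth.

## Loop calling

### PET classification

Each PET carries two tags. Libraries built with two barcoded half-linkers
mark inter-molecular ligation artifacts with mixed codes: full linkers AA/BB
are non-chimeric, AB/BA are chimeric and discarded
(`classify_linker()`). Libraries built with a single bridge linker carry no
codes and are treated as non-chimeric. Non-chimeric PETs are deduplicated
(clonal PCR copies merge when both tag coordinates agree within 2 bp) and
classified by geometry (`classify_pet()`): different chromosomes are
inter-chromosomal; same-chromosome spans of at most 8 kb are self-ligation
(one fragment, not a contact); larger spans are intra-chromosomal and carry
the loop signal. Only intra-chromosomal PETs enter clustering.

Duplicate merging is defined as the transitive closure of the
"within-tolerance at both ends" relation, keeping the lexicographically
smallest member of each group. A one-pass greedy scan over the sorted table
can retain two PETs that are mutual duplicates whenever an unrelated PET
interleaves between them in sort order; the closure cannot, which is why it
is used even though it is marginally more work.

### Clustering and significance

Intra-chromosomal PETs cluster by single linkage: two PETs join one cluster
iff their left ends lie within the extension distance (default 1 kb) *and*
their right ends do, transitively closed (`cluster_intra_pets()`). Cluster
anchors span the member tag coordinates on each side; singletons are noise
and are dropped. The iPET count `c` of a cluster is its member count.

Significance uses the hypergeometric model standard in ChIA-PET processing:
for a cluster with anchor tag counts `n_a` and `n_b` (all deduplicated
intra-chromosomal tag ends overlapping each anchor, both PET sides counted)
out of `T` total intra-chromosomal PETs,

$$p = P(X \ge c), \qquad X \sim \mathrm{Hypergeom}(T,\, n_a,\, n_b),$$

which is symmetric in `n_a` and `n_b` and accounts for both anchor coverage
and sequencing depth. p-values are adjusted with Benjamini-Hochberg
(`bh_fdr()`); the source analysis states an FDR cutoff without naming the
procedure, and BH is the conventional choice. A cluster is significant iff
`c >= min_ipet`, `q < 0.05` and `p < 0.05`. Two protocol dialects are kept:
`tr1` (sonication/half-linker chemistry, `min_ipet = 2`) and the default
`insitu` (tagmentation chemistry, `min_ipet = 3`).

Design choices worth making explicit:

* The hypergeometric parameterization (population `T`, draws `n_a`,
  successes `n_b`) is the classic ChIA-PET-tool formulation; the
  non-central-hypergeometric refinement used by some callers is out of scope.
* Anchor tag counts are taken over the cluster-derived anchor span without
  further extension.
* "Respective ends within 1 kb" is read as tag-to-tag distance at each end
  (not midpoint or gap distance), which makes the clustering relation a
  simple conjunction of two 1-D proximities.

### Noise by tag re-pairing

`shuffle_noise()` estimates how many clusters arise by coincidence: left and
right tags of the observed intra-chromosomal PETs are pooled per chromosome
and re-paired uniformly at random, the simulated PETs are re-clustered, and
the noise level is the mean simulated PET-2+ cluster count divided by the
real count. On data that is itself uniformly paired the ratio is ~1 by
construction; on data with planted loops it is far below 1.

A note on calibration: the hypergeometric p-values of *selected* clusters
are not uniform under the null — a cluster exists only because a coincidence
was found, so its p is small by selection. The package's calibration
property is therefore stated over pre-defined candidate anchor pairs (fixed
1-kb bins), where the model's p-values are verifiably super-uniform on
re-paired data.

## Anchor annotation and interaction typing

Anchors are annotated with priority P > G > I at 1-bp overlap
(`annotate_anchor()`): P if the anchor overlaps any TSS ± 2.5 kb window, else
G if it overlaps a gene body, else intergenic. An interaction's type is the
combination of its two anchor classes, collapsing G and I into "nonP".
Overlapping anchors merge transitively into *nodes* (`build_nodes()`), whose
promoter status is decided on the merged interval. Pol II-mediated
interactions are those with a Pol II peak on *both* anchors; SOX2 flags
distinguish occupancy of any anchor from occupancy of the distal anchor of a
P-nonP interaction, the configuration that defines a SOX2-bound
promoter-enhancer (P-E) loop.

Two distinct promoter windows coexist deliberately: ±2.5 kb for
anchor/node annotation and ±1 kb for histone-mark region classification.
Both constants come from the underlying analyses and are independently
configurable.

## Histone-mark layer

Narrow peaks are standardized to at least 2 kb (symmetric extension around
the midpoint, then merging) to match peak resolution; regions within 1 kb of
a TSS are promoter regions, the rest putative distal enhancers
(`standardize_peaks()`, `split_promoter_distal()`). Distal regions carrying
both H3K27ac and H3K4me1 are *active* enhancers; H3K4me1 alone marks
*poised* enhancers (`enhancer_state()`).

For segmentation-style analyses the genome is tiled in 200-bp bins; a bin is
mark-positive when its read count exceeds the upper tail of a Poisson
background at `p < 1e-4`, with the background rate estimated as the mean
reads per bin (over unmasked bins when a mask is supplied). WT/MUT
differential bins use a 1-df chi-square on the 2x2 table of in-bin versus
out-of-bin reads per condition, without continuity correction (the Yates
correction is available by flag); `p < 1e-4` marks a differential bin. The
2x2 form is the natural reading of a test parameterized by per-region counts
and genome-wide totals in both conditions.

Enrichment of one interval set in another (e.g. SOX2 peaks in distal
H3K27ac regions) is measured against 1,000 random interval sets matched in
element count and exact element lengths, placed uniformly in the genome
after excluding a mask (assembly gaps, blacklists, and zero-coverage 3-kb
sliding windows at 500-bp stride; `build_unmappable_mask()`). Placement
weights every chromosome segment by its number of valid start positions, so
no sampled interval ever intersects the mask. The empirical p uses the
add-one estimator `(1 + #{null >= obs}) / (n_sets + 1)`, which can never be
zero; an observation above all 1,000 nulls reports `p < 0.001`. The overlap
statistic is the element count by default (base-pair overlap by flag);
element counts are heavily tied under the null, which makes the estimator
conservative there, so the package's uniformity calibration uses the
base-pair statistic and bounds the element statistic by super-uniformity.

## Expression analysis

Expression is in TPM with replicate columns per condition. Three floors are
used at different stages, on purpose: TPM > 0 for distribution comparisons,
TPM > 1 for log2 fold-ratio analyses (`fold_ratio()`), and TPM > 5 (in WT or
MUT) for differential grouping and co-association.

Differential evidence (`differential_qvalues()`) defaults to a limma
moderated t-statistic on log2(TPM + 1), BH-adjusted. The original analysis
used NOISeqBIO, which shares noise information across genes; a moderated
statistic is the closest widely-used equivalent and remains powered at three
replicates per condition. A pure per-gene label-permutation test is kept as
`method = "permutation"` for reference, but note its granularity: with 3v3
replicates only 20 label splits exist, so its smallest two-sided p is 0.1 —
below any 5% FDR threshold, no gene can ever reach significance. That
granularity is the reason the permutation test is not the default.
Precomputed q-values from any external DE tool can be used instead.

Genes above the grouping floor are partitioned (`assign_groups()`):
*group 1* (significant decrease): linear WT/MUT fold > 1.5 and q < 0.05;
*group 2* (moderate): not group 1 but q < 0.2; *group 3*: the rest.
Distribution shifts between WT and MUT are tested with a two-sided Wilcoxon
paired signed-rank test (`paired_signed_rank()`); for up to 25 non-zero
differences the exact null distribution is computed by convolution over the
(possibly midranked) rank weights — this handles ties exactly, and reduces
to the textbook signed-rank distribution without ties — and the normal
approximation with tie correction is used beyond that.

## Co-association scores

For an expression group of size `n`, an interaction category with `m` member
genes, `k` genes in both, and `N` eligible genes, the overlap probability
comes from a Fisher exact test on `[[k, n-k], [m-k, N-n-m+k]]`
(`fisher_p()`). The signed score is

$$s = \begin{cases} -\log_{10} p & k > nm/N \\ +\log_{10} p & \text{otherwise,} \end{cases}$$

so positive scores mean enrichment and negative scores depletion, with
`|s| > 2` conventionally significant. The test is two-sided by default: the
signed score reports both directions, which implies a two-sided reference
(one-sided is available by flag). Categories are set-valued per gene (P-E,
SOX2-bound P-E, P-E without SOX2, P-P, SOX2-bound promoter) and each is
tested marginally; no multiple-testing correction is applied across cells,
matching the reporting convention of the source analysis.

## The synthetic generator

`make_genome()` places non-overlapping genes by jittered slotting on two or
more chromosomes. `make_architecture()` plants loops with a configurable
type mixture — defaults 87.5% promoter-mediated, split evenly between P-P
and P-nonP, i.e. the middle of the observed 85-90% range — places distal
anchors clear of every promoter window so planted labels always agree with
downstream annotation, and derives peak sets: Pol II on every loop anchor,
SOX2 in a configurable fraction of enhancers (default 40%, the middle of the
observed 34-43% range), and mark states such that at least 95% of SOX2-bound
enhancers are active (enforced by count, not by chance). `simulate_pets()`
scatters signal PETs uniformly within the two anchors of each loop
(per-loop intensity 8 + Poisson(4)) over a background of self-ligation,
intra- and inter-chromosomal PETs in proportions 0.2/0.6/0.2, matching the
class shares of in-situ-style libraries. Background intra-chromosomal spans
follow a truncated power law (exponent 1, minimum 8,001 bp) — a heavy-tailed
stand-in chosen because ligation noise in real libraries is strongly
distance-dependent; no claim is made that it matches any particular
library's empirical distance law. `simulate_expression()` draws base TPM
log-normally (meanlog log 30, sdlog 1, a realistic right-skewed expression
distribution), multiplies by 1.5 per connected enhancer, and applies the MUT
downregulation factor (default 0.15, the magnitude seen for strongly
SOX2-dependent targets) to genes connected to at least one SOX2-bound
enhancer; replicates are mean-preserving log-normal draws at CV 0.2.

What the generator does *not* emulate: sequence content and mappability
structure, copy-number and GC biases, distance-dependent contact decay
within loops, partially penetrant effects, inter-gene expression
correlation, and peak-calling uncertainty (peak sets are emitted directly).
Passing tests therefore demonstrate correctness of the statistical machinery
and recoverability of planted structure, not robustness to every artifact of
real sequencing data.

## Problem sizes and numerical choices

The verification suite runs on deliberately scaled-down worlds chosen so
that every statistic retains its qualitative regime: loop recovery on
2 x 10 Mb chromosomes with 50 planted loops over a 20x background (planted
tags ~8% of intra-chromosomal PETs, as in real in-situ libraries);
interaction-type proportions on 1,000 loops over 4 x 20 Mb; co-association
on 1,600 genes and 300 loops, where the expected group-1 overlap with
non-SOX2 P-E genes is a few genes, so its score stays within ±2 while the
SOX2-bound P-E score is far above 2. Coordinates are 1-based closed
internally on `GRanges` (the Bioconductor convention); BED and bedGraph
conversion happens at the I/O boundary. Hypergeometric tails are floored at
the smallest positive double so reported p-values stay in (0, 1];
normalized per-million loop rates round half away from zero, the convention
under which all published summary rates reproduce exactly.

## Limitations

Inter-chromosomal interactions are classified but never clustered (the
source analysis calls intra-chromosomal loops only). The permutation DE mode
is granularity-limited at small replicate counts, as discussed. The
ChromHMM-style segmentation is reduced to its binarization and differential
test; no multi-state HMM is fitted. Reported q-values are BH over the genes
or clusters in hand and inherit BH's assumptions under dependence.
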