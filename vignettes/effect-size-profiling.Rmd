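---
title: "Effect-size profiling for cross-species single-cell comparisons"
author: "esProfiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effect-size profiling for cross-species single-cell comparisons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esProfiler)
```

## The problem

Comparative single-cell RNA-seq studies across species frequently end up
with one sample per condition: one control and one stimulated library per
organism. Two things then break simultaneously. First, per-gene
between-sample offsets (library preparation, sequencing depth, annotation
differences — collectively, batch effects) dominate cell-type variation
as soon as samples are merged, so joint clustering groups cells by sample
rather than by biology. Second, with a single sample per condition there
is no replicate-level variance, so p-value-based differential expression
is not defined at the level at which the question is asked.

esProfiler sidesteps both problems by never merging samples. Each sample
is processed on its own (QC, normalisation, clustering), and all
cross-sample comparisons go through *effect-size profiles*: per cluster,
the vector of Glass rank biserial coefficients of every gene, contrasting
the cluster's cells against the rest of the same sample.

Two properties make these profiles comparable across samples and species:

* the rank biserial coefficient is computed *within* one sample, so any
  per-gene, per-sample multiplicative or additive offset — precisely the
  form of a batch effect on the expression scale — shifts all cells of
  the sample equally and leaves the ranks, hence the coefficient,
  unchanged;
* it is invariant under strictly monotone transforms of the values, so
  the choice of normalisation cannot leak between-sample differences into
  the comparison.

## The statistic

For a gene $g$ and a cluster $C$ within a sample of $N$ cells, pool the
log-normalised values of the cluster cells (group 1, $n_1$ cells) and all
other cells (group 2, $n_2$ cells), assign midranks $R$, and set

$$ r_g \;=\; \frac{2\,(\bar R_1 - \bar R_2)}{N} \in [-1, 1]. $$

Without ties this equals $2U/(n_1 n_2) - 1$ with $U$ the Mann–Whitney
statistic, reaching $\pm 1$ exactly at complete separation; the test
suite verifies the identity against an exhaustive pair-counting oracle to
$10^{-12}$. The per-cluster vector $(r_g)_g$ over the entire gene list is
the cluster's effect-size profile.

Downstream, the profiles are used three ways:

1. **Cluster linkage.** Spearman correlation between a query cluster's
   profile and every reference cluster's profile (over the shared,
   optionally ortholog-mapped gene list); the reference with the highest
   *positive* correlation names the query's cell type. Correlations are
   computed over all genes rather than marker subsets, which makes their
   magnitude modest (typically 0.3–0.4 on the bundled simulations) but
   the diagonal dominance robust. With no positive correlation the query
   stays unassigned rather than being forced.
2. **Response genes.** With linked cell types in hand, each gene gets
   the ratio $|r^{\text{stim}}_g| / |r^{\text{ctrl}}_g|$; genes whose
   |effect size| is below 0.1 in *either* sample are excluded first (the
   negligible-effect filter — a ratio of two near-zero numbers carries
   no information), and genes with ratio above 1.5 are selected as
   candidate stimulation-responsive biomarkers. A sign-concordance flag
   records whether the effect direction agrees between conditions, since
   ratios of absolute values discard sign. Genes whose ratio exceeds 1
   in both species form the cross-species consensus set, which can be
   screened against user-supplied gene sets with a one-sided
   hypergeometric test (BH-adjusted).
3. **Clustering comparison.** Two labelings of the same cells are
   compared by the weighted Dice–Sørensen index: clusters matched
   one-to-one by maximising the total confusion-matrix intersection
   (optimal assignment; a greedy variant is available), each pair scored
   $2|A \cap B|/(|A|+|B|)$, and the scores averaged with the query
   clusters' fractional sizes as weights. The index is 1 exactly for
   identical partitions, and values near 0.9 correspond to labelings
   differing in roughly 5% of cells.

## Clustering: DivIK

Each sample is clustered with divisive intelligent k-means. Per node:

* **amplitude filtration** — a 1-D Gaussian mixture (EM, component count
  1–3 by BIC) on the log per-gene means; the lowest-mean component is
  discarded as a noise floor. Applied at the root only by default
  (`amplitude_filter_at_root_only`), matching the reference description
  of the algorithm; the stage also does not apply to signed data, where
  abundance is undefined.
* **variance filtration** — the same mixture machinery on log per-gene
  variances; only the highest-variance component is retained. A
  single-component BIC outcome disables the stage (all genes kept), and
  below 10 genes the stage is skipped with a warning.
* **gap statistic** — for $k = 1..k_{\max}$, k-means (best of
  `kmeans_restarts` seeded restarts, Euclidean distance on the z-scaled
  selected features) gives $\log W_k$; $B$ reference datasets drawn
  uniformly over the feature-wise bounding box give $E^*[\log W_k]$ and
  its standard error $s_k$ (inflated by $\sqrt{1 + 1/B}$). The node is
  split into the smallest $k$ with
  $\mathrm{gap}(k) \ge \mathrm{gap}(k+1) - s_{k+1}$; $k = 1$ means no
  split. Coincident-point geometries are handled with a floor under the
  log.
* **recursion** — children are recursed into while every child keeps at
  least `max(min_cluster_cells, min_cluster_fraction * n_root)` cells
  and the depth stays below `max_depth`. Leaf labels are path-encoded
  (`"0.2.1"`), and one seed makes the whole tree deterministic.

Defaults: `max_k = 10`, `B = 10`, `kmeans_restarts = 10`,
`min_cluster_cells = 20`, `min_cluster_fraction = 0.01`,
`max_depth = 5`. The stop rules are not part of the published method
description; they encode its stated goal — finding small and rare cell
populations — while preventing the recursion from shattering noise. On
real-scale data DivIK typically subdivides broad cell types into pure
subtypes (the bundled simulation yields, e.g., two monocyte leaves whose
union is exactly the planted monocyte population); linkage then maps
each subtype to the reference type, so over-segmentation is benign for
the downstream analysis.

## QC and normalisation

Following standard single-cell practice, genes detected in no cell are
discarded; cells are retained when they have **more than 200** detected
features and **less than 10%** mitochondrial counts (symbol prefix
`MT-`, configurable). Both thresholds are read as strict inequalities
exactly as printed — a boundary cell with exactly 200 features or
exactly 10.0% mito is removed. An empty cell has its mito percentage
defined as 0 and is removed by the feature criterion, avoiding a
division by zero. Retained counts are log-normalised,
$\ln(1 + 10^4 \cdot c_{gc} / \mathrm{total}_c)$ (natural log), then
gene-wise centred and standardised without clipping; profiles are
computed on the log-normalised values, where rank invariance makes the
distinction from z-scores immaterial except for centring-induced ties,
while clustering distances use the z-scores.

## The synthetic two-species experiment

Real cross-species stimulation datasets of this shape are not bundled;
instead the package ships a seeded generator (`simulateTwoSpecies()`)
that emulates the *structure* the method assumes, and every statistical
claim in the test suite is made against it:

* two "species" sharing 80% of gene symbols (the rest species-private,
  exercising the ortholog-mapping path), four shared cell types
  (Monocytes 30%, T 40%, B 20%, NK 10%) with 40 markers each at 8-fold
  enrichment;
* negative-binomial counts (dispersion 0.3) with log-normal baselines,
  species-specific library-size distributions, and per-gene,
  per-species N(0, 0.3) log-scale batch offsets — large enough that
  naive joint clustering would group cells by species, reproducing the
  failure mode that motivates the method;
* 50 planted stimulation-responsive genes in the monocytes at 4-fold
  under stimulation. These are drawn from well-expressed genes and carry
  a 2-fold baseline monocyte enrichment in *both* conditions
  (`response_baseline_fold`): inflammatory response genes are
  myeloid-expressed at rest and amplified by stimulation, and a gene
  with a truly zero control effect size would be — correctly — removed
  by the negligible-effect filter, so a detectable planted signal must
  clear it;
* 10 mitochondrial pseudo-genes with per-cell mito fractions from
  Beta(2, 198) (mean 1%; the tail probability beyond 9.5% is ~5e-8, so
  unplanted cells essentially never cross the QC threshold), plus 2% of
  cells forced to 15–30% mito and 2% forced below 200 detected features
  to exercise QC exactly.

What the generator does *not* emulate: realistic transcriptome-wide
co-expression, zero inflation beyond the negative binomial, doublets,
ambient RNA, or the actual PBMC composition of any organism. Passing
tests therefore demonstrate the pipeline's statistical behaviour under
its own assumptions — batch offsets that are per-gene and per-sample,
cluster-defining markers, rank-detectable responses — not performance on
any particular real dataset.

## Numerical and design choices

* GMM component count is capped at 3 and chosen by BIC; amplitude and
  variance are log-transformed (offset $10^{-6}$) before fitting because
  their raw-scale right tails make mixture fits degenerate. Constant
  inputs short-circuit to one component with a variance floor of
  $10^{-12}$.
* The gap statistic uses the original uniform-over-bounding-box
  reference and the one-standard-error selection rule; the within
  dispersion is the plain within-cluster sum of squares (an independent
  implementation of the same criterion differs by a constant factor of
  2, which cancels inside the gap — the test suite checks agreement
  after removing it).
* The profile contrast is one-vs-rest within a sample. This is the only
  reading that yields exactly one vector per cluster, as the linkage
  correlograms require; a condition-vs-condition contrast within a
  cluster is the noted alternative and is deliberately not implemented.
* Ratios are computed on absolute effect sizes with a separate
  sign-concordance flag; signed ratios can be negative, which is
  incompatible with a "ratio above 1.5" selection rule.
* The negligible filter reads "in any sample" as *either member of the
  compared pair*.
* In the weighted Dice–Sørensen index the weights are the fractional
  sizes of the first (query) labeling's clusters and matching is the
  optimal one-to-one assignment; both are stated interpretations — the
  published description names neither — with greedy matching exposed as
  an option.
* Ties in linkage go to the lowest-index reference and are flagged; a
  gene map must be one-to-one, and an empty map falls back to plain
  symbol intersection.
* The pipeline fans a single global seed out to per-stage seeds
  deterministically; stages communicate via on-disk artifacts and a
  manifest with per-file checksums, so a rerun with the same
  configuration is bitwise identical.

## Problem sizes used by the bundled checks

Unit tests run on reduced fixtures (hundreds of cells, hundreds of
genes). The acceptance suite runs the generator at its default study
conditions — 4 samples x 1500 cells x 2000 genes — for 20 seeds (plus
20 null seeds with `response_fold = 1`), the clustering recovery checks
at 300 points x 20 features for 20 seeds, and the full-pipeline
determinism check at default scale with a gap search of `max_k = 6`,
`B = 5`, `kmeans_restarts = 4`. `scripts/acceptance.R` recomputes the
same quantities with 5-10 seeds per stochastic summary. These sizes are
the package's chosen desk-scale study conditions; the statistics they
produce (linkage accuracy, recall/precision of the planted response
genes, null selection rate) are stable across seeds at this scale.

## Known limitations

* The method is designed for the single-sample-per-condition regime;
  with replicates available, standard differential expression with
  proper variance estimation is preferable, and effect-size ratios
  should be read as a screening heuristic, not inference.
* Ratio-based selection inherits the negligible filter's blind spot:
  genes truly silent in the control cannot be selected however strongly
  they respond, because their control effect size is negligible by
  construction.
* Linkage assumes the reference clustering is trustworthy and its
  labels meaningful; an unassigned query cluster (no positive
  correlation) may be a genuinely novel population or an artefact, and
  the package deliberately does not guess.
* DivIK's feature filtration is calibrated for abundance-like data; on
  small gene panels (< ~1000 genes) the mixture fits become unstable
  and the filtration may keep uninformative features.
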