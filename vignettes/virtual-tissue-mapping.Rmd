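---
title: "Virtual-tissue mapping of single-cell omics and enhancer-to-gene links"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual-tissue mapping of single-cell omics and enhancer-to-gene links}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scregmap)
```

## The problem

Single-cell RNA-seq and single-cell ATAC-seq measure complementary layers of
gene regulation, but when the two assays are run on separate cells there is no
direct pairing between a cell's transcriptome and its chromatin. In tissues
organized along spatial axes — a differentiation wavefront sweeping across an
epithelium, or concentric rings of a developing appendage — pseudotime
recovered from either modality is a proxy for the *same* spatial axis. This
package exploits that: both modalities are projected onto a shared virtual 2D
template, and the resulting virtual cells, each carrying one expression profile
and one accessibility profile, support analyses that need both layers at once,
most importantly enhancer-to-gene link inference.

## The mapping model

A *virtual template* is a set of labeled pixels (virtual cells) drawn from a
schematic of the tissue. For every spatially restricted cell type a *landmark*
defines the spatial axis: either a vertical reference line (distance taken
along x, appropriate for a wavefront) or a reference point (radial distance,
appropriate for rings). Real cells of each type are ordered by diffusion
pseudotime on their embedding; virtual cells of the same type are ordered by
landmark distance. Both orderings are cut into the same number of equal-count
bins (10 by default), and each virtual cell receives one real profile sampled
from the matching bin — without replacement when real cells are plentiful, with
guaranteed full coverage of the real pool when they are not. Non-spatial cell
types (e.g. glia, hemocytes) are matched type-wide without binning. Profiles
are copied, never averaged or interpolated, so any statistic of the source
cells is preserved exactly.

Assumptions worth keeping in mind: each cell type is a *single* 1-D trajectory
(no branching within a type); pseudotime orientation is biological knowledge
supplied by the user through the landmark's `direction` field (automatic
orientation is deliberately refused); and equal-count binning assumes cells are
sampled roughly evenly along the axis.

### Diffusion pseudotime

The package delegates nothing here: pseudotime is computed from a k-nearest-
neighbour graph (Euclidean distances on the embedding), a Gaussian kernel with
per-cell local scaling (`sigma_i` = distance to the `ceiling(k/2)`-th
neighbour), symmetrization by union, anisotropic normalization (removing
sampling-density effects), and an eigendecomposition; pseudotime is the
distance from the root cell in the space of the top diffusion components
weighted by `lambda/(1-lambda)`. A user-supplied pseudotime vector can replace
this routine everywhere. Input rows are canonicalized by cell id first, so the
result is invariant to input order; a disconnected neighbour graph is an error
that reports the component sizes rather than silently producing two
incomparable orderings.

## Topic-model accessibility and gene activity

Chromatin accessibility arrives as a topic decomposition: a region-topic
matrix (each topic a probability distribution over regions — a set of
co-accessible regions) and a topic-cell matrix (each cell a distribution over
topics). Their product is the region-cell predictive distribution — the
probability of each region in each cell — which doubles as dropout imputation.
Topics are binarized by keeping each topic's top-probability regions: a region
is kept while the cumulative probability of higher-ranked regions is below
`1 - threshold` (default threshold 0.985, i.e. the top 1.5% of probability
mass). We chose this tail rule because it is deterministic, monotone (raising
the threshold never adds a region, and threshold 1 selects nothing) and
reproduces the intent of distribution-fitting binarizers without their fitted
internals.

Gene activity scores aggregate region-cell probabilities over the regions
around each gene: the 5 kb window upstream of every TSS (upstream in the
biological sense — the window ends at the TSS on the `+` strand and starts at
it on the `-` strand) plus introns. Any 1 bp overlap counts; a region is
counted once per gene. For multi-TSS genes the *activity* aggregation uses the
union of windows over all TSSs, whereas the *link search space* (below)
samples a single TSS — aggregation is a proxy where more coverage helps, while
the search space mimics a single randomly chosen promoter context.

## Enhancer-to-gene links

For each gene, candidate regions are those within ±50 kb of its TSS (one TSS
sampled, seeded, for multi-TSS genes) plus intronic regions at any distance.
Two complementary statistics are computed across virtual cells:

* the Pearson correlation between region accessibility probability and gene
  expression, filtered at the 1st/99th percentiles of a normal distribution
  fitted by maximum likelihood to *all* candidate correlations (correlations
  from constant vectors are reported as 0 and excluded from the fit so they
  cannot distort the null);
* the importance of each region in a 1,000-tree random-forest regression of
  expression on candidate accessibility (variance-reduction splits,
  `ceiling(sqrt(p))` candidate predictors per split, importances normalized to
  sum to 1 per gene), with the top regions per gene selected by binarizing the
  importances at their strongest discontinuity.

A pair is kept if *either* filter retains it; the `kept_by` column records the
provenance so either stricter rule can be applied post hoc. We chose the union
because the combined-filter totals are what the procedure is designed to
produce and the intersection can be recovered from the provenance, while the
reverse is not true. The link sign is the sign of the correlation; negative
links (regions accessible where the gene is silent) are reported but are
expected to be noisier in sparse single-cell data, where absence of signal may
be dropout. Redundant ("shadow") enhancers are summarized as pairs of linked
regions whose accessibility profiles correlate above 0.8.

### Step-function (BASC-style) binarization

The importance binarizer sorts the values, computes for every number of jumps
`d = 1..n-2` the optimal (least-squares) step function by dynamic programming,
locates in each the strongest discontinuity (largest jump between adjacent
block means, ties to the lower position), takes the lower median of these
locations across all step functions, and thresholds at the midpoint of that
jump. Values strictly above the threshold are selected, so the selection is
never empty; all-equal inputs are a refused degenerate case. On two-cluster
inputs whose gap dominates the within-cluster spread the threshold provably
lands in the gap, which the tests verify against exhaustive split enumeration.

## Enhancer specificity

Broad enhancer-reporter constructs are represented as intervals whose
accessibility is the summed region-cell probability of their member regions.
Specificity is the gini index of that vector across virtual cells, in the
population form `G = sum|x_i - x_j| / (2 n^2 mean)` (computed via the
equivalent sorted form): 0 for uniform accessibility, `(n-1)/n` for
accessibility confined to one cell. We use the population denominator `n^2`
(not `n(n-1)`) so that the uniform vector scores exactly 0 and the one-hot
maximum is `(n-1)/n`; both identities are asserted in the tests. Enhancers
with gini below 0.2 are "general", above 0.4 "specific". Agreement between
accessibility and binary reporter activity is a Spearman correlation with
midranks (binary vectors are almost all ties); constant vectors are flagged
rather than given an arbitrary value. The generated tissue plants both
*coupled* enhancers (accessibility tracks activity) and *primed* ones
(ubiquitously accessible, locally active), and the tests require coupled
enhancers to outscore primed ones in rank correlation.

## caQTLs and motif effects

Across an inbred panel, each SNP inside an accessible region is coded 0/1/NA
(homozygous reference / homozygous alternate / heterozygous-or-missing — the
panel is assumed homozygous, so heterozygous calls are treated as unknown).
Counts are CPM-normalized per line (the minimal depth correction; log1p is an
optional flag), and each SNP-region pair is tested by ordinary least squares —
the default Gaussian GLM — with a two-sided Wald test on the genotype slope
and BH adjustment across all tested pairs; calls at FDR < 0.05 are caQTLs,
classified as opening or closing by the slope sign. Pairs with fewer than 10
informative lines or fewer than 3 lines in either genotype class are skipped:
slopes estimated from one or two lines are meaningless.

For motif consequences, each caQTL region yields an "open" and a "closed"
allele sequence (the allele associated with higher accessibility is the open
one). Every motif is scored by its best log2-odds hit over all windows and
both strands — for a single motif this best hit dominates cluster-style CRM
scores, which is why the scanner deliberately implements the single-hit
maximum; windows containing ambiguous bases are excluded. The delta score is
open minus closed. Motifs with `|delta| > 3` significantly more often among
caQTLs than among control SNPs (no-effect SNPs in accessible regions, sampled
at GLM FDR > 0.95) are reported by a one-sided Fisher exact test ("more
affected" is a directional question, hence one-sided) with BH adjustment, plus
a cumulative delta per motif. The per-topic variant restricts caQTLs and
controls to regions in each topic's binarized set.

## What the synthetic generators emulate — and what they do not

`make_tissue()` generates the full mapping/linking input: a fixed 100×100
template (two wedge compartments on an axis landmark, two ring compartments on
a radial landmark), 500 real cells per type and modality with uniform latent
positions, 40 genes with sigmoid or Gaussian-bump axis profiles, one planted
positive or negative link per gene among 10 decoys, primed and coupled
enhancer regions, Gaussian noise (sd 0.1), dropout (10%), and a topic model
built explicitly as a product of column-stochastic factors (one topic per cell
type × axis segment with triangular weights, a partition of unity on the
axis), so the predictive distribution reproduces the intended region-cell
probabilities exactly. `make_caqtl_panel()` generates a 50-line panel with 360
one-SNP regions: 40 consensus-disrupting caQTLs confined to one topic, 20
motif-free caQTLs, 300 null SNPs, one causal motif among 50 decoys, and
Poisson counts with line-specific depths.

What passing these tests shows: the estimators recover planted structure at
realistic noise, the filters are calibrated on nulls, and every stochastic
stage is reproducible. What they do not show: robustness to doublets, batch
effects, branching trajectories, uneven sampling along the axis, linkage
disequilibrium between SNPs, or real motif redundancy — none of which the
generators emulate. Counts from a real template drawing (numbers of pixels per
compartment) are properties of the drawing, not of the method.

## Numerical choices and degenerate inputs

* Ties in distance or pseudotime binning are broken by a stable sort on cell
  id; bin sizes within a type differ by at most one.
* When a bin holds fewer real than virtual cells, each real cell is used
  `floor` or `ceiling` of the ratio times — every profile is used at least
  once — and the placement is a random permutation; empty bins fall back to
  the whole-type pool with a loud warning.
* All sampling draws from a single RNG stream in lexicographic (cell type,
  bin) order, so one seed fixes the whole mapping; per-stage seeds are derived
  from the global seed by hashing the stage name (`derive_seed()`).
* Forests are fitted on predictors sorted by region id and virtual cells
  sorted by id, making results independent of input order.
* Pearson correlations of constant vectors are 0 with a flag; Spearman of a
  constant vector is flagged NA; the gini of an all-zero vector and the
  binarization of an all-equal vector are errors, not silent defaults.
* All internal coordinates are 0-based half-open; VCF positions are converted
  on read. PWM count rows get a pseudocount of 1 per cell and a uniform
  background unless one is supplied.

## Problem sizes used by the test suite

The packaged checks run the default tissue (4 types × 500 cells, 440
candidate pairs, 10 bins), a 10^5-draw threshold fit, 10^4 null association
pairs plus 200 planted effects over 50 lines, 100 scanner-oracle cases up to
200 bp, 500 two-cluster binarization instances, and 100 seeded panel
simulations for the enrichment recovery; the acceptance script repeats the
same computations (20 panel simulations) and writes the resulting quantities
as JSON.

## Known limitations

One real profile per virtual cell means local averaging must be done by the
user if wanted; each cell type is mapped independently, so cross-type
continuity of the axis is not enforced; the association scan is marginal
(one SNP at a time) with no covariates or population structure correction;
and the motif scanner scores single best hits, not homotypic clusters.
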