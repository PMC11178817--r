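---
title: "Methods: hierarchical atlas queries for expression and connectivity data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical atlas queries for expression and connectivity data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atlasfuse)
```

## The integration model

Heterogeneous brain datasets — single-cell and bulk RNA-seq count matrices,
microarray biopsies, voxel-level expression images, tracer-derived structural
connectivity, grayordinate functional connectivity — can only be compared
after they are placed in one coordinate system. `atlasfuse` uses a voxel
reference space (a 3D grid with a physical voxel size) plus a hierarchical
brain-region ontology bound to that grid by a label volume (the
parcellation). Imaging data live directly on the grid; sample-based data are
attached to ontology regions and inherit, through the parcellation, a voxel
footprint. Anything mapped this way can then be queried at any anatomical
level: a region query expands to the union of its descendants' voxels, and a
hand-drawn "brush" mask is treated identically.

Two conventions are fixed package-wide and worth stating precisely:

* Voxel indices are 0-based, the first axis is fastest when linearized, and
  the physical center of voxel $(x, y, z)$ is at
  $\mathrm{origin} + (\mathrm{index} + 0.5) \cdot \mathrm{voxelsize}$.
  Center-based coordinates make nearest-neighbor resampling unambiguous.
* Label 0 is reserved for outside-brain and is never a region id.

Nearest-neighbor resampling between grids factorizes per axis because both
grids are axis-aligned; equidistant ties go to the lower source index (hence
the lowest linearized source index), so resampled volumes are deterministic.

## Sample selection and the four queries

A query is built from three sample subsets of a dataset with expression
matrix $m_{g,s}$ (genes $g \in G$, samples $s \in S$):

* $V$ — samples in the volume of interest. A region-annotated sample is in
  $V$ when its annotation region's voxel set intersects the VOI (unweighted:
  any overlap counts). A voxel-backed sample (one sample per voxel) is in
  $V$ when its voxel is in the VOI.
* $C$ — samples of the chosen cell type(s).
* $F$ — samples passing all remaining metadata filters.

The four per-gene scores are means and ratios of means:

$$\mathrm{mean}(g) = \frac{1}{|V \cap C \cap F|} \sum_{s \in V \cap C \cap F} m_{g,s}$$

$$\mathrm{regionspecificity}(g) =
  \frac{\mathrm{mean}_{V \cap C \cap F}(g)}{\mathrm{mean}_{C \cap F}(g)},
\qquad
\mathrm{celltypespecificity}(g) =
  \frac{\mathrm{mean}_{V \cap C \cap F}(g)}{\mathrm{mean}_{V \cap F}(g)},
\qquad
\mathrm{enrichment}(g) =
  \frac{\mathrm{mean}_{V \cap C \cap F}(g)}{\mathrm{mean}_{V}(g)}.$$

The region-specificity denominator is the mean over $C \cap F$ — the whole
brain including the VOI, not its complement. That is the exact form of the
statistic this package implements; describing it as "versus the rest of the
brain" is an approximation that holds when the VOI is small.

Design choices in this layer:

* Unweighted VOI membership makes the hierarchy exact: any VOI whose voxels
  are a nonempty subset of an annotation region's voxels selects the same
  samples — and therefore returns identical scores — as the region itself.
  This invariance is tested exactly, not to a tolerance. Weighting samples
  by fractional voxel overlap would break it and is deliberately not done.
* A zero denominator yields an *undefined* score (excluded from ranking),
  never 0 or Inf; an empty selection yields an empty result object with a
  warning, never NaN propagation.
* Queries compute on whatever normalization state the dataset carries
  (log-CPM, TPM, sigmoid-unit, ...); the query layer never re-normalizes.
* Ranks are descending (rank 1 = highest), ties get the average rank.
  Ranks are the batch-robust way to compare across datasets whose absolute
  values are not comparable.

## Preprocessing defaults

The ingest functions implement the standard normalization ladder for each
data kind, with these parameter choices:

* **QC** (`qc_filter_cells`): retain samples with 50–5000 unique genes
  detected, then drop samples whose unique-gene count deviates from the
  median by more than 5 times the median absolute deviation. The MAD is
  unscaled (no 1.4826 normal-consistency factor): the rule is a plain
  robust-deviation cut, and the multiplier 5 is generous enough that the
  scaling constant makes no practical difference. The range filter runs
  first; the MAD statistics are computed on what survives it.
* **CPM / RPKM→TPM**: per-sample rescale to a total of $10^6$. For RPKM
  input, gene-length normalization is already present, so the conversion to
  TPM is the same per-column rescale.
* **log2(x+1)**: applied after CPM/TPM, offset 1 to accommodate zeros.
* **Scaled robust sigmoid** (microarray): per-gene
  $y = 1/(1 + \exp(-(x - \mathrm{median})/(\mathrm{IQR}/1.349)))$, then
  min-max rescaled to $[0, 1]$. IQR/1.349 is the normal-consistent robust
  spread. A zero IQR yields constant 0 with a warning rather than an error,
  since constant probes are uninformative but not malformed.
* **Gene matching**: symbol, then Ensembl, then Entrez; first hit wins.
  Duplicate canonical genes collapse to the row with the largest total
  count — deterministic, and avoids double-counting reads in CPM. Unmatched
  genes are dropped (and counted in the report) rather than kept unmapped.

## Connectome assembly

A structural connectome is assembled from injection records (site, injection
volume, target image). Every voxel covered by at least one injection volume
becomes a source row; voxels covered by several records take the per-target
**maximum** across the covering images. To compensate hemispheric injection
imbalance, records can be mirrored about the mid-plane of a configurable
axis (index $\mapsto$ shape$-1-$index; default axis 1, since template axis
conventions differ between atlases), which exactly doubles the effective
injection-site count. Finally, weights strictly below $10^{-4.5}$ are zeroed
to suppress false-positive projections; a weight exactly at the threshold
survives. Thresholding is idempotent, and no assembled weight can lie in
$(0, 10^{-4.5})$.

VOI-level aggregation takes the arithmetic **mean** over the VOI's covered
source voxels (sources without data are excluded from the mean, not counted
as zero). The mean matches the group-average framing of the input data and
is linear in the weights; a max statistic is available behind a flag for
"strongest single source" questions. The strongest-targets cutoff (`k` or a
top fraction) is a free parameter of the exploration, not a fixed constant;
ties at the cutoff are broken by Morton key order for determinism.
Grayordinate connectomes are brought to voxel space by assigning every voxel
the nearest grayordinate coordinate (Euclidean distance between the voxel
center and the grayordinate position, ties to the lowest grayordinate
index).

## Spatial indexing

Rows/columns of connectivity matrices, per-voxel image stacks, and located
samples are ordered along a Morton z-order curve: the key interleaves the
coordinate bits (x least significant), so spatially close voxels get close
keys and a VOI decomposes into few contiguous key ranges. Morton order was
chosen over alternatives (e.g. Hilbert) because the key is a pure bit
interleave — trivially correct, cheap, and with locality adequate for
block-wise retrieval. Grids are conceptually padded to the next power of
two; the sort is stable on ties so the permutation is deterministic.
`range_query` fetches exactly the VOI's items as contiguous slices of the
key-sorted order and is tested for multiset equality with a naive full scan.

Pre-aggregation stores per (metadata group × annotation region) the
per-gene mean and sample count. Any mean-expression query whose filters
align with the grouping attributes is then a count-weighted average of group
means — algebraically identical to the raw per-sample mean, and tested to
agree within 1e-9 relative. A filter on an attribute outside the grouping
keys makes the aggregate path return `NULL` so callers fall back to the raw
path: correctness over speed.

## Cross-species statistics

Regional expression (the queries-module output: mean expression, or
cell-type specificity when the question is cell-type-specific contrast) is
correlated per gene against a region-level connectivity profile using
Spearman's rank correlation with average ranks on ties. Spearman is forced
by the data: absolute expression is not comparable across platforms, ranks
are. Per-gene p-values are deliberately not computed — the workflow selects
genes by coefficient quantile (top/bottom 1%, `ceiling(q n)` genes, ties at
the cutoff broken by gene id), not by significance. Cross-species overlap
maps one species' extreme sets through a homolog table into the other's.
Distribution shifts between cell types use the two-sample
Kolmogorov–Smirnov test; directionality of homolog coefficients uses a
one-sample t-test against zero. Inter-dataset concordance computes Spearman
correlations between per-cell-type mean expression vectors over shared
genes and compares matched vs unmatched cell-type pairs with a one-sided
Wilcoxon rank-sum test.

## What the synthetic fixtures emulate — and what they do not

The generator (`make_toy_atlas`, `make_expression_dataset`,
`make_connectome_records`, `make_species_pair`) produces the full input
stack with known ground truth, deterministically per seed:

* balanced ontologies whose leaves tile the grid as contiguous blocks;
* count matrices with lognormal noise (sd 0.5 on the log scale, a typical
  overdispersion level for aggregated counts) and multiplicative planted
  fold-changes for (gene, cell type) or (gene, region) pairs — lognormal
  rather than Poisson/negative-binomial because fold-change recovery is
  then controlled analytically; counts are rounded half-even;
* injection records whose background noise is drawn strictly below the
  $10^{-4.5}$ threshold, so assembly of a planted projection is exactly the
  planted signal;
* two-species bundles sharing 10 consensus regions (the cross-species
  analysis scale), 500 genes, 2 cell types, and 20 samples per
  (region × cell type). Non-planted genes receive a latent
  expression–connectivity correlation drawn from $N(0, 0.1)$ for excitatory
  and $N(-0.3, 0.1)$ for inhibitory cells — the shift magnitude at which a
  two-sample KS test on ~500 coefficients per group rejects essentially
  always at $p \le 10^{-4}$. Planted conserved correlates are built exactly
  monotone (Spearman $\pm 1$) against connectivity profiles whose values
  are spaced by 0.2, far above the region-mean noise
  ($0.1/\sqrt{20} \approx 0.022$), so their recovery is near-certain rather
  than probabilistic.

What the fixtures do **not** emulate: scRNA-seq dropout and library-size
gradients, batch effects, anatomical realism of region shapes, partial
overlap of injection volumes with region borders, and inter-dataset
technical biases. Passing tests on these fixtures therefore demonstrates
the correctness of the mapping, query, assembly, indexing and statistical
machinery — not that real datasets meet the model assumptions.

The cross-species acceptance run feeds the **mean-expression** query into
the correlations: the generator plants its ground truth in mean expression,
so that is the path with a known answer. The cell-type-specificity input
(used when contrast between cell types is the point) is exercised separately
through the planted-marker recovery check, where an 8× marker in a cell type
must reach the top 1% of specificity ranks.

## Numerical and degenerate-input choices

* Empty VOIs, empty selections, empty homolog maps: warning + typed empty
  result, never an error, never NaN.
* Resampling requires overlapping physical extents; ties at equidistant
  centers and Morton-key ties are all resolved toward the lower index.
* Problem sizes in the test and acceptance runs — $4^3$/$8^3$ grids,
  100–500 genes, up to 500 samples per group, 100-seed replicate loops —
  were chosen so each statistical check has enough replicates for a stable
  rate while the whole suite stays interactive on a laptop-class single
  core.
* All RNG flows through a single seed argument; sub-seeds are small integer
  offsets so runs are reproducible across platforms with R's default RNG.

## Known limitations

* Partial-volume voxels at region borders are treated as exact labels.
* Dense in-memory connectome storage: fixture scale, not the ~90 GB scale
  of production voxel connectomes (whose on-disk chunked layout is what the
  Morton ordering is designed for).
* On-disk interchange is plain text (TSV/CSV/NIfTI/JSON); no chunked binary
  store is bundled.
* `region_specificity` uses the whole-brain denominator (see
  above); a complement-of-VOI variant would differ for large VOIs.
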