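# atlasfuse

Joint analysis of brain gene expression and connectivity requires putting
very different datasets — single-cell and bulk RNA-seq count matrices,
microarray biopsies, voxel-level expression images, tracer-derived
structural connectomes, resting-state functional connectomes — into one
coordinate system. `atlasfuse` does that with a voxel reference space plus a
hierarchical brain-region ontology bound to the grid by a label volume, and
then lets you query the fused data at any anatomical level: a named region,
any of its subregions, or a hand-drawn voxel mask (a VOI, volume of
interest). It is aimed at computational neuroscientists and bioinformaticians
who need reproducible, scriptable versions of the aggregation steps that
atlas browsers perform interactively.

## What it computes

For a dataset with expression matrix *m<sub>g,s</sub>* and sample subsets
*V* (in the VOI), *C* (chosen cell types) and *F* (metadata filters), the
four VOI queries are:

* **mean expression**   mean of *m<sub>g,s</sub>* over *V ∩ C ∩ F*
* **region specificity**   mean over *V ∩ C ∩ F* / mean over *C ∩ F*
* **cell-type specificity**  mean over *V ∩ C ∩ F* / mean over *V ∩ F*
* **enrichment**     mean over *V ∩ C ∩ F* / mean over *V*

plus descending gene ranks (average ties; undefined ratios are excluded,
not coerced). Around the queries the package provides:

* ingest: QC filtering (50–5000 unique genes, 5×MAD outlier rule), CPM,
  RPKM→TPM, log2(x+1), scaled robust sigmoid, gene matching
  (symbol > Ensembl > Entrez), region annotation;
* connectome assembly from injection records (per-target max-combine,
  optional hemisphere mirroring, 10^−4.5 thresholding), grayordinate→voxel
  mapping, VOI aggregation, strongest-targets selection, region profiles;
* Morton z-order spatial indexing with block-range retrieval and metadata
  pre-aggregation;
* cross-species statistics: per-gene Spearman correlation of regional
  expression with connectivity profiles, top/bottom-1% extreme sets,
  homolog-mapped overlap, Kolmogorov–Smirnov shift tests, one-sample
  t-tests, inter-dataset rank concordance;
* a deterministic synthetic-fixture generator with planted ground truth
  (markers, projections, conserved cross-species correlates).

## Worked example

Plant an 8× inhibitory-cell marker in a synthetic dataset and recover it
with the cell-type specificity query:

```r
library(atlasfuse)

atlas  <- make_toy_atlas(shape = c(4, 4, 4), depth = 2, fanout = 2)
marker <- data.frame(gene = 1, kind = "cell_type", group = "inhibitory", fold = 8)
ds     <- make_expression_dataset(atlas, seed = 1, n_genes = 5,
                                  markers = marker, n_per_group = 100)
ds
#> <expression_dataset 'synthetic'> 5 genes x 400 samples [raw]

voi <- region_voxels(atlas$parc, atlas$ont, 1)      # whole-brain VOI
sel <- select_samples(ds, voi, atlas$parc, atlas$ont,
                      cell_types = "inhibitory")
sel
#> <sample_selection> |V|=400 |C|=200 |F|=400 |V&C&F|=200

res <- gene_ranks(cell_type_specificity(ds, sel))
res[order(res$rank), ]
#>    gene score rank
#> g1   g1 1.773    1
#> g2   g2 1.067    2
#> g3   g3 1.040    3
#> g4   g4 0.979    4
#> g5   g5 0.974    5
```

The planted marker ranks first with specificity ≈ 1.77: with two equally
sized cell-type groups an 8× fold gives 8·2/(8+1) ≈ 1.78, and the remaining
genes sit at ≈ 1 (no cell-type contrast). `write_query_result()` exports any
result as a TSV with a self-describing header (dataset, query type, VOI,
filters, seed, config hash).

A command-line wrapper is installed as `exec/atlasfuse` with subcommands
`synth`, `query`, `coverage`, `connectome` and `xspecies`; see
`?run_cli`.

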