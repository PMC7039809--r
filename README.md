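# rscope

Regulon activity and specificity analysis for single-cell RNA-seq.

`rscope` is an R package for analysts who want to go from a droplet
UMI count matrix to an interpretable map of **which transcription-factor
programs (regulons) drive which cell clusters**. It grew out of the
analysis style used to dissect intestinal mononuclear phagocyte
populations under different microbial colonization states (e.g. specific
pathogen-free vs germ-free mice), but every stage is generic: any
genes-by-cells count matrix with optional per-cell condition labels and
any collection of gene sets will do.

The package covers, as tested and configurable components:

* **Expression pipeline** — QC filtering (200–2,500 genes/cell, genes in
  ≥ 3 cells), log-normalization to 10,000 counts/cell, binned-dispersion
  variable-gene selection (mean window 0.0125–3, z ≥ 0.5), nUMI
  regression, PCA (11 PCs), and shared-nearest-neighbor Louvain
  clustering (resolution 1.2).
* **Markers & composition** — Wilcoxon rank-sum cluster markers and
  condition-wise differential expression; per-cluster condition
  composition with sequencing-depth-normalized shares.
* **Regulon activity (RAS)** — per-cell recovery-curve AUC scoring of
  gene sets over the top 5% of each cell's gene ranking,

  RAS = Σₓ rc(x) / Σₓ min(x, m),  x = 1..T,  T = ⌈0.05·n_genes⌉,

  normalized to [0, 1] by the maximal achievable curve; Avg20 metacell
  pooling (mean profiles of 20 random same-cluster cells) and per-regulon
  activity z-scores (AUCZ).
* **Regulon specificity (RSS/RSSZ)** — RSS = 1 − √JSD(P, Q) between a
  regulon's normalized activity distribution over cells (P) and a
  cluster's indicator distribution (Q), base-2 logs; RSSZ z-scores RSS
  across regulons within each cluster. Pairs with mean RAS > 0.2 and
  RSSZ > 1.0 are flagged cluster-specific.
* **Regulon modules (CSI)** — connection specificity index of every
  regulon pair (fraction of other regulons whose correlations with both
  members fall below the pair's own correlation minus 0.05), hierarchical
  module/sub-module detection, and Sankey-ready cluster-to-module
  connectivity tables (cells with module-level AUCZ > 2.0).
* **Synthetic data** — a negative-binomial generator with planted
  clusters, per-cluster regulon programs, correlated regulon modules, and
  condition-composition shifts, emitting full ground truth so the entire
  pipeline is verifiable without any external download.

## Worked example

Simulate the default verification scenario (5 clusters × 400 cells,
2,000 genes, 20 regulons in 3 modules) and run the full pipeline:

```r
library(rscope)

design <- simulation_design(seed = 1)
sim <- simulate_counts(design)
sim$counts
#> sc_counts: 2000 genes x 2000 cells
#> conditions: SPF=1039, GF=961

res <- run_pipeline(sim$counts, sim$regulons, default_config(seed = 1))

table(predicted = res$clusters, truth = sim$truth$cluster[names(res$clusters)])
#>          truth
#> predicted   0   1   2   3   4
#>         0 400   0   0   0   0
#>         1   0 400   0   0   0
#>         2   0   0 400   0   0
#>         3   0   0   0 400   0
#>         4   0   0   0   0 400
```

Every planted cluster is recovered exactly. The specificity table flags
the regulons driving each cluster (strict RAS > 0.2 & RSSZ > 1.0):

```r
head(subset(res$specificity, significant), 5)
#>   regulon cluster   rss rssz mean_ras
#> 4  R04(+)       0 0.591 1.44    0.322
#> 2  R02(+)       0 0.586 1.42    0.254
#> 3  R03(+)       0 0.582 1.40    0.249
#> 6  R06(+)       0 0.576 1.38    0.254
#> 5  R05(+)       0 0.570 1.36    0.301
```

`rss` is the Jensen–Shannon specificity (1 = all activity inside the
cluster), `rssz` its per-cluster z-score across regulons, and `mean_ras`
the mean recovery-curve activity over the cluster's Avg20 metacells.
CSI-based module detection groups the regulons into their planted
modules, and the connectivity table links each module to the cluster it
is active in:

```r
subset(res$connectivity, count > 0)
#>    cluster module count fraction
#> 1        0      1   125        1
#> 7        1      2   131        1
#> 13       2      3   142        1
```

i.e. 125 cells of cluster 0 exceed the AUCZ 2.0 cutoff for module 1 —
and no cell anywhere links a cluster to a module that is not planted
there.

Real data enter through `read_counts()` (Matrix Market + sidecars, or
dense TSV; a `transpose` flag accepts cells-as-rows matrices) and
`read_regulons()` (GMT). All thresholds live in `default_config()` /
`read_config()` (flat YAML).

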