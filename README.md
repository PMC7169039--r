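# scatacpipe

Processing, quality control and clustering of single-cell ATAC-seq
(scATAC-seq) fragment files, for analysts who receive a deduplicated
fragment table — one row per unique `(chrom, start, end, barcode)` with a
duplicate count — and need everything downstream of alignment: per-barcode
QC, cell calling, peak calling, a peak-by-cell count matrix, normalization,
dimension reduction, clustering, differential accessibility, TF motif
deviation scores and genome tracks, plus the simulation framework used to
benchmark it all.

## What is inside

* **Quality control** — FRiP (fraction of fragments in peaks),
  annotation-class fractions, insert-size distribution, TSS enrichment
  (±2 kb window, flank-normalized, 51-bp smoothed score), library
  complexity by Lander–Waterman inversion `U = C(1 − e^{−N/C})`, and
  aggregate library statistics.
* **Cell calling** — default filter (`unique fragments > 5000` and
  `FRiP > 0.5`, strictly), a two-component zero-inflated negative binomial
  mixture fit by EM with posterior-probability calls, and a knee-point
  detector on the log-log barcode rank curve.
* **Peak calling** — a sliding-window Poisson caller (200-bp windows,
  100-bp step, local ±10-kb lambda, Benjamini–Hochberg FDR) and the
  combined two-step strategy: prefilter barcodes (≥ 1000 fragments),
  cluster on 5-kb bin counts, call peaks per cluster, merge peaks closer
  than 200 bp, remove blacklisted regions — so peaks private to rare
  populations survive.
* **Normalization & clustering** — TF-IDF (binarized;
  `IDF = log(1 + n/(1 + df))`) or log-transform with per-peak depth
  regression; PCA (30 components) followed by per-component depth
  regression — the fast equivalent of regressing every feature first;
  shared-nearest-neighbour graph (k = 20, Jaccard weights, prune 1/15) and
  Louvain clustering (resolution 0.8), all seeded and reproducible.
* **Downstream** — Wilcoxon differential accessibility with BH correction,
  chromVAR-style motif deviation z-scores on the top 30% most variable
  peaks against GC/accessibility-matched backgrounds, per-cluster enriched
  TFs, and RPKM bedGraph tracks per cluster.
* **Simulators** — a binomial noise model
  (`count ~ Binom(2, (1−q)·n·r_i/2 + q·n/(2k))`, `q` = noise level), bulk
  subsampling (10,000 reads per cell without replacement, 13 types),
  Dirichlet cell-type compositions (α = 3), a full fragment-level dataset
  generator with ground truth, and the adjusted Rand index for scoring.

## Worked example

```r
library(scatacpipe)

# a synthetic experiment with known truth: 3 cell types x 200 cells,
# 300 true peaks, 500 ambient barcodes
ds <- generate_dataset(seed = 1)
frags <- filter_fragments(ds$fragments, min_mapq = 30)

peaks <- call_peaks_combined(filter_fragments(frags, exclude_chroms = "chrM"),
                             ds$chrom_sizes, seed = 1)
length(peaks)
#> [1] 300

qc <- per_barcode_qc(frags, peaks)
qc <- call_cells_filter(qc)                      # > 5000 frags & FRiP > 0.5
sum(qc$is_cell)
#> [1] 527

m  <- count_features(frags, peaks, barcodes = qc$barcode[qc$is_cell])
cl <- cluster_counts(m, seed = 1)                # TF-IDF -> PCA -> SNN -> Louvain
table(cl$labels)
#>   0   1   2
#> 180 179 168

truth <- ds$labels[names(cl$labels)]$type
adjusted_rand_index(truth, cl$labels)
#> [1] 0.955
```

The 527 called cells are the barcodes that clear both thresholds; the three
clusters recover the three simulated cell types with an adjusted Rand index
of 0.96 against the ground-truth labels.

The same pipeline runs from the shell, stage by stage or end to end:

```sh
Rscript inst/cli/scatacpipe.R --step all --output_dir ./output
Rscript inst/cli/scatacpipe.R --step qc --input fragments.tsv --config configure.txt
```

Each stage writes its outputs plus a provenance JSON under
`output_dir/<step>/`, and `--step report` assembles a machine-readable
summary (JSON) and an HTML rendering of whatever stages have run.

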