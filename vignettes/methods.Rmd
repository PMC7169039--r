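---
title: "Models and methods behind scatacpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scatacpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

scatacpipe processes single-cell chromatin accessibility (scATAC-seq)
experiments starting from a deduplicated fragment file — one row per unique
(chromosome, start, end, barcode) with the number of collapsed read pairs —
through quality control, cell calling, peak calling, count-matrix
construction, normalization, dimension reduction, clustering and downstream
differential/motif analyses. This vignette explains each model, the
parameters that matter, and the choices made where the design was open.

## Coordinate conventions

Fragment files and BED annotations use 0-based half-open coordinates, as on
disk; interval length is always `end - start`. Internally intervals live in
`GRanges` (1-based closed) and the conversion happens exactly once in each
reader/writer, so every overlap query uses the same ≥ 1 bp overlap rule.
Input fragment coordinates are used as-is: if the upstream aligner already
applied a Tn5 +4/−5 shift the package neither repeats nor undoes it.

## Per-barcode quality metrics

For each barcode we compute the duplicate-weighted read total, the unique
fragment count, the fraction of fragments in peaks (FRiP), the
mitochondrial fraction, and the fraction overlapping any user-supplied
annotation class (promoters, enhancers, TSS). A fragment counts toward a
class when it overlaps any interval of the class by at least one base and
at most once per class, so FRiP numerators can never exceed the fragment
count.

**TSS enrichment.** Both fragment ends are insertion events. Insertions are
profiled over ±2000 bp around each TSS (minus-strand sites mirrored), the
profile is divided by the mean over the outermost 100 bp on each side, and
the score is the maximum of a 51-bp moving average of the normalized
profile. Window, flank and smoothing width are conventional values and are
exposed as arguments; a profile whose flanks received no insertions has no
defined background and yields an `NA` score rather than a number.

**Library complexity.** The number of distinct molecules `C` is estimated
from total reads `N` and unique fragments `U` by inverting the
Lander–Waterman relation `U = C(1 − exp(−N/C))` with bisection to a relative
tolerance of 1e−6. `U = N` (no observed duplication) leaves `C` unbounded
and returns `NA`. The estimate is monotone in `N` and never below `U`.

## Cell calling

The default rule is the transparent filter: a barcode is a cell when its
unique-fragment count is **greater than 5000** and its FRiP is **greater
than 0.5** — both strictly, so a barcode sitting exactly on a threshold is
not a cell. Optional thresholds on mitochondrial, promoter, enhancer and
TSS fractions tighten the rule; raising any threshold can only remove
cells.

The model-based alternative fits a two-component zero-inflated negative
binomial (ZINB) mixture to per-barcode in-peak counts by EM, with latent
component labels and structural-zero indicators. The NB components use the
mean/dispersion parameterization; means update as weighted averages and the
dispersion maximizes the weighted profile likelihood within each M-step, so
the observed log-likelihood is non-decreasing. Initialization is 2-means on
`log1p` counts; components are relabeled so the cell mean is the larger
one, making the output invariant to initialization. Convergence is a
relative log-likelihood change below 1e−6 (at most 500 iterations), and a
non-converged fit refuses to call cells. Barcodes with posterior cell
probability ≥ 0.99 are called; the conservative cutoff is a package default
and configurable. Degenerate inputs (all zeros, a single distinct value)
abort with a pointer to the filter strategy.

The knee-point detector sorts counts decreasingly and returns the count at
the maximum perpendicular distance between the log10(rank)–log10(count)
curve and the chord joining its endpoints; constant curves have no knee and
return `NA`.

## Peak calling

The internal caller scores 200-bp windows stepped every 100 bp by their
fragment-overlap count against a Poisson null. Because a fragment of width
`f` overlaps a `w`-bp window whenever its start falls in a `(w + f − 1)`-bp
interval, the null rate is the per-bp fragment-start rate times this
effective width; the rate is the larger of the genome-wide rate and the
local rate in a ±10-kb neighbourhood, which protects against broad
enrichment artefacts. Window p-values are Benjamini–Hochberg adjusted;
windows with `q < 0.05` and at least 5 fragments are kept and merged when
overlapping or touching. Each peak reports the maximum-coverage base as its
summit and its best constituent q-value.

The **combined strategy** addresses peaks private to rare populations,
which pooled calling dilutes below its own background: barcodes with fewer
than 1000 unique fragments are removed (kept at exactly 1000), the rest are
counted over 5-kb genome bins, clustered (TF-IDF → PCA → SNN → Louvain),
and the caller runs once per cluster. Per-cluster peak sets are pooled,
merged when closer than 200 bp (a gap of exactly 200 bp stays separate),
and only then screened against the blacklist — removing after the merge
guarantees no blacklist-overlapping base survives via a merged neighbour.
Summits are recomputed on pooled coverage, and each peak records the
clusters that contributed it.

## Normalization and dimension reduction

Two normalizations are provided. **TF-IDF** binarizes the matrix, divides
each cell by its accessible-site total and weights each peak by
`log(1 + n_cells / (1 + n_cells_with_peak))`; the smoothed logarithmic IDF
is pinned as the default (a raw-frequency variant is available) and the
result is invariant to count scaling. **Log-regression** takes `log1p`
counts and removes, per peak, an ordinary least-squares fit on log depth,
leaving residuals exactly orthogonal to the depth covariate; constant depth
degrades gracefully to row-centering with a warning.

PCA keeps 30 components by default. Rather than regressing depth out of
every feature and then decomposing — a cost proportional to the number of
peaks — the package decomposes first and regresses log depth out of each of
the 30 components. The two orders produce near-identical clusterings (the
package's tests require an adjusted Rand index of at least 0.8 between
them) at a small fraction of the cost. Features are centered before the
decomposition; component signs are fixed so the largest-magnitude loading
is positive, making coordinates reproducible run to run.

Clustering builds a shared-nearest-neighbour graph (Euclidean k = 20
neighbours including self, Jaccard edge weights, weights below 1/15
pruned) and runs Louvain modularity optimization at resolution 0.8 under a
fixed seed; labels are renumbered by decreasing cluster size. k, pruning
and resolution are conventional defaults, all configurable. The 2-D
embedding used for figures is pluggable; the default is the deterministic
first two components, with UMAP delegated to `uwot` when installed.

## Differential accessibility and motif deviations

Differential accessibility between two disjoint cell groups (each ≥ 3
cells) is a two-sided Wilcoxon rank-sum test per peak on normalized values
with Benjamini–Hochberg correction across peaks; fold changes are
`log2((m1 + ε)/(m2 + ε))` with ε = 1e−9 to tolerate empty means.

Motif deviation scores follow the chromVAR idea with one economy: only the
top 30% most variable peaks (by variance of depth-normalized counts) are
scored, which leaves the z-scores' null behaviour intact while cutting the
cost several-fold. For motif `m` and cell `j`, the observed count over the
motif's peaks is compared with the expectation under the cell's depth and
the peaks' pooled accessibility, `d = (o − E)/E`. The raw deviation is
z-scored against 50 background peak sets matched in standardized
(GC content, mean accessibility) space: background iteration `b` replaces
every motif peak with its `b`-th nearest matched neighbour, so the same
background peak is never reused for the same motif peak and backgrounds are
deterministic up to an infinitesimal seeded tie-break. Backgrounds are
drawn within the selected peak set, matching the matrix actually scored.
Motifs with no member among the selected peaks, or with a degenerate
background spread, yield `NA` sentinels rather than inflated scores.
Per-cluster TF enrichment is a one-sided Wilcoxon test of each motif's
z-scores (cluster vs rest), BH-corrected within cluster and ranked by
q-value then effect size.

Per-cluster genome tracks count each fragment once at its start position in
50-bp bins and normalize to reads per kilobase per million mapped fragments
(RPKM), so uniform duplication of a cluster's fragments leaves its track
unchanged; zero bins are omitted from the bedGraph output.

## The simulators and what they do (not) show

**Binomial noise model.** Counts for peak `i` in a cell of type `t` are
`Binomial(2, p)` with `p = (1 − q)·n·r_i^t/2 + q·n/(2k)`, where the bulk
profile column `r^t` sums to one, `k` is the peak count and `n` the
expected fragments per cell. The noise level `q` interpolates between the
bulk profile (`q = 0`) and a uniform profile over peaks (`q = 1`) at
constant expected depth `n`; probabilities outside [0, 1] are an error, not
a clamp. The binomial cap at 2 mirrors the two alleles of a diploid locus.
Defaults — 3 types, k = 1000 peaks, n = k/10 = 100 fragments per cell, 200
cells per type, each type concentrating 80% of its reads on its own 100
marker peaks — give cleanly separable types at `q = 0`, which is the point:
the benchmark measures how clustering accuracy decays as `q` rises, not
absolute difficulty.

**Bulk subsampling.** Per-type read pools (synthesized from skewed peak
profiles, 13 types by default) are subsampled without replacement, exactly
10,000 reads per simulated cell, 200 cells per type; varying compositions
come from a symmetric Dirichlet with shape 3 per component over 1000 cells.

**Fragment-level generator.** For end-to-end tests, a toy genome (two 1-Mb
autosomes plus chrM) carries 300 non-overlapping 400-bp true peaks; each of
3 cell types weights its 50 private marker peaks 8-fold over shared peaks.
Cells draw log-normal depths (median 8000, well above the 5000-fragment
calling threshold) and place 75% of fragments in peaks; 500 ambient
barcodes draw shallow depths (median 300) from a mostly background profile.
Fragment sizes mix nucleosome-free and mono-nucleosome modes; duplicates
are geometric with expected rate 0.3; MAPQ is 60 with probability 0.92 and
uniform below 30 otherwise. The truth bundle (labels, peaks, annotations,
motif membership, GC) suffices to score every stage.

These simulators reproduce the statistical structure the pipeline assumes —
peak-concentrated signal, depth variation, ambient noise, duplication —
but not read sequences, mappability artefacts, batch effects, doublets or
realistic motif co-occurrence. Passing tests therefore demonstrate correct
and calibrated behaviour under the assumed model, not performance claims on
any particular tissue.

## Numerical choices and problem sizes

Deterministic behaviour is part of the contract: every stochastic stage
takes a seed, PCA signs are fixed, Louvain runs under `set.seed`, and a
rerun of the full pipeline on the default scenario is byte-identical — the
test suite checks file digests. Tolerances: EM convergence 1e−6 (relative),
bisection 1e−6, SNN pruning 1/15, BH FDR 0.05 throughout. Test and
acceptance runs use the default scenario sizes above (600 cells + 500
ambient barcodes, ~5M fragments; benchmark grids of 600 cells × 1000 peaks
per replicate), sizes chosen so the whole suite exercises every stage at
full fidelity on a single CPU.

## Known limitations

The internal Poisson caller is a calibrated stand-in for a dedicated peak
caller; it does not model fragment-length structure or strand
cross-correlation, and an external caller can be slotted in at the
interface. EmptyDrops-style ambient testing and topic-model reductions are
out of scope. The Wilcoxon differential test ignores covariates; counts
with strong batch structure need upstream correction. Motif membership and
GC content are inputs — motif scanning is deliberately not reimplemented.
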