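---
title: "Methods: regional TAM analysis with tamscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional TAM analysis with tamscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in
`tamscape`, the assumptions behind them, the parameters a user might want
to change, and the design choices made where the methodology was genuinely
open. It states no empirical results beyond what the package's tests and
`scripts/acceptance.R` themselves compute.

## Scientific setting

Glioblastoma tissue splits into a hypoxic core and an invasive periphery,
and tumor-associated macrophages (TAMs) — recruited either from circulating
bone-marrow-derived monocytes (BMDM) or from resident microglia — appear to
differ by region in origin, recruitment signaling and activation dynamics.
The pipeline quantifies these differences on single-cell counts annotated
with a `core`/`periphery` label, optionally validated on bulk samples from
five anatomic structures ("leading edge" and "infiltrating tumour" mapped
to periphery; "cellular tumour", "microvascular proliferation" and
"pseudopalisading cells" mapped to core).

## Preprocessing

Counts are log-normalized per cell (`log(1 + count/total × 10⁴)`). The
tumor-of-origin label is regressed out gene-wise (indicator least squares;
residuals equal within-label deviations, so per-gene within-label means are
exactly zero afterwards). Centering and scaling use the population SD
(divide by *n*); zero-variance genes become all-zero rows, never `NaN`.
Label regression is applied to the log-normalized values, not raw integer
counts: residuals of raw counts are not meaningful inputs to scaling, and
everything downstream of the regression operates on the log scale. QC
follows two rules: genes must be expressed (count > 0) in at least 10
cells, and cells whose log10 total count lies more than 2 population SDs
from the mean are dropped. Spike-in controls (ids starting `ERCC`) are
removed on read.

## Meta-genes and the activation surrogate

A meta-gene score is the centered-mean expression of a gene list minus the
centered-mean expression of all remaining genes; by construction it is zero
on expression-free data and antisymmetric under swapping signature and
complement. The polarization (MPI) and maturation (AMDI) indices are
differences of meta-gene scores over positive/negative signature pairs,
affinely mapped per dataset so the least/most extreme cell sits at −50/+50.
This is a deliberate surrogate: the published activation-index tool is a
closed model, so the package preserves its *semantics* — the [−50, 50]
range, higher MPI = more pro-inflammatory, higher AMDI = more mature, and
the quadrant labels (`M0`, `M1-pre`, `M1-like`, `M2-like`) — while making
the inputs (four gene signatures) explicit and user-supplied. A score of
exactly 0 counts as the negative side; the published quadrants use strict
inequalities, which leaves 0 unassigned, so a convention is mandatory and
this one is pinned by tests.

## Ligand–receptor graphs

Ligand and receptor panels are filtered to genes expressed by at least 5%
of cells; receptors enter via the pair table (only partners of retained
ligands) and are filtered the same way. "Expressed" means count > 0
throughout. Graph edges carry expressing *fractions* per activation state
rather than mean expression, matching the binary language of the panel
filters. Loop importance sums, over qualifying 3-edge cycles
(state → ligand → receptor → state), the *sum* of the three edge weights;
that is the literal reading of a "sum of edge weights in all loops", and a
product convention is available behind `combine = "product"` since the
phrase is ambiguous. Both conventions are validated against an exhaustive
cycle enumerator. Ranks are competition-style (ties share the smaller
rank) with deterministic id-based tie-breaks.

## Regional separability

BMDM and microglia meta-gene scores feed a radial-kernel SVM classifier of
region, tuned by 10-fold cross-validation over cost and kernel width grids
{0.1, 1, 10} on a random 70% split, with ROC/AUC computed from continuous
decision values on the held-out 30%. "Support vector regression" in the
source methodology is read as a kernel SVM with continuous decision values,
because an ROC requires a score. AUC differences between states are tested
with DeLong's structural-component z-test, implemented directly (identical
curves return p = 1 exactly, which reference implementations reject as
degenerate) and cross-checked in the tests against `pROC::roc.test`. Bulk
tables are normalized as log2(CPM + 1) after dropping all-zero genes.

## Census normalization

Relative transcript counts divide each cell's counts by its total and
rescale so the *mode* of the per-cell log relative-expression distribution
(located by Gaussian kernel density over nonzero genes) maps to one
transcript. The output is exactly depth-invariant. Cells with fewer than
10 nonzero genes cannot support the density estimate and fall back to
depth scaling with the median modal scale of the remaining cells.

## Ordering genes: embedding, density peaks, LRT

The feature-selection stage embeds cells (genes expressed in ≥5% of cells)
in 2-D with Barnes–Hut t-SNE — the embedding is pluggable; anything
producing an n × 2 coordinate matrix works, and PCA (`embed_pca`) is the
linear alternative — then clusters the embedding with density-peak
clustering: local density P (Gaussian kernel, bandwidth 0.2 × median
pairwise distance) and distance D to the nearest higher-density point,
with the global maximum assigned the maximum pairwise distance.

Peaks are points with D at or above its 0.95 quantile whose density clears
the median. The symmetric-sounding alternative — both P *and* D in their
top 5% — was evaluated and rejected: on two equally dense, well-separated
clusters it detects the second cluster only about half the time, because
the global top-5% of density is dominated by whichever cluster is
fractionally denser; with the density term read as a noise floor the same
configuration is recovered essentially always (simulated in the test
suite). When a caller needs a minimum number of clusters (the pipeline
asks for 4 so the ordering-gene test has contrast), additional peaks are
promoted by the standard γ = P·D decision-graph criterion.

Ordering genes are then ranked by a negative-binomial likelihood-ratio
test of per-cluster means against a common mean. Dispersion is estimated
per gene by method of moments and floored at 10⁻⁴; with dispersion held
fixed the NB mean MLE per group is the group mean, so both likelihoods
have closed form and the test runs vectorized over thousands of genes. The
test consumes counts (Census output rounded to integers) — an NB
likelihood on log-scale values would be ill-defined. P-values use χ²(k−1)
and Benjamini–Hochberg adjustment; the top 1000 genes by q (ties by p,
then id) default.

## The principal tree

Cells (ordering genes only) are embedded by PCA to 2 dimensions and a
tree-structured set of K centroids is fit by alternating optimization:
soft assignment with a Gaussian kernel (scale σ = 0.01 × total embedding
variance), a centroid update solving `(Λ + λL) C = RᵀX` where L is the
Laplacian of the current spanning tree (shrinking adjacent centroids
together), and a minimum-spanning-tree rebuild over the updated centroids.
Each step minimizes the same penalized objective (assignment cost +
entropy + λ × summed squared edge lengths), so the objective is
non-increasing — asserted on every run — and iteration stops at a relative
decrease below 10⁻⁵ or 100 iterations.

Two defaults matter and were chosen by simulation against planted
trajectories:

* **λ = 0.5 × n_cells.** The tree-length penalty must scale with the
  assignment cost (a sum over cells); a constant λ that recovers a clean
  branched topology at 400 cells over-smooths or under-smooths at other
  sizes.
* **K = n_cells/10, clamped to [30, 100].** With substantially more
  centroids than this the spanning tree sprouts noise twigs and spurious
  branch points on a few-hundred-cell dataset (a K of `max(50, n/20)` was
  tried first and produced multi-branch-point topologies on a sizeable
  fraction of seeds); with many fewer it cannot trace the manifold.

States are maximal tree paths between nodes of degree ≠ 2 (a path is one
state; a single Y is three states and one branch point; two cascaded Ys
give five states and two branch points — the topology reported for both
regional analyses in the motivating study). `assign_states` optionally
collapses terminal twigs supported by fewer than a given fraction of cells
(the pipeline uses 5%) before extracting states; this removes
noise-induced micro-branches without touching well-populated structure.

Pseudotime is rooted at the leaf of the state with the lowest mean AMDI
(ties break to the lexicographically smaller state id, with a warning; if
the root state has several leaves the one whose local neighbourhood has
the lowest mean AMDI wins). Every cell is projected *continuously* onto
its nearest tree edge and pseudotime is the geodesic distance from the
root to the projection, shifted so the earliest cell is exactly 0.
Node-level pseudotime (distance to the assigned centroid only) was
rejected: it piles a large fraction of the cells of each arm onto the
terminal node, destroying within-branch dynamics and with them most of the
power of the branch test.

## Branch analysis

For the two output arms of a branch point, each gene is tested with an NB
GLM likelihood ratio: natural-spline basis of pseudotime crossed with the
branch label against the spline-only model, per-gene method-of-moments
dispersion held fixed in both fits, χ² with the parameter-count difference,
BH-adjusted, flagged at q < 0.05. Pseudotime is rescaled to 0–100 *within
each branch* before the basis is built — the same convention the smoothed
curve heatmaps use. This rescaling is essential, not cosmetic: output arms
generally differ in geodesic length, and on the raw scale a
pseudotime-only spline can absorb genuine branch differences wherever one
arm extends past the other (observed directly in simulation as a
collapse of power). Spline knots sit at the within-branch quartiles,
dropping knots that collide with a boundary (heavily tied pseudotime), with
a linear fallback for degenerate supports.

Curves are smoothed per branch on a shared 0–100 grid, standardized
jointly, clustered by 1 − Pearson correlation with Ward linkage, and k is
chosen by maximum mean silhouette over 2..10 unless given. Cluster
divergence is |mean_A − mean_B| / pooled SD of the cluster meta-gene over
the terminal 10% of cells per arm (arms with fewer than 5 terminal cells
use all their cells, with a warning); clusters at divergence ≥ 1 are
selected. Over-representation of a cluster in a gene-set collection is a
one-sided hypergeometric (upper tail including the observed overlap) with
BH across sets — a local, offline replacement for web-based enrichment
queries.

## The synthetic generator

`simulate_tam_cells` draws, per cell: a uniform latent maturation time on
[0, 1]; a branch label (trunk before the branch time, default 0.4, then A
or B with equal probability); and an ontogeny fraction (Beta(8, 2) in the
core, Beta(2, 8) in the periphery — BMDM-dominant core, microglia-dominant
periphery). Disjoint gene blocks respond log-linearly with slope
`effect_size`: ontogeny blocks to the ontogeny fraction, the
differentiation block to latent time (one half up, one half down), the
polarization block to a maturation ramp whose *direction depends on
region* (pro-inflammatory in core, anti-inflammatory in periphery) and
whose amplitude is larger on branch A than B (making it branch-dependent),
ligand genes to immature states, receptor genes to pro-inflammatory
states, pathway-1 genes to branch A only (rising), and pathway-2 genes to
the terminal fifth of branch B. Column means are rescaled to a lognormal
library size (CV ≈ 0.25) around `depth_mean`, and counts are negative
binomial with a single shared dispersion (default 0.3) — the simplest
model consistent with the count-distribution assumption the Census step
makes. Defaults follow the regional sample sizes of the motivating study
(2343 core, 1246 periphery cells); library size and dispersion are free
parameters (the study reports neither), set to values typical of
deeply-sequenced plate-based scRNA-seq. At `effect_size = 0` the mean
structure is label-free, making nulls exact.

What the generator does **not** emulate: real gene-gene correlation
structure beyond the planted programs, batch effects beyond the tumor
label, doublets, ambient RNA, zero-inflation beyond NB sampling, and
non-macrophage cell types. Passing recovery tests therefore demonstrates
the pipeline's correctness on data satisfying its own assumptions, not
robustness to everything real tissue does.

## Problem sizes used by tests and the acceptance script

Simulation-backed tests run at 400 core + 300 periphery cells and 600
genes (signal blocks of 20–40 genes), 20 seeds for recovery rates, and
2000-gene null panels for calibration — sizes chosen so the planted
effects match the study-scale signal-to-noise while a full run of the
suite stays in the minutes range. Determinism is asserted by running the
full pipeline twice at a fixed seed and comparing artifacts byte for byte.

## Known limitations

* The activation surrogate reproduces ranges and quadrant semantics, not
  the published tool's numeric indices on real data.
* The principal tree is fit in a 2-D PCA of the ordering genes; strongly
  nonlinear manifolds may need a different embedding (any n × 2 coordinate
  matrix can be passed with `embedded = TRUE`).
* The branch test conditions on the fitted tree; uncertainty in tree
  topology is not propagated.
* Ligand/receptor curation is a user input (two-column pair table); no
  interaction database ships with the package.
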