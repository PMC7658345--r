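# tamscape

Regional analysis of tumor-associated macrophages (TAMs) in glioblastoma
from single-cell and bulk RNA-seq.

Glioblastoma is sharply compartmentalized: a hypoxic, contrast-enhancing
core and an invasive periphery that interfaces with brain tissue. Up to half
of the tumor bulk is macrophages, recruited either from circulating
bone-marrow-derived monocytes (BMDM) or from brain-resident microglia, and
there is growing evidence that their origin, recruitment and activation
differ by region. `tamscape` packages the computational machinery needed to
dissect those regional differences: signature scoring, activation-state
classification, composition statistics, ligand–receptor co-expression
graphs, trajectory/pseudotime analysis, and branch-dependent gene-program
discovery — together with a synthetic-data generator that plants known
structure so that every stage can be validated by parameter recovery.

## The statistics at the core

**Meta-gene score.** For a gene set *S* and log-normalized, gene-centered
expression *x*, a cell's meta-gene score is

    m(c) = mean_{g in S} x(g, c)  -  mean_{g not in S} x(g, c),

the difference between the centered mean expression of the signature and of
all remaining genes. Cells with no expression structure score exactly 0.

**Activation indices.** A polarization index (MPI) and a maturation index
(AMDI) are built as differences of meta-gene scores over positive/negative
signature pairs, affinely rescaled across cells to [−50, 50]. The sign
quadrant of (AMDI, MPI) labels each cell `M0` (pre-activation), `M1-pre`
(transitional pro-inflammatory), `M1-like` or `M2-like`; a score of 0
counts as negative.

**Ligand–receptor loop importance.** Expression-filtered ligand and
receptor panels (≥5% of cells) form a tri-layer directed graph
state → ligand → receptor → state, with state edges weighted by expressing
fractions. The importance of a receptor for an activation state is the sum
of loop weights over all 3-edge cycles through that state and receptor
(additive loop weight by default; a product convention is available).

**Principal-tree pseudotime.** Counts are converted to Census-style
relative transcript counts (per-cell mode of the log relative-expression
distribution mapped to one transcript); ordering genes are selected by a
negative-binomial likelihood-ratio test across density-peak clusters of a
t-SNE embedding; a tree-structured set of centroids is fit by alternating
soft assignment, regularized centroid updates and minimum-spanning-tree
rebuilding; pseudotime is geodesic distance along the tree from the
terminus of the lowest-AMDI state, with every cell projected continuously
onto its nearest edge.

**Branch analysis.** At a branch point, each gene is tested for
branch-dependent dynamics with an NB likelihood-ratio test of
spline(pseudotime) × branch against spline-only (pseudotime rescaled 0–100
within each output arm); q < 0.05 flags branch dependence. Flagged genes
are clustered by the correlation of their smoothed curves (Ward linkage,
silhouette-chosen k), clusters are scored for terminal-cell divergence in
pooled-SD units, and divergent clusters are annotated by local
hypergeometric over-representation against user gene sets.

## Worked example

Simulate a study-like dataset (core/periphery cells, a planted branched
trajectory, region-dependent ontogeny and polarization) and run the full
regional pipeline on the core cells:

```r
library(tamscape)

cfg <- synth_config(n_cells_core = 400, n_cells_periphery = 300,
                    n_genes = 600, seed = 2)
sim <- simulate_tam_cells(cfg)
sim$counts
#> tam_counts: 600 genes x 700 cells
#>   regions: core=400, periphery=300

bundle <- run_regional_analysis(
  list(dataset = sim, seed = 2, top_n_ordering = 200), region = "core")

bundle$tree
#> principal_tree: 38 centroids, 384 cells, 1 branch point(s)
round(bundle$correlations$amdi$r, 2)   # maturation rises with pseudotime
#> [1] 0.96
round(bundle$correlations$mpi$r, 2)    # core matures pro-inflammatory
#> [1] 0.72
sum(bundle$branch$test$branch_dependent)
#> [1] 94
bundle$branch$divergence
#>   cluster n_genes     mean_A     mean_B divergence selected
#> 1       1      49  0.4214758 -0.4328951   6.876704     TRUE
#> 2       2      45 -0.3441817  0.5313171  10.667889     TRUE
```

The tree has exactly one branch point (the planted fate decision), AMDI
climbs along pseudotime (r = 0.96), and in the core the polarization index
climbs too (r = 0.72) — run the same call with `region = "periphery"` and
the MPI correlation flips sign, the package's analogue of the
pro-inflammatory-core / anti-inflammatory-periphery contrast. The two
divergent gene clusters recover the planted branch programs; feeding one
to `overrepresentation()` against `sim$signatures` identifies it.

Composition tables with per-state core-vs-periphery chi-squared tests
(Yates-corrected) come from `composition_table()` / `run_table_stats()`;
`round(chisq_2x2(358, 156, 802, 490)$p, 3)` gives `0.003`, i.e. the
familiar "31% vs 24%, p = 0.003" style of comparison.

A thin CLI wrapper is installed at `inst/scripts/tamscape`
(`tamscape simulate|run|tablestats`).

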