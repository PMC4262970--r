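---
title: "scqmap: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{scqmap: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scqmap)
```

`scqmap` implements the computational core of a single-cell qPCR study
of leukemic heterogeneity: censored Ct preprocessing, projection of
cells onto a reference hematopoietic hierarchy, rank-sum differential
expression between the mapped subtypes, and weighted co-expression
network comparison. This vignette explains each model, the tunable
parameters and their defaults, the numerical conventions, and what the
synthetic-data experiments do and do not demonstrate.

## Censored expression model

Multiplex qPCR reports a threshold cycle per reaction; each cycle is a
doubling, so Ct differences are log2 expression differences. With
background level $B$ (cycles, default 28), expression is

$$E = \max(0,\; B - \mathrm{Ct}),$$

after first clamping Ct values above $B$ to $B$. Zero therefore encodes
"not detected", a *censored* value rather than a measured one. Two
conventions follow from this:

* **Anti-log transform.** Network analysis runs on the linear scale
  $2^E$. A literal anti-log would send $E = 0$ to $1$, conflating
  non-detection with low expression, so `to_linear()` maps 0 to 0. The
  source studies do not state how they handled this case; the 0 → 0
  convention is this package's choice and it matters most for
  dropout-heavy genes, whose linear-scale correlations depend on how the
  censored mass is placed.
* **Validation.** A Ct matrix must be finite and strictly positive with
  no missing values: an undetected reaction is encoded as Ct at or above
  the background, never as a blank. Violations are rejected with the
  offending cell and gene named.

$B$ is a parameter everywhere, not a constant; 28 is the default because
it is the background of the instrument protocol this pipeline was built
around. Matrices are oriented cells × genes in files and in memory.

## Mapping cells onto a reference hierarchy

The reference is a tree of cell clusters (in the motivating study, 56
SPADE-derived clusters of >1,000 normal hematopoietic cells), each node
carrying a mean log2 profile over a reference gene set. A cell is
assigned to the node minimising Euclidean distance over a **gene
panel**, by default the intersection of the data's genes with the
reference's (the motivating study had 33 such shared genes). Distances
are computed on the log2 scale — the scale on which the node centroids
were averaged.

*Tie rule.* Exact distance ties go to the lexicographically smallest
node id. Ties have probability zero for continuous data but occur in
degenerate panels; a deterministic rule keeps every run reproducible.

**Concordance** summarises a re-mapping experiment: the fraction of
cells assigned exactly to their original node, and within `max_steps`
tree edges of it (default 2, counting unit-weight steps on the tree;
original SPADE edge lengths are not used). It is non-decreasing in
`max_steps` by construction. **Random-panel validation** re-maps all
cells with `n_lists` (default 100) random panels of `panel_size`
(default 33) genes drawn uniformly without replacement from the shared
set, under a caller-supplied seed.

**Subtypes** are branch labels: each tree node belongs to a branch
(supplied with the tree or as an explicit `branch_map`, since branch
membership is a labelling of the reference, not something derivable from
expression), and a cell inherits the branch of its assigned node.
`phenotype_crosstab()` then cross-tabulates subtypes against
immunophenotypes with row- and column-conditional proportions.

## Differential expression

The recipe is deliberately simple and robust for censored, zero-inflated
log2 data:

* **Test:** two-sided Wilcoxon–Mann–Whitney per gene. For pooled sizes
  $n + m \le$ `exact_threshold` (default 20) with no ties, the p-value
  comes from the exact permutation null (via the exact distribution of
  the Mann–Whitney $U$); otherwise a normal approximation with midrank
  tie correction and continuity correction. The mode is exposed
  (`"auto"`, `"exact"`, `"approx"`). At the group sizes of interest
  (tens of cells per group) the approximation is in force; the exact
  path exists so that small-sample results are reproducible and
  testable against enumeration. When all pooled values are identical the
  null variance is zero and $p = 1$.
* **Multiplicity:** Benjamini–Hochberg across exactly the genes tested
  in the comparison (the family is the tested set, nothing more).
* **Effect size:** log fold change $=$ difference of group medians of
  log2 expression, group A − group B. The sign convention is fixed and
  documented rather than inferred.
* **Call:** significant iff adjusted $p <$ `alpha` (default $10^{-5}$)
  **and** $|\mathrm{LFC}| \ge$ `lfc_min` (default 2). The stringent dual
  cutoff trades sensitivity for specificity; with $n = m = 2$ the
  smallest attainable two-sided $p$ is $1/3$, so tiny groups can never
  be called, which is intended.

## Weighted co-expression networks

Per cell subset: anti-log to linear scale, drop zero-variance genes
(recorded in the result), Pearson correlation, unsigned power adjacency
$a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$ with unit diagonal, and
connectivity $k_i = \sum_{j \ne i} a_{ij}$.

**Soft threshold.** The scale-free fit index $R^2$ is the squared
correlation between $\log_{10} p(k)$ and $\log_{10} k$ after binning
$k$ into `n_bins` (default 10) equal-width bins, dropping empty bins and
using the within-bin mean $k$ as abscissa. `choose_beta()` scans
candidates in order (default 1–20) and returns the smallest exponent
with $R^2 >$ 0.85; if none qualifies the error carries the full scan
table so the caller can inspect or relax. A two-bin fit is degenerately
1 and warns. The pipeline default is instead a *fixed* β = 6: with only
tens of cells and one or two hundred genes per subset the $R^2$ scan is
noisy, and fixing the exponent per network — as the motivating study did
after its own scans (β = 6, 4, 5, 4 for its four networks) — keeps runs
deterministic and comparable.

**Topological overlap.**
$$\mathrm{TOM}_{ij} = \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
                           {\min(k_i, k_j) + 1 - a_{ij}},\qquad
  \mathrm{TOM}_{ii} = 1.$$
This is the standard unsigned TOM; the implementation is matrix-level
($A^2$ minus diagonal corrections) and is verified in the tests against
a literal triple-loop evaluation.

**Module detection.** Genes are clustered by average linkage (UPGMA) on
$1 - \mathrm{TOM}$ and the dendrogram is cut at a *fixed* dissimilarity
height (`cut_height`, default 0.99); clusters smaller than
`min_module_size` (default 10) are unassigned (label 0), and modules are
numbered by decreasing size. The published analyses used dynamic tree
cutting, whose parameters they do not state; a deterministic static cut
is testable and tunable, at the cost of not reproducing module
boundaries gene-for-gene. An earlier variant of this package cut at a
quantile of the merge heights instead; that rule degenerates whenever
most genes are unclustered background (their merges pile up at
dissimilarity ≈ 1, dragging any height quantile to the top and merging
everything), so the fixed-height convention — the same convention as
classic static tree cutting in the co-expression literature — was
adopted.

Average linkage itself delegates to `stats::hclust`; merge heights are
monotone for UPGMA, and tiny floating-point inversions are repaired with
a running maximum before cutting. Dendrograms export to Newick (via
`ape`) and to a merge table for external viewers.

**Comparison.** `module_overlap()` reports, for every module pair
across two networks, the intersection size, Jaccard index, containment
fraction and the shared gene list — the accounting used to ask whether a
module is retained or lost between cell subsets.

## The synthetic-data generator

`synthetic_spec()` describes a study; its defaults are the regime of the
motivating dataset: a 56-node tree, 175 genes, a 33-gene marker panel,
20 cells per node, background Ct 28, 14 planted differential genes with
a 4-log2 shift, and two latent-factor modules of 25 and 20 genes
(loading 2, factor sd 1). Baseline log2 levels are uniform on [4, 12] —
mid-range for a 0–28 censored scale, so censoring is present but not
dominant. Per-edge centroid drift is Gaussian with sd 2 log2 units and
per-cell noise sd defaults to 1, values at which mapping is nearly
perfect at low noise and degrades visibly across the tested noise grid,
matching the qualitative behaviour expected of well-separated
progenitor populations.

Structure of a generated dataset:

* **Tree.** Sequential random-parent attachment; nodes 2 and 3 attach
  to the root and seed the two designated branches "A" and "B"; later
  nodes inherit their parent's branch ("other" for the root's other
  descendants). Centroids drift along edges in the *marker-panel genes
  only* and are clamped to $[0, B - 1]$ — strictly below background, so
  a noise-free cell at a centroid always produces a valid positive Ct.
* **Genes.** Roles partition the gene universe in column order: panel
  (lineage signal), planted DE genes (branch-A shift), module genes
  (gene value += loading × per-cell latent factor, giving controllable
  pairwise correlations ≈ loading²/(loading² + noise²)), background
  (flat baseline). Confining lineage drift to the panel mirrors the
  motivating design — the reference hierarchy was built from surface
  markers, while the additional genes were assayed to find subtype
  programs — and it makes planted truth well defined: only the planted
  genes differ systematically between branches, so DE
  precision/recall against the planted set is meaningful. With
  `drift_genes = "all"` every gene carries lineage signal, at the price
  that branch-vs-branch comparisons genuinely differ in many non-planted
  genes.
* **Cells.** Cell = node centroid + noise + planted effects, converted
  to Ct space (Ct $= B -$ value, floored at 0.25 cycles) where the
  detection limit censors values at or below zero exactly as real data
  would be censored. An immunophenotype correlated with the branch
  (fidelity 0.8 by default) is drawn per cell for cross-tabulation
  exercises.

For the same reason, the pipeline's DE and network stages default to
the non-panel genes (`exclude_panel_genes = TRUE`): the marker panel
defines the hierarchy, so asking which *programs* distinguish subtypes
is a question about the remaining genes. Both stages accept arbitrary
gene sets.

Tree seed and cell seed are separate arguments: replicate experiments
regenerate cells on one fixed reference hierarchy, as in the real study
where the reference tree is a fixed input, and all randomness flows from
the given seeds.

**What the generator does not emulate:** amplification-efficiency
differences between assays, probe-level artefacts, cell-cycle or batch
structure, doublets, and the fat-tailed dropout patterns of real
single-cell chemistry. Passing recovery tests therefore shows the
*algorithms* are correct and calibrated under the stated noise model,
not that any particular biological dataset will map as cleanly.

## Numerical conventions and degenerate inputs

* Zero-variance vectors are rejected by name in correlation routines;
  `build_network()` filters them first and records the dropped genes.
* Correlation distances are clamped to [0, 2], correlations to
  [−1, 1], TOM to [0, 1]; TOM is symmetrised against rounding.
* Linkage ties resolve toward the lexicographically smallest cluster
  pair; nearest-centroid ties toward the smallest node id; module
  numbering ties toward the earliest gene position.
* BH inputs outside [0, 1] are rejected; approximate rank-sum p-values
  are floored at the smallest positive double.
* `scale_free_fit()` rejects constant connectivity (undefined fit) and
  requires two usable bins.
* Genes constant in both DE groups get $p = 1$ and an LFC from medians;
  they are never called.

## Problem sizes in the test suite

The tests exercise the defaults end to end: the zero-noise and
noise-grid experiments run the full 56-node / 175-gene / 1,120-cell
regime (10 replicate cell draws at noise sds 0.5, 1, 2 and 4); null
calibration uses 10,000 genes at 30 vs 30 cells plus 100 replicate
175-gene null runs; oracle comparisons sweep every rank-sum sample size
with $n + m \le 16$ against full enumeration, 1,000 random BH vectors,
200 random 8-gene TOMs and 100 random UPGMA instances. Monotone
degradation over the noise grid is asserted as "no statistically
significant increase" (two paired standard errors over the replicate
seeds), the appropriate finite-sample reading of a claim about
expectations.

## Known limitations

* The static module cut will not reproduce dynamic-tree-cut module
  boundaries gene-for-gene; module *counts* and *overlap patterns* are
  the comparable outputs.
* Housekeeping normalisation, amplification-efficiency modelling and
  probe QC are out of scope; inputs are assumed pre-filtered.
* Networks built from a few dozen cells are noisy regardless of
  machinery; the scale-free $R^2$ reported for small subsets should be
  read as descriptive, not inferential.
* Signed networks, bi-weight midcorrelation, module eigengenes and
  differential co-expression are not implemented.
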