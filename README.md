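# scqmap

Analysis toolkit for **multiplex single-cell qPCR** studies of leukemic
heterogeneity. Starting from a cells × genes matrix of threshold-cycle
(Ct) values, `scqmap`:

1. converts Ct to detection-limit-censored log2 expression,
2. projects each cell onto a **reference hematopoietic-hierarchy tree**
   (e.g. a SPADE-derived minimum-spanning tree of cell clusters) by
   nearest-centroid assignment over a reduced marker panel, and scores
   how faithfully the panel preserves the hierarchy,
3. compares the resulting leukemic subtypes by **Wilcoxon rank-sum
   differential expression** with Benjamini–Hochberg correction, and
4. builds **weighted gene co-expression networks** per cell subset and
   compares their module structure.

A synthetic-data generator with planted ground truth (tree-structured
centroids, censoring, planted differential genes, latent-factor
co-expression modules) makes every stage testable end to end.

It is aimed at computational biologists analysing targeted single-cell
qPCR panels (BioMark-style, ~10–300 genes) in hematopoiesis or leukemia,
where droplet-scale RNA-seq tooling is a poor fit.

## The methods in brief

**Preprocessing.** With background threshold cycle *B* (default 28),
expression is *E = max(0, B − Ct)*, an approximation to log2 expression
in which Ct ≥ *B* (no detection) becomes 0. The anti-log transform used
for network analysis maps *E* > 0 to 2^*E* and keeps 0 at 0, so
"not detected" never masquerades as "expression 1".

**Hierarchy mapping.** The reference tree supplies one mean log2 profile
(centroid) per node. Each cell is assigned to the node minimising the
Euclidean distance over a gene panel — by default the genes shared
between the data and the reference. Concordance is the fraction of cells
landing exactly on, or within *s* tree edges (default 2) of, their
original node; panel sufficiency is validated by re-mapping with random
gene panels of the same size. Subtype labels are the branch labels of
the assigned nodes.

**Differential expression.** Per gene, a two-sided
Wilcoxon–Mann–Whitney test (exact for small untied samples, tie- and
continuity-corrected normal approximation otherwise), BH adjustment
across the tested family, and a log fold change defined as the
*difference of group medians* of log2 expression. A gene is called at
the stringent dual criterion adjusted *p* < 1e−5 **and** |LFC| ≥ 2.

**Co-expression networks.** On linear-scale expression, an unsigned
power adjacency *a_ij = |cor(x_i, x_j)|^β*. The soft threshold β is
either fixed or chosen as the smallest exponent whose connectivity
distribution is approximately scale-free: R², the squared correlation of
log10 *p(k)* versus log10 *k* over binned connectivities, must exceed
0.85. Module detection clusters genes by average linkage on the
topological-overlap dissimilarity

    TOM_ij = (Σ_{u≠i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)

with a deterministic static cut (dissimilarity height 0.99, minimum
module size 10). Module overlap between networks is reported as
intersection counts, Jaccard indices and containment fractions.

## Worked example

Simulate a study at the default regime — a 56-node reference tree,
175 genes of which 33 form the marker panel, 20 cells per node,
per-cell noise sd 1 — then map, test and build a network:

```r
library(scqmap)

spec <- synthetic_spec(noise_sd = 1, seed = 42)
tree <- generate_tree(spec)
sim  <- generate_cells(tree, spec)
expr <- ct_to_expression(sim$ct, background_ct = 28)

panel <- subset(spec$gene_roles, role == "panel")$gene_id
truth <- sim$truth$cells
mapping <- map_cells(expr, tree, panel = panel,
                     original = setNames(truth$node_id, truth$cell_id))
concordance(mapping, tree, max_steps = 2)
#> concordance over 1120 cells: 100.0% exact, 100.0% within <=2 steps

mapping <- assign_subtypes(mapping, tree)
table(mapping$subtype)
#>     A     B other
#>    80   480   560
```

At this noise level every cell returns to its node of origin, and the
two designated leukemic branches separate perfectly. Differential
expression between the branches, over the 142 non-panel genes:

```r
extra <- setdiff(colnames(expr), panel)
de <- differential_genes(expr, mapping$cell_id[mapping$subtype == "A"],
                         mapping$cell_id[mapping$subtype == "B"],
                         genes = extra)
head(as.data.frame(de), 4)
#>   gene statistic        p    p_adj  lfc significant
#> 1 G040     38334 2.90e-46 6.06e-45 4.27        TRUE
#> 2 G045     38329 3.06e-46 6.06e-45 4.26        TRUE
#> 3 G046     38317 3.48e-46 6.06e-45 4.23        TRUE
#> 4 G044     38370 1.97e-46 6.06e-45 4.03        TRUE
```

The top hits are planted differential genes (true shift 4 log2 units;
the estimated LFCs scatter around 4). A co-expression network on the
branch-A cells recovers the two planted latent-factor modules:

```r
net <- build_network(expr, cells = mapping$cell_id[mapping$subtype == "A"],
                     genes = extra, beta = 6)
net
#> scq_network: 142 genes (0 dropped), 80 cells, beta = 6, R^2 = 0.365
#> modules: 1 (n=29), 2 (n=22) ; unassigned 91
```

The detected modules contain the 25- and 20-gene planted modules plus a
few noise genes; unassigned genes (label 0) carry no co-expression
structure. `run_all(pipeline_config(spec = spec), "out/")` performs all
of the above (plus random-panel validation, phenotype cross-tabulation
and per-subset network comparison) and writes every intermediate and a
`summary.json` to the output directory. A command-line wrapper lives at
`inst/scripts/scqmap.R`.

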