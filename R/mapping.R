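#' Mean expression profile per tree node
#'
#' Arithmetic mean of the log2 expression of the cells assigned to each
#' node, gene by gene — the per-node centroids that single cells are
#' later matched against.
#'
#' @param expr An `"scq_expr"` (log2) or plain cells x genes matrix.
#' @param node_assignment Character vector of node labels, one per cell
#'   (named by cell id or in row order of `expr`).
#' @return Numeric matrix, rows = nodes (sorted by id), columns = genes.
#'   Labels referencing no cells are dropped with a warning.
#' @export
compute_node_centroids <- function(expr, node_assignment) {
  m <- unclass(as.matrix(expr))
  lab <- align_cell_labels(node_assignment, rownames(m), "node_assignment")
  if (is.factor(lab)) {
    empty <- setdiff(levels(lab), as.character(lab))
    if (length(empty) > 0)
      warning("node(s) with no cells omitted: ", paste(empty, collapse = ", "))
    lab <- as.character(lab)
  }
  nodes <- sort(unique(lab))
  cent <- t(vapply(nodes, function(nd) colMeans(m[lab == nd, , drop = FALSE]),
                   numeric(ncol(m))))
  rownames(cent) <- nodes
  cent
}

#' Project single cells onto a reference tree by nearest centroid
#'
#' Each cell is assigned to the tree node whose mean expression profile is
#' closest in Euclidean distance, computed on the log2 scale and
#' restricted to a reduced gene panel (by default the intersection of the
#' data's genes with the reference gene set — the "shared genes" panel).
#' Exact distance ties go to the lexicographically smallest node id.
#'
#' @param expr An `"scq_expr"` log2 matrix (or plain cells x genes
#'   matrix).
#' @param tree An `"scq_tree"` reference.
#' @param panel Character vector of gene ids to use; `NULL` selects all
#'   genes shared between `expr` and the reference (reported via a
#'   message).
#' @param original Optional per-cell original/true node id (named by cell
#'   or in row order), retained for concordance analysis.
#' @return A `data.frame` of class `"scq_mapping"` with columns
#'   `cell_id`, `node_id`, `distance` (and `original` if supplied);
#'   attribute `panel` records the genes used.
#' @seealso [concordance()], [assign_subtypes()]
#' @export
map_cells <- function(expr, tree, panel = NULL, original = NULL) {
  m <- unclass(as.matrix(expr))
  shared <- intersect(colnames(m), colnames(tree$centroids))
  if (is.null(panel)) {
    panel <- shared
    message(sprintf("using %d shared gene(s) as mapping panel", length(panel)))
  } else {
    panel <- as.character(panel)
    missing <- setdiff(panel, shared)
    if (length(missing) > 0)
      stop("panel gene(s) absent from data or reference: ",
           paste(missing, collapse = ", "))
  }
  if (length(panel) == 0) stop("effective mapping panel is empty")

  nodes <- sort(tree_nodes(tree))          # sorted: ties -> lowest node id
  E <- m[, panel, drop = FALSE]
  C <- tree$centroids[nodes, panel, drop = FALSE]
  # squared Euclidean distances via ||x||^2 + ||c||^2 - 2 x.c
  d2 <- outer(rowSums(E^2), rowSums(C^2), "+") - 2 * (E %*% t(C))
  d2[d2 < 0] <- 0
  idx <- apply(d2, 1, which.min)           # first minimum = lowest node id
  res <- data.frame(cell_id = rownames(m),
                    node_id = nodes[idx],
                    distance = sqrt(d2[cbind(seq_len(nrow(d2)), idx)]),
                    row.names = NULL)
  if (!is.null(original)) {
    res$original <- as.character(
      align_cell_labels(original, rownames(m), "original"))
  }
  structure(res, panel = panel, class = c("scq_mapping", "data.frame"))
}

#' Mapping concordance with the original tree positions
#'
#' Fraction of cells whose assigned node equals their original node
#' (exact) and whose assigned node lies within `max_steps` tree edges of
#' it (proximity), the summary used to judge whether a reduced marker
#' panel preserves the lineage hierarchy.
#'
#' @param mapping An `"scq_mapping"` with an `original` column.
#' @param tree The `"scq_tree"` the cells were mapped onto.
#' @param max_steps Proximity radius in tree edges (default 2).
#' @return List of class `"scq_concordance"`: `fraction_exact`,
#'   `fraction_within`, `max_steps`, `n`.
#' @export
concordance <- function(mapping, tree, max_steps = 2) {
  if (is.null(mapping$original))
    stop("`mapping` carries no original node assignment")
  steps <- tree_distance(tree, mapping$node_id, mapping$original)
  out <- list(fraction_exact = mean(steps == 0),
              fraction_within = mean(steps <= max_steps),
              max_steps = max_steps,
              n = nrow(mapping))
  class(out) <- "scq_concordance"
  out
}

#' @export
print.scq_concordance <- function(x, ...) {
  cat(sprintf(
    "concordance over %d cells: %.1f%% exact, %.1f%% within <=%d steps\n",
    x$n, 100 * x$fraction_exact, 100 * x$fraction_within, x$max_steps))
  invisible(x)
}

#' Validate panel sufficiency by random gene-list resampling
#'
#' Draws `n_lists` random panels of `panel_size` genes (uniformly, without
#' replacement within a panel) from the genes shared between the data and
#' the reference, re-maps all cells with each panel, and scores the
#' concordance with the original positions — the resampling control for
#' whether a small marker panel suffices to preserve the hierarchy.
#'
#' @inheritParams map_cells
#' @param original Per-cell original node id (named by cell or in row
#'   order).
#' @param panel_size Genes per random panel (default 33).
#' @param n_lists Number of random panels (default 100).
#' @param max_steps Proximity radius in tree edges (default 2).
#' @param seed Integer seed; runs with the same seed are identical.
#' @return List of class `"scq_panel_validation"`: `per_panel`
#'   (data.frame `panel`, `fraction_exact`, `fraction_within`),
#'   `mean_exact`, `mean_within`, `panels` (list of gene vectors),
#'   `panel_size`, `max_steps`.
#' @export
random_panel_validation <- function(expr, tree, original, panel_size = 33,
                                    n_lists = 100, max_steps = 2,
                                    seed = NULL) {
  shared <- intersect(colnames(expr), colnames(tree$centroids))
  if (panel_size > length(shared))
    stop(sprintf("panel_size %d exceeds the %d shared genes",
                 panel_size, length(shared)))
  if (n_lists < 1) stop("`n_lists` must be at least 1")
  draw <- function() sample(shared, panel_size)
  panels <- if (is.null(seed)) replicate(n_lists, draw(), simplify = FALSE)
            else withr::with_seed(seed,
                   replicate(n_lists, draw(), simplify = FALSE))
  per <- lapply(panels, function(p) {
    cc <- concordance(map_cells(expr, tree, panel = p, original = original),
                      tree, max_steps = max_steps)
    c(cc$fraction_exact, cc$fraction_within)
  })
  per <- do.call(rbind, per)
  out <- list(per_panel = data.frame(panel = seq_len(n_lists),
                                     fraction_exact = per[, 1],
                                     fraction_within = per[, 2]),
              mean_exact = mean(per[, 1]),
              mean_within = mean(per[, 2]),
              panels = panels,
              panel_size = panel_size,
              max_steps = max_steps)
  class(out) <- "scq_panel_validation"
  out
}

#' @export
print.scq_panel_validation <- function(x, ...) {
  cat(sprintf(
    "%d random panels of %d genes: mean %.1f%% exact, mean %.1f%% within <=%d steps\n",
    nrow(x$per_panel), x$panel_size, 100 * x$mean_exact,
    100 * x$mean_within, x$max_steps))
  invisible(x)
}

#' Derive per-cell subtype labels from tree branches
#'
#' A cell's subtype is the branch label of the node it mapped to; two
#' leukemic subpopulations landing on different branches of the reference
#' (e.g. a GMP-like and a DC/macrophage-like branch) thereby receive
#' distinct labels.
#'
#' @param mapping An `"scq_mapping"`.
#' @param tree The `"scq_tree"` used for mapping.
#' @param branch_map Named character vector node id -> branch label;
#'   defaults to the tree's own branch labels. Must cover every node that
#'   received a cell.
#' @return The mapping `data.frame` with a `subtype` column appended.
#' @export
assign_subtypes <- function(mapping, tree, branch_map = NULL) {
  if (is.null(branch_map)) branch_map <- tree$branch
  if (is.null(branch_map))
    stop("no branch labels: supply `branch_map` or a tree with branches")
  used <- unique(mapping$node_id)
  uncovered <- setdiff(used, names(branch_map))
  if (length(uncovered) > 0)
    stop("node(s) without a branch label: ",
         paste(uncovered, collapse = ", "))
  mapping$subtype <- unname(branch_map[mapping$node_id])
  mapping
}

#' Cross-tabulate subtypes against immunophenotypes
#'
#' Contingency counts plus row-conditional (`P(subtype | phenotype)`) and
#' column-conditional (`P(phenotype | subtype)`) proportions, used e.g. to
#' ask which fraction of cells of a FACS immunophenotype fall into each
#' mapped subtype.
#'
#' @param subtypes,phenotypes Per-cell labels over the same cells; if
#'   named, names must agree as sets (order-independent), otherwise
#'   positions are matched.
#' @return List of class `"scq_crosstab"`: `counts` (phenotype x
#'   subtype), `p_subtype_given_phenotype`, `p_phenotype_given_subtype`,
#'   and the marginal counts.
#' @export
phenotype_crosstab <- function(subtypes, phenotypes) {
  if (length(subtypes) != length(phenotypes))
    stop("`subtypes` and `phenotypes` must cover the same cells")
  if (!is.null(names(subtypes)) && !is.null(names(phenotypes))) {
    if (!setequal(names(subtypes), names(phenotypes)))
      stop("`subtypes` and `phenotypes` must cover the same cells")
    phenotypes <- phenotypes[names(subtypes)]
  }
  counts <- table(phenotype = as.character(phenotypes),
                  subtype = as.character(subtypes))
  out <- list(counts = counts,
              p_subtype_given_phenotype = prop.table(counts, margin = 1),
              p_phenotype_given_subtype = prop.table(counts, margin = 2),
              phenotype_totals = rowSums(counts),
              subtype_totals = colSums(counts))
  class(out) <- "scq_crosstab"
  out
}

#' @export
print.scq_crosstab <- function(x, ...) {
  cat("P(subtype | phenotype):\n")
  print(round(x$p_subtype_given_phenotype, 3))
  invisible(x)
}

#' Write a mapping result to CSV
#'
#' @param mapping An `"scq_mapping"` (optionally with `subtype`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_mapping <- function(mapping, path) {
  utils::write.csv(as.data.frame(mapping), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Align a per-cell label vector with the matrix rows: by name when named,
# by position otherwise.
align_cell_labels <- function(labels, cell_ids, what) {
  if (!is.null(names(labels))) {
    missing <- setdiff(cell_ids, names(labels))
    if (length(missing) > 0)
      stop(sprintf("`%s` lacks label(s) for cell(s): %s", what,
                   paste(utils::head(missing, 5), collapse = ", ")))
    labels[cell_ids]
  } else {
    if (length(labels) != length(cell_ids))
      stop(sprintf("`%s` must have one label per cell", what))
    labels
  }
}
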