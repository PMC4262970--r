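#' Specification of a synthetic single-cell qPCR study
#'
#' Bundles the parameters of the generator that emulates the data regime
#' of a multiplex single-cell qPCR study of leukemic heterogeneity: a
#' reference hierarchy tree whose node centroids drift along edges in the
#' marker-panel genes, per-cell Gaussian noise in log2 space,
#' detection-limit censoring at a background Ct, two designated branches
#' with planted differentially expressed genes, and latent-factor
#' co-expression modules. See the methods vignette for what the model
#' does and does not emulate.
#'
#' Gene roles are assigned deterministically in column order: the first
#' `panel_size` genes form the marker panel (lineage drift), the next
#' `n_de_genes` carry the planted branch-A shift, the following blocks
#' belong to the latent-factor modules, and the remainder are flat
#' background genes.
#'
#' @param n_nodes Number of tree nodes (default 56).
#' @param n_genes Number of genes (default 175).
#' @param panel_size Marker-panel size (default 33).
#' @param cells_per_node Cells generated per node (default 20).
#' @param centroid_drift_sd Gaussian drift of panel-gene centroids per
#'   tree edge, log2 units (default 2).
#' @param noise_sd Per-cell Gaussian noise, log2 units (default 1).
#' @param background_ct Background threshold cycle (default 28).
#' @param n_de_genes Planted differential genes (default 14).
#' @param de_shift Log2 shift added to DE genes in branch-A cells
#'   (default 4).
#' @param modules List of module specs, each
#'   `list(size =, loading =, factor_sd =)`; default two modules of 25
#'   and 20 genes with loading 2 and unit factor sd.
#' @param baseline_range Range of the uniform per-gene baseline log2
#'   level (default `c(4, 12)`).
#' @param drift_genes `"panel"` (default) drifts only the marker panel;
#'   `"all"` drifts every gene.
#' @param phenotype_fidelity Probability that a branch-A cell carries the
#'   branch-A-enriched immunophenotype (branch-B cells carry it with the
#'   complementary probability; unassigned-branch cells with 0.5).
#'   Default 0.8.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return List of class `"scq_spec"`, including the derived per-gene
#'   role table `gene_roles`.
#' @export
synthetic_spec <- function(n_nodes = 56, n_genes = 175, panel_size = 33,
                           cells_per_node = 20, centroid_drift_sd = 2,
                           noise_sd = 1, background_ct = 28,
                           n_de_genes = 14, de_shift = 4,
                           modules = list(
                             list(size = 25, loading = 2, factor_sd = 1),
                             list(size = 20, loading = 2, factor_sd = 1)),
                           baseline_range = c(4, 12),
                           drift_genes = c("panel", "all"),
                           phenotype_fidelity = 0.8, seed = 1) {
  drift_genes <- match.arg(drift_genes)
  if (n_nodes < 2) stop("`n_nodes` must be at least 2")
  if (panel_size > n_genes) stop("`panel_size` exceeds `n_genes`")
  if (centroid_drift_sd < 0 || noise_sd < 0)
    stop("standard deviations must be non-negative")
  if (background_ct <= 0) stop("`background_ct` must be positive")
  mod_sizes <- vapply(modules, function(m) as.integer(m$size), 0L)
  if (panel_size + n_de_genes + sum(mod_sizes) > n_genes)
    stop("panel, DE and module genes exceed the gene universe")
  gene_ids <- sprintf("G%03d", seq_len(n_genes))
  role <- rep("background", n_genes)
  role[seq_len(panel_size)] <- "panel"
  de_idx <- panel_size + seq_len(n_de_genes)
  role[de_idx] <- "de"
  module <- integer(n_genes)
  at <- panel_size + n_de_genes
  for (mi in seq_along(modules)) {
    idx <- at + seq_len(mod_sizes[mi])
    role[idx] <- "module"
    module[idx] <- mi
    at <- at + mod_sizes[mi]
  }
  spec <- list(n_nodes = n_nodes, n_genes = n_genes, panel_size = panel_size,
               cells_per_node = cells_per_node,
               centroid_drift_sd = centroid_drift_sd, noise_sd = noise_sd,
               background_ct = background_ct, n_de_genes = n_de_genes,
               de_shift = de_shift, modules = modules,
               baseline_range = baseline_range, drift_genes = drift_genes,
               phenotype_fidelity = phenotype_fidelity, seed = seed,
               gene_roles = data.frame(gene_id = gene_ids, role = role,
                                       de = role == "de",
                                       shift = ifelse(role == "de",
                                                      de_shift, 0),
                                       module = module))
  class(spec) <- "scq_spec"
  spec
}

#' Generate a synthetic reference tree
#'
#' Builds a random tree by sequential random-parent attachment (nodes 2
#' and 3 attach to the root and seed the two designated branches "A" and
#' "B"; later nodes attach to a uniformly chosen earlier node and inherit
#' its branch label). The root centroid is a uniform baseline log2
#' profile; each child's centroid equals its parent's plus Gaussian drift
#' in the drifting gene set, clamped to stay strictly below the
#' background so a noise-free cell always yields a valid positive Ct.
#'
#' @param spec An `"scq_spec"`.
#' @param seed Seed for the tree draw (default `spec$seed`). Keeping this
#'   fixed while varying the cell seed regenerates cell populations on
#'   one fixed reference hierarchy.
#' @return An `"scq_tree"` with branch labels `"A"`, `"B"`, `"other"`.
#' @export
generate_tree <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "scq_spec"))
  withr::with_seed(seed, {
    n <- spec$n_nodes
    ids <- sprintf("N%0*d", nchar(n), seq_len(n))
    drift_idx <- if (spec$drift_genes == "panel")
      which(spec$gene_roles$role == "panel") else seq_len(spec$n_genes)
    baseline <- stats::runif(spec$n_genes, spec$baseline_range[1],
                             spec$baseline_range[2])
    cent <- matrix(0, n, spec$n_genes,
                   dimnames = list(ids, spec$gene_roles$gene_id))
    cent[1, ] <- baseline
    parent <- integer(n)
    branch <- character(n)
    branch[1] <- "other"
    for (i in seq(2, n)) {
      parent[i] <- if (i <= 3) 1L else sample.int(i - 1, 1)
      cent[i, ] <- cent[parent[i], ]
      cent[i, drift_idx] <- cent[i, drift_idx] +
        stats::rnorm(length(drift_idx), 0, spec$centroid_drift_sd)
      cent[i, ] <- pmin(pmax(cent[i, ], 0), spec$background_ct - 1)
      branch[i] <- if (i == 2) "A" else if (i == 3) "B" else branch[parent[i]]
    }
    edges <- cbind(node_a = ids[parent[-1]], node_b = ids[-1])
    reference_tree(cent, edges, branch = stats::setNames(branch, ids))
  })
}

#' Generate synthetic cells with planted ground truth
#'
#' Each node of the tree emits `cells_per_node` cells. A cell's log2
#' expression is its node centroid plus Gaussian noise, plus the planted
#' DE shift (DE genes, branch-A cells only), plus the latent-factor
#' module term (`loading * z_cell` per module, `z` drawn once per cell).
#' Values are converted to Ct space (`Ct = background - value`) where the
#' detection limit censors them: values at or below zero become
#' `Ct >= background`, which decodes to zero expression. An
#' immunophenotype correlated with the branch is drawn per cell.
#'
#' @param tree An `"scq_tree"` from [generate_tree()].
#' @param spec The `"scq_spec"` used to build the tree.
#' @param seed Seed for the cell draw (default `spec$seed`); vary it to
#'   obtain replicate cell populations on the same tree.
#' @return List of class `"scq_sim"`: `ct` (cells x genes Ct matrix),
#'   `truth` (list with `cells`: cell_id, node_id, branch, phenotype;
#'   `genes`: per-gene role / DE flag / shift / module), and `spec`.
#' @export
generate_cells <- function(tree, spec, seed = spec$seed) {
  stopifnot(inherits(spec, "scq_spec"), inherits(tree, "scq_tree"))
  withr::with_seed(seed, {
    ids <- tree_nodes(tree)
    n_cells <- length(ids) * spec$cells_per_node
    cell_ids <- sprintf("C%0*d", nchar(n_cells), seq_len(n_cells))
    node_of <- rep(ids, each = spec$cells_per_node)
    branch_of <- unname(tree$branch[node_of])
    value <- tree$centroids[node_of, , drop = FALSE]
    rownames(value) <- cell_ids
    if (spec$noise_sd > 0)
      value <- value + matrix(stats::rnorm(length(value), 0, spec$noise_sd),
                              nrow(value), ncol(value))
    if (spec$n_de_genes > 0) {
      de_cols <- which(spec$gene_roles$de)
      in_a <- branch_of == "A"
      value[in_a, de_cols] <- value[in_a, de_cols] + spec$de_shift
    }
    for (mi in seq_along(spec$modules)) {
      ms <- spec$modules[[mi]]
      z <- stats::rnorm(n_cells, 0, ms$factor_sd)
      cols <- which(spec$gene_roles$module == mi)
      value[, cols] <- value[, cols] + ms$loading * z
    }
    ct <- spec$background_ct - value
    ct <- pmax(ct, 0.25)                  # instrument floor, keeps Ct > 0
    p_a <- ifelse(branch_of == "A", spec$phenotype_fidelity,
                  ifelse(branch_of == "B", 1 - spec$phenotype_fidelity, 0.5))
    phenotype <- ifelse(stats::runif(n_cells) < p_a, "Kit+CD24-", "CD24+")
    structure(list(
      ct = ct,
      truth = list(cells = data.frame(cell_id = cell_ids, node_id = node_of,
                                      branch = branch_of,
                                      phenotype = phenotype),
                   genes = spec$gene_roles),
      spec = spec), class = "scq_sim")
  })
}

#' @export
print.scq_sim <- function(x, ...) {
  cat(sprintf(
    "scq_sim: %d cells x %d genes on %d nodes (noise sd %g, seed-reproducible)\n",
    nrow(x$ct), ncol(x$ct), length(unique(x$truth$cells$node_id)),
    x$spec$noise_sd))
  invisible(x)
}

#' Score pipeline outputs against planted ground truth
#'
#' Computes whichever recovery metrics the supplied outputs allow:
#' mapping accuracy (exact and within `max_steps` tree edges of the true
#' node), subtype-label accuracy, differential-expression precision and
#' recall against the planted genes, and per-planted-module best Jaccard
#' overlap with the detected modules.
#'
#' @param truth The `truth` element of an [generate_cells()] result.
#' @param tree The `"scq_tree"` the cells were generated from (needed for
#'   step distances).
#' @param mapping Optional `"scq_mapping"` (with `subtype` column for
#'   subtype accuracy).
#' @param de Optional `"scq_de"` table.
#' @param network Optional `"scq_network"` (or named module label
#'   vector).
#' @param max_steps Proximity radius in tree edges (default 2).
#' @return List with any of `mapping_exact`, `mapping_within`,
#'   `subtype_accuracy`, `de_precision` (`NA` when nothing was flagged),
#'   `de_recall`, `de_flagged`, `module_jaccard` (one value per planted
#'   module).
#' @export
truth_metrics <- function(truth, tree, mapping = NULL, de = NULL,
                          network = NULL, max_steps = 2) {
  out <- list()
  if (!is.null(mapping)) {
    idx <- match(mapping$cell_id, truth$cells$cell_id)
    if (anyNA(idx))
      stop("mapping contains cell(s) absent from the truth")
    true_node <- truth$cells$node_id[idx]
    steps <- tree_distance(tree, mapping$node_id, true_node)
    out$mapping_exact <- mean(steps == 0)
    out$mapping_within <- mean(steps <= max_steps)
    if (!is.null(mapping$subtype))
      out$subtype_accuracy <- mean(mapping$subtype == truth$cells$branch[idx])
  }
  if (!is.null(de)) {
    planted <- truth$genes$gene_id[truth$genes$de]
    tested <- as.character(de$gene)
    flagged <- tested[de$significant]
    tp <- length(intersect(flagged, planted))
    out$de_flagged <- length(flagged)
    out$de_precision <- if (length(flagged) == 0) NA_real_
                        else tp / length(flagged)
    planted_tested <- intersect(planted, tested)
    out$de_recall <- if (length(planted_tested) == 0) NA_real_
                     else length(intersect(flagged, planted_tested)) /
                          length(planted_tested)
  }
  if (!is.null(network)) {
    labels <- module_labels(network)
    planted_mods <- sort(unique(truth$genes$module[truth$genes$module > 0]))
    jac <- vapply(planted_mods, function(mi) {
      pg <- truth$genes$gene_id[truth$genes$module == mi]
      detected <- sort(unique(labels[labels > 0]))
      if (length(detected) == 0) return(0)
      max(vapply(detected, function(d) {
        dg <- names(labels)[labels == d]
        length(intersect(pg, dg)) / length(union(pg, dg))
      }, 0))
    }, 0)
    out$module_jaccard <- stats::setNames(jac, paste0("module", planted_mods))
  }
  out
}
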