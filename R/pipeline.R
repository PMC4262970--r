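#' Assemble a pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with the study's
#' defaults: background Ct 28, 33-gene panel, 100 resampled panels,
#' 2-step proximity, DE cutoffs adjusted p < 1e-5 and |LFC| >= 2, and
#' scale-free fit threshold 0.85. Input is either a synthetic
#' specification (`spec`) or file paths (`ct_csv`, `nodes_csv`,
#' `edges_csv`, optionally `annotations_csv` with columns `cell_id`,
#' `original`, `phenotype`).
#'
#' @param spec An `"scq_spec"` for synthetic runs, or `NULL` to read
#'   files.
#' @param ct_csv,nodes_csv,edges_csv,annotations_csv Input paths (file
#'   mode).
#' @param background_ct Background threshold cycle (default 28).
#' @param panel Optional explicit gene panel; default: all shared genes.
#' @param panel_size,n_lists Random-panel validation settings (defaults
#'   33 and 100; `n_lists = 0` skips the stage).
#' @param max_steps Concordance radius in tree edges (default 2).
#' @param de_groups Two branch labels to compare (default `c("A", "B")`,
#'   the synthetic generator's leukemic branches).
#' @param alpha,lfc_min DE cutoffs (defaults `1e-5`, 2).
#' @param test_mode Rank-sum mode: `"auto"`, `"exact"` or `"approx"`.
#' @param beta Soft threshold: a whole number for a fixed exponent
#'   (default 6) or `"auto"` for smallest-qualifying selection.
#' @param r2_threshold,n_bins,min_module_size,cut_height Network
#'   parameters (defaults 0.85, 10, 10, 0.99).
#' @param exclude_panel_genes Run DE and networks on the non-panel genes
#'   (default `TRUE`; the marker panel defines the hierarchy, so subtype
#'   programs are sought among the remaining genes — see the vignette).
#' @param seed Master seed for every stochastic stage (default 1).
#' @return List of class `"scq_config"`.
#' @export
pipeline_config <- function(spec = NULL, ct_csv = NULL, nodes_csv = NULL,
                            edges_csv = NULL, annotations_csv = NULL,
                            background_ct = 28, panel = NULL,
                            panel_size = 33, n_lists = 100, max_steps = 2,
                            de_groups = c("A", "B"), alpha = 1e-5,
                            lfc_min = 2, test_mode = "auto", beta = 6,
                            r2_threshold = 0.85, n_bins = 10,
                            min_module_size = 10, cut_height = 0.99,
                            exclude_panel_genes = TRUE, seed = 1) {
  cfg <- list(spec = spec, ct_csv = ct_csv, nodes_csv = nodes_csv,
              edges_csv = edges_csv, annotations_csv = annotations_csv,
              background_ct = background_ct, panel = panel,
              panel_size = panel_size, n_lists = n_lists,
              max_steps = max_steps, de_groups = de_groups, alpha = alpha,
              lfc_min = lfc_min, test_mode = test_mode, beta = beta,
              r2_threshold = r2_threshold, n_bins = n_bins,
              min_module_size = min_module_size,
              cut_height = cut_height,
              exclude_panel_genes = exclude_panel_genes, seed = seed)
  class(cfg) <- "scq_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (is.null(cfg$spec)) {
    needed <- c("ct_csv", "nodes_csv", "edges_csv")
    missing <- needed[vapply(needed, function(f) is.null(cfg[[f]]), TRUE)]
    if (length(missing) > 0)
      stop("config lacks input file(s): ", paste(missing, collapse = ", "))
    absent <- Filter(function(f) !file.exists(cfg[[f]]), needed)
    if (length(absent) > 0)
      stop("input file(s) not found: ",
           paste(unlist(cfg[absent]), collapse = ", "))
  } else if (!inherits(cfg$spec, "scq_spec")) {
    stop("`spec` must be an 'scq_spec'")
  }
  if (length(cfg$de_groups) != 2)
    stop("`de_groups` must name exactly two branches")
  if (!(identical(cfg$beta, "auto") ||
        (is.numeric(cfg$beta) && cfg$beta >= 1)))
    stop("`beta` must be 'auto' or a whole number >= 1")
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; a `spec:` block with
#' [synthetic_spec()] arguments requests a synthetic run.
#'
#' @param path YAML file path.
#' @return An `"scq_config"`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$spec)) y$spec <- do.call(synthetic_spec, y$spec)
  do.call(pipeline_config, y)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data generation or ingestion, Ct preprocessing,
#' projection onto the reference tree, concordance and (optionally)
#' random-panel validation, subtype assignment and phenotype
#' cross-tabulation, differential expression between the two configured
#' branches, co-expression network construction for the pooled and
#' per-branch cell subsets, and cross-network module comparison. Every
#' intermediate is written to `out_dir` and a machine-readable summary to
#' `summary.json`. The run is a pure function of (inputs, config): a
#' rerun with the same config reproduces the summary byte for byte.
#'
#' @param config An `"scq_config"` from [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return The summary, invisibly (a named list mirroring
#'   `summary.json`).
#' @export
run_all <- function(config, out_dir) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(seed = config$seed)

  # --- inputs -------------------------------------------------------------
  truth <- NULL
  phenotypes <- NULL
  original <- NULL
  if (!is.null(config$spec)) {
    spec <- config$spec
    tree <- generate_tree(spec)
    sim <- generate_cells(tree, spec, seed = spec$seed)
    ct <- sim$ct
    truth <- sim$truth
    original <- stats::setNames(truth$cells$node_id, truth$cells$cell_id)
    phenotypes <- stats::setNames(truth$cells$phenotype,
                                  truth$cells$cell_id)
    background <- spec$background_ct
    write_cells_csv(ct, file.path(out_dir, "ct.csv"))
    write_reference_tree(tree, file.path(out_dir, "nodes.csv"),
                         file.path(out_dir, "edges.csv"))
    utils::write.csv(truth$cells, file.path(out_dir, "annotations.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(truth$genes, file.path(out_dir, "gene_truth.csv"),
                     row.names = FALSE, quote = FALSE)
  } else {
    background <- config$background_ct
    ct <- read_ct_matrix(config$ct_csv, background)
    tree <- read_reference_tree(config$nodes_csv, config$edges_csv)
    if (!is.null(config$annotations_csv)) {
      ann <- utils::read.csv(config$annotations_csv, check.names = FALSE)
      if ("original" %in% names(ann))
        original <- stats::setNames(as.character(ann$original),
                                    as.character(ann$cell_id))
      if ("phenotype" %in% names(ann))
        phenotypes <- stats::setNames(as.character(ann$phenotype),
                                      as.character(ann$cell_id))
    }
  }
  summary$n_cells <- nrow(ct)
  summary$n_genes <- ncol(ct)

  # --- preprocess ---------------------------------------------------------
  expr <- ct_to_expression(ct, background)
  write_cells_csv(expr, file.path(out_dir, "expression_log2.csv"))

  # --- mapping ------------------------------------------------------------
  panel <- config$panel
  if (is.null(panel)) {
    panel <- if (!is.null(config$spec))   # synthetic runs: the marker panel
      config$spec$gene_roles$gene_id[config$spec$gene_roles$role == "panel"]
    else intersect(colnames(expr), colnames(tree$centroids))
  }
  mapping <- suppressMessages(
    map_cells(expr, tree, panel = panel, original = original))
  summary$panel_size <- length(panel)
  if (!is.null(original)) {
    cc <- concordance(mapping, tree, max_steps = config$max_steps)
    summary$concordance <- list(fraction_exact = cc$fraction_exact,
                                fraction_within = cc$fraction_within,
                                max_steps = cc$max_steps)
  }
  if (config$n_lists > 0 && !is.null(original) &&
      config$panel_size <= length(panel)) {
    pv <- random_panel_validation(expr, tree, original,
                                  panel_size = config$panel_size,
                                  n_lists = config$n_lists,
                                  max_steps = config$max_steps,
                                  seed = config$seed)
    utils::write.csv(pv$per_panel,
                     file.path(out_dir, "panel_validation.csv"),
                     row.names = FALSE, quote = FALSE)
    summary$panel_validation <- list(panel_size = pv$panel_size,
                                     n_lists = nrow(pv$per_panel),
                                     mean_exact = pv$mean_exact,
                                     mean_within = pv$mean_within)
  }

  # --- subtypes -----------------------------------------------------------
  mapping <- assign_subtypes(mapping, tree)
  write_mapping(mapping, file.path(out_dir, "mapping.csv"))
  sizes <- table(mapping$subtype)
  summary$subtype_sizes <- as.list(stats::setNames(as.integer(sizes),
                                                   names(sizes)))
  if (!is.null(phenotypes)) {
    xt <- phenotype_crosstab(
      stats::setNames(mapping$subtype, mapping$cell_id), phenotypes)
    utils::write.csv(as.data.frame(xt$counts),
                     file.path(out_dir, "phenotype_crosstab.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  # --- differential expression -------------------------------------------
  grp_a <- mapping$cell_id[mapping$subtype == config$de_groups[1]]
  grp_b <- mapping$cell_id[mapping$subtype == config$de_groups[2]]
  if (length(grp_a) == 0 || length(grp_b) == 0)
    stop(sprintf("differential expression: no cells mapped to branch '%s'",
                 config$de_groups[if (length(grp_a) == 0) 1 else 2]))
  analysis_genes <- colnames(expr)
  if (isTRUE(config$exclude_panel_genes))
    analysis_genes <- setdiff(analysis_genes, panel)
  de <- differential_genes(expr, grp_a, grp_b, alpha = config$alpha,
                           lfc_min = config$lfc_min, genes = analysis_genes,
                           mode = config$test_mode)
  write_de(de, file.path(out_dir, "de.csv"))
  summary$de <- list(
    n_tested = nrow(de), n_significant = sum(de$significant),
    top_genes = utils::head(de$gene[de$significant], 10),
    top_lfc = if (any(de$significant)) de$lfc[de$significant][1] else NULL)

  # --- co-expression networks --------------------------------------------
  beta <- if (identical(config$beta, "auto")) NULL else config$beta
  net_of <- function(cells) build_network(
    expr, cells = cells, genes = analysis_genes, beta = beta,
    r2_threshold = config$r2_threshold, n_bins = config$n_bins,
    min_module_size = config$min_module_size,
    cut_height = config$cut_height)
  nets <- list(all = net_of(c(grp_a, grp_b)),
               group_a = net_of(grp_a),
               group_b = net_of(grp_b))
  summary$networks <- lapply(nets, function(nt) {
    ms <- table(nt$modules[nt$modules > 0])
    list(n_genes = length(nt$genes), n_cells = nt$n_cells, beta = nt$beta,
         scale_free_r2 = nt$scale_free_r2,
         module_sizes = as.list(stats::setNames(as.integer(ms), names(ms))),
         unassigned = sum(nt$modules == 0))
  })
  for (nm in names(nets)) write_network(nets[[nm]], file.path(out_dir, nm))
  ov <- module_overlap(nets$group_a, nets$group_b)
  utils::write.csv(ov$pairs, file.path(out_dir, "module_overlap.csv"),
                   row.names = FALSE, quote = FALSE)
  summary$module_overlap <- ov$pairs

  # --- ground-truth recovery ---------------------------------------------
  if (!is.null(truth)) {
    tm <- truth_metrics(truth, tree, mapping = mapping, de = de,
                        network = nets$group_a,
                        max_steps = config$max_steps)
    tm$module_jaccard <- as.list(tm$module_jaccard)
    summary$truth_metrics <- tm
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(summary)
}
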