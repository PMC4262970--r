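#' Pearson correlation matrix between genes
#'
#' Computed on linear-scale expression (anti-logged), the input to the
#' power adjacency. Zero-variance genes are rejected: they must be
#' filtered out first (see [build_network()], which does this and logs the
#' dropped genes).
#'
#' @param expr Cells x genes matrix on the linear scale (an `"scq_expr"`
#'   with `scale = "linear"`, or a plain matrix).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(expr) {
  if (inherits(expr, "scq_expr") && expr_scale(expr) != "linear")
    stop("`expr` must be on the linear scale (see to_linear())")
  m <- unclass(as.matrix(expr))
  if (nrow(m) < 3) stop("need at least 3 cells")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance gene(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  cc <- stats::cor(m)
  cc[cc > 1] <- 1; cc[cc < -1] <- -1
  diag(cc) <- 1
  cc
}

#' Power adjacency of an unsigned weighted network
#'
#' Connection strength `a_ij = |cor(x_i, x_j)|^beta` between every pair of
#' genes; soft thresholding rather than a hard correlation cutoff. The
#' diagonal is set to 1 by convention and excluded from connectivity.
#'
#' @param cor_mat Symmetric correlation matrix (entries in `[-1, 1]`).
#' @param beta Soft-threshold exponent: whole number `>= 1`.
#' @return Adjacency matrix with entries in `[0, 1]`, unit diagonal.
#' @export
power_adjacency <- function(cor_mat, beta) {
  if (!is.numeric(beta) || length(beta) != 1 || beta < 1 ||
      abs(beta - round(beta)) > 1e-8)
    stop("`beta` must be a whole number >= 1")
  a <- abs(cor_mat)^beta
  diag(a) <- 1
  a
}

#' Network connectivity
#'
#' Per-gene connectivity `k_i = sum_{j != i} a_ij` (row sums of the
#' adjacency excluding the diagonal).
#'
#' @param adjacency Adjacency matrix from [power_adjacency()].
#' @return Numeric vector `k`, named by gene.
#' @export
connectivity <- function(adjacency) {
  rowSums(adjacency) - diag(adjacency)
}

#' Scale-free topology fit index
#'
#' Bins the connectivity values `k` into `n_bins` equal-width bins over
#' `[min(k), max(k)]`, drops empty bins, and returns the squared Pearson
#' correlation between `log10(p(k))` and `log10(mean k per bin)` — the
#' model-fitting index R^2 that is near 1 when the connectivity
#' distribution follows a power law.
#'
#' @param k Connectivity vector.
#' @param n_bins Number of equal-width bins (default 10).
#' @return R^2 as a single number with attribute `"bins"` (a `data.frame`
#'   of bin mean `k`, counts and frequencies). A fit through only two
#'   usable bins is degenerately 1 and triggers a warning.
#' @export
scale_free_fit <- function(k, n_bins = 10) {
  k <- as.numeric(k)
  if (length(k) < 2 || diff(range(k)) == 0)
    stop("scale-free fit undefined: connectivity values are all identical")
  breaks <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- findInterval(k, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  tab <- tapply(k, factor(bin, levels = seq_len(n_bins)), length)
  counts <- ifelse(is.na(tab), 0L, tab)
  mean_k <- tapply(k, factor(bin, levels = seq_len(n_bins)), mean)
  keep <- counts > 0 & !is.na(mean_k) & mean_k > 0
  if (sum(keep) < 2)
    stop("scale-free fit needs at least 2 non-empty bins")
  if (sum(keep) == 2)
    warning("only 2 usable bins: R^2 is degenerately 1")
  pk <- counts[keep] / length(k)
  r2 <- stats::cor(log10(pk), log10(mean_k[keep]))^2
  structure(r2, bins = data.frame(mean_k = as.numeric(mean_k[keep]),
                                  count = as.integer(counts[keep]),
                                  p_k = as.numeric(pk)))
}

#' Choose the soft-threshold exponent
#'
#' Scans candidate exponents in order and returns the smallest `beta`
#' whose power-adjacency network attains a scale-free fit
#' `R^2 > r2_threshold`. The full scan table is returned alongside (and
#' attached to the error condition when no candidate qualifies, so the
#' caller can inspect or relax the threshold).
#'
#' @param cor_mat Gene correlation matrix.
#' @param candidates Exponents to try, in order (default `1:20`).
#' @param r2_threshold Required fit (default 0.85).
#' @param n_bins Bins for [scale_free_fit()] (default 10).
#' @return List with `beta`, `r2` and `scan` (`data.frame` of `beta`,
#'   `r2`).
#' @export
choose_beta <- function(cor_mat, candidates = 1:20, r2_threshold = 0.85,
                        n_bins = 10) {
  if (length(candidates) == 0) stop("`candidates` must be non-empty")
  scan <- data.frame(beta = as.numeric(candidates), r2 = NA_real_)
  for (i in seq_along(candidates)) {
    b <- candidates[i]
    r2 <- tryCatch(
      suppressWarnings(
        as.numeric(scale_free_fit(
          connectivity(power_adjacency(cor_mat, b)), n_bins = n_bins))),
      error = function(e) NA_real_)
    scan$r2[i] <- r2
    if (!is.na(r2) && r2 > r2_threshold)
      return(list(beta = b, r2 = r2, scan = scan[seq_len(i), ]))
  }
  cond <- structure(
    class = c("scq_no_beta", "error", "condition"),
    list(message = sprintf(
           "no candidate beta reaches R^2 > %.3g (best %.3f at beta %s)",
           r2_threshold, max(scan$r2, na.rm = TRUE),
           scan$beta[which.max(scan$r2)]),
         call = sys.call(-1), scan = scan))
  stop(cond)
}

#' Topological overlap matrix
#'
#' Similarity counting shared network neighbours:
#' `TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' for `i != j`, with `TOM_ii = 1`. Genes connected to roughly the same
#' set of genes have high topological overlap even if their direct
#' connection is modest; `1 - TOM` is the dissimilarity used for module
#' detection.
#'
#' @param adjacency Valid adjacency matrix (symmetric, entries in
#'   `[0, 1]`, unit diagonal).
#' @return Symmetric TOM with entries in `[0, 1]` and unit diagonal.
#' @export
topological_overlap <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (any(a < 0) || any(a > 1) || any(abs(diag(a) - 1) > 1e-10) ||
      !isTRUE(all.equal(a, t(a), tolerance = 1e-10)))
    stop("`adjacency` must be symmetric with entries in [0,1] and unit diagonal")
  k <- connectivity(a)
  L <- a %*% a                 # L_ij includes u = i and u = j, each a_ij
  num <- L - a                 # = sum_{u != i,j} a_iu a_uj + a_ij (diag = 1)
  den <- outer(k, k, pmin) + 1 - a
  if (any(den[upper.tri(den)] <= 0))
    stop("non-positive TOM denominator: adjacency is not valid")
  tom <- num / den
  diag(tom) <- 1
  tom[tom < 0] <- 0; tom[tom > 1] <- 1
  tom <- (tom + t(tom)) / 2    # exact symmetry against rounding
  dimnames(tom) <- dimnames(a)
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Genes are clustered by average linkage on the dissimilarity `1 - TOM`;
#' the dendrogram is cut at the fixed dissimilarity height `cut_height`,
#' and resulting clusters smaller than `min_module_size` are left
#' unassigned (label 0). Modules are numbered 1, 2, ... by decreasing
#' size (ties by first gene position). This is a deterministic static-cut
#' variant of dynamic tree cutting (the `cutreeStatic` convention); see
#' the methods vignette for the rationale.
#'
#' @param tom Topological overlap matrix.
#' @param min_module_size Smallest cluster kept as a module (default 10).
#' @param cut_height Dissimilarity height at which the dendrogram is cut
#'   (default 0.99): genes merging below this `1 - TOM` level form a
#'   candidate module.
#' @return Integer vector of module labels named by gene (0 =
#'   unassigned), with the dendrogram attached as attribute
#'   `"dendrogram"`.
#' @export
detect_modules <- function(tom, min_module_size = 10, cut_height = 0.99) {
  n <- nrow(tom)
  if (is.null(rownames(tom)))
    rownames(tom) <- colnames(tom) <- paste0("g", seq_len(n))
  if (n < min_module_size) {
    warning(sprintf(
      "fewer genes (%d) than min_module_size (%d): all unassigned",
      n, min_module_size))
    return(structure(stats::setNames(integer(n), rownames(tom)),
                     dendrogram = NULL))
  }
  d <- 1 - tom
  d[d < 0] <- 0
  diag(d) <- 0
  hc <- average_linkage(d)
  # UPGMA heights are monotone in exact arithmetic; repair float jitter so
  # cutree accepts them
  hc$height <- cummax(hc$height)
  raw <- if (max(hc$height) <= cut_height)
    stats::setNames(rep(1L, n), rownames(tom))  # everything merges below cut
  else stats::cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_module_size]
  labels <- stats::setNames(integer(n), rownames(tom))
  if (length(keep) > 0) {
    ord <- keep[order(-sizes[keep],
                      vapply(keep, function(cl) min(which(raw == cl)), 0L))]
    for (i in seq_along(ord)) labels[raw == ord[i]] <- i
  }
  structure(labels, dendrogram = hc)
}

#' Build a weighted co-expression network for a cell subset
#'
#' The full pipeline for one network: restrict to a cell subset, anti-log
#' to the linear scale, drop zero-variance genes (logged in the result),
#' Pearson correlation, soft-threshold adjacency (fixed `beta` or the
#' smallest exponent with scale-free fit `R^2 > r2_threshold`),
#' topological overlap, and module detection. Deterministic given its
#' inputs.
#'
#' @param expr An `"scq_expr"` log2 matrix.
#' @param cells Cell ids (rows) to use; `NULL` keeps all.
#' @param genes Gene ids (columns) to consider; `NULL` keeps all.
#' @param beta Fixed soft-threshold exponent, or `NULL` to select via
#'   [choose_beta()].
#' @param r2_threshold,n_bins Passed to [choose_beta()] /
#'   [scale_free_fit()].
#' @param min_module_size,cut_height Passed to [detect_modules()].
#' @return Object of class `"scq_network"`: list with `genes`,
#'   `dropped_genes`, `n_cells`, `cor`, `beta`, `beta_scan` (when
#'   auto-selected), `adjacency`, `k`, `scale_free_r2`, `tom`, `modules`,
#'   `dendrogram`, `params`.
#' @export
build_network <- function(expr, cells = NULL, genes = NULL, beta = NULL,
                          r2_threshold = 0.85, n_bins = 10,
                          min_module_size = 10, cut_height = 0.99) {
  sub <- subset_expr(expr, cells = cells, genes = genes)
  if (nrow(sub) < 3) stop("cell subset must contain at least 3 cells")
  lin <- to_linear(sub)
  m <- unclass(lin)
  sds <- apply(m, 2, stats::sd)
  dropped <- colnames(m)[sds == 0]
  if (length(dropped) == ncol(m) || sum(sds > 0) < 2)
    stop("fewer than 2 genes with non-zero variance in this subset")
  m <- m[, sds > 0, drop = FALSE]
  cc <- pearson_matrix(m)
  scan <- NULL
  if (is.null(beta)) {
    sel <- choose_beta(cc, r2_threshold = r2_threshold, n_bins = n_bins)
    beta <- sel$beta
    scan <- sel$scan
  }
  adj <- power_adjacency(cc, beta)
  k <- connectivity(adj)
  r2 <- tryCatch(as.numeric(suppressWarnings(scale_free_fit(k, n_bins))),
                 error = function(e) NA_real_)
  tom <- topological_overlap(adj)
  mods <- detect_modules(tom, min_module_size = min_module_size,
                         cut_height = cut_height)
  structure(list(genes = colnames(m),
                 dropped_genes = dropped,
                 n_cells = nrow(m),
                 cor = cc,
                 beta = beta,
                 beta_scan = scan,
                 adjacency = adj,
                 k = k,
                 scale_free_r2 = r2,
                 tom = tom,
                 modules = stats::setNames(as.integer(mods), names(mods)),
                 dendrogram = attr(mods, "dendrogram"),
                 params = list(r2_threshold = r2_threshold, n_bins = n_bins,
                               min_module_size = min_module_size,
                               cut_height = cut_height)),
            class = "scq_network")
}

#' @export
print.scq_network <- function(x, ...) {
  ms <- table(x$modules[x$modules > 0])
  cat(sprintf(
    "scq_network: %d genes (%d dropped), %d cells, beta = %s, R^2 = %.3f\n",
    length(x$genes), length(x$dropped_genes), x$n_cells,
    format(x$beta), x$scale_free_r2))
  if (length(ms) > 0)
    cat("modules:", paste(sprintf("%s (n=%d)", names(ms), ms),
                          collapse = ", "),
        sprintf("; unassigned %d\n", sum(x$modules == 0)))
  else cat("no modules detected\n")
  invisible(x)
}

#' Compare module memberships of two networks
#'
#' For every pair of modules (one from each network): intersection size,
#' Jaccard index, fraction of the first module contained in the second,
#' and explicit shared gene lists — the accounting used to ask whether a
#' module of one cell subset's network is retained or lost in another's.
#'
#' @param net_a,net_b `"scq_network"` objects, or bare named integer
#'   label vectors as returned by [detect_modules()].
#' @return List of class `"scq_module_overlap"`: `pairs` (`data.frame`
#'   with columns `module_a`, `module_b`, `size_a`, `size_b`,
#'   `intersection`, `jaccard`, `fraction_a_in_b`) and `genes` (named
#'   list of shared-gene vectors, one per pair).
#' @export
module_overlap <- function(net_a, net_b) {
  la <- module_labels(net_a); lb <- module_labels(net_b)
  mods_a <- sort(unique(la[la > 0])); mods_b <- sort(unique(lb[lb > 0]))
  rows <- list(); genes <- list()
  for (i in mods_a) for (j in mods_b) {
    ga <- names(la)[la == i]; gb <- names(lb)[lb == j]
    shared <- intersect(ga, gb)
    key <- sprintf("A%d:B%d", i, j)
    rows[[key]] <- data.frame(
      module_a = i, module_b = j,
      size_a = length(ga), size_b = length(gb),
      intersection = length(shared),
      jaccard = length(shared) / length(union(ga, gb)),
      fraction_a_in_b = length(shared) / length(ga))
    genes[[key]] <- shared
  }
  pairs <- if (length(rows) > 0) do.call(rbind, c(rows, make.row.names = FALSE))
           else data.frame(module_a = integer(0), module_b = integer(0),
                           size_a = integer(0), size_b = integer(0),
                           intersection = integer(0), jaccard = numeric(0),
                           fraction_a_in_b = numeric(0))
  structure(list(pairs = pairs, genes = genes),
            class = "scq_module_overlap")
}

#' @export
print.scq_module_overlap <- function(x, ...) {
  print(x$pairs)
  invisible(x)
}

module_labels <- function(x) {
  if (inherits(x, "scq_network")) return(x$modules)
  if (is.numeric(x) && !is.null(names(x)))
    return(stats::setNames(as.integer(x), names(x)))
  stop("expected an 'scq_network' or a named integer label vector")
}

#' Export a network's matrices and modules to a directory
#'
#' Writes `adjacency.csv`, `tom.csv` (gene x gene matrices),
#' `modules.csv` (gene, module) and, when the exponent was auto-selected,
#' `beta_scan.csv`.
#'
#' @param net An `"scq_network"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_network <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gene_mat_csv <- function(m, path) {
    df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                     row.names = NULL)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  gene_mat_csv(net$adjacency, file.path(dir, "adjacency.csv"))
  gene_mat_csv(net$tom, file.path(dir, "tom.csv"))
  utils::write.csv(data.frame(gene = names(net$modules),
                              module = as.integer(net$modules)),
                   file.path(dir, "modules.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(net$beta_scan))
    utils::write.csv(net$beta_scan, file.path(dir, "beta_scan.csv"),
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
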