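#' Pearson-correlation distance between cells or genes
#'
#' Dissimilarity `d = 1 - cor(x, y)` (Pearson), the metric used for
#' unsupervised hierarchical clustering of expression profiles. Values lie
#' in `[0, 2]`: 0 for perfectly correlated vectors, 2 for perfectly
#' anti-correlated ones.
#'
#' @param expr Numeric matrix, rows = cells, columns = genes (an
#'   `"scq_expr"` matrix or plain matrix).
#' @param axis `"cells"` to compute distances between cells (across genes)
#'   or `"genes"` for distances between genes (across cells).
#' @return Symmetric dissimilarity matrix with zero diagonal.
#' @export
correlation_distance <- function(expr, axis = c("cells", "genes")) {
  axis <- match.arg(axis)
  m <- unclass(as.matrix(expr))
  x <- if (axis == "cells") t(m) else m   # columns = observations to compare
  if (nrow(x) < 3)
    stop("need at least 3 observations per vector to correlate")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance ", sub("s$", "", axis), "(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  d <- 1 - stats::cor(x)
  d[d < 0] <- 0
  d[d > 2] <- 2
  diag(d) <- 0
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerative clustering where the distance between two clusters is the
#' mean of all between-cluster pairwise dissimilarities. Exact ties in the
#' merge sequence are resolved toward the lexicographically smallest pair
#' of cluster indices, so the result is fully deterministic.
#'
#' @param dissim Symmetric, zero-diagonal, non-negative dissimilarity
#'   matrix (or a `dist` object).
#' @return An [stats::hclust] object (merge sequence, heights, leaf order).
#' @seealso [dendrogram_newick()], [merge_table()]
#' @export
average_linkage <- function(dissim) {
  if (inherits(dissim, "dist")) dissim <- as.matrix(dissim)
  dissim <- as.matrix(dissim)
  if (nrow(dissim) != ncol(dissim) ||
      !isTRUE(all.equal(dissim, t(dissim), tolerance = 1e-10)))
    stop("`dissim` must be a symmetric matrix")
  if (any(dissim < 0)) stop("`dissim` must be non-negative")
  if (any(abs(diag(dissim)) > 1e-12)) stop("`dissim` must have a zero diagonal")
  if (is.null(rownames(dissim)))
    rownames(dissim) <- colnames(dissim) <- paste0("L", seq_len(nrow(dissim)))
  stats::hclust(stats::as.dist(dissim), method = "average")
}

#' Export a dendrogram as a Newick string
#'
#' @param hc An [stats::hclust] object.
#' @return Single Newick string (rooted, branch lengths from merge
#'   heights).
#' @export
dendrogram_newick <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc))
}

#' Merge table of a dendrogram
#'
#' Tabular form of the merge sequence for CSV export: negative entries
#' refer to leaves, positive entries to earlier merge steps (the
#' [stats::hclust] convention).
#'
#' @param hc An [stats::hclust] object.
#' @return `data.frame` with columns `step`, `merge1`, `merge2`, `height`.
#' @export
merge_table <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  data.frame(step = seq_len(nrow(hc$merge)),
             merge1 = hc$merge[, 1],
             merge2 = hc$merge[, 2],
             height = hc$height)
}
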