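#' Construct a reference hierarchy tree
#'
#' The reference is a tree of cell clusters (e.g. a SPADE-derived
#' minimum-spanning-tree of hematopoietic populations), each node carrying
#' the mean log2 expression profile of its cells over a reference gene
#' set, and optionally a branch label (HSC, GMP, DC/macrophage, ...).
#'
#' @param centroids Numeric matrix, rows = nodes (unique rownames =
#'   node ids), columns = reference genes.
#' @param edges Two-column matrix or data.frame of undirected edges
#'   (node id pairs). Must form a connected acyclic graph:
#'   `|E| = |V| - 1`.
#' @param branch Optional named character vector mapping node id to
#'   branch label.
#' @return An object of class `"scq_tree"`: list with elements
#'   `centroids`, `edges` (two-column character matrix), `branch`.
#' @export
reference_tree <- function(centroids, edges, branch = NULL) {
  centroids <- as.matrix(centroids)
  if (is.null(rownames(centroids)) || anyDuplicated(rownames(centroids)))
    stop("`centroids` must have unique node-id rownames")
  if (is.null(colnames(centroids)))
    stop("`centroids` must have gene colnames")
  if (any(!is.finite(centroids)))
    stop("node centroids must be finite")
  edges <- as.matrix(as.data.frame(edges, stringsAsFactors = FALSE))
  if (ncol(edges) != 2) stop("`edges` must have two columns")
  storage.mode(edges) <- "character"
  colnames(edges) <- c("node_a", "node_b")
  ids <- rownames(centroids)
  unknown <- setdiff(c(edges), ids)
  if (length(unknown) > 0)
    stop("edge endpoints not in node table: ", paste(unknown, collapse = ", "))
  if (nrow(edges) != length(ids) - 1)
    stop(sprintf("a tree on %d nodes needs exactly %d edges, got %d",
                 length(ids), length(ids) - 1, nrow(edges)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- g + igraph::vertices(setdiff(ids, igraph::V(g)$name))
  if (!igraph::is_connected(g))
    stop("`edges` do not form a connected tree")
  if (!is.null(branch)) {
    if (is.null(names(branch)) || !all(names(branch) %in% ids))
      stop("`branch` must be named by node ids")
    branch <- branch[ids[ids %in% names(branch)]]
  }
  structure(list(centroids = centroids, edges = edges, branch = branch),
            class = "scq_tree")
}

#' @export
print.scq_tree <- function(x, ...) {
  cat(sprintf("scq_tree: %d nodes, %d genes%s\n",
              nrow(x$centroids), ncol(x$centroids),
              if (is.null(x$branch)) ""
              else sprintf(", branches: %s",
                           paste(sort(unique(x$branch)), collapse = ", "))))
  invisible(x)
}

#' Node ids of a reference tree
#' @param tree An `"scq_tree"` object.
#' @return Character vector of node identifiers.
#' @export
tree_nodes <- function(tree) rownames(tree$centroids)

tree_graph <- function(tree) {
  g <- igraph::graph_from_edgelist(tree$edges, directed = FALSE)
  g + igraph::vertices(setdiff(tree_nodes(tree), igraph::V(g)$name))
}

#' Path length (steps) between two tree nodes
#'
#' Number of edges on the unique path between nodes `a` and `b`, the
#' "steps" used to score how far a cell landed from its reference
#' position.
#'
#' @param tree An `"scq_tree"` object.
#' @param a,b Node ids (vectors are recycled element-wise).
#' @return Integer vector of step counts; `tree_distance(tree, x, x)` is 0.
#' @seealso [tree_distances()] for the full matrix.
#' @export
tree_distance <- function(tree, a, b) {
  d <- tree_distances(tree)
  unknown <- setdiff(c(a, b), rownames(d))
  if (length(unknown) > 0)
    stop("unknown node(s): ", paste(unique(unknown), collapse = ", "))
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  as.integer(d[cbind(a, b)])
}

#' All pairwise step counts of a tree
#'
#' @param tree An `"scq_tree"` object.
#' @return Integer matrix of path lengths, node ids as dimnames.
#' @export
tree_distances <- function(tree) {
  g <- tree_graph(tree)
  d <- igraph::distances(g)
  ids <- tree_nodes(tree)
  storage.mode(d) <- "integer"
  d[ids, ids]
}

#' Read a reference tree from node and edge CSV files
#'
#' `nodes_csv` layout: `node_id`, optional `branch`, then one column per
#' reference gene. `edges_csv` layout: `node_a`, `node_b`.
#'
#' @param nodes_csv,edges_csv File paths.
#' @return An `"scq_tree"` object.
#' @export
read_reference_tree <- function(nodes_csv, edges_csv) {
  nd <- utils::read.csv(nodes_csv, check.names = FALSE)
  if (names(nd)[1] != "node_id")
    stop("first column of the node table must be 'node_id'")
  branch <- NULL
  gene_cols <- setdiff(names(nd), c("node_id", "branch"))
  if ("branch" %in% names(nd))
    branch <- stats::setNames(as.character(nd$branch), as.character(nd$node_id))
  cent <- as.matrix(nd[, gene_cols, drop = FALSE])
  rownames(cent) <- as.character(nd$node_id)
  ed <- utils::read.csv(edges_csv, check.names = FALSE)
  reference_tree(cent, ed[, c("node_a", "node_b")], branch = branch)
}

#' Write a reference tree to node and edge CSV files
#'
#' @param tree An `"scq_tree"` object.
#' @param nodes_csv,edges_csv Output paths.
#' @return Invisibly, `c(nodes_csv, edges_csv)`.
#' @export
write_reference_tree <- function(tree, nodes_csv, edges_csv) {
  nd <- data.frame(node_id = tree_nodes(tree), check.names = FALSE)
  if (!is.null(tree$branch))
    nd$branch <- unname(tree$branch[nd$node_id])
  nd <- cbind(nd, as.data.frame(tree$centroids, check.names = FALSE))
  utils::write.csv(nd, nodes_csv, row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(tree$edges), edges_csv,
                   row.names = FALSE, quote = FALSE)
  invisible(c(nodes_csv, edges_csv))
}

#' Serialize a reference tree to a single JSON document
#'
#' @param tree An `"scq_tree"` object.
#' @param path Optional output path; if `NULL` the JSON string is
#'   returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
tree_to_json <- function(tree, path = NULL) {
  doc <- list(
    nodes = rownames(tree$centroids),
    genes = colnames(tree$centroids),
    centroids = unname(apply(tree$centroids, 1, as.numeric, simplify = FALSE)),
    edges = apply(tree$edges, 1, as.character, simplify = FALSE),
    branch = if (is.null(tree$branch)) NULL else as.list(tree$branch))
  if (is.null(path))
    return(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a reference tree from its JSON form
#'
#' @param path JSON file written by [tree_to_json()], or a JSON string.
#' @return An `"scq_tree"` object.
#' @export
tree_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cent <- if (is.matrix(doc$centroids)) doc$centroids
          else do.call(rbind, doc$centroids)
  rownames(cent) <- doc$nodes
  colnames(cent) <- doc$genes
  edges <- if (is.matrix(doc$edges)) doc$edges else do.call(rbind, doc$edges)
  branch <- if (is.null(doc$branch)) NULL else unlist(doc$branch)
  reference_tree(cent, edges, branch = branch)
}
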