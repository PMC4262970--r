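#' Convert a raw Ct matrix to censored log2 expression
#'
#' Single-cell qPCR reports a threshold cycle (Ct) per reaction; lower Ct
#' means higher expression, and reactions at or beyond the instrument's
#' background level carry no signal. Expression is estimated as
#' `background_ct - Ct`, with Ct values above the background first clamped
#' to the background, so the result approximates log2 expression with
#' non-detection represented by zero.
#'
#' @param ct Numeric matrix of Ct values, rows = cells, columns = genes.
#'   Row and column names are required and must be unique. All values must
#'   be finite and strictly positive; a no-signal reaction is encoded as
#'   `Ct >= background_ct`, never as `NA`.
#' @param background_ct Background threshold cycle (cycles, default 28).
#' @return A numeric matrix of the same shape with class `"scq_expr"`,
#'   attribute `scale = "log2"` and attribute `background_ct`. Entries lie
#'   in `[0, background_ct]`.
#' @seealso [to_linear()], [read_ct_matrix()]
#' @examples
#' ct <- matrix(c(25, 28, 31.4, 20), 2, 2,
#'              dimnames = list(c("c1", "c2"), c("gA", "gB")))
#' ct_to_expression(ct)
#' @export
ct_to_expression <- function(ct, background_ct = 28) {
  ct <- as_ct_matrix(ct, background_ct)
  vals <- pmin(unclass(ct), background_ct)
  expr <- background_ct - vals
  scq_expression(expr, scale = "log2", background_ct = background_ct)
}

#' Anti-log transform censored log2 expression to the linear scale
#'
#' Positive log2 values map to `2^value`; exact zeros, which encode
#' "no expression" under the detection-limit censoring rule, map to 0
#' rather than to `2^0 = 1`, so non-detection stays distinct from low
#' expression on the linear scale.
#'
#' @param expr An `"scq_expr"` matrix on the log2 scale
#'   (see [ct_to_expression()]).
#' @return An `"scq_expr"` matrix with attribute `scale = "linear"`.
#' @export
to_linear <- function(expr) {
  if (!inherits(expr, "scq_expr"))
    stop("`expr` must be an 'scq_expr' matrix (see ct_to_expression())")
  if (expr_scale(expr) != "log2")
    stop("`expr` is already on the linear scale")
  vals <- unclass(expr)
  out <- ifelse(vals > 0, 2^vals, 0)
  dimnames(out) <- dimnames(vals)
  scq_expression(out, scale = "linear",
                 background_ct = attr(expr, "background_ct"))
}

#' Build an expression matrix object
#'
#' Thin constructor used by [ct_to_expression()] and the synthetic-data
#' generator; validates axes and (for the log2 scale) the censoring range.
#'
#' @param values Numeric matrix, rows = cells, columns = genes, with unique
#'   dimnames.
#' @param scale `"log2"` or `"linear"`.
#' @param background_ct Background threshold cycle the censoring refers to.
#' @return The matrix with class `"scq_expr"` and `scale`/`background_ct`
#'   attributes.
#' @export
scq_expression <- function(values, scale = c("log2", "linear"),
                           background_ct = 28) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  check_axes(values)
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  if (scale == "log2" &&
      (any(values < 0) || any(values > background_ct)))
    stop("log2 expression must lie in [0, background_ct]")
  if (scale == "linear" && any(values < 0))
    stop("linear expression must be non-negative")
  structure(values, scale = scale, background_ct = background_ct,
            class = c("scq_expr", "matrix", "array"))
}

#' Scale tag of an expression matrix
#' @param expr An `"scq_expr"` matrix.
#' @return `"log2"` or `"linear"`.
#' @export
expr_scale <- function(expr) {
  sc <- attr(expr, "scale")
  if (is.null(sc)) stop("`expr` carries no scale attribute")
  sc
}

#' @export
print.scq_expr <- function(x, ...) {
  cat(sprintf("scq_expr: %d cells x %d genes (%s scale, background Ct %s)\n",
              nrow(x), ncol(x), expr_scale(x), attr(x, "background_ct")))
  utils::str(unclass(x))
  invisible(x)
}

#' Subset an expression matrix, keeping its attributes
#'
#' `[.scq_expr` would silently drop the scale tag, so subsetting goes
#' through this helper.
#'
#' @param expr An `"scq_expr"` matrix.
#' @param cells,genes Row / column indices or names (`NULL` keeps all).
#' @return An `"scq_expr"` matrix.
#' @export
subset_expr <- function(expr, cells = NULL, genes = NULL) {
  stopifnot(inherits(expr, "scq_expr"))
  vals <- unclass(expr)
  if (!is.null(cells)) vals <- vals[cells, , drop = FALSE]
  if (!is.null(genes)) vals <- vals[, genes, drop = FALSE]
  scq_expression(vals, scale = expr_scale(expr),
                 background_ct = attr(expr, "background_ct"))
}

#' Read a Ct matrix from CSV
#'
#' Expected layout: first column `cell_id`, header row of gene symbols,
#' one row per cell; no missing values (a no-signal reaction is encoded
#' as a Ct at or above the background, never blank).
#'
#' @param path CSV file path.
#' @param background_ct Background threshold cycle (default 28).
#' @return Numeric Ct matrix with cell ids as rownames, validated against
#'   the Ct invariants.
#' @export
read_ct_matrix <- function(path, background_ct = 28) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "cell_id")
    stop("first column of a Ct CSV must be 'cell_id'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df$cell_id)
  storage.mode(m) <- "double"
  as_ct_matrix(m, background_ct)
}

#' Write a cells x genes matrix to CSV
#'
#' Inverse of the [read_ct_matrix()] layout: first column `cell_id`, then
#' one column per gene.
#'
#' @param x Matrix with cell rownames and gene colnames.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cells_csv <- function(x, path) {
  df <- data.frame(cell_id = rownames(x), unclass(x),
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Validate a Ct matrix: finite, strictly positive, unique axes.
as_ct_matrix <- function(ct, background_ct = 28) {
  ct <- as.matrix(ct)
  check_axes(ct)
  if (!is.numeric(background_ct) || length(background_ct) != 1 ||
      !is.finite(background_ct) || background_ct <= 0)
    stop("`background_ct` must be a single positive number")
  bad <- which(!is.finite(ct) | ct <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "non-finite or non-positive Ct value(s), first at cell '%s', gene '%s'",
      rownames(ct)[bad[1, 1]], colnames(ct)[bad[1, 2]]))
  }
  ct
}

check_axes <- function(m) {
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("matrix must carry cell rownames and gene colnames")
  if (anyDuplicated(rownames(m)))
    stop("duplicate cell identifiers: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (anyDuplicated(colnames(m)))
    stop("duplicate gene identifiers: ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  invisible(m)
}
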