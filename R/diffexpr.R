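#' Two-sided Wilcoxon-Mann-Whitney rank-sum test
#'
#' Compares two samples of log2 expression values. For small untied
#' samples (`n + m <= exact_threshold`) the p-value comes from the exact
#' permutation null of the Mann-Whitney U statistic; otherwise a normal
#' approximation with midrank tie correction and continuity correction is
#' used. When every pooled value is identical the samples are perfectly
#' exchangeable and `p = 1`.
#'
#' @param x,y Numeric vectors, each non-empty and finite.
#' @param mode `"auto"` (default: exact when small and untied),
#'   `"exact"` (error if ties are present) or `"approx"`.
#' @param exact_threshold Largest pooled size `n + m` for which the exact
#'   null is used in `"auto"` mode (default 20).
#' @return List with `statistic` (Mann-Whitney U of `x`), `p_value`
#'   (two-sided, in `(0, 1]`) and `method` (`"exact"` or `"approx"`).
#' @export
rank_sum_test <- function(x, y, mode = c("auto", "exact", "approx"),
                          exact_threshold = 20) {
  mode <- match.arg(mode)
  if (length(x) < 1 || length(y) < 1)
    stop("both samples must be non-empty")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("samples must be finite")
  n <- length(x); m <- length(y); N <- n + m
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- anyDuplicated(pooled) > 0

  use_exact <- switch(mode,
    auto = !ties && N <= exact_threshold,
    exact = if (ties) stop("exact mode requires untied samples") else TRUE,
    approx = FALSE)

  if (use_exact) {
    p_low <- stats::pwilcox(u, n, m)
    p_high <- 1 - stats::pwilcox(u - 1, n, m)
    p <- min(1, 2 * min(p_low, p_high))
    return(list(statistic = u, p_value = p, method = "exact"))
  }

  mu <- n * m / 2
  tab <- table(pooled)
  tie_term <- sum(tab^3 - tab) / (N * (N - 1))
  sigma2 <- (n * m / 12) * ((N + 1) - tie_term)
  if (sigma2 <= 0) {                        # all pooled values identical
    return(list(statistic = u, p_value = 1, method = "approx"))
  }
  z <- u - mu
  z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)  # continuity correction
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  p <- max(p, .Machine$double.xmin)
  list(statistic = u, p_value = p, method = "approx")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment over one family of raw
#' p-values, position-preserving and capped at 1.
#'
#' @param pvals Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Log fold change as a difference of medians
#'
#' On log2-scale expression the fold change between two groups is the
#' difference of their medians, `median(x) - median(y)` — robust to the
#' heavy zero-inflation of censored single-cell qPCR data.
#'
#' @param x,y Non-empty numeric vectors of log2 expression.
#' @return A single number (log2 units).
#' @export
log_fold_change <- function(x, y) {
  if (length(x) < 1 || length(y) < 1)
    stop("both samples must be non-empty")
  stats::median(x) - stats::median(y)
}

#' Differential expression between two cell groups
#'
#' Per gene: two-sided rank-sum test of group A versus group B,
#' Benjamini-Hochberg adjustment across all tested genes, and the
#' median-difference log fold change (A minus B). A gene is flagged
#' significant when `p_adj < alpha` **and** `|lfc| >= lfc_min` — the dual
#' stringency criterion.
#'
#' @param expr An `"scq_expr"` log2 matrix (or plain cells x genes
#'   matrix).
#' @param group_a,group_b Disjoint, non-empty vectors of cell ids (row
#'   names of `expr`).
#' @param alpha Adjusted-p cutoff (default `1e-5`).
#' @param lfc_min Minimum absolute log fold change (default 2).
#' @param genes Optional subset of genes to test (default: all columns);
#'   the BH family is exactly the tested set.
#' @inheritParams rank_sum_test
#' @return `data.frame` of class `"scq_de"` with columns `gene`,
#'   `statistic`, `p`, `p_adj`, `lfc`, `significant`, sorted by `p_adj`
#'   then decreasing `|lfc|`.
#' @export
differential_genes <- function(expr, group_a, group_b, alpha = 1e-5,
                               lfc_min = 2, genes = NULL,
                               mode = c("auto", "exact", "approx"),
                               exact_threshold = 20) {
  mode <- match.arg(mode)
  m <- unclass(as.matrix(expr))
  group_a <- as.character(group_a); group_b <- as.character(group_b)
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both groups must be non-empty")
  if (length(intersect(group_a, group_b)) > 0)
    stop("groups overlap: ",
         paste(utils::head(intersect(group_a, group_b), 5), collapse = ", "))
  missing <- setdiff(c(group_a, group_b), rownames(m))
  if (length(missing) > 0)
    stop("unknown cell id(s): ", paste(utils::head(missing, 5), collapse = ", "))
  if (is.null(genes)) genes <- colnames(m)
  A <- m[group_a, genes, drop = FALSE]
  B <- m[group_b, genes, drop = FALSE]
  res <- vapply(seq_along(genes), function(j) {
    ts <- rank_sum_test(A[, j], B[, j], mode = mode,
                        exact_threshold = exact_threshold)
    c(ts$statistic, ts$p_value, log_fold_change(A[, j], B[, j]))
  }, numeric(3))
  out <- data.frame(gene = genes,
                    statistic = res[1, ],
                    p = res[2, ],
                    p_adj = bh_adjust(res[2, ]),
                    lfc = res[3, ],
                    row.names = NULL)
  out$significant <- out$p_adj < alpha & abs(out$lfc) >= lfc_min
  out <- out[order(out$p_adj, -abs(out$lfc)), ]
  rownames(out) <- NULL
  structure(out, alpha = alpha, lfc_min = lfc_min,
            class = c("scq_de", "data.frame"))
}

#' Write a differential-expression table to CSV
#'
#' @param de An `"scq_de"` table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_de <- function(de, path) {
  utils::write.csv(as.data.frame(de), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
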