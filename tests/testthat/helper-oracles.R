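# Independent brute-force oracles. Each one re-derives a quantity from its
# definition, without reusing the code path under test.

# Two-sided rank-sum p by full enumeration of all C(n+m, n) assignments of
# the pooled ranks to the first sample.
oracle_rank_sum_p <- function(x, y) {
  n <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  sets <- utils::combn(length(pooled), n)
  u_all <- apply(sets, 2, function(idx) sum(r[idx])) - n * (n + 1) / 2
  p_low <- mean(u_all <= u_obs)
  p_high <- mean(u_all >= u_obs)
  min(1, 2 * min(p_low, p_high))
}

# Literal step-up BH: sort ascending, adj_(i) = min_{j >= i} m p_(j) / j.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  s <- p[ord]
  adj <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, m * s[i] / i)
    adj[i] <- min(1, running)
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Triple-loop TOM from the definition.
oracle_tom <- function(a) {
  n <- nrow(a)
  k <- rowSums(a) - diag(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- a[i, j]
    for (u in seq_len(n)) if (u != i && u != j) num <- num + a[i, u] * a[u, j]
    tom[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# Naive UPGMA: repeatedly merge the pair of clusters with the smallest
# mean of original pairwise dissimilarities; returns the cophenetic
# matrix (which fully determines the dendrogram).
oracle_upgma_cophenetic <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h - 1e-12) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- best_h
    coph[b, a] <- best_h
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  dimnames(coph) <- dimnames(d)
  coph
}

# Breadth-first search path lengths from one node over an edge list.
oracle_bfs_steps <- function(edges, ids, from) {
  adj <- lapply(stats::setNames(ids, ids), function(v)
    c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1]))
  dist <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  dist[from] <- 0L
  frontier <- from
  while (length(frontier) > 0) {
    nxt <- character(0)
    for (v in frontier) for (w in adj[[v]]) {
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        nxt <- c(nxt, w)
      }
    }
    frontier <- nxt
  }
  dist
}
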