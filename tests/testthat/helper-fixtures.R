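# Small in-code fixtures shared across test files.

named_matrix <- function(vals, nr, nc, prefix = c("c", "g")) {
  matrix(vals, nr, nc, dimnames = list(sprintf("%s%02d", prefix[1], seq_len(nr)),
                                       sprintf("%s%02d", prefix[2], seq_len(nc))))
}

# A tiny hand-built reference tree: chain N1 - N2 - N3 with a side branch
# N2 - N4, two genes.
toy_tree <- function() {
  cent <- matrix(c(0, 0,
                   4, 0,
                   8, 0,
                   4, 6), 4, 2, byrow = TRUE,
                 dimnames = list(paste0("N", 1:4), c("gA", "gB")))
  edges <- rbind(c("N1", "N2"), c("N2", "N3"), c("N2", "N4"))
  reference_tree(cent, edges,
                 branch = c(N1 = "root", N2 = "root", N3 = "left",
                            N4 = "right"))
}

# Random valid adjacency matrix: symmetric, entries in [0,1], unit diagonal.
random_adjacency <- function(n) {
  a <- matrix(stats::runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  dimnames(a) <- list(paste0("g", seq_len(n)), paste0("g", seq_len(n)))
  a
}

# Expression matrix with two planted correlation blocks plus background
# genes, for module-detection tests.
block_expression <- function(n_cells = 60, block_sizes = c(15, 12),
                             n_background = 20, noise_sd = 0.3) {
  n_genes <- sum(block_sizes) + n_background
  vals <- matrix(stats::rnorm(n_cells * n_genes, 8, noise_sd),
                 n_cells, n_genes)
  at <- 0
  for (bs in block_sizes) {
    z <- stats::rnorm(n_cells)
    vals[, at + seq_len(bs)] <- vals[, at + seq_len(bs)] + 2 * z
    at <- at + bs
  }
  vals <- pmin(pmax(vals, 0), 28)
  dimnames(vals) <- list(sprintf("c%03d", seq_len(n_cells)),
                         sprintf("g%03d", seq_len(n_genes)))
  scq_expression(vals, scale = "log2", background_ct = 28)
}
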