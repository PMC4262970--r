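test_that("pearson matrix matches the direct formula and rejects flat genes", {
  withr::local_seed(41)
  m <- named_matrix(stats::runif(5 * 10, 0, 50), 5, 10)
  cc <- pearson_matrix(m)
  expect_equal(diag(cc), stats::setNames(rep(1, 10), colnames(m)))
  # brute-force covariance / sd oracle on a few pairs
  for (pair in list(c(1, 2), c(3, 7), c(9, 10))) {
    x <- m[, pair[1]]; y <- m[, pair[2]]
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(unname(cc[pair[1], pair[2]]), r)
  }
  # anti-correlated pair
  m2 <- cbind(a = c(1, 2, 3), b = c(3, 2, 1))
  rownames(m2) <- paste0("c", 1:3)
  expect_equal(pearson_matrix(m2)["a", "b"], -1)
  m3 <- cbind(a = c(1, 2, 3), flat = c(2, 2, 2))
  rownames(m3) <- paste0("c", 1:3)
  expect_error(pearson_matrix(m3), "flat")
})

test_that("power adjacency takes |cor|^beta with unit diagonal", {
  cc <- matrix(c(1, 0.5, -0.5, 0.5, 1, 0, -0.5, 0, 1), 3, 3)
  expect_equal(power_adjacency(cc, 2)[1, 2], 0.25)
  expect_equal(power_adjacency(cc, 4)[1, 3], 0.0625)  # |-0.5|^4
  expect_equal(power_adjacency(cc, 1)[1, 3], 0.5)     # identity power
  expect_equal(diag(power_adjacency(cc, 3)), rep(1, 3))
  expect_error(power_adjacency(cc, 0), "beta")
  expect_error(power_adjacency(cc, 2.5), "beta")
  # adjacency non-increasing in beta for |cor| < 1, invariant at 0 and 1
  for (b in 1:5) {
    a1 <- power_adjacency(cc, b); a2 <- power_adjacency(cc, b + 1)
    expect_true(all(a2 <= a1 + 1e-12))
  }
})

test_that("connectivity is the off-diagonal row sum", {
  a <- matrix(1, 3, 3)
  expect_equal(unname(connectivity(a)), c(2, 2, 2))
  a2 <- diag(3)
  expect_equal(unname(connectivity(a2)), c(0, 0, 0))   # isolated genes
  withr::local_seed(42)
  a3 <- random_adjacency(7)
  expect_equal(connectivity(a3),
               apply(a3, 1, sum) - 1)                   # direct sum oracle
})

test_that("topological overlap matches a triple-loop oracle", {
  # all-ones triangle: TOM_12 = (1 + 1) / (2 + 1 - 1) = 1
  a <- matrix(1, 3, 3)
  expect_equal(topological_overlap(a)[1, 2], 1)
  # disconnected pair with no shared neighbours: TOM = 0
  a2 <- diag(4)
  expect_equal(topological_overlap(a2)[1, 2], 0)
  withr::local_seed(43)
  for (rep in 1:10) {
    a3 <- random_adjacency(8)
    tom <- topological_overlap(a3)
    expect_equal(tom, oracle_tom(a3), tolerance = 1e-12)
    expect_true(all(tom >= 0 & tom <= 1))
    expect_true(isSymmetric(unname(tom)))
  }
  expect_error(topological_overlap(matrix(c(1, 2, 2, 1), 2, 2)), "adjacency")
})

test_that("scale-free fit is 1 on an exact power law and warns on 2 bins", {
  # counts proportional to k^-1 at k = 1, 2, 4, 8: exactly log-log linear
  k <- rep(c(1, 2, 4, 8), times = c(8, 4, 2, 1))
  r2 <- scale_free_fit(k)
  expect_equal(as.numeric(r2), 1)
  expect_equal(sum(attr(r2, "bins")$count), length(k))
  expect_warning(r2b <- scale_free_fit(c(1, 1, 1, 5)), "2 usable bins")
  expect_equal(as.numeric(r2b), 1)
  expect_error(scale_free_fit(rep(3, 10)), "identical")
})

test_that("choose_beta returns the smallest qualifying exponent", {
  withr::local_seed(44)
  expr <- block_expression()
  cc <- pearson_matrix(unclass(to_linear(expr)))
  # threshold 0: the first candidate qualifies by construction
  first <- choose_beta(cc, candidates = 3:10, r2_threshold = 0)
  expect_equal(first$beta, 3)
  # recomputation oracle: rescan all candidates independently, set the
  # threshold just below the best attainable fit, and check the
  # smallest-qualifying rule
  rescan <- vapply(1:20, function(b)
    suppressWarnings(as.numeric(scale_free_fit(
      connectivity(power_adjacency(cc, b))))), 0)
  thr <- max(rescan) - 0.05
  sel <- choose_beta(cc, r2_threshold = thr)
  expect_equal(sel$beta, min(which(rescan > thr)))
  expect_equal(sel$r2, rescan[sel$beta])
  # unattainable threshold: error carries the full scan table
  err <- tryCatch(choose_beta(cc, candidates = 1:3, r2_threshold = 0.9999),
                  scq_no_beta = function(e) e)
  expect_s3_class(err, "scq_no_beta")
  expect_equal(nrow(err$scan), 3)
})

test_that("module detection recovers planted blocks and obeys size rules", {
  # two planted blocks with high intra-TOM and near-zero inter-TOM
  n1 <- 14; n2 <- 11; nb <- 6
  tom <- diag(n1 + n2 + nb) * 0 + 0.005
  tom[seq_len(n1), seq_len(n1)] <- 0.9
  tom[n1 + seq_len(n2), n1 + seq_len(n2)] <- 0.85
  diag(tom) <- 1
  dimnames(tom) <- list(paste0("g", seq_len(n1 + n2 + nb)),
                        paste0("g", seq_len(n1 + n2 + nb)))
  mods <- detect_modules(tom, min_module_size = 10)
  expect_equal(unname(mods[seq_len(n1)]), rep(1L, n1))     # largest first
  expect_equal(unname(mods[n1 + seq_len(n2)]), rep(2L, n2))
  expect_equal(unname(mods[n1 + n2 + seq_len(nb)]), rep(0L, nb))
  # all-ones TOM: a single module containing every gene
  tom1 <- matrix(1, 12, 12,
                 dimnames = list(paste0("g", 1:12), paste0("g", 1:12)))
  expect_equal(as.integer(detect_modules(tom1)), rep(1L, 12))
  # fewer genes than the minimum size: everything unassigned, with warning
  expect_warning(m0 <- detect_modules(tom1[1:4, 1:4], min_module_size = 10),
                 "unassigned")
  expect_equal(unname(m0), rep(0L, 4))
})

test_that("build_network composes the stages deterministically", {
  withr::local_seed(45)
  expr <- block_expression()
  net <- build_network(expr, beta = 6)
  expect_s3_class(net, "scq_network")
  expect_equal(net$adjacency, power_adjacency(net$cor, 6))
  expect_equal(net$tom, topological_overlap(net$adjacency))
  expect_equal(sort(unique(net$modules[net$modules > 0])), 1:2)
  # beta = 1 on a small toy: adjacency equals |cor|
  toy <- scq_expression(named_matrix(c(1, 2, 3, 4,
                                       2, 4, 6, 9,
                                       9, 5, 3, 1), 4, 3),
                        scale = "log2")
  nt <- suppressWarnings(build_network(toy, beta = 1, min_module_size = 2))
  expect_equal(nt$adjacency[1, 2], abs(nt$cor[1, 2]))
  # bit-identical rerun
  net2 <- build_network(expr, beta = 6)
  expect_identical(net$tom, net2$tom)
  expect_identical(net$modules, net2$modules)
  # zero-variance genes are dropped and logged
  vals <- unclass(expr)
  vals[, 1] <- 0
  e2 <- scq_expression(vals, scale = "log2")
  net3 <- build_network(e2, beta = 6)
  expect_equal(net3$dropped_genes, colnames(vals)[1])
  expect_error(build_network(subset_expr(expr, cells = 1:2), beta = 1),
               "3 cells")
})

test_that("module overlap reports intersections, Jaccard and containment", {
  la <- stats::setNames(c(1, 1, 1, 1, 1, 0, 0), paste0("g", 1:7))
  lb <- stats::setNames(c(0, 0, 1, 1, 1, 1, 1), paste0("g", 1:7))
  ov <- module_overlap(la, lb)
  expect_equal(ov$pairs$intersection, 3)          # g3..g5
  expect_equal(ov$pairs$jaccard, 3 / 7)
  expect_equal(ov$pairs$fraction_a_in_b, 3 / 5)
  expect_setequal(ov$genes[["A1:B1"]], c("g3", "g4", "g5"))
  # identical modules: Jaccard 1
  ov2 <- module_overlap(la, la)
  expect_equal(ov2$pairs$jaccard, 1)
  # random labelings equal brute-force set intersections
  withr::local_seed(46)
  ra <- stats::setNames(sample(0:3, 30, replace = TRUE), paste0("g", 1:30))
  rb <- stats::setNames(sample(0:2, 30, replace = TRUE), paste0("g", 1:30))
  ov3 <- module_overlap(ra, rb)
  for (r in seq_len(nrow(ov3$pairs))) {
    i <- ov3$pairs$module_a[r]; j <- ov3$pairs$module_b[r]
    expect_equal(ov3$pairs$intersection[r],
                 sum(ra == i & rb == j))
  }
})

test_that("TOM stays within [0,1] across many random valid adjacencies", {
  withr::local_seed(47)
  for (rep in 1:50) {
    tom <- topological_overlap(random_adjacency(sample(4:12, 1)))
    expect_true(all(tom >= 0 & tom <= 1))
  }
})

test_that("networks export matrices, modules and scan tables", {
  withr::local_seed(48)
  expr <- block_expression(n_cells = 30, block_sizes = c(12, 11),
                           n_background = 5)
  net <- build_network(expr, r2_threshold = 0)   # auto beta, scan retained
  dir <- withr::local_tempdir()
  write_network(net, dir)
  expect_true(all(file.exists(file.path(dir, c("adjacency.csv", "tom.csv",
                                               "modules.csv",
                                               "beta_scan.csv")))))
  mods <- utils::read.csv(file.path(dir, "modules.csv"))
  expect_equal(nrow(mods), length(net$genes))
})
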