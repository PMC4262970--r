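test_that("reference trees validate their structure", {
  tree <- toy_tree()
  expect_s3_class(tree, "scq_tree")
  # a cycle / wrong edge count is rejected
  cent <- tree$centroids
  expect_error(reference_tree(cent, rbind(tree$edges, c("N3", "N4"))),
               "edges")
  expect_error(reference_tree(cent, tree$edges[1:2, ]), "edges")
  expect_error(reference_tree(cent, rbind(c("N1", "N9"), tree$edges[1:2, ])),
               "N9")
})

test_that("tree step distances match a breadth-first-search oracle", {
  # chain A-B-C: d(A,C) = 2, d(x,x) = 0
  tree <- toy_tree()
  expect_equal(tree_distance(tree, "N1", "N3"), 2L)
  expect_equal(tree_distance(tree, "N3", "N4"), 2L)
  expect_equal(tree_distance(tree, "N2", "N2"), 0L)
  expect_error(tree_distance(tree, "N1", "Nx"), "unknown")
  # random 20-node tree vs BFS from every node
  spec <- synthetic_spec(n_nodes = 20, n_genes = 10, panel_size = 5,
                         n_de_genes = 2,
                         modules = list(list(size = 3, loading = 1,
                                             factor_sd = 1)), seed = 3)
  rt <- generate_tree(spec)
  d <- tree_distances(rt)
  for (v in tree_nodes(rt)) {
    expect_equal(d[v, ], oracle_bfs_steps(rt$edges, tree_nodes(rt), v))
  }
})

test_that("tree files and JSON round-trip", {
  tree <- toy_tree()
  nodes <- withr::local_tempfile(fileext = ".csv")
  edges <- withr::local_tempfile(fileext = ".csv")
  write_reference_tree(tree, nodes, edges)
  back <- read_reference_tree(nodes, edges)
  expect_equal(back$centroids, tree$centroids)
  expect_equal(sort(back$branch), sort(tree$branch))
  js <- withr::local_tempfile(fileext = ".json")
  tree_to_json(tree, js)
  back2 <- tree_from_json(js)
  expect_equal(back2$centroids, tree$centroids)
})

test_that("node centroids are per-gene means of member cells", {
  m <- named_matrix(c(0, 4, 1, 2, 2, 3), 2, 3)
  cent <- compute_node_centroids(m, c("n1", "n1"))
  expect_equal(unname(cent[1, ]), c(2, 1.5, 2.5))
  # one cell per node: centroid equals the cell
  cent2 <- compute_node_centroids(m, c("n1", "n2"))
  expect_equal(unname(cent2["n2", ]), unname(m[2, ]))
  # random 10-cell node equals a direct summation oracle
  withr::local_seed(8)
  mm <- named_matrix(stats::rnorm(10 * 4), 10, 4)
  cent3 <- compute_node_centroids(mm, rep("nd", 10))
  expect_equal(unname(cent3["nd", ]), unname(colSums(mm) / 10))
  # empty referenced node warns and is omitted
  f <- factor(rep("n1", 2), levels = c("n1", "ghost"))
  expect_warning(c4 <- compute_node_centroids(m, f), "ghost")
  expect_equal(rownames(c4), "n1")
})

test_that("cells map to the nearest centroid with low-id tie breaking", {
  tree <- toy_tree()
  cells <- rbind(c(8, 0),      # exactly node N3
                 c(4, 3),      # equidistant from N2 (d=3) and N4 (d=3)
                 c(0.4, 0))    # near N1
  dimnames(cells) <- list(c("c1", "c2", "c3"), c("gA", "gB"))
  mp <- map_cells(cells, tree, panel = c("gA", "gB"))
  expect_equal(mp$node_id, c("N3", "N2", "N1"))
  expect_equal(mp$distance[1], 0)
  expect_equal(mp$distance[2], 3)
  # brute-force check of assignments on random cells
  withr::local_seed(13)
  rc <- named_matrix(stats::runif(50 * 2, -2, 10), 50, 2)
  colnames(rc) <- c("gA", "gB")
  mp2 <- map_cells(rc, tree, panel = c("gA", "gB"))
  nodes <- sort(tree_nodes(tree))
  for (i in seq_len(50)) {
    dd <- apply(tree$centroids[nodes, ], 1,
                function(ct) sqrt(sum((rc[i, ] - ct)^2)))
    expect_equal(mp2$node_id[i], nodes[which.min(dd)])
    expect_equal(mp2$distance[i], min(dd))
  }
  expect_error(map_cells(rc, tree, panel = character(0)), "panel")
  expect_error(map_cells(rc, tree, panel = "gZ"), "gZ")
})

test_that("concordance counts exact and within-step fractions", {
  tree <- toy_tree()
  mp <- structure(data.frame(cell_id = c("c1", "c2", "c3"),
                             node_id = c("N1", "N2", "N3"),
                             distance = 0,
                             original = c("N1", "N1", "N1")),
                  class = c("scq_mapping", "data.frame"))
  cc <- concordance(mp, tree, max_steps = 2)
  expect_equal(cc$fraction_exact, 1 / 3)
  expect_equal(cc$fraction_within, 1)     # steps 0, 1, 2
  cc1 <- concordance(mp, tree, max_steps = 1)
  expect_equal(cc1$fraction_within, 2 / 3)
  # monotone in max_steps
  expect_true(cc1$fraction_within <= cc$fraction_within)
  # identical mapping gives (1, 1); all-one-step gives (0, 1)
  mp$node_id <- mp$original
  expect_equal(concordance(mp, tree)$fraction_exact, 1)
  mp2 <- mp
  mp2$original <- c("N2", "N2", "N2")     # all one edge away
  cc2 <- concordance(mp2, tree)
  expect_equal(cc2$fraction_exact, 0)
  expect_equal(cc2$fraction_within, 1)
  mp$original <- NULL
  expect_error(concordance(mp, tree), "original")
})

test_that("random panel validation is seeded and composes map+concordance", {
  spec <- synthetic_spec(n_nodes = 8, n_genes = 12, panel_size = 12,
                         cells_per_node = 3, noise_sd = 0, n_de_genes = 0,
                         modules = list(), drift_genes = "all", seed = 9)
  tree <- generate_tree(spec)
  sim <- generate_cells(tree, spec)
  expr <- ct_to_expression(sim$ct)
  org <- stats::setNames(sim$truth$cells$node_id, sim$truth$cells$cell_id)
  pv1 <- random_panel_validation(expr, tree, org, panel_size = 5,
                                 n_lists = 7, seed = 4)
  pv2 <- random_panel_validation(expr, tree, org, panel_size = 5,
                                 n_lists = 7, seed = 4)
  expect_identical(pv1$per_panel, pv2$per_panel)       # same seed, same result
  # n_lists = 1 equals manual composition with that panel
  pv3 <- random_panel_validation(expr, tree, org, panel_size = 5,
                                 n_lists = 1, seed = 4)
  manual <- concordance(map_cells(expr, tree, panel = pv3$panels[[1]],
                                  original = org), tree)
  expect_equal(pv3$mean_within, manual$fraction_within)
  # full-size panels: every list identical to the full-panel concordance
  pvf <- random_panel_validation(expr, tree, org, panel_size = 12,
                                 n_lists = 3, seed = 1)
  full <- concordance(suppressMessages(
    map_cells(expr, tree, original = org)), tree)
  expect_true(all(pvf$per_panel$fraction_within == full$fraction_within))
  # zero-noise cells at centroids (all genes informative): perfect recovery
  expect_equal(pv1$mean_exact, 1)
  expect_error(random_panel_validation(expr, tree, org, panel_size = 99),
               "exceeds")
})

test_that("subtype labels come from the branch of the assigned node", {
  tree <- toy_tree()
  mp <- structure(data.frame(cell_id = c("c1", "c2", "c3"),
                             node_id = c("N3", "N3", "N4"),
                             distance = 0),
                  class = c("scq_mapping", "data.frame"))
  st <- assign_subtypes(mp, tree)
  expect_equal(st$subtype, c("left", "left", "right"))
  expect_error(assign_subtypes(mp, tree, branch_map = c(N3 = "left")),
               "N4")
})

test_that("phenotype crosstab reproduces hand counts", {
  sub <- c(a = "S1", b = "S1", c = "S2", d = "S2")
  phe <- c(a = "P1", b = "P1", c = "P1", d = "P2")
  xt <- phenotype_crosstab(sub, phe)
  expect_equal(unname(xt$p_subtype_given_phenotype["P1", "S1"]), 2 / 3)
  expect_equal(unname(xt$p_phenotype_given_subtype["P2", "S2"]), 1 / 2)
  expect_equal(sum(xt$counts), 4)
  # single phenotype, single subtype: proportion 1
  xt1 <- phenotype_crosstab(c("S", "S"), c("P", "P"))
  expect_equal(as.numeric(xt1$p_subtype_given_phenotype), 1)
  # random labels equal brute-force contingency counts
  withr::local_seed(17)
  s <- sample(c("S1", "S2", "S3"), 40, replace = TRUE)
  p <- sample(c("P1", "P2"), 40, replace = TRUE)
  xt2 <- phenotype_crosstab(s, p)
  for (pp in c("P1", "P2")) for (ss in c("S1", "S2", "S3"))
    expect_equal(unname(xt2$counts[pp, ss]), sum(p == pp & s == ss))
  expect_error(phenotype_crosstab(sub, phe[1:3]), "same cells")
})
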