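test_that("removing everything in one step empties the network", {
  g <- generate_signed_network(30, "random", density = 0.2, seed = 1)
  tr <- percolate(g, "random", step_fraction = 1, seed = 1)
  expect_equal(nrow(tr), 2L)
  final <- tr[nrow(tr), ]
  expect_equal(final$n_nodes, 0L)
  expect_equal(final$n_edges, 0L)
  expect_equal(final$n_components, 0L)
  expect_equal(final$fraction_removed, 1)
})

test_that("step 0 records the intact network and degree targeting splits P5 first", {
  p5 <- as_coocc(igraph::make_graph(~ a - b, b - c, c - d, d - e))
  tr <- percolate(p5, "degree", step_fraction = 0.2, seed = 1)
  expect_equal(tr$n_nodes[1], 5L)
  expect_equal(tr$n_components[1], 1L)
  # highest degree is a middle node; removing one disconnects the path
  expect_equal(tr$n_nodes[2], 4L)
  expect_equal(tr$n_components[2], 2L)
})

test_that("group percolation removes whole groups and detaches the bridge", {
  # two 10-cliques joined through a single bridge node
  g <- igraph::disjoint_union(igraph::make_full_graph(10), igraph::make_full_graph(10))
  g <- igraph::add_vertices(g, 1)
  g <- igraph::add_edges(g, c(1, 21, 11, 21))
  net <- as_coocc(g)
  groups <- tibble::tibble(
    taxon_id = igraph::V(net)$name,
    group = c(rep("A", 10), rep("B", 10), "bridge")
  )
  tr <- percolate(net, "group", groups = groups, group_order = c("bridge", "A", "B"),
                  seed = 1)
  expect_equal(tr$n_components[2], 2L)
  expect_equal(tr$giant_fraction[2], 0.5)
  expect_equal(tr$n_nodes[nrow(tr)], 0L)
  expect_error(percolate(net, "group", groups = groups[1:5, ]), "cover")
})

test_that("random percolation is reproducible and removes every node exactly once", {
  g <- generate_signed_network(40, "random", density = 0.15, seed = 5)
  t1 <- percolate(g, "random", step_fraction = 0.25, seed = 9)
  t2 <- percolate(g, "random", step_fraction = 0.25, seed = 9)
  expect_identical(tibble::as_tibble(t1), tibble::as_tibble(t2))
  removed_per_step <- -diff(t1$n_nodes)
  expect_equal(sum(removed_per_step), 40L)
  expect_true(all(diff(t1$n_nodes) <= 0))
  expect_equal(t1$fraction_removed[nrow(t1)], 1)
})

test_that("degree-targeted removal breaks a scale-free graph faster than random", {
  areas <- vapply(1:10, function(s) {
    g <- generate_signed_network(80, "scale_free", density = 0.05, seed = s)
    a_deg <- robustness_report(percolate(g, "degree", step_fraction = 0.1, seed = s))
    a_rnd <- robustness_report(percolate(g, "random", step_fraction = 0.1, seed = s))
    c(deg = a_deg$auc[a_deg$metric == "giant_fraction"],
      rnd = a_rnd$auc[a_rnd$metric == "giant_fraction"])
  }, numeric(2))
  expect_lt(mean(areas["deg", ]), mean(areas["rnd", ]))
})

test_that("the robustness report has one row per tracked metric", {
  g <- generate_signed_network(30, "random", density = 0.2, seed = 2)
  rep <- robustness_report(percolate(g, "random", step_fraction = 0.5, seed = 2))
  expect_equal(nrow(rep), 7L)
  expect_true("giant_fraction" %in% rep$metric)
  thr <- rep$threshold_fraction[rep$metric == "giant_fraction"]
  expect_true(is.na(thr) || (thr > 0 && thr <= 1))

  # degenerate: edgeless network at step 0 handled without error
  e <- as_coocc(igraph::make_empty_graph(4, directed = FALSE))
  tr <- percolate(e, "random", step_fraction = 0.5, seed = 1)
  expect_equal(tr$giant_fraction[1], 1 / 4)
  expect_error(robustness_report(tr), NA)
})
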