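test_that("closed-form metrics on K5 and P4 are reproduced", {
  k5 <- as_coocc(igraph::make_full_graph(5))
  s <- summarize_topology(k5, sw_replicates = 3, seed = 1)
  expect_equal(s$density, 1)
  expect_equal(s$clustering, 1)
  expect_equal(s$diameter, 1)
  expect_equal(s$avg_path, 1)
  expect_false(is.na(s$small_world))

  p4 <- as_coocc(igraph::make_graph(~ a - b, b - c, c - d))
  s4 <- summarize_topology(p4, sw_replicates = 3, seed = 1)
  expect_equal(s4$density, 0.5)
  expect_equal(s4$diameter, 3)
  expect_equal(s4$avg_path, 10 / 6)
  expect_equal(s4$avg_degree, 2 * s4$n_edges / s4$n_nodes)
})

test_that("edgeless networks get undefined markers, not exceptions", {
  g <- as_coocc(igraph::make_empty_graph(5, directed = FALSE))
  s <- summarize_topology(g, sw_replicates = 3, seed = 1)
  expect_equal(s$n_edges, 0L)
  expect_true(is.na(s$avg_path) && is.na(s$diameter) && is.na(s$small_world))
  expect_true(is.na(s$pos_neg_ratio))
})

test_that("pos:neg ratio uses raw signs, with an infinity marker when all positive", {
  g <- generate_signed_network(30, "random", density = 0.3, p_negative = 0.4, seed = 2)
  s <- summarize_topology(g, sw_replicates = 3, seed = 1)
  w <- igraph::E(g)$raw_weight
  expect_equal(s$pos_neg_ratio, sum(w > 0) / sum(w < 0))
  gp <- generate_signed_network(20, "random", density = 0.3, p_negative = 0, seed = 2)
  expect_equal(summarize_topology(gp, sw_replicates = 3, seed = 1)$pos_neg_ratio, Inf)
})

test_that("the small-world index of matched random graphs concentrates near 1", {
  sw <- vapply(1:10, function(s) {
    g <- withr::with_seed(s, igraph::sample_gnp(200, 0.1))
    small_world_index(g, n_replicates = 10, seed = s)
  }, numeric(1))
  expect_gt(mean(sw), 0.8)
  expect_lt(mean(sw), 1.2)
})

test_that("null distributions discriminate planted topologies", {
  # preferential attachment overshoots/undershoots sparse targets slightly
  ba <- suppressWarnings(generate_signed_network(150, "scale_free", density = 0.06, seed = 7))
  nulls <- null_distributions(ba, topologies = "random", n_replicates = 20,
                              seed = 7, include_sw = FALSE)
  expect_equal(nrow(nulls), 20L)
  q <- null_quantiles(nulls)
  expect_gt(q$quantile[q$metric == "degree_sd"], 0.95)

  # ring-lattice degree rounding may miss the density target slightly
  ws <- suppressWarnings(generate_signed_network(150, "small_world", density = 0.06, seed = 8))
  nulls_ws <- null_distributions(ws, topologies = "random", n_replicates = 10,
                                 seed = 8, include_sw = TRUE, sw_replicates = 5)
  q2 <- null_quantiles(nulls_ws)
  expect_gte(q2$quantile[q2$metric == "small_world"], 0.5)
  expect_gte(q2$quantile[q2$metric == "clustering"], 0.5)
})

test_that("degree binning reproduces the printed PDF/CDF/CCDF formulas", {
  g <- as_coocc(igraph::make_graph(~ a - b, c - d))  # degrees 1,1,1,1
  g2 <- as_coocc(igraph::make_graph(~ a - b, b - c, c - d, d - a))  # all degree 2
  # degrees {1,1,2,2}: two unit bins
  g3 <- as_coocc(igraph::make_graph(~ a - b, b - c, c - d))
  cc <- degree_ccdf(g3)
  expect_equal(cc$pdf, c(0.5, 0.5))
  expect_equal(cc$cdf, c(0.5, 1))
  expect_equal(cc$ccdf, c(0.5, 0))
  expect_equal(sum(cc$pdf), 1, tolerance = 1e-9)
  # general properties
  r <- degree_ccdf(generate_signed_network(60, "random", density = 0.1, seed = 3))
  expect_equal(tail(r$ccdf, 1), 0)
  expect_true(all(diff(r$ccdf) <= 1e-12))
  expect_true(all(diff(r$cdf) >= -1e-12))
})

test_that("the CCDF comparison carries four matched curves", {
  net <- generate_signed_network(80, "random", density = 0.1, seed = 4)
  cmp <- compare_ccdf(net, seed = 4)
  expect_setequal(unique(cmp$topology),
                  c("observed", "random", "small_world", "scale_free"))
  tails <- vapply(1:10, function(s) {
    g <- generate_signed_network(100, "random", density = 0.08, seed = s)
    d <- compare_ccdf(g, seed = s)
    top <- max(d$degree) * 0.9
    c(sf = sum(d$ccdf[d$topology == "scale_free" & d$degree >= top]),
      rnd = sum(d$ccdf[d$topology == "random" & d$degree >= top]))
  }, numeric(2))
  expect_gt(mean(tails["sf", ]), mean(tails["rnd", ]))
})

test_that("metrics are invariant under node relabeling", {
  g <- generate_signed_network(40, "random", density = 0.15, seed = 9)
  perm <- withr::with_seed(1, sample(40))
  gplain <- g; class(gplain) <- "igraph"
  gp <- igraph::permute(gplain, perm)
  class(gp) <- class(g)
  s1 <- summarize_topology(g, sw_replicates = 3, seed = 5)
  s2 <- summarize_topology(gp, sw_replicates = 3, seed = 5)
  # greedy modularity is a heuristic whose tie-breaking follows vertex
  # order, so its partition (not the metric definition) may shift slightly
  expect_equal(dplyr::select(s1, -"modularity"), dplyr::select(s2, -"modularity"))
  expect_lt(abs(s1$modularity - s2$modularity), 0.1)
})
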