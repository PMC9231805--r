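test_that("community sampling respects depth, determinism and the planted null", {
  spec <- community_spec(n_taxa = 10, n_samples = 40, depth = 2000)
  com <- generate_community(spec, seed = 11)
  m <- abundance_matrix(com$table)
  expect_true(all(colSums(m) == 2000))
  expect_equal(dim(m), c(10L, 40L))

  com2 <- generate_community(spec, seed = 11)
  expect_identical(com$table, com2$table)
  com3 <- generate_community(spec, seed = 12)
  expect_false(identical(com$table, com3$table))
})

test_that("identity basis yields weak empirical log-abundance correlations", {
  spec <- community_spec(n_taxa = 10, n_samples = 500, depth = 50000)
  com <- generate_community(spec, seed = 21)
  m <- abundance_matrix(com$table)
  logs <- t(log(m + 0.5))
  r <- cor(logs)
  # compositional closure leaves mild negative bias; mean |r| stays small
  expect_lt(mean(abs(r[upper.tri(r)])), 0.15)
})

test_that("non-PSD basis matrices are rejected with a repair hint", {
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_error(community_spec(3, 10, 100, basis_correlation = bad), "nearest_psd")
  fixed <- nearest_psd_correlation(bad)
  ev <- eigen(fixed, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  expect_equal(diag(fixed), rep(1, 3))
})

test_that("sparse basis plants the requested pairs", {
  expect_equal(generate_sparse_basis(8, 0, seed = 1), diag(8), ignore_attr = TRUE)

  b <- generate_sparse_basis(50, 10, strength = 0.8, seed = 5)
  planted <- attr(b, "planted_pairs")
  expect_equal(nrow(planted), 10L)
  expect_true(all(abs(abs(planted$value) - 0.8) <= 0.05))
  expect_equal(b, t(b))
  expect_equal(diag(b), rep(1, 50))
  ev <- eigen(b, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)

  expect_error(generate_sparse_basis(4, 100, seed = 1), "exceeds")
})

test_that("signed benchmark networks respect sign fraction and density", {
  pos <- generate_signed_network(50, "random", density = 0.2, p_negative = 0, seed = 3)
  expect_true(all(igraph::E(pos)$raw_weight >= 0))

  g <- generate_signed_network(100, "random", density = 0.1, seed = 4)
  expect_equal(igraph::vcount(g), 100L)
  expect_gte(igraph::edge_density(g), 0.09)
  expect_lte(igraph::edge_density(g), 0.11)
  expect_true(all(abs(igraph::E(g)$raw_weight) <= 1))
  expect_equal(igraph::E(g)$norm_weight, (igraph::E(g)$raw_weight + 1) / 2)
})

test_that("scale-free graphs have more degree spread than matched random graphs", {
  vars <- vapply(1:20, function(s) {
    sf <- generate_signed_network(100, "scale_free", density = 0.08, seed = s)
    er <- generate_signed_network(100, "random",
                                  density = igraph::edge_density(sf), seed = s)
    c(var(igraph::degree(sf)), var(igraph::degree(er)))
  }, numeric(2))
  expect_gt(mean(vars[1, ]), mean(vars[2, ]))
})

test_that("SparCC recovers a planted strong pair from generated communities", {
  errs <- vapply(1:10, function(s) {
    b <- diag(20); b[1, 2] <- b[2, 1] <- 0.8
    com <- generate_community(community_spec(20, 200, 10000, b), seed = s)
    fit <- sparcc(com$table, n_iterations = 20, seed = s + 100)
    fit$correlations[1, 2] - 0.8
  }, numeric(1))
  expect_lte(median(abs(errs)), 0.15)
})
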