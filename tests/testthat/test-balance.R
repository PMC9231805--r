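test_that("the four triangle types classify as balance theory dictates", {
  expect_true(classify_triad("+", "+", "+")$balanced)
  expect_equal(classify_triad("+", "+", "+")$type, "ppp")
  expect_true(classify_triad("+", "-", "-")$balanced)
  expect_equal(classify_triad("+", "-", "-")$type, "pmm")
  expect_false(classify_triad("+", "+", "-")$balanced)
  expect_equal(classify_triad("+", "+", "-")$type, "ppm")
  expect_false(classify_triad("-", "-", "-")$balanced)
  expect_equal(classify_triad("-", "-", "-")$type, "mmm")

  # invariant to edge order: all 3! permutations of a mixed triple agree
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  signs <- c(0.4, -0.7, -0.1)
  res <- lapply(perms, function(p) classify_triad(signs[p[1]], signs[p[2]], signs[p[3]]))
  expect_true(all(vapply(res, function(r) r$type == "pmm" && r$balanced, logical(1))))

  expect_error(classify_triad(1, 0, 1), "zero")
})

test_that("K4 censuses match hand enumeration", {
  k4 <- as_coocc(igraph::make_full_graph(4), weights = rep(0.5, 6))
  cs <- triad_census_signed(k4)
  expect_equal(cs$total, 4L)
  expect_equal(cs$balanced_fraction, 1.0)
  expect_equal(unname(cs$counts["ppp"]), 4L)

  # flip one edge negative: it sits in 2 of the 4 triangles
  w <- rep(0.5, 6); w[1] <- -0.5
  k4n <- as_coocc(igraph::make_full_graph(4), weights = w)
  cs2 <- triad_census_signed(k4n)
  expect_equal(unname(cs2$counts[c("ppp", "ppm")]), c(2L, 2L))
  expect_equal(cs2$balanced_fraction, 0.5)
  expect_equal(sum(cs2$percent), 100, tolerance = 1e-9)
})

test_that("the census equals brute-force triple enumeration on random signed graphs", {
  for (s in 1:10) {
    net <- generate_signed_network(30, "random", density = 0.3,
                                   p_negative = 0.4, seed = s)
    cs <- triad_census_signed(net)
    oracle <- brute_census(net)
    expect_equal(cs$counts[names(oracle)], oracle)
    expect_equal(cs$total, sum(oracle))
  }
})

test_that("flipping every sign maps ppp<->mmm and pmm<->ppm", {
  net <- generate_signed_network(25, "random", density = 0.35,
                                 p_negative = 0.5, seed = 17)
  cs <- triad_census_signed(net)
  flipped <- net
  igraph::E(flipped)$raw_weight <- -igraph::E(flipped)$raw_weight
  cf <- triad_census_signed(flipped)
  expect_equal(unname(cf$counts["mmm"]), unname(cs$counts["ppp"]))
  expect_equal(unname(cf$counts["ppp"]), unname(cs$counts["mmm"]))
  expect_equal(unname(cf$counts["ppm"]), unname(cs$counts["pmm"]))
  expect_equal(unname(cf$counts["pmm"]), unname(cs$counts["ppm"]))
  expect_equal(cf$total, cs$total)
})

test_that("cycle-basis mode undercounts (at most equals) the full enumeration", {
  for (s in c(3, 5)) {
    net <- generate_signed_network(30, "random", density = 0.3, seed = s)
    expect_lte(triad_census_signed(net, mode = "cycle_basis")$total,
               triad_census_signed(net)$total)
  }
})

test_that("a triangle-free network reports an undefined balanced fraction", {
  star <- as_coocc(igraph::make_star(6, mode = "undirected"))
  cs <- triad_census_signed(star)
  expect_equal(cs$total, 0L)
  expect_true(is.na(cs$balanced_fraction))
})
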