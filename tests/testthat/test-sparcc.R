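test_that("variation matrix matches hand-computed log-ratio variances", {
  # log-ratios of taxa a vs b across 3 samples are {0, 1, 2}: var = 1
  f <- cbind(a = exp(c(0, 1, 2)), b = c(1, 1, 1), c = c(2, 2, 2))
  f <- f / rowSums(f)
  t_mat <- variation_matrix(f)
  expect_equal(t_mat["a", "b"], 1.0)
  expect_equal(t_mat["b", "c"], 0)      # proportional taxa
  expect_equal(diag(t_mat), c(a = 0, b = 0, c = 0))

  r <- withr::with_seed(5, matrix(runif(60, 0.01, 1), 20, 3))
  r <- r / rowSums(r)
  tr <- variation_matrix(r)
  expect_equal(tr, t(tr))
  expect_true(all(tr >= 0))
  expect_error(variation_matrix(cbind(c(0, 1), c(1, 1), c(1, 1))), "positive")
})

test_that("basis solver reproduces the closed-form three-taxon solution", {
  t_mat <- matrix(c(0, 2, 2, 2, 0, 2, 2, 2, 0), 3)
  res <- basis_correlations(t_mat)
  expect_equal(res$omega, rep(1, 3))
  expect_equal(res$rho[1, 2], 0)

  # omega_1 = (t12 + t13 - t23)/2 = -0.5: degenerate taxon path
  t_bad <- matrix(c(0, 0.5, 0.5, 0.5, 0, 2, 0.5, 2, 0), 3)
  res2 <- basis_correlations(t_bad)
  expect_equal(res2$degenerate, 1L)
  expect_equal(res2$rho[1, 2], 0)
  expect_equal(res2$rho[1, 3], 0)
  expect_equal(diag(res2$rho), rep(1, 3))

  # correlations are clamped into [-1, 1]
  t_clamp <- matrix(c(0, 0.01, 4, 0.01, 0, 4, 4, 4, 0), 3)
  res3 <- basis_correlations(t_clamp)
  expect_true(all(res3$rho >= -1 & res3$rho <= 1))

  expect_error(basis_correlations(matrix(0, 2, 2)), "3 taxa")
})

test_that("single-pass SparCC without resampling equals the independent D=3 closed form", {
  f <- withr::with_seed(9, matrix(runif(30, 0.05, 1), 10, 3))
  f <- f / rowSums(f)
  tbl <- abundance_tbl(t(f), ids = c("a", "b", "c"))

  fit <- sparcc(tbl, n_iterations = 1, exclusion_max = 0, resample = FALSE, seed = 1)

  # independent oracle: variances of pairwise log-ratios and the D=3 formulas
  lr <- function(i, j) var(log(f[, i] / f[, j]))
  t12 <- lr(1, 2); t13 <- lr(1, 3); t23 <- lr(2, 3)
  w1 <- (t12 + t13 - t23) / 2
  w2 <- (t12 + t23 - t13) / 2
  w3 <- (t13 + t23 - t12) / 2
  rho12 <- (w1 + w2 - t12) / (2 * sqrt(w1 * w2))
  rho13 <- (w1 + w3 - t13) / (2 * sqrt(w1 * w3))
  rho23 <- (w2 + w3 - t23) / (2 * sqrt(w2 * w3))

  expect_equal(fit$correlations["a", "b"], rho12, tolerance = 1e-10)
  expect_equal(fit$correlations["a", "c"], rho13, tolerance = 1e-10)
  expect_equal(fit$correlations["b", "c"], rho23, tolerance = 1e-10)
})

test_that("the estimate is exactly symmetric with unit diagonal on random inputs", {
  for (s in 1:3) {
    m <- withr::with_seed(s, matrix(rpois(8 * 20, 10), 8, 20))
    # degenerate basis-variance iterations may warn; symmetry must still hold
    fit <- suppressWarnings(sparcc(abundance_tbl(m), n_iterations = 5, seed = s))
    expect_identical(fit$correlations, t(fit$correlations))
    expect_equal(diag(fit$correlations), setNames(rep(1, 8), paste0("t", 1:8)))
    expect_true(all(abs(fit$correlations) <= 1))
  }
})

test_that("defaults match the established pipeline settings", {
  f <- formals(sparcc)
  expect_equal(eval(f$n_iterations), 50)
  expect_equal(eval(f$exclusion_threshold), 0.10)
  expect_equal(eval(f$exclusion_max), 10)
  expect_equal(eval(formals(sparcc_pvalues)$n_permutations), 100)
  expect_true(eval(formals(sparcc_pvalues)$one_sided))
})

test_that("a null community yields small correlations and a planted pair dominates", {
  com <- generate_community(community_spec(50, 200, 10000), seed = 31)
  fit <- sparcc(com$table, seed = 31)
  off <- fit$correlations[upper.tri(fit$correlations)]
  expect_lt(median(abs(off)), 0.1)

  b <- diag(15); b[3, 7] <- b[7, 3] <- 0.8
  com2 <- generate_community(community_spec(15, 200, 10000, b), seed = 32)
  fit2 <- sparcc(com2$table, n_iterations = 20, seed = 32)
  r <- abs(fit2$correlations); diag(r) <- 0
  expect_equal(sort(which(r == max(r))), sort(c(which(row(r) == 3 & col(r) == 7),
                                                which(row(r) == 7 & col(r) == 3))))
})

test_that("disk-backed scratch mode reproduces the in-memory estimate", {
  com <- generate_community(community_spec(12, 50, 2000), seed = 41)
  scratch <- tempfile(fileext = ".h5")
  f_mem <- sparcc(com$table, n_iterations = 6, seed = 7)
  f_dsk <- sparcc(com$table, n_iterations = 6, seed = 7, scratch_path = scratch)
  expect_equal(f_dsk$correlations, f_mem$correlations, tolerance = 1e-12)
  ls <- rhdf5::h5ls(scratch)
  expect_true(all(paste0("/iter_", 1:6) %in% ls$group[ls$name == "rho"]))
  expect_error(sparcc(com$table, n_iterations = 2, seed = 7,
                      scratch_path = "/nonexistent-dir/x.h5"),
               "scratch")
})

test_that("permutation p-values honour the add-one bounds and tail conventions", {
  b <- diag(10); b[1, 2] <- b[2, 1] <- 0.8
  com <- generate_community(community_spec(10, 100, 5000, b), seed = 51)
  fit <- sparcc(com$table, n_iterations = 10, seed = 51)
  fit <- sparcc_pvalues(com$table, fit, n_permutations = 50, seed = 52)
  p <- fit$pvalues
  expect_equal(min(p[upper.tri(p)]), 1 / 51)            # strong planted signal
  expect_equal(p[1, 2], 1 / 51)
  expect_true(all(p[upper.tri(p)] >= 1 / 51 & p[upper.tri(p)] <= 1))
  expect_equal(p, t(p))
  expect_equal(diag(p), setNames(rep(0, 10), paste0("taxon_", 1:10)))

  # two-sided mode is symmetric in the sign of the observed value
  fit_pos <- fit; fit_neg <- fit
  fit_neg$correlations <- -fit$correlations; diag(fit_neg$correlations) <- 1
  p_pos <- sparcc_pvalues(com$table, fit_pos, n_permutations = 20,
                          one_sided = FALSE, seed = 53)$pvalues
  p_neg <- sparcc_pvalues(com$table, fit_neg, n_permutations = 20,
                          one_sided = FALSE, seed = 53)$pvalues
  expect_equal(p_pos, p_neg)
})

test_that("tidy and glance expose the pairwise estimates", {
  com <- generate_community(community_spec(5, 30, 1000), seed = 61)
  fit <- sparcc(com$table, n_iterations = 3, seed = 61)
  td <- tidy(fit)
  expect_equal(nrow(td), choose(5, 2))
  expect_equal(td$estimate[td$taxon1 == "taxon_1" & td$taxon2 == "taxon_2"],
               fit$correlations[1, 2])
  g <- glance(fit)
  expect_equal(g$n_taxa, 5L)
  expect_equal(g$n_iterations, 3)
})
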