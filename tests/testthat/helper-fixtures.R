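# Small fixtures and independent oracles shared across tests.

# Abundance tibble from a taxa-by-samples matrix.
abundance_tbl <- function(m, taxonomy = NULL, ids = NULL) {
  ids <- ids %||% rownames(m) %||% paste0("t", seq_len(nrow(m)))
  out <- tibble::tibble(taxon_id = ids)
  if (!is.null(taxonomy)) out$taxonomy <- taxonomy
  colnames(m) <- colnames(m) %||% paste0("s", seq_len(ncol(m)))
  dplyr::bind_cols(out, tibble::as_tibble(as.data.frame(m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Wrap a plain igraph as a signed co-occurrence network.
as_coocc <- function(g, weights = NULL) {
  if (is.null(igraph::V(g)$name)) igraph::V(g)$name <- paste0("n", seq_len(igraph::vcount(g)))
  w <- weights %||% rep(0.5, igraph::ecount(g))
  igraph::E(g)$raw_weight <- w
  igraph::E(g)$norm_weight <- (w + 1) / 2
  class(g) <- c("cooccurrence_network", class(g))
  g
}

# Brute-force signed triangle census over all C(n, 3) vertex triples
# (vectorised; the independent oracle for the census).
brute_census <- function(net) {
  n <- igraph::vcount(net)
  am <- igraph::as_adjacency_matrix(net, sparse = FALSE)
  w <- matrix(0, n, n)
  el <- igraph::as_edgelist(net, names = FALSE)
  for (e in seq_len(nrow(el))) {
    w[el[e, 1L], el[e, 2L]] <- w[el[e, 2L], el[e, 1L]] <- igraph::E(net)$raw_weight[e]
  }
  trip <- t(utils::combn(n, 3L))
  ix <- function(tr, cols) tr[, cols, drop = FALSE]
  is_tri <- (am[ix(trip, 1:2)] > 0) & (am[ix(trip, c(1, 3))] > 0) & (am[ix(trip, 2:3)] > 0)
  trip <- trip[is_tri, , drop = FALSE]
  if (nrow(trip) == 0L) return(c(ppp = 0L, ppm = 0L, pmm = 0L, mmm = 0L))
  npos <- (w[ix(trip, 1:2)] > 0) + (w[ix(trip, c(1, 3))] > 0) + (w[ix(trip, 2:3)] > 0)
  counts <- vapply(0:3, function(k) sum(npos == k), integer(1))
  c(ppp = counts[4L], ppm = counts[3L], pmm = counts[2L], mmm = counts[1L])
}

# Adjusted Rand index between two labelings (independent of any package).
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Abundance table with three planted taxon blocks, each enriched in its own
# third of the samples.
block_table <- function(seed, n_per = 30, n_samples = 30) {
  withr::with_seed(seed, {
    m <- matrix(stats::rpois(3 * n_per * n_samples, 2), 3 * n_per, n_samples)
    per_block_samples <- n_samples %/% 3
    for (b in 1:3) {
      rows <- ((b - 1) * n_per + 1):(b * n_per)
      cols <- ((b - 1) * per_block_samples + 1):(b * per_block_samples)
      m[rows, cols] <- m[rows, cols] + matrix(stats::rpois(n_per * length(cols), 60), n_per)
    }
    abundance_tbl(m)
  })
}
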