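#' Specify a synthetic multinomial log-normal community
#'
#' Describes the benchmark generator used throughout the package: absolute
#' abundances are log-normal with a planted *basis* correlation matrix, and
#' sequencing is emulated by multinomial sampling of a fixed number of reads
#' per sample. This is the classical validation design for compositional
#' correlation estimators (50 taxa, 200 samples in the reference setting).
#'
#' @param n_taxa Number of taxa.
#' @param n_samples Number of samples.
#' @param depth Reads per sample (multinomial size).
#' @param basis_correlation Symmetric positive semi-definite correlation
#'   matrix with unit diagonal, `n_taxa` x `n_taxa`. Default: identity
#'   (uncorrelated community).
#' @param log_mean,log_sd Mean and standard deviation of the per-taxon
#'   log-abundances; scalars are recycled.
#' @return A `community_spec` list.
#' @seealso [generate_community()], [generate_sparse_basis()]
#' @export
community_spec <- function(n_taxa = 50, n_samples = 200, depth = 10000,
                           basis_correlation = NULL, log_mean = 0, log_sd = 1) {
  basis_correlation <- basis_correlation %||% diag(n_taxa)
  if (!is.matrix(basis_correlation) || nrow(basis_correlation) != n_taxa ||
      ncol(basis_correlation) != n_taxa) {
    abort("'basis_correlation' must be an n_taxa x n_taxa matrix")
  }
  if (max(abs(basis_correlation - t(basis_correlation))) > 1e-8) {
    abort("'basis_correlation' must be symmetric")
  }
  if (max(abs(diag(basis_correlation) - 1)) > 1e-8) {
    abort("'basis_correlation' must have unit diagonal")
  }
  ev <- eigen(basis_correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    abort(paste0("'basis_correlation' is not positive semi-definite ",
                 "(smallest eigenvalue ", signif(min(ev), 3),
                 "); consider nearest_psd_correlation()"))
  }
  log_sd <- rep_len(log_sd, n_taxa)
  if (any(log_sd <= 0)) abort("'log_sd' must be positive")
  structure(list(
    n_taxa = n_taxa, n_samples = n_samples, depth = depth,
    basis_correlation = basis_correlation,
    log_mean = rep_len(log_mean, n_taxa), log_sd = log_sd
  ), class = "community_spec")
}

#' Project a symmetric matrix to the nearest PSD correlation matrix
#'
#' Eigenvalue clipping (negative eigenvalues set to zero) followed by
#' rescaling to unit diagonal.
#'
#' @param m Symmetric matrix.
#' @return A positive semi-definite matrix with unit diagonal.
#' @export
nearest_psd_correlation <- function(m) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  out <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(pmax(diag(out), .Machine$double.eps))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  (out + t(out)) / 2
}

#' Generate a synthetic community with known basis correlations
#'
#' For each sample, draws log-abundances from a multivariate normal with
#' covariance `diag(log_sd) %*% basis_correlation %*% diag(log_sd)`,
#' exponentiates, normalises to fractions, and draws `depth` multinomial
#' reads. Deterministic given `seed`.
#'
#' @param spec A [community_spec()].
#' @param seed Integer seed.
#' @return A list with elements `table` (abundance tibble with taxa
#'   `taxon_1..n` and samples `sample_1..m`) and `basis` (the planted
#'   correlation matrix).
#' @examples
#' com <- generate_community(community_spec(n_taxa = 10, n_samples = 20,
#'                                          depth = 1000), seed = 1)
#' dim(abundance_matrix(com$table))
#' @export
generate_community <- function(spec, seed = 1L) {
  if (!inherits(spec, "community_spec")) abort("'spec' must be a community_spec")
  withr::with_seed(seed, {
    sigma <- diag(spec$log_sd) %*% spec$basis_correlation %*% diag(spec$log_sd)
    logs <- MASS::mvrnorm(spec$n_samples, mu = spec$log_mean, Sigma = sigma,
                          tol = 1e-6)
    logs <- matrix(logs, nrow = spec$n_samples)
    fracs <- exp(logs)
    fracs <- fracs / rowSums(fracs)
    counts <- apply(fracs, 1L, function(p) rmultinom(1L, spec$depth, p))
  })
  taxa <- paste0("taxon_", seq_len(spec$n_taxa))
  samples <- paste0("sample_", seq_len(spec$n_samples))
  dimnames(counts) <- list(taxa, samples)
  basis <- spec$basis_correlation
  dimnames(basis) <- list(taxa, taxa)
  tbl <- dplyr::bind_cols(
    tibble::tibble(taxon_id = taxa),
    tibble::as_tibble(as.data.frame(counts))
  )
  list(table = tbl, basis = basis)
}

#' Generate a sparse strong basis correlation matrix
#'
#' Identity plus `n_strong` randomly chosen off-diagonal pairs set to
#' `strength` (with a fraction `p_negative` flipped to `-strength`), then
#' projected to the nearest PSD correlation matrix. While
#' `n_strong <= n_taxa / 2` the planted pairs are taxon-disjoint, so the
#' matrix is block-diagonal and already PSD and the planted values are
#' exact; with more pairs than that, taxa must be shared, mutually
#' inconsistent strong correlations can arise, and the PSD repair may
#' shrink some planted values.
#'
#' @param n_taxa Matrix dimension.
#' @param n_strong Number of planted strong pairs; at most
#'   `n_taxa * (n_taxa - 1) / 2`.
#' @param strength Magnitude of the planted correlations, in (0, 1).
#' @param p_negative Probability a planted pair is negative. Default 0.
#' @param seed Integer seed.
#' @return A correlation matrix with attribute `"planted_pairs"`: a tibble
#'   with columns `i`, `j`, `value` (the values after PSD repair).
#' @export
generate_sparse_basis <- function(n_taxa, n_strong, strength = 0.8,
                                  p_negative = 0, seed = 1L) {
  max_pairs <- n_taxa * (n_taxa - 1) / 2
  if (n_strong > max_pairs) {
    abort(paste0("'n_strong' (", n_strong, ") exceeds the number of off-diagonal pairs (",
                 max_pairs, ")"))
  }
  if (strength <= 0 || strength >= 1) abort("'strength' must be in (0, 1)")
  m <- diag(n_taxa)
  if (n_strong > 0) {
    pairs <- withr::with_seed(seed, {
      if (2 * n_strong <= n_taxa) {
        taxa <- sample.int(n_taxa, 2L * n_strong)
        sel <- cbind(taxa[seq_len(n_strong)], taxa[n_strong + seq_len(n_strong)])
        sel <- cbind(pmin(sel[, 1L], sel[, 2L]), pmax(sel[, 1L], sel[, 2L]))
      } else {
        all_pairs <- which(upper.tri(m), arr.ind = TRUE)
        sel <- all_pairs[sample.int(max_pairs, n_strong), , drop = FALSE]
      }
      sgn <- ifelse(runif(n_strong) < p_negative, -1, 1)
      list(sel = sel, sgn = sgn)
    })
    sel <- pairs$sel
    for (k in seq_len(n_strong)) {
      m[sel[k, 1L], sel[k, 2L]] <- m[sel[k, 2L], sel[k, 1L]] <- pairs$sgn[k] * strength
    }
    m <- nearest_psd_correlation(m)
    planted <- tibble::tibble(
      i = as.integer(sel[, 1L]), j = as.integer(sel[, 2L]),
      value = m[sel]
    )
  } else {
    planted <- tibble::tibble(i = integer(), j = integer(), value = double())
  }
  attr(m, "planted_pairs") <- planted
  m
}

#' Generate a signed benchmark network
#'
#' Builds a random (Erdős–Rényi), small-world (Watts–Strogatz) or scale-free
#' (Barabási–Albert) graph at a target density and decorates edges with
#' weights drawn uniformly from \[-1, 1\], with the sign fraction controlled
#' by `p_negative`.
#'
#' @param n_nodes Number of nodes.
#' @param topology `"random"`, `"small_world"` or `"scale_free"`.
#' @param density Target edge density (achieved exactly for `"random"`,
#'   within about 10% for the structured topologies).
#' @param p_negative Fraction of negative edge weights.
#' @param seed Integer seed.
#' @return An igraph co-occurrence network (see [build_network()] for the
#'   edge attribute contract).
#' @export
generate_signed_network <- function(n_nodes, topology = c("random", "small_world", "scale_free"),
                                    density = 0.1, p_negative = 0.5, seed = 1L) {
  topology <- match.arg(topology)
  if (density <= 0 || density > 1) abort("'density' must be in (0, 1]")
  withr::with_seed(seed, {
    g <- make_topology_graph(n_nodes, density, topology)
    ne <- igraph::ecount(g)
    mag <- runif(ne)
    sgn <- ifelse(runif(ne) < p_negative, -1, 1)
    w <- mag * sgn
    igraph::E(g)$raw_weight <- w
    igraph::E(g)$norm_weight <- normalize_weight(w)
  })
  igraph::V(g)$name <- paste0("taxon_", seq_len(n_nodes))
  class(g) <- c("cooccurrence_network", class(g))
  g
}

# Matched-topology generator shared with the null-model machinery.
# Caller is responsible for seeding.
make_topology_graph <- function(n_nodes, density, topology) {
  m_target <- round(density * n_nodes * (n_nodes - 1) / 2)
  avg_degree <- density * (n_nodes - 1)
  g <- switch(topology,
    random = igraph::sample_gnm(n_nodes, m_target),
    small_world = {
      nei <- max(1L, round(avg_degree / 2))
      igraph::simplify(igraph::sample_smallworld(1L, n_nodes, nei, p = 0.1))
    },
    scale_free = {
      m <- max(1L, round(avg_degree / 2))
      igraph::simplify(igraph::sample_pa(n_nodes, m = m, directed = FALSE))
    }
  )
  achieved <- igraph::edge_density(g)
  if (m_target > 0 && abs(achieved - density) / density > 0.1) {
    warn(paste0("achieved density ", signif(achieved, 3), " for topology '", topology,
                "' differs from target ", signif(density, 3), " by more than 10%"))
  }
  g
}
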