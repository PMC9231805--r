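#' Log-ratio variation matrix
#'
#' The sufficient statistic of the SparCC estimator:
#' `t[i, j] = Var(log(x[, i] / x[, j]))` across samples, with the unbiased
#' (n - 1) variance. Computed from the covariance matrix of the
#' log-fractions, so it costs one `cov()` call rather than a pairwise loop.
#'
#' @param fractions Samples-by-taxa matrix of strictly positive fractions
#'   (zeros must be handled upstream, e.g. by Dirichlet resampling of
#'   counts; see [sparcc()]).
#' @return A symmetric non-negative taxa-by-taxa matrix with zero diagonal.
#' @export
variation_matrix <- function(fractions) {
  fractions <- as.matrix(fractions)
  if (any(fractions <= 0)) {
    abort("all fractions must be strictly positive; resample counts first (see sparcc(resample = TRUE))")
  }
  l <- log(fractions)
  v <- cov(l)
  d <- diag(v)
  t_mat <- outer(d, rep(1, length(d))) + outer(rep(1, length(d)), d) - 2 * v
  t_mat <- (t_mat + t(t_mat)) / 2
  t_mat[t_mat < 0] <- 0
  diag(t_mat) <- 0
  dimnames(t_mat) <- dimnames(v)
  t_mat
}

#' Solve for basis variances and correlations
#'
#' Given the variation matrix `t`, solves the SparCC linear system for the
#' basis variances `omega` under the sparsity approximation, restricted to
#' non-excluded pairs, then forms
#' `rho[i, j] = (omega[i] + omega[j] - t[i, j]) / (2 * sqrt(omega[i] * omega[j]))`,
#' clamped to \[-1, 1\]. Excluded pairs drop out of the linear system only;
#' their correlations are still reported from the solved `omega` and their
#' `t` values.
#'
#' Taxa whose solved basis variance is non-positive are flagged as
#' degenerate: their off-diagonal correlations are set to 0 and their indices
#' returned in `degenerate`.
#'
#' @param t_mat Variation matrix (symmetric, zero diagonal).
#' @param excluded Optional two-column matrix of excluded index pairs.
#' @return A list with `omega` (basis variances), `rho` (correlation matrix,
#'   unit diagonal) and `degenerate` (integer indices).
#' @export
basis_correlations <- function(t_mat, excluded = NULL) {
  d_n <- nrow(t_mat)
  if (is.null(d_n) || d_n < 3L) {
    abort("at least 3 taxa are required to identify basis correlations")
  }
  incl <- matrix(TRUE, d_n, d_n)
  diag(incl) <- FALSE
  if (!is.null(excluded) && nrow(excluded) > 0L) {
    for (k in seq_len(nrow(excluded))) {
      i <- excluded[k, 1L]; j <- excluded[k, 2L]
      incl[i, j] <- incl[j, i] <- FALSE
    }
  }
  deg_free <- rowSums(incl)
  if (any(deg_free < 1)) {
    abort("a taxon has every pair excluded; reduce 'exclusion_max'")
  }
  m_mat <- incl * 1
  diag(m_mat) <- deg_free
  rhs <- rowSums(t_mat * incl)
  omega <- solve(m_mat, rhs)

  degenerate <- which(omega <= 0)
  omega_safe <- pmax(omega, .Machine$double.eps)
  denom <- 2 * sqrt(outer(omega_safe, omega_safe))
  rho <- (outer(omega_safe, rep(1, d_n)) + outer(rep(1, d_n), omega_safe) - t_mat) / denom
  rho <- pmin(pmax(rho, -1), 1)
  if (length(degenerate) > 0L) {
    rho[degenerate, ] <- 0
    rho[, degenerate] <- 0
  }
  diag(rho) <- 1
  list(omega = omega, rho = rho, degenerate = degenerate)
}

# One full SparCC pass on a samples-by-taxa fraction matrix: variation
# matrix, then iterative exclusion of the most strongly correlated pair
# while |rho| > threshold, re-solving omega after each exclusion.
sparcc_pass <- function(fractions, exclusion_threshold, exclusion_max) {
  t_mat <- variation_matrix(fractions)
  excluded <- matrix(integer(), 0L, 2L)
  res <- basis_correlations(t_mat)
  n_degenerate <- length(res$degenerate)
  while (nrow(excluded) < exclusion_max) {
    rho <- abs(res$rho)
    diag(rho) <- 0
    if (nrow(excluded) > 0L) {
      rho[excluded] <- 0
      rho[excluded[, 2:1, drop = FALSE]] <- 0
    }
    m <- max(rho)
    if (m <= exclusion_threshold) break
    # lexicographically smallest (row, col) pair among ties, i < j
    hits <- which(rho == m, arr.ind = TRUE)
    hits <- hits[hits[, 1L] < hits[, 2L], , drop = FALSE]
    hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
    excluded <- rbind(excluded, hits[1L, , drop = FALSE])
    res <- basis_correlations(t_mat, excluded)
    n_degenerate <- max(n_degenerate, length(res$degenerate))
  }
  list(rho = res$rho, n_excluded = nrow(excluded), n_degenerate = n_degenerate)
}

# Counts (taxa x samples) -> list of per-iteration handling; returns the
# entrywise-median correlation matrix across outer resampling iterations.
sparcc_core <- function(counts, n_iterations, exclusion_threshold, exclusion_max,
                        resample, seed, scratch_path = NULL) {
  p <- nrow(counts)
  tm <- t(counts)
  use_scratch <- !is.null(scratch_path)
  if (use_scratch) {
    if (!requireNamespace("rhdf5", quietly = TRUE)) {
      abort("package 'rhdf5' is required for disk-backed scratch storage")
    }
    if (file.exists(scratch_path)) file.remove(scratch_path)
    ok <- try(rhdf5::h5createFile(scratch_path), silent = TRUE)
    if (inherits(ok, "try-error") || !isTRUE(ok)) {
      abort(paste0("scratch path not writable: '", scratch_path, "'"))
    }
  }
  iter_rhos <- if (!use_scratch) vector("list", n_iterations)
  n_degenerate <- 0L
  for (k in seq_len(n_iterations)) {
    fracs <- withr::with_seed(seed + k, {
      if (resample) {
        g <- matrix(rgamma(length(tm), shape = tm + 1), nrow(tm), ncol(tm))
        g / rowSums(g)
      } else {
        if (any(tm <= 0)) {
          abort("zero abundances present; use resample = TRUE (Dirichlet resampling)")
        }
        tm / rowSums(tm)
      }
    })
    pass <- sparcc_pass(fracs, exclusion_threshold, exclusion_max)
    n_degenerate <- n_degenerate + (pass$n_degenerate > 0L)
    if (use_scratch) {
      grp <- paste0("iter_", k)
      rhdf5::h5createGroup(scratch_path, grp)
      rhdf5::h5write(pass$rho, scratch_path, paste0(grp, "/rho"))
    } else {
      iter_rhos[[k]] <- pass$rho
    }
    if (!resample) {
      # without resampling every iteration is identical; one pass suffices
      if (use_scratch) rhdf5::h5closeAll()
      rho <- pass$rho
      return(list(rho = rho, n_degenerate = n_degenerate))
    }
  }

  if (use_scratch) {
    # stream the entrywise median in row chunks so only O(chunk * p) of each
    # iteration is ever resident
    chunk <- max(1L, floor(4e6 / (n_iterations * p)))
    rho <- matrix(0, p, p)
    for (start in seq(1L, p, by = chunk)) {
      rows <- start:min(start + chunk - 1L, p)
      block <- array(0, dim = c(length(rows), p, n_iterations))
      for (k in seq_len(n_iterations)) {
        block[, , k] <- rhdf5::h5read(scratch_path, paste0("iter_", k, "/rho"),
                                      index = list(rows, NULL))
      }
      rho[rows, ] <- apply(block, c(1L, 2L), median)
    }
    rhdf5::h5closeAll()
  } else {
    rho <- apply(simplify2array(iter_rhos), c(1L, 2L), median)
  }
  rho <- (rho + t(rho)) / 2
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  list(rho = rho, n_degenerate = n_degenerate)
}

#' SparCC basis correlations from an abundance table
#'
#' Estimates pairwise basis correlations from compositional count data.
#' Each outer iteration draws per-sample fractions from a
#' `Dirichlet(counts + 1)` posterior (which also resolves zero counts),
#' computes the log-ratio variation matrix, solves for basis variances with
#' iterative exclusion of strongly correlated pairs, and the final estimate
#' is the entrywise median across iterations.
#'
#' Defaults follow the established pipeline settings: 50 iterations,
#' exclusion threshold 0.10, at most 10 excluded pairs.
#'
#' @param x Abundance tibble (see [read_abundance()]); typically filtered
#'   with [filter_low_abundance()] first.
#' @param n_iterations Outer resampling iterations.
#' @param exclusion_threshold Exclude the most strongly correlated pair
#'   while its `|rho|` exceeds this value.
#' @param exclusion_max Maximum number of excluded pairs per pass.
#' @param resample Draw fractions from `Dirichlet(counts + 1)`? With
#'   `FALSE` the table must be zero-free and is normalised directly; all
#'   iterations are then identical, so a single pass is run.
#' @param seed Integer seed; per-iteration substreams are derived from it by
#'   fixed offsets.
#' @param scratch_path Optional HDF5 file; when set, each iteration's
#'   correlation matrix is written to `/iter_<k>/rho` on disk and the median
#'   is aggregated in row chunks instead of holding all iterations in RAM.
#' @return A `sparcc_fit` object with elements `taxon_ids`, `correlations`
#'   (symmetric, unit diagonal, entries in \[-1, 1\]), `pvalues` (`NULL`
#'   until [sparcc_pvalues()] is run) and `config`.
#' @examples
#' com <- generate_community(community_spec(n_taxa = 10, n_samples = 30,
#'                                          depth = 2000), seed = 1)
#' fit <- sparcc(com$table, n_iterations = 5, seed = 1)
#' tidy(fit)
#' @export
sparcc <- function(x, n_iterations = 50, exclusion_threshold = 0.10,
                   exclusion_max = 10, resample = TRUE, seed = 1L,
                   scratch_path = NULL) {
  validate_abundance(x)
  stopifnot(n_iterations >= 1, exclusion_threshold > 0, exclusion_threshold < 1,
            exclusion_max >= 0)
  counts <- abundance_matrix(x)
  if (nrow(counts) < 3L) abort("SparCC requires at least 3 taxa")
  if (ncol(counts) < 4L) warn("fewer than 4 samples: SparCC estimates will be unstable")

  core <- sparcc_core(counts, n_iterations, exclusion_threshold, exclusion_max,
                      resample, seed, scratch_path)
  if (core$n_degenerate > 0L) {
    warn(paste0("degenerate basis variances (omega <= 0) in ", core$n_degenerate,
                " iteration(s); affected taxa were zeroed"))
  }
  rho <- core$rho
  dimnames(rho) <- list(x$taxon_id, x$taxon_id)
  structure(list(
    taxon_ids = x$taxon_id,
    correlations = rho,
    pvalues = NULL,
    config = list(n_iterations = n_iterations,
                  exclusion_threshold = exclusion_threshold,
                  exclusion_max = exclusion_max, resample = resample,
                  seed = seed, scratch_path = scratch_path),
    n_samples = ncol(counts)
  ), class = "sparcc_fit")
}

#' Monte-Carlo permutation p-values for SparCC correlations
#'
#' For each permutation, every taxon's counts are shuffled independently
#' across samples (destroying all pairwise association while keeping
#' marginals), SparCC is re-run, and one-sided p-values are computed with
#' the add-one estimator
#' `p = (1 + #\{rho_perm >= rho_obs\}) / (n_permutations + 1)` for
#' non-negative observed correlations and the mirrored lower tail for
#' negative ones. Two-sided p-values use `|rho|`.
#'
#' Permutation runs use the observed fit's exclusion settings but fewer
#' outer iterations (`perm_iterations`, default 5) — the permutation null
#' does not need the full resampling depth of the point estimate.
#'
#' @param x The abundance tibble the fit was computed on.
#' @param fit A [sparcc()] fit.
#' @param n_permutations Number of Monte-Carlo permutations. 100 is the
#'   pipeline default; 50 is a common quick-mode setting.
#' @param one_sided Use one-sided tail probabilities (default) or two-sided.
#' @param perm_iterations Outer iterations per permutation run.
#' @param seed Integer seed; defaults to a fixed offset of the fit's seed.
#' @return The fit with `pvalues` filled in (symmetric, zero diagonal,
#'   entries in `[1/(n+1), 1]`).
#' @export
sparcc_pvalues <- function(x, fit, n_permutations = 100, one_sided = TRUE,
                           perm_iterations = 5, seed = NULL) {
  stopifnot(inherits(fit, "sparcc_fit"), n_permutations >= 1)
  validate_abundance(x)
  if (!identical(x$taxon_id, fit$taxon_ids)) {
    abort("'x' does not match the table the fit was computed on")
  }
  seed <- seed %||% (fit$config$seed + 90001L)
  counts <- abundance_matrix(x)
  obs <- fit$correlations
  exceed <- matrix(0L, nrow(obs), ncol(obs))
  for (b in seq_len(n_permutations)) {
    sb <- (seed + b * 131L) %% 2147483629L
    perm <- withr::with_seed(sb, {
      t(apply(counts, 1L, sample))
    })
    core <- sparcc_core(perm, perm_iterations, fit$config$exclusion_threshold,
                        fit$config$exclusion_max, resample = TRUE,
                        seed = sb + 1L, scratch_path = NULL)
    if (one_sided) {
      hit <- (obs >= 0 & core$rho >= obs) | (obs < 0 & core$rho <= obs)
    } else {
      hit <- abs(core$rho) >= abs(obs)
    }
    exceed <- exceed + hit
  }
  p <- (1 + exceed) / (n_permutations + 1)
  p <- (p + t(p)) / 2
  diag(p) <- 0
  dimnames(p) <- dimnames(obs)
  fit$pvalues <- p
  fit$config$n_permutations <- n_permutations
  fit$config$one_sided <- one_sided
  fit
}

#' @export
print.sparcc_fit <- function(x, ...) {
  cat("SparCC fit:", length(x$taxon_ids), "taxa,", x$n_samples, "samples\n")
  off <- x$correlations[upper.tri(x$correlations)]
  cat("  iterations:", x$config$n_iterations,
      " exclusion: |rho| >", x$config$exclusion_threshold,
      " (max", x$config$exclusion_max, "pairs)\n")
  cat("  off-diagonal |rho|: median", signif(median(abs(off)), 3),
      " max", signif(max(abs(off)), 3), "\n")
  if (!is.null(x$pvalues)) {
    cat("  p-values:", x$config$n_permutations, "permutations,",
        if (isTRUE(x$config$one_sided)) "one-sided" else "two-sided", "\n")
  }
  invisible(x)
}

#' Tidy a SparCC fit into a pairwise tibble
#'
#' @param x A `sparcc_fit`.
#' @param ... Unused.
#' @return A tibble with one row per unordered taxon pair: `taxon1`,
#'   `taxon2`, `estimate` and, when computed, `p.value`.
#' @export
tidy.sparcc_fit <- function(x, ...) {
  ut <- which(upper.tri(x$correlations), arr.ind = TRUE)
  out <- tibble::tibble(
    taxon1 = x$taxon_ids[ut[, 1L]],
    taxon2 = x$taxon_ids[ut[, 2L]],
    estimate = x$correlations[ut]
  )
  if (!is.null(x$pvalues)) out$p.value <- x$pvalues[ut]
  out
}

#' One-row summary of a SparCC fit
#'
#' @param x A `sparcc_fit`.
#' @param ... Unused.
#' @return A one-row tibble with fit dimensions, settings and the median and
#'   maximum off-diagonal `|rho|`.
#' @export
glance.sparcc_fit <- function(x, ...) {
  off <- abs(x$correlations[upper.tri(x$correlations)])
  tibble::tibble(
    n_taxa = length(x$taxon_ids),
    n_samples = x$n_samples,
    n_iterations = x$config$n_iterations,
    exclusion_threshold = x$config$exclusion_threshold,
    exclusion_max = x$config$exclusion_max,
    median_abs_correlation = median(off),
    max_abs_correlation = max(off),
    n_permutations = x$config$n_permutations %||% NA_integer_
  )
}
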