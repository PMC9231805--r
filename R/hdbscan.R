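#' HDBSCAN density clustering with GLOSH outlier scores
#'
#' Hierarchical density-based clustering on a precomputed distance matrix:
#' mutual-reachability distances (`max(core_i, core_j, d_ij)`, with the core
#' distance of a point its distance to the `min_samples`-th nearest
#' neighbour, the point itself included), single-linkage hierarchy, a
#' condensed cluster tree in which branches smaller than
#' `min_cluster_size` fall out as individual points, and excess-of-mass
#' cluster selection. Points not captured by any selected cluster are
#' *noise* (label `-1`). Each point also receives a GLOSH outlier score in
#' \[0, 1\]: `(death(c) - lambda(p)) / death(c)`, where `c` is the last
#' cluster the point belonged to and `death(c)` the largest density level
#' attained in its subtree.
#'
#' The root cluster (the full data set) is never selected, so data with no
#' density structure at the requested `min_cluster_size` comes back as all
#' noise.
#'
#' @param d A `dist` object or symmetric distance matrix.
#' @param min_cluster_size Smallest branch size that counts as a cluster
#'   (at least 2).
#' @param min_samples Neighbourhood size for the core distance.
#' @return An `hdbscan_fit` list: `cluster` (integer labels `0..K-1`, noise
#'   `-1`), `outlier_score`, `n_clusters`, `min_cluster_size`,
#'   `min_samples`.
#' @examples
#' x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 8), 20))
#' fit <- hdbscan_fit(dist(x), min_cluster_size = 5, min_samples = 3)
#' table(fit$cluster)
#' @export
hdbscan_fit <- function(d, min_cluster_size = 15, min_samples = 5) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < 2L || nrow(dm) != ncol(dm)) abort("'d' must be a distance matrix over >= 2 points")
  if (min_cluster_size < 2L) abort("'min_cluster_size' must be at least 2")
  if (min_samples < 1L || min_samples > n) abort("'min_samples' must be in [1, n]")
  diag(dm) <- 0

  core <- apply(dm, 1L, function(r) sort(r)[min_samples])
  mr <- pmax(dm, outer(core, rep(1, n)), outer(rep(1, n), core))
  diag(mr) <- 0
  hc <- stats::hclust(stats::as.dist(mr), method = "single")

  merge <- hc$merge
  lambda_node <- ifelse(hc$height > 0, 1 / hc$height, Inf)
  node_size <- integer(n - 1L)
  for (m in seq_len(n - 1L)) {
    node_size[m] <- sum(ifelse(merge[m, ] < 0, 1L, node_size[pmax(merge[m, ], 1L)]))
  }
  leaves_under <- function(node) {
    out <- integer(0); stack <- node
    while (length(stack) > 0L) {
      nd <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (ch in merge[nd, ]) {
        if (ch < 0) out <- c(out, -ch) else stack <- c(stack, ch)
      }
    }
    out
  }

  # --- condensed tree ---------------------------------------------------
  pt_parent <- integer(n); pt_lambda <- numeric(n)       # one entry per point
  cl_parent <- 1L; cl_birth <- 0; cl_size <- n           # per cluster (id 1 = root)
  cl_minpt <- integer(0)
  entries_cl_parent <- integer(0); entries_cl_child <- integer(0)
  entries_cl_lambda <- numeric(0); entries_cl_size <- integer(0)
  n_clusters <- 1L

  if (n >= 2L) {
    stack <- list(list(node = n - 1L, cl = 1L))
    while (length(stack) > 0L) {
      top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      node <- top$node; cl <- top$cl
      lam <- lambda_node[node]
      ch <- merge[node, ]
      sizes <- ifelse(ch < 0, 1L, node_size[pmax(ch, 1L)])
      big <- sizes >= min_cluster_size
      if (all(big)) {
        for (k in 1:2) {
          n_clusters <- n_clusters + 1L
          cid <- n_clusters
          cl_parent[cid] <- cl; cl_birth[cid] <- lam; cl_size[cid] <- sizes[k]
          entries_cl_parent <- c(entries_cl_parent, cl)
          entries_cl_child <- c(entries_cl_child, cid)
          entries_cl_lambda <- c(entries_cl_lambda, lam)
          entries_cl_size <- c(entries_cl_size, sizes[k])
          stack[[length(stack) + 1L]] <- list(node = ch[k], cl = cid)
        }
      } else {
        for (k in 1:2) {
          if (big[k]) {
            stack[[length(stack) + 1L]] <- list(node = ch[k], cl = cl)
          } else {
            pts <- if (ch[k] < 0) -ch[k] else leaves_under(ch[k])
            pt_parent[pts] <- cl
            pt_lambda[pts] <- lam
          }
        }
      }
    }
  }

  # duplicate points merge at distance 0 (lambda = Inf); cap at the largest
  # finite level so stabilities and GLOSH stay finite
  finite_max <- max(c(pt_lambda[is.finite(pt_lambda)],
                      entries_cl_lambda[is.finite(entries_cl_lambda)], 1))
  pt_lambda[!is.finite(pt_lambda)] <- finite_max
  entries_cl_lambda[!is.finite(entries_cl_lambda)] <- finite_max
  cl_birth[!is.finite(cl_birth)] <- finite_max

  # --- excess-of-mass selection ----------------------------------------
  stability <- numeric(n_clusters)
  for (cid in seq_len(n_clusters)) {
    own <- which(pt_parent == cid)
    stability[cid] <- sum(pt_lambda[own] - cl_birth[cid])
    kids <- which(entries_cl_parent == cid)
    stability[cid] <- stability[cid] +
      sum((entries_cl_lambda[kids] - cl_birth[cid]) * entries_cl_size[kids])
  }
  selected <- logical(n_clusters)
  s_hat <- stability
  if (n_clusters >= 2L) {
    for (cid in n_clusters:2) {
      kids <- entries_cl_child[entries_cl_parent == cid]
      if (length(kids) == 0L) {
        selected[cid] <- TRUE
      } else {
        child_mass <- sum(s_hat[kids])
        if (stability[cid] >= child_mass) {
          selected[cid] <- TRUE
          s_hat[cid] <- stability[cid]
        } else {
          s_hat[cid] <- child_mass
        }
      }
    }
  }
  has_selected_ancestor <- function(cid) {
    p <- cl_parent[cid]
    while (p != 1L) {
      if (selected[p]) return(TRUE)
      p <- cl_parent[p]
    }
    FALSE
  }
  final <- which(selected & !vapply(seq_len(n_clusters), has_selected_ancestor, logical(1)))

  # --- labels ------------------------------------------------------------
  labels <- rep(-1L, n)
  if (length(final) > 0L) {
    for (p in seq_len(n)) {
      cid <- pt_parent[p]
      while (cid != 0L) {
        if (cid %in% final) { labels[p] <- cid; break }
        if (cid == 1L) break
        cid <- cl_parent[cid]
      }
    }
    # contiguous 0..K-1, ordered by first member for determinism
    kept <- sort(unique(labels[labels > 0L]))
    first_pt <- vapply(kept, function(cid) min(which(labels == cid)), integer(1))
    kept <- kept[order(first_pt)]
    relab <- setNames(seq_along(kept) - 1L, kept)
    labels[labels > 0L] <- relab[as.character(labels[labels > 0L])]
  }

  # --- GLOSH -------------------------------------------------------------
  death <- numeric(n_clusters)
  for (cid in seq_len(n_clusters)) {
    own <- pt_lambda[pt_parent == cid]
    death[cid] <- if (length(own) > 0L) max(own) else 0
  }
  if (n_clusters >= 2L) {
    for (cid in n_clusters:2) {
      p <- cl_parent[cid]
      death[p] <- max(death[p], death[cid])
    }
  }
  glosh <- vapply(seq_len(n), function(p) {
    d_c <- death[pt_parent[p]]
    if (d_c <= 0) return(0)
    min(max((d_c - pt_lambda[p]) / d_c, 0), 1)
  }, numeric(1))

  structure(list(
    cluster = labels,
    outlier_score = glosh,
    n_clusters = length(final),
    min_cluster_size = min_cluster_size,
    min_samples = min_samples
  ), class = "hdbscan_fit")
}

#' @export
print.hdbscan_fit <- function(x, ...) {
  cat("HDBSCAN:", x$n_clusters, "cluster(s),",
      sum(x$cluster == -1L), "noise point(s) of", length(x$cluster), "\n")
  invisible(x)
}
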