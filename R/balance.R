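#' Classify a signed triangle by structural balance
#'
#' A triangle is *balanced* when the product of its three edge signs is
#' positive: all-positive (`ppp`, "my friend's friend is my friend") and
#' one-positive/two-negative (`pmm`, "my friend's enemy is my enemy")
#' triangles are balanced; two-positive/one-negative (`ppm`) and
#' all-negative (`mmm`) triangles are imbalanced. The classification only
#' depends on the multiset of signs, so it is invariant to edge order.
#'
#' @param sign_a,sign_b,sign_c Edge signs: numeric weights (their sign is
#'   used) or the characters `"+"` / `"-"`. Vectors are classified
#'   elementwise. Zero signs are invalid (zero-weight edges are not edges).
#' @return A tibble with columns `type` (`"ppp"`, `"ppm"`, `"pmm"`, `"mmm"`)
#'   and `balanced`.
#' @examples
#' classify_triad("+", "-", "-") # balanced, pmm
#' @export
classify_triad <- function(sign_a, sign_b, sign_c) {
  to_sign <- function(s) {
    if (is.character(s)) s <- ifelse(s == "+", 1, ifelse(s == "-", -1, 0))
    out <- sign(as.numeric(s))
    if (any(out == 0)) abort("zero edge signs are invalid: zero-weight edges are not edges")
    out
  }
  a <- to_sign(sign_a); b <- to_sign(sign_b); c <- to_sign(sign_c)
  n_pos <- (a > 0) + (b > 0) + (c > 0)
  type <- c("mmm", "pmm", "ppm", "ppp")[n_pos + 1L]
  tibble::tibble(type = type, balanced = a * b * c > 0)
}

# All triangles of g as a 3-column matrix of vertex indices.
all_triangles <- function(g) {
  tri <- igraph::triangles(g)
  if (length(tri) == 0L) return(matrix(integer(), 0L, 3L))
  matrix(as.integer(tri), ncol = 3L, byrow = TRUE)
}

# Length-3 cycles of a fundamental cycle basis built on a BFS spanning
# forest: for each non-tree edge (u, v) whose tree paths meet immediately,
# the triangle (u, v, parent). Reproduces the basis-restricted enumeration
# used by cycle-basis implementations; it does not visit every triangle.
basis_triangles <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0L) return(matrix(integer(), 0L, 3L))
  comp <- igraph::components(g)
  parent <- rep(NA_integer_, n)
  depth <- rep(NA_integer_, n)
  adj <- igraph::as_adj_list(g)
  for (root in vapply(seq_len(comp$no), function(k) which(comp$membership == k)[1L], integer(1))) {
    queue <- root; depth[root] <- 0L
    while (length(queue) > 0L) {
      u <- queue[1L]; queue <- queue[-1L]
      for (v in as.integer(adj[[u]])) {
        if (is.na(depth[v])) {
          depth[v] <- depth[u] + 1L
          parent[v] <- u
          queue <- c(queue, v)
        }
      }
    }
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  tris <- list()
  for (e in seq_len(nrow(el))) {
    u <- el[e, 1L]; v <- el[e, 2L]
    if (identical(parent[v], u) || identical(parent[u], v)) next # tree edge
    # fundamental cycle of (u, v); keep it when it is a triangle
    if (identical(parent[u], parent[v]) && !is.na(parent[u])) {
      tris[[length(tris) + 1L]] <- c(u, v, parent[u])
    } else if (!is.na(parent[v]) && identical(parent[parent[v]] , u)) {
      tris[[length(tris) + 1L]] <- c(u, v, parent[v])
    } else if (!is.na(parent[u]) && identical(parent[parent[u]], v)) {
      tris[[length(tris) + 1L]] <- c(u, v, parent[u])
    }
  }
  if (length(tris) == 0L) return(matrix(integer(), 0L, 3L))
  unique(t(vapply(tris, function(x) sort(as.integer(x)), integer(3))))
}

#' Structural-balance triad census of a signed network
#'
#' Enumerates the triangles of the network and classifies each by the signs
#' of its `raw_weight` edges (see [classify_triad()]). The default mode
#' enumerates *every* 3-clique exactly once; `mode = "cycle_basis"`
#' restricts the census to the length-3 cycles of a fundamental cycle basis,
#' the enumeration some published pipelines use, which in general
#' undercounts triangles and is retained only for parity checks.
#'
#' @param net An igraph co-occurrence network with signed `raw_weight`
#'   edges. Exact-zero weights are dropped (with a warning) before the
#'   census.
#' @param mode `"all_triangles"` (default) or `"cycle_basis"`.
#' @return A `triad_census` object: list with `counts` (named: ppp, ppm,
#'   pmm, mmm), `total`, `balanced_fraction` (`NA` when no triangles),
#'   `percent` (per-type percentages summing to 100) and `mode`.
#' @examples
#' net <- generate_signed_network(20, "random", density = 0.4,
#'                                p_negative = 0.3, seed = 1)
#' triad_census_signed(net)
#' @export
triad_census_signed <- function(net, mode = c("all_triangles", "cycle_basis")) {
  mode <- match.arg(mode)
  g <- igraph_plain(net)
  if (!"raw_weight" %in% igraph::edge_attr_names(g)) {
    abort("network edges carry no 'raw_weight' attribute")
  }
  zero <- which(igraph::E(g)$raw_weight == 0)
  if (length(zero) > 0L) {
    warn(paste0("dropping ", length(zero), " zero-weight edge(s) before the census"))
    g <- igraph::delete_edges(g, zero)
  }
  tri <- switch(mode, all_triangles = all_triangles(g), cycle_basis = basis_triangles(g))
  counts <- c(ppp = 0L, ppm = 0L, pmm = 0L, mmm = 0L)
  if (nrow(tri) > 0L) {
    sgn <- function(i, j) {
      ids <- igraph::get_edge_ids(g, as.vector(rbind(i, j)))
      sign(igraph::E(g)$raw_weight[ids])
    }
    cls <- classify_triad(sgn(tri[, 1L], tri[, 2L]),
                          sgn(tri[, 1L], tri[, 3L]),
                          sgn(tri[, 2L], tri[, 3L]))
    tab <- table(factor(cls$type, levels = names(counts)))
    counts[names(tab)] <- as.integer(tab)
  }
  total <- sum(counts)
  structure(list(
    counts = counts,
    total = total,
    balanced_fraction = if (total == 0L) NA_real_ else
      (counts[["ppp"]] + counts[["pmm"]]) / total,
    percent = if (total == 0L) setNames(rep(NA_real_, 4L), names(counts)) else
      100 * counts / total,
    mode = mode
  ), class = "triad_census")
}

#' @export
print.triad_census <- function(x, ...) {
  cat("Signed triad census (", x$mode, "): ", x$total, " triangles\n", sep = "")
  if (x$total > 0L) {
    cat("  balanced fraction:", signif(x$balanced_fraction, 4), "\n")
    for (tp in names(x$counts)) {
      cat(sprintf("  %s: %d (%.2f%%)%s\n", tp, x$counts[[tp]], x$percent[[tp]],
                  if (tp %in% c("ppp", "pmm")) "  [balanced]" else "  [imbalanced]"))
    }
  }
  invisible(x)
}

#' Tidy a triad census
#'
#' @param x A `triad_census`.
#' @param ... Unused.
#' @return A tibble with one row per triangle type: `type`, `balanced`,
#'   `n`, `percent`.
#' @export
tidy.triad_census <- function(x, ...) {
  tibble::tibble(
    type = names(x$counts),
    balanced = names(x$counts) %in% c("ppp", "pmm"),
    n = as.integer(x$counts),
    percent = as.numeric(x$percent)
  )
}

#' @export
glance.triad_census <- function(x, ...) {
  tibble::tibble(total_triangles = x$total,
                 balanced_fraction = x$balanced_fraction,
                 mode = x$mode)
}
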