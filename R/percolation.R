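# Louvain partition on a plain igraph (deterministic given seed); returns
# membership vector, or one community per node for edgeless graphs.
louvain_membership <- function(g, seed = 1L, weights = NULL) {
  if (igraph::ecount(g) == 0L) return(seq_len(igraph::vcount(g)))
  withr::with_seed(seed, as.integer(igraph::membership(
    igraph::cluster_louvain(g, weights = weights))))
}

percolation_metrics <- function(g, fraction_removed, seed) {
  n <- igraph::vcount(g)
  if (n == 0L) {
    return(tibble::tibble(
      fraction_removed = fraction_removed, n_nodes = 0L, n_edges = 0L,
      density = NA_real_, avg_degree = NA_real_, n_components = 0L,
      giant_size = 0L, giant_fraction = NA_real_,
      n_communities = 0L, modularity = NA_real_
    ))
  }
  comp <- igraph::components(g)
  memb <- louvain_membership(g, seed)
  mod <- if (igraph::ecount(g) == 0L) NA_real_ else igraph::modularity(g, memb)
  tibble::tibble(
    fraction_removed = fraction_removed,
    n_nodes = n,
    n_edges = igraph::ecount(g),
    density = if (n > 1L) igraph::edge_density(g) else NA_real_,
    avg_degree = mean(igraph::degree(g)),
    n_components = comp$no,
    giant_size = max(comp$csize),
    giant_fraction = max(comp$csize) / n,
    n_communities = length(unique(memb)),
    modularity = mod
  )
}

#' Percolation (node-removal) simulation
#'
#' Removes nodes cumulatively, without replacement, until the network is
#' empty, recording at every step the degradation metrics: density, average
#' degree, number of connected components, giant-component size and
#' fraction, Louvain community count and modularity. Step 0 is the intact
#' network.
#'
#' Strategies: `"random"` samples nodes uniformly; `"degree"`,
#' `"closeness"`, `"betweenness"` remove highest-centrality nodes first,
#' with centralities computed once on the intact network (static ordering;
#' `adaptive = TRUE` recomputes after each step); `"group"` removes one
#' whole group per step, in the order of `group_order` or by decreasing
#' group size.
#'
#' @param net An igraph co-occurrence network.
#' @param strategy One of `"random"`, `"degree"`, `"closeness"`,
#'   `"betweenness"`, `"group"`.
#' @param step_fraction Fraction of the original node count removed per
#'   step, in (0, 1]; the per-step count is `ceiling(step_fraction * n)`.
#' @param groups For `strategy = "group"`: a data frame with columns
#'   `taxon_id` and `group` (or a named vector) covering every node.
#' @param group_order Optional character vector giving the order in which
#'   groups are removed.
#' @param adaptive Recompute centralities on the remaining network after
#'   each step? Default `FALSE` (static ordering).
#' @param seed Integer seed (random strategy and per-step Louvain runs).
#' @return A `percolation_trace` tibble with one row per step (step 0 =
#'   intact network) and columns `step`, `fraction_removed`, `n_nodes`,
#'   `n_edges`, `density`, `avg_degree`, `n_components`, `giant_size`,
#'   `giant_fraction`, `n_communities`, `modularity`. The strategy, seed and
#'   group order are attached as attributes.
#' @examples
#' net <- generate_signed_network(40, "scale_free", density = 0.1, seed = 1)
#' percolate(net, "degree", step_fraction = 0.25, seed = 1)
#' @export
percolate <- function(net, strategy = c("random", "degree", "closeness", "betweenness", "group"),
                      step_fraction = 0.1, groups = NULL, group_order = NULL,
                      adaptive = FALSE, seed = 1L) {
  strategy <- match.arg(strategy)
  if (step_fraction <= 0 || step_fraction > 1) abort("'step_fraction' must be in (0, 1]")
  g <- igraph_plain(net)
  n0 <- igraph::vcount(g)
  ids <- igraph::V(g)$name %||% as.character(seq_len(n0))

  group_map <- NULL
  if (strategy == "group") {
    if (is.null(groups)) abort("strategy = 'group' requires 'groups'")
    if (is.data.frame(groups)) {
      if (!all(c("taxon_id", "group") %in% names(groups))) {
        abort("'groups' data frame needs columns 'taxon_id' and 'group'")
      }
      group_map <- setNames(as.character(groups$group), groups$taxon_id)
    } else {
      group_map <- setNames(as.character(groups), names(groups))
    }
    missing <- setdiff(ids, names(group_map))
    if (length(missing) > 0L) {
      abort(paste0("'groups' does not cover node(s): ",
                   paste(head(missing, 5L), collapse = ", ")))
    }
    group_map <- group_map[ids]
    if (is.null(group_order)) {
      sizes <- sort(table(group_map), decreasing = TRUE)
      group_order <- names(sizes)
    }
  }

  centrality_order <- function(graph) {
    score <- switch(strategy,
      degree = igraph::degree(graph),
      closeness = closeness_wf(graph),
      betweenness = igraph::betweenness(graph, directed = FALSE, weights = NA,
                                        normalized = TRUE)
    )
    nm <- igraph::V(graph)$name
    nm[order(-score, nm)]
  }

  step_size <- max(1L, ceiling(step_fraction * n0))
  removed_total <- 0L
  step <- 0L
  trace <- list()
  trace[[1L]] <- dplyr::bind_cols(
    tibble::tibble(step = 0L),
    percolation_metrics(g, fraction_removed = 0, seed = seed)
  )
  static_order <- if (strategy %in% c("degree", "closeness", "betweenness") && !adaptive) {
    centrality_order(g)
  } else NULL
  remaining_groups <- group_order

  while (igraph::vcount(g) > 0L) {
    if (strategy == "group" && length(remaining_groups) == 0L) break
    step <- step + 1L
    current <- igraph::V(g)$name
    to_remove <- switch(strategy,
      random = withr::with_seed((seed + step) %% 2147483629L, {
        sample(current, min(step_size, length(current)))
      }),
      group = {
        grp <- remaining_groups[1L]
        remaining_groups <- remaining_groups[-1L]
        intersect(current, names(group_map)[group_map == grp])
      },
      {
        ord <- if (adaptive) centrality_order(g) else intersect(static_order, current)
        head(ord, min(step_size, length(ord)))
      }
    )
    if (length(to_remove) == 0L) next
    g <- igraph::delete_vertices(g, to_remove)
    removed_total <- removed_total + length(to_remove)
    trace[[step + 1L]] <- dplyr::bind_cols(
      tibble::tibble(step = step),
      percolation_metrics(g, fraction_removed = removed_total / n0,
                          seed = (seed + step) %% 2147483629L)
    )
  }

  out <- dplyr::bind_rows(trace)
  attr(out, "strategy") <- strategy
  attr(out, "seed") <- seed
  attr(out, "group_order") <- group_order
  class(out) <- c("percolation_trace", class(out))
  out
}

#' Robustness summary of a percolation trace
#'
#' For every tracked metric, the area under its trajectory against the
#' removed fraction (trapezoidal rule; larger giant-fraction area means a
#' slower breakdown). The `giant_fraction` row additionally reports the
#' removal fraction at which the giant component first drops below half the
#' remaining nodes (`threshold_fraction`; `NA` if it never does).
#'
#' @param trace A [percolate()] trace.
#' @return A tibble with one row per metric: `metric`, `auc`,
#'   `threshold_fraction`.
#' @export
robustness_report <- function(trace) {
  if (nrow(trace) == 0L) abort("empty percolation trace")
  metrics <- c("density", "avg_degree", "n_components", "giant_size",
               "giant_fraction", "n_communities", "modularity")
  x <- trace$fraction_removed
  auc <- vapply(metrics, function(m) {
    y <- trace[[m]]
    ok <- !is.na(y)
    if (sum(ok) < 2L) return(NA_real_)
    sum(diff(x[ok]) * (head(y[ok], -1L) + tail(y[ok], -1L)) / 2)
  }, numeric(1))
  below <- which(trace$giant_fraction < 0.5)
  tibble::tibble(
    metric = metrics,
    auc = unname(auc),
    threshold_fraction = ifelse(metrics == "giant_fraction",
                                if (length(below) > 0L) trace$fraction_removed[below[1L]] else NA_real_,
                                NA_real_)
  )
}
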