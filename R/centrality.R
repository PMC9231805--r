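# Closeness with the Wasserman-Faust component-size correction:
# ((r - 1) / (n - 1)) * ((r - 1) / sum of distances to reachable nodes),
# where r is the size of the node's connected component. On a connected
# graph this is plain normalized closeness; on disconnected graphs it keeps
# values comparable across components. Isolated nodes score 0.
closeness_wf <- function(g) {
  n <- igraph::vcount(g)
  d <- igraph::distances(g, weights = NA)
  vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    reach <- di[is.finite(di)]
    r <- length(reach) + 1L
    if (length(reach) == 0L || sum(reach) == 0) return(0)
    ((r - 1) / (n - 1)) * ((r - 1) / sum(reach))
  }, numeric(1))
}

#' Per-node centralities of a co-occurrence network
#'
#' The four key-taxa metrics, computed on the unweighted graph: degree
#' centrality (`degree / (n - 1)`, "popularity"), closeness (how fast a
#' node can influence the rest; component-size scaled on disconnected
#' graphs), normalized betweenness ("bridge" nodes), and PageRank (damping
#' `damping`, entries summing to 1). A rank column accompanies every
#' metric, with ties broken by `taxon_id` for determinism.
#'
#' @param net An igraph co-occurrence network with at least 2 nodes.
#' @param damping PageRank damping factor (default 0.85).
#' @return A tibble with columns `taxon_id`, `degree`, `closeness`,
#'   `betweenness`, `pagerank` and `rank_<metric>` columns (1 = most
#'   central).
#' @examples
#' net <- generate_signed_network(10, "random", density = 0.4, seed = 1)
#' centralities(net)
#' @export
centralities <- function(net, damping = 0.85) {
  g <- igraph_plain(net)
  n <- igraph::vcount(g)
  if (n < 2L) abort("centralities need at least 2 nodes")
  ids <- igraph::V(g)$name %||% as.character(seq_len(n))
  out <- tibble::tibble(
    taxon_id = ids,
    degree = unname(igraph::degree(g)) / (n - 1),
    closeness = closeness_wf(g),
    betweenness = unname(igraph::betweenness(g, directed = FALSE, weights = NA,
                                             normalized = TRUE)),
    pagerank = unname(igraph::page_rank(g, damping = damping, weights = NA)$vector)
  )
  for (m in c("degree", "closeness", "betweenness", "pagerank")) {
    ord <- order(-out[[m]], out$taxon_id)
    rk <- integer(n)
    rk[ord] <- seq_len(n)
    out[[paste0("rank_", m)]] <- rk
  }
  out
}
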