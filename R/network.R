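#' Map a correlation to the unit interval
#'
#' The affine rescaling `(raw + 1) / 2` used so that analyses that cannot
#' handle negative weights can run on the correlation network. It is
#' strictly increasing, so ranks are preserved and `raw > 0` iff
#' `norm > 0.5`.
#'
#' @param raw Numeric vector of correlations in \[-1, 1\].
#' @return Values in \[0, 1\].
#' @export
normalize_weight <- function(raw) {
  if (any(raw < -1 - 1e-12 | raw > 1 + 1e-12, na.rm = TRUE)) {
    abort("raw weights must lie in [-1, 1]")
  }
  (pmin(pmax(raw, -1), 1) + 1) / 2
}

#' Build a signed co-occurrence network from correlations
#'
#' Turns a correlation matrix (optionally with p-values) into an undirected
#' signed igraph network: one node per taxon, and an edge for every pair that
#' passes the inclusion rule, carrying the correlation as `raw_weight` and
#' its \[0, 1\] rescaling as `norm_weight`.
#'
#' Inclusion rules: `"pvalue"` keeps pairs with `p < alpha` (requires
#' p-values), `"magnitude"` keeps pairs with `|rho| >= min_abs_corr`, and
#' `"all"` keeps every pair. The default `"auto"` picks `"pvalue"` when
#' p-values are available and otherwise `"magnitude"` with its default
#' threshold of 0 (i.e. the complete weighted graph, the non-destructive
#' choice).
#'
#' @param x A [sparcc()] fit, or a square correlation matrix.
#' @param include_rule `"auto"`, `"pvalue"`, `"magnitude"` or `"all"`.
#' @param alpha Significance level for the p-value rule.
#' @param min_abs_corr Magnitude threshold for the magnitude rule.
#' @param pvalues Optional p-value matrix (only when `x` is a matrix).
#' @param taxonomy Optional character vector of taxonomy strings, attached
#'   as a vertex attribute.
#' @return An igraph graph of class `cooccurrence_network`; vertices are
#'   named by taxon, edges carry `raw_weight`, `norm_weight` and `sign`.
#' @examples
#' m <- diag(3); m[1, 2] <- m[2, 1] <- 0.6
#' rownames(m) <- colnames(m) <- c("a", "b", "c")
#' net <- build_network(m, include_rule = "magnitude", min_abs_corr = 0.5)
#' igraph::ecount(net)
#' @export
build_network <- function(x, include_rule = c("auto", "pvalue", "magnitude", "all"),
                          alpha = 0.05, min_abs_corr = 0, pvalues = NULL,
                          taxonomy = NULL) {
  include_rule <- match.arg(include_rule)
  if (inherits(x, "sparcc_fit")) {
    corr <- x$correlations
    pvalues <- pvalues %||% x$pvalues
  } else if (is.matrix(x)) {
    if (nrow(x) != ncol(x)) abort("correlation matrix must be square")
    corr <- x
    if (is.null(rownames(corr))) {
      rownames(corr) <- colnames(corr) <- paste0("taxon_", seq_len(nrow(corr)))
    }
  } else {
    abort("'x' must be a sparcc_fit or a square correlation matrix")
  }
  if (include_rule == "auto") {
    include_rule <- if (!is.null(pvalues)) "pvalue" else "magnitude"
  }
  if (include_rule == "pvalue" && is.null(pvalues)) {
    abort("include_rule = 'pvalue' requires a p-value matrix")
  }

  ids <- rownames(corr)
  ut <- which(upper.tri(corr), arr.ind = TRUE)
  keep <- switch(include_rule,
    pvalue = pvalues[ut] < alpha,
    magnitude = abs(corr[ut]) >= min_abs_corr,
    all = rep(TRUE, nrow(ut))
  )
  sel <- ut[keep, , drop = FALSE]
  g <- igraph::make_empty_graph(n = nrow(corr), directed = FALSE)
  igraph::V(g)$name <- ids
  if (nrow(sel) > 0L) {
    edges <- rbind(sel[, 1L], sel[, 2L])
    g <- igraph::add_edges(g, as.vector(edges))
    w <- corr[sel]
    igraph::E(g)$raw_weight <- w
    igraph::E(g)$norm_weight <- normalize_weight(w)
    if (include_rule == "pvalue") igraph::E(g)$p_value <- pvalues[sel]
  } else {
    g <- igraph::set_edge_attr(g, "raw_weight", value = numeric(0))
    g <- igraph::set_edge_attr(g, "norm_weight", value = numeric(0))
  }
  if (!is.null(taxonomy)) {
    if (length(taxonomy) != nrow(corr)) abort("'taxonomy' length must match taxon count")
    igraph::V(g)$taxonomy <- taxonomy
  }
  class(g) <- c("cooccurrence_network", class(g))
  g
}

#' Edges of a co-occurrence network as a tibble
#'
#' @param net An igraph co-occurrence network.
#' @return A tibble with columns `from`, `to`, `raw_weight`, `norm_weight`
#'   (and any further edge attributes).
#' @export
edge_tibble <- function(net) {
  if (igraph::ecount(net) == 0L) {
    return(tibble::tibble(from = character(), to = character(),
                          raw_weight = double(), norm_weight = double()))
  }
  ends <- igraph::ends(net, igraph::E(net), names = TRUE)
  out <- tibble::tibble(from = ends[, 1L], to = ends[, 2L])
  for (a in igraph::edge_attr_names(net)) out[[a]] <- igraph::edge_attr(net, a)
  out
}

#' Export a co-occurrence network
#'
#' @param net An igraph co-occurrence network.
#' @param path Output file path.
#' @param format `"graphml"` (nodes, attributes and isolated vertices
#'   preserved) or `"edge_list"` (CSV with columns `from`, `to`,
#'   `raw_weight`, `norm_weight`).
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "edge_list")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- net
    class(g) <- "igraph"
    igraph::write_graph(g, path, format = "graphml")
  } else {
    readr::write_csv(edge_tibble(net)[, c("from", "to", "raw_weight", "norm_weight")],
                     path)
  }
  invisible(path)
}

#' Import a co-occurrence network written by [export_network()]
#'
#' @param path GraphML file path.
#' @return An igraph co-occurrence network.
#' @export
import_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  # GraphML round-trips vertex 'name' as an attribute; restore it
  if (!"name" %in% igraph::vertex_attr_names(g) &&
      "id" %in% igraph::vertex_attr_names(g)) {
    igraph::V(g)$name <- igraph::V(g)$id
  }
  class(g) <- c("cooccurrence_network", class(g))
  g
}

igraph_plain <- function(net) {
  class(net) <- "igraph"
  net
}
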