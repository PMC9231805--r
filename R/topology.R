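# Average local clustering coefficient with degree-<2 nodes counted as 0
# (the convention of networkx's average_clustering).
avg_clustering <- function(g) {
  if (igraph::vcount(g) == 0L) return(NA_real_)
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}

# Giant component as an induced subgraph, plus whether the graph was connected.
giant_component <- function(g) {
  comp <- igraph::components(g)
  keep <- which(comp$membership == which.max(comp$csize))
  list(graph = igraph::induced_subgraph(g, keep),
       connected = comp$no == 1L,
       n_components = comp$no,
       giant_size = max(comp$csize))
}

# Path-based metrics on the giant component; NA markers for edgeless graphs.
path_metrics <- function(g) {
  gc <- giant_component(g)
  if (igraph::vcount(gc$graph) < 2L || igraph::ecount(gc$graph) == 0L) {
    return(list(avg_path = NA_real_, diameter = NA_real_,
                giant_component_only = !gc$connected))
  }
  list(avg_path = igraph::mean_distance(gc$graph, directed = FALSE),
       diameter = igraph::diameter(gc$graph, directed = FALSE, weights = NA),
       giant_component_only = !gc$connected)
}

#' Small-world index against matched random graphs
#'
#' `SW = (cc / cc_rand) / (l / l_rand)`, where `cc` and `l` are the average
#' clustering coefficient and average shortest path length of the network,
#' and `cc_rand`, `l_rand` are those of an Erdős–Rényi graph with the same
#' number of nodes and edges. The comparison is repeated `n_replicates`
#' times and the mean SW returned; `SW > 1` indicates small-world character.
#'
#' @param net An igraph network.
#' @param n_replicates Number of matched random graphs (default 50).
#' @param seed Integer seed.
#' @return The mean SW index (`NA` when undefined, e.g. zero clustering in
#'   every matched graph or an edgeless network).
#' @export
small_world_index <- function(net, n_replicates = 50, seed = 1L) {
  n <- igraph::vcount(net)
  m <- igraph::ecount(net)
  if (n < 2L || m == 0L) return(NA_real_)
  cc <- avg_clustering(net)
  l <- path_metrics(net)$avg_path
  if (is.na(l) || cc <= 0) return(NA_real_)
  vals <- withr::with_seed(seed, {
    vapply(seq_len(n_replicates), function(i) {
      gr <- igraph::sample_gnm(n, m)
      ccr <- avg_clustering(gr)
      lr <- path_metrics(gr)$avg_path
      if (is.na(lr) || ccr <= 0 || lr <= 0) return(NA_real_)
      (cc / ccr) / (l / lr)
    }, numeric(1))
  })
  if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
}

#' Global topology summary of a co-occurrence network
#'
#' Computes the standard large-scale metrics on the unweighted edge set:
#' density, average degree and its standard deviation, the
#' positive:negative edge ratio (from the signs of `raw_weight`; `Inf` when
#' no negative edges exist), average local clustering coefficient, average
#' shortest path length and diameter (on the giant component when the graph
#' is disconnected, flagged by `giant_component_only`), modularity of the
#' greedy-modularity partition, and the mean small-world index over
#' `sw_replicates` matched random graphs.
#'
#' @param net An igraph co-occurrence network.
#' @param sw_replicates Random replicates for the small-world index.
#' @param seed Integer seed (small-world replicates).
#' @return A one-row tibble.
#' @examples
#' net <- generate_signed_network(50, "random", density = 0.1, seed = 1)
#' summarize_topology(net, sw_replicates = 5, seed = 1)
#' @export
summarize_topology <- function(net, sw_replicates = 50, seed = 1L) {
  g <- igraph_plain(net)
  n <- igraph::vcount(g)
  if (n < 2L) abort("network must have at least 2 nodes")
  m <- igraph::ecount(g)
  deg <- igraph::degree(g)
  w <- if ("raw_weight" %in% igraph::edge_attr_names(g)) igraph::E(g)$raw_weight else NULL
  pos_neg <- if (is.null(w) || m == 0L) {
    NA_real_
  } else {
    npos <- sum(w > 0); nneg <- sum(w < 0)
    if (nneg == 0L) Inf else npos / nneg
  }
  pm <- path_metrics(g)
  modularity <- if (m == 0L) NA_real_ else {
    fg <- igraph::cluster_fast_greedy(g, weights = NULL)
    igraph::modularity(g, igraph::membership(fg))
  }
  tibble::tibble(
    n_nodes = n,
    n_edges = m,
    density = igraph::edge_density(g),
    avg_degree = mean(deg),
    degree_sd = sd(deg),
    pos_neg_ratio = pos_neg,
    clustering = avg_clustering(g),
    avg_path = pm$avg_path,
    diameter = pm$diameter,
    modularity = modularity,
    small_world = if (m == 0L) NA_real_ else
      small_world_index(g, n_replicates = sw_replicates, seed = seed),
    n_components = giant_component(g)$n_components,
    giant_component_only = pm$giant_component_only
  )
}

# Metrics recorded for each null replicate.
replicate_metrics <- function(g, include_sw, sw_replicates, seed) {
  deg <- igraph::degree(g)
  pm <- path_metrics(g)
  mod <- if (igraph::ecount(g) == 0L) NA_real_ else {
    igraph::modularity(g, igraph::membership(igraph::cluster_fast_greedy(g)))
  }
  tibble::tibble(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    density = igraph::edge_density(g),
    avg_degree = mean(deg),
    degree_sd = sd(deg),
    clustering = avg_clustering(g),
    avg_path = pm$avg_path,
    modularity = mod,
    small_world = if (include_sw)
      small_world_index(g, n_replicates = sw_replicates, seed = seed) else NA_real_
  )
}

#' Null metric distributions under canonical topologies
#'
#' Generates replicate random (Erdős–Rényi), small-world (Watts–Strogatz)
#' and scale-free (Barabási–Albert) graphs matched to the observed network's
#' node count, density and average degree, decorates them with symmetric
#' uniform \[-1, 1\] weights, and records the large-scale metrics of each
#' replicate. The observed network's metrics can then be located within each
#' null with [null_quantiles()].
#'
#' @param net The observed igraph network.
#' @param topologies Subset of `c("random", "small_world", "scale_free")`.
#' @param n_replicates Replicates per topology.
#' @param seed Integer seed.
#' @param include_sw Also compute the small-world index per replicate
#'   (slower); default `TRUE`.
#' @param sw_replicates Random replicates inside each SW computation.
#' @return A tibble with columns `topology`, `replicate` and the per-replicate
#'   metrics; the observed network's [summarize_topology()] row is attached
#'   as attribute `"reference"`.
#' @export
null_distributions <- function(net, topologies = c("random", "small_world", "scale_free"),
                               n_replicates = 50, seed = 1L, include_sw = TRUE,
                               sw_replicates = 10) {
  topologies <- match.arg(topologies, several.ok = TRUE)
  n <- igraph::vcount(net)
  if (n < 10L) abort("null comparison needs at least 10 nodes")
  density <- igraph::edge_density(igraph_plain(net))
  rows <- purrr::map(topologies, function(topo) {
    purrr::map(seq_len(n_replicates), function(r) {
      rep_seed <- (seed + 7919L * match(topo, c("random", "small_world", "scale_free")) + r) %% 2147483629L
      g <- withr::with_seed(rep_seed, {
        g <- make_topology_graph(n, density, topo)
        w <- runif(igraph::ecount(g), -1, 1)
        igraph::E(g)$raw_weight <- w
        g
      })
      dplyr::bind_cols(tibble::tibble(topology = topo, replicate = r),
                       replicate_metrics(g, include_sw, sw_replicates, rep_seed + 1L))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  attr(rows, "reference") <- summarize_topology(net, sw_replicates = sw_replicates,
                                                seed = seed)
  class(rows) <- c("null_distributions", class(rows))
  rows
}

#' Locate the observed network within its null distributions
#'
#' @param nulls Output of [null_distributions()].
#' @param reference Optional one-row [summarize_topology()] tibble; defaults
#'   to the reference attached to `nulls`.
#' @return A tibble with columns `topology`, `metric`, `observed` and
#'   `quantile` (the empirical fraction of null replicates at or below the
#'   observed value).
#' @export
null_quantiles <- function(nulls, reference = NULL) {
  reference <- reference %||% attr(nulls, "reference", exact = TRUE)
  if (is.null(reference)) abort("no reference summary available")
  metrics <- intersect(c("density", "avg_degree", "degree_sd", "clustering",
                         "avg_path", "modularity", "small_world"),
                       names(nulls))
  nulls |>
    tibble::as_tibble() |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric",
                        values_to = "value") |>
    dplyr::group_by(.data$topology, .data$metric) |>
    dplyr::summarise(
      observed = reference[[unique(.data$metric)]][1L],
      quantile = mean(.data$value <= .data$observed, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Degree distribution with PDF, CDF and CCDF
#'
#' Bins the node degrees, computes each bin's probability as
#' `frequency / total`, the CDF as the cumulative sum of the PDF, and the
#' complementary cumulative distribution `CCDF = 1 - CDF`.
#'
#' @param net An igraph network.
#' @param n_bins `"auto"` for unit-width integer bins over the observed
#'   degree range (exact for integer degrees), or an integer number of
#'   equal-width bins.
#' @return A tibble with columns `bin_lo`, `bin_hi`, `degree` (bin
#'   midpoint), `count`, `pdf`, `cdf`, `ccdf`.
#' @export
degree_ccdf <- function(net, n_bins = "auto") {
  deg <- igraph::degree(igraph_plain(net))
  if (length(deg) == 0L) abort("network has no nodes")
  if (identical(n_bins, "auto")) {
    lo <- seq(min(deg), max(deg))
    hi <- lo
    counts <- vapply(lo, function(k) sum(deg == k), numeric(1))
  } else {
    breaks <- seq(min(deg), max(deg), length.out = n_bins + 1L)
    cuts <- cut(deg, breaks = breaks, include.lowest = TRUE, right = TRUE)
    counts <- as.numeric(table(cuts))
    lo <- head(breaks, -1L)
    hi <- tail(breaks, -1L)
  }
  pdf <- counts / sum(counts)
  cdf <- cumsum(pdf)
  tibble::tibble(
    bin_lo = lo, bin_hi = hi, degree = (lo + hi) / 2,
    count = counts, pdf = pdf, cdf = cdf, ccdf = 1 - cdf
  )
}

#' Compare the degree CCDF with matched canonical topologies
#'
#' Generates one matched replicate per canonical topology (same node count
#' and density as the observed network) and evaluates all four degree CCDFs
#' on shared unit-width bins, for log-log comparison.
#'
#' @param net The observed igraph network.
#' @param seed Integer seed.
#' @return A `ccdf_comparison` tibble with columns `topology` (`"observed"`,
#'   `"random"`, `"small_world"`, `"scale_free"`), `degree`, `pdf`, `cdf`,
#'   `ccdf`. Plot with [autoplot()].
#' @export
compare_ccdf <- function(net, seed = 1L) {
  n <- igraph::vcount(net)
  density <- igraph::edge_density(igraph_plain(net))
  graphs <- list(observed = igraph_plain(net))
  for (topo in c("random", "small_world", "scale_free")) {
    graphs[[topo]] <- withr::with_seed(
      (seed + match(topo, c("random", "small_world", "scale_free"))) %% 2147483629L,
      make_topology_graph(n, density, topo)
    )
  }
  max_deg <- max(vapply(graphs, function(g) max(igraph::degree(g)), numeric(1)))
  bins <- seq(0, max_deg)
  out <- purrr::imap(graphs, function(g, nm) {
    deg <- igraph::degree(g)
    counts <- vapply(bins, function(k) sum(deg == k), numeric(1))
    pdf <- counts / sum(counts)
    cdf <- cumsum(pdf)
    tibble::tibble(topology = nm, degree = bins, pdf = pdf, cdf = cdf,
                   ccdf = 1 - cdf)
  }) |> dplyr::bind_rows()
  class(out) <- c("ccdf_comparison", class(out))
  out
}
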