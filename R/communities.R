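#' Louvain community partition
#'
#' Modularity-maximising Louvain partition of the co-occurrence network,
#' on the unweighted edge set by default (set `weighted = TRUE` to use the
#' \[0, 1\] normalised weights). Deterministic given `seed`. An edgeless
#' network yields one community per node, with a warning.
#'
#' @param net An igraph co-occurrence network.
#' @param seed Integer seed.
#' @param weighted Use `norm_weight` as edge weights?
#' @return A tibble with columns `taxon_id` and `community` (integer labels
#'   starting at 1).
#' @export
louvain_partition <- function(net, seed = 1L, weighted = FALSE) {
  g <- igraph_plain(net)
  ids <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  if (igraph::ecount(g) == 0L) {
    warn("edgeless network: every node is its own community")
    return(tibble::tibble(taxon_id = ids, community = seq_along(ids)))
  }
  w <- if (weighted) igraph::E(g)$norm_weight else NULL
  memb <- louvain_membership(g, seed = seed, weights = w)
  tibble::tibble(taxon_id = ids, community = memb)
}

# Normalise a partition argument into a named character vector over ids.
as_partition <- function(partition, ids) {
  if (is.data.frame(partition)) {
    label_col <- intersect(c("community", "cluster", "group", "label"), names(partition))
    if (!"taxon_id" %in% names(partition) || length(label_col) == 0L) {
      abort("partition data frame needs 'taxon_id' and one of 'community', 'cluster', 'group'")
    }
    map <- setNames(as.character(partition[[label_col[1L]]]), partition$taxon_id)
  } else {
    map <- setNames(as.character(partition), names(partition))
  }
  missing <- setdiff(ids, names(map))
  if (length(missing) > 0L) {
    abort(paste0("partition does not cover node(s): ", paste(head(missing, 5L), collapse = ", ")))
  }
  map[ids]
}

#' Per-subnetwork metrics and phylum composition
#'
#' Splits the network by a partition (Louvain communities, HDBSCAN clusters,
#' or any custom grouping), isolates each group's induced subgraph, and
#' reports its node and intra-group edge counts, density, average degree,
#' clustering coefficient, and (giant-component) diameter and average
#' shortest path. HDBSCAN noise (label `-1`) is reported as its own
#' `"noise"` group, and single-node groups are flagged `noise_like`.
#'
#' When the network carries (or is given) taxonomy strings, each group's
#' phylum composition — the second `";"`-delimited rank, `"NA"` when
#' unassigned — is attached as a list-column of named counts; see
#' [phylum_composition()] for the long format.
#'
#' @param net An igraph co-occurrence network.
#' @param partition A tibble with `taxon_id` and a label column (as returned
#'   by [louvain_partition()] or [embed_cluster()]), or a named vector.
#' @param taxonomy Optional character vector of taxonomy strings (one per
#'   node, in vertex order); defaults to the `taxonomy` vertex attribute.
#' @return A `subnetwork_report` tibble with one row per group.
#' @export
subnetwork_metrics <- function(net, partition, taxonomy = NULL) {
  g <- igraph_plain(net)
  ids <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  map <- as_partition(partition, ids)
  map[map == "-1"] <- "noise"
  taxonomy <- taxonomy %||%
    (if ("taxonomy" %in% igraph::vertex_attr_names(g)) igraph::V(g)$taxonomy else NULL)

  groups <- unique(map)
  rows <- purrr::map(groups, function(grp) {
    members <- ids[map == grp]
    sg <- igraph::induced_subgraph(g, members)
    n <- igraph::vcount(sg)
    pm <- path_metrics(sg)
    phylum <- if (!is.null(taxonomy)) {
      tab <- table(extract_phylum(taxonomy[match(members, ids)]))
      list(setNames(as.integer(tab), names(tab)))
    } else {
      list(NULL)
    }
    tibble::tibble(
      group = grp,
      n_nodes = n,
      n_edges = igraph::ecount(sg),
      density = if (n > 1L) igraph::edge_density(sg) else NA_real_,
      avg_degree = if (n > 0L) mean(igraph::degree(sg)) else NA_real_,
      clustering = avg_clustering(sg),
      diameter = pm$diameter,
      avg_path = pm$avg_path,
      noise_like = grp == "noise" | n == 1L,
      phylum_counts = phylum
    )
  })
  out <- dplyr::bind_rows(rows) |> dplyr::arrange(dplyr::desc(.data$n_nodes))
  class(out) <- c("subnetwork_report", class(out))
  out
}

#' Phylum composition per group, in long form
#'
#' @param report A [subnetwork_metrics()] report.
#' @return A tibble with columns `group`, `phylum`, `n`.
#' @export
phylum_composition <- function(report) {
  purrr::map2(report$group, report$phylum_counts, function(grp, counts) {
    if (is.null(counts)) return(NULL)
    tibble::tibble(group = grp, phylum = names(counts), n = as.integer(counts))
  }) |> dplyr::bind_rows()
}
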