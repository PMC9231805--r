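# Pairwise distances between rows of x under the metrics the embedding and
# clustering steps support. Bray-Curtis on possibly-negative coordinates
# (e.g. an embedding) falls back to the generalised form
# sum|u-v| / sum|u+v|.
pair_dist <- function(x, metric) {
  metric <- match.arg(metric, c("bray-curtis", "euclidean", "manhattan", "hellinger"))
  x <- as.matrix(x)
  switch(metric,
    "euclidean" = stats::dist(x),
    "manhattan" = stats::dist(x, method = "manhattan"),
    "hellinger" = stats::dist(vegan::decostand(x, method = "hellinger")),
    "bray-curtis" = {
      if (all(x >= 0)) {
        vegan::vegdist(x, method = "bray")
      } else {
        n <- nrow(x)
        m <- matrix(0, n, n)
        for (i in seq_len(n - 1L)) {
          for (j in (i + 1L):n) {
            den <- sum(abs(x[i, ] + x[j, ]))
            m[i, j] <- m[j, i] <- if (den == 0) 0 else sum(abs(x[i, ] - x[j, ])) / den
          }
        }
        stats::as.dist(m)
      }
    }
  )
}

#' Embed taxa with UMAP and cluster the embedding with HDBSCAN
#'
#' Treats each taxon as a point with its per-sample abundance profile as
#' features, embeds the taxa into `n_components` dimensions with UMAP on
#' the chosen input dissimilarity (Bray-Curtis by default, the standard
#' choice for community data), then clusters the embedding with HDBSCAN and
#' flags outliers by the GLOSH score quantile rule. Counts are converted to
#' per-sample relative abundances first unless `relative = FALSE`.
#'
#' Defaults follow the common visual-analysis settings: 15 neighbours,
#' minimum distance 0.1, 2 components, HDBSCAN with Bray-Curtis metric,
#' minimum cluster size 15, minimum samples 5, and outlier quantile 0.9.
#' The low-dimensional layout is optimised under Euclidean output geometry.
#'
#' @param x Abundance tibble (see [read_abundance()]).
#' @param n_neighbors UMAP neighbourhood size; must be smaller than the
#'   number of taxa.
#' @param min_dist UMAP minimum distance.
#' @param n_components Embedding dimensionality (>= 2).
#' @param input_metric Dissimilarity between taxa profiles:
#'   `"bray-curtis"`, `"euclidean"`, `"manhattan"` or `"hellinger"`.
#' @param hdb_min_cluster_size,hdb_min_samples HDBSCAN parameters.
#' @param hdb_metric Metric for HDBSCAN on the embedding coordinates.
#' @param outlier_quantile Points with GLOSH score above this empirical
#'   quantile are flagged as outliers; in (0, 1).
#' @param relative Convert counts to per-sample relative abundances before
#'   embedding? Default `TRUE`.
#' @param seed Integer seed (the embedding is reproducible on one machine).
#' @return An `embedding_tbl` tibble with columns `taxon_id`, `x`, `y`
#'   (plus `dim3`, ... for higher `n_components`), `cluster` (integer,
#'   `-1` = noise), `outlier_score`, `is_outlier`.
#' @examples
#' com <- generate_community(community_spec(n_taxa = 40, n_samples = 30,
#'                                          depth = 5000), seed = 1)
#' emb <- embed_cluster(com$table, n_neighbors = 10,
#'                      hdb_min_cluster_size = 5, seed = 1)
#' table(emb$cluster)
#' @export
embed_cluster <- function(x, n_neighbors = 15, min_dist = 0.1, n_components = 2,
                          input_metric = "bray-curtis",
                          hdb_min_cluster_size = 15, hdb_min_samples = 5,
                          hdb_metric = "bray-curtis",
                          outlier_quantile = 0.9, relative = TRUE, seed = 1L) {
  validate_abundance(x)
  if (outlier_quantile <= 0 || outlier_quantile >= 1) {
    abort("'outlier_quantile' must be in (0, 1)")
  }
  if (n_components < 2) abort("'n_components' must be at least 2")
  m <- abundance_matrix(x)
  if (nrow(m) <= n_neighbors) {
    abort(paste0("n_taxa (", nrow(m), ") must exceed 'n_neighbors' (", n_neighbors,
                 "); choose a smaller neighbourhood"))
  }
  if (relative) {
    cs <- colSums(m)
    cs[cs == 0] <- 1
    m <- sweep(m, 2L, cs, "/")
  }
  d_in <- pair_dist(m, input_metric)
  coords <- withr::with_seed(seed, {
    uwot::umap(d_in, n_neighbors = n_neighbors, min_dist = min_dist,
               n_components = n_components, n_threads = 1, n_sgd_threads = 0)
  })

  hdb <- hdbscan_fit(pair_dist(coords, hdb_metric),
                     min_cluster_size = hdb_min_cluster_size,
                     min_samples = hdb_min_samples)
  thr <- quantile(hdb$outlier_score, outlier_quantile, names = FALSE)

  out <- tibble::tibble(taxon_id = x$taxon_id)
  dim_names <- c("x", "y", if (n_components > 2) paste0("dim", 3:n_components))
  for (k in seq_len(n_components)) out[[dim_names[k]]] <- coords[, k]
  out$cluster <- hdb$cluster
  out$outlier_score <- hdb$outlier_score
  out$is_outlier <- hdb$outlier_score > thr
  attr(out, "config") <- list(
    n_neighbors = n_neighbors, min_dist = min_dist, n_components = n_components,
    input_metric = input_metric, hdb_min_cluster_size = hdb_min_cluster_size,
    hdb_min_samples = hdb_min_samples, hdb_metric = hdb_metric,
    outlier_quantile = outlier_quantile, relative = relative, seed = seed
  )
  class(out) <- c("embedding_tbl", class(out))
  out
}

#' Write an embedding/clustering result to CSV
#'
#' Column order is fixed: `taxon_id`, `x`, `y`, `cluster_label`,
#' `outlier_score`, `is_outlier` (noise rows carry label `-1`).
#'
#' @param result An [embed_cluster()] tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_clusters <- function(result, path) {
  out <- tibble::tibble(
    taxon_id = result$taxon_id,
    x = result$x,
    y = result$y,
    cluster_label = result$cluster,
    outlier_score = result$outlier_score,
    is_outlier = result$is_outlier
  )
  readr::write_csv(out, path)
  invisible(path)
}
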