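default_pipeline_config <- function() {
  list(
    seed = 1L,
    filter = list(min_total = 5, remove_unique = TRUE),
    sparcc = list(n_iterations = 50, exclusion_threshold = 0.10, exclusion_max = 10),
    pvalues = list(enabled = TRUE, n_permutations = 100, one_sided = TRUE,
                   perm_iterations = 5),
    embedding = list(enabled = TRUE, n_neighbors = 15, min_dist = 0.1,
                     n_components = 2, input_metric = "bray-curtis",
                     hdb_min_cluster_size = 15, hdb_min_samples = 5,
                     hdb_metric = "bray-curtis", outlier_quantile = 0.9),
    network = list(include_rule = "auto", alpha = 0.05, min_abs_corr = 0),
    topology = list(sw_replicates = 50),
    percolation = list(strategy = "random", step_fraction = 0.1)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Read a pipeline configuration file
#'
#' A YAML file mirroring the arguments of the individual stages; unset keys
#' fall back to the package defaults. Every stage seed derives
#' deterministically from the single global `seed`.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return A nested configuration list.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg
}

run_stage <- function(name, log_path, expr) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " stage '", name, "'")
  cat(msg, "\n", file = log_path, append = TRUE)
  message(msg)
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full co-occurrence pipeline
#'
#' Chains filtering, SparCC estimation with permutation p-values, optional
#' UMAP/HDBSCAN embedding, network construction, and the downstream
#' analyses (topology summary, triad census, Louvain community report,
#' centralities, percolation), writing one artifact file per stage plus an
#' aggregate `summary.json` and a `run.log`. The visualization and network
#' branches are independent: with `embed = FALSE` no `clusters.csv` is
#' produced and every network analysis still runs.
#'
#' @param input Abundance tibble or path to a `.tsv`/`.csv` table.
#' @param out_dir Output directory (created if needed).
#' @param config Configuration list from [read_pipeline_config()]; `NULL`
#'   for defaults.
#' @param seed Global seed; overrides the config.
#' @param embed Run the embedding stage? Overrides the config.
#' @return Invisibly, a list with the in-memory results (`filtered`, `fit`,
#'   `embedding`, `network`, `topology`, `census`, `communities`,
#'   `centrality`, `trace`) and `artifacts`, the named file paths.
#' @export
run_pipeline <- function(input, out_dir, config = NULL, seed = NULL, embed = NULL) {
  cfg <- config %||% default_pipeline_config()
  if (!is.null(seed)) cfg$seed <- seed
  if (!is.null(embed)) cfg$embedding$enabled <- embed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " sparccnet ",
      as.character(utils::packageVersion("sparccnet")), " seed=", cfg$seed, "\n",
      sep = "", file = log_path)

  tbl <- if (is.character(input)) {
    run_stage("read", log_path, read_abundance(input))
  } else {
    validate_abundance(input)
  }

  filtered <- run_stage("filter", log_path, {
    f <- filter_low_abundance(tbl, min_total = cfg$filter$min_total,
                              remove_unique = cfg$filter$remove_unique)
    write_removal_report(f, file.path(out_dir, "removed.csv"))
    f
  })

  fit <- run_stage("sparcc", log_path, {
    fit <- sparcc(filtered,
                  n_iterations = cfg$sparcc$n_iterations,
                  exclusion_threshold = cfg$sparcc$exclusion_threshold,
                  exclusion_max = cfg$sparcc$exclusion_max,
                  seed = cfg$seed)
    write_matrix(fit$correlations, file.path(out_dir, "corr.csv"))
    fit
  })

  if (isTRUE(cfg$pvalues$enabled)) {
    fit <- run_stage("pvalues", log_path, {
      fit <- sparcc_pvalues(filtered, fit,
                            n_permutations = cfg$pvalues$n_permutations,
                            one_sided = cfg$pvalues$one_sided,
                            perm_iterations = cfg$pvalues$perm_iterations,
                            seed = cfg$seed + 90001L)
      write_matrix(fit$pvalues, file.path(out_dir, "pval.csv"))
      fit
    })
  }

  embedding <- NULL
  if (isTRUE(cfg$embedding$enabled)) {
    embedding <- run_stage("embedding", log_path, {
      e <- cfg$embedding
      emb <- embed_cluster(filtered, n_neighbors = e$n_neighbors,
                           min_dist = e$min_dist, n_components = e$n_components,
                           input_metric = e$input_metric,
                           hdb_min_cluster_size = e$hdb_min_cluster_size,
                           hdb_min_samples = e$hdb_min_samples,
                           hdb_metric = e$hdb_metric,
                           outlier_quantile = e$outlier_quantile,
                           seed = cfg$seed + 17L)
      export_clusters(emb, file.path(out_dir, "clusters.csv"))
      emb
    })
  }

  net <- run_stage("network", log_path, {
    g <- build_network(fit, include_rule = cfg$network$include_rule,
                       alpha = cfg$network$alpha,
                       min_abs_corr = cfg$network$min_abs_corr,
                       taxonomy = if ("taxonomy" %in% names(filtered)) filtered$taxonomy)
    export_network(g, file.path(out_dir, "net.graphml"), format = "graphml")
    g
  })

  topo <- run_stage("topology", log_path,
    summarize_topology(net, sw_replicates = cfg$topology$sw_replicates,
                       seed = cfg$seed + 29L))

  census <- run_stage("balance", log_path, {
    cs <- triad_census_signed(net)
    jsonlite::write_json(
      list(counts = as.list(cs$counts), total = cs$total,
           balanced_fraction = cs$balanced_fraction,
           percent = as.list(cs$percent)),
      file.path(out_dir, "census.json"), auto_unbox = TRUE, digits = NA)
    cs
  })

  comm <- run_stage("communities", log_path, {
    part <- louvain_partition(net, seed = cfg$seed + 31L)
    rep <- subnetwork_metrics(net, part)
    readr::write_csv(dplyr::select(tibble::as_tibble(rep), -"phylum_counts"),
                     file.path(out_dir, "report.csv"))
    list(partition = part, report = rep)
  })

  centr <- run_stage("centrality", log_path, {
    ct <- centralities(net)
    readr::write_csv(ct, file.path(out_dir, "centrality.csv"))
    ct
  })

  trace <- run_stage("percolation", log_path, {
    tr <- percolate(net, strategy = cfg$percolation$strategy,
                    step_fraction = cfg$percolation$step_fraction,
                    seed = cfg$seed + 37L)
    readr::write_csv(tibble::as_tibble(tr), file.path(out_dir, "trace.csv"))
    tr
  })

  run_stage("summary", log_path, {
    jsonlite::write_json(list(
      seed = cfg$seed,
      n_taxa_input = nrow(tbl),
      n_taxa_filtered = nrow(filtered),
      topology = as.list(topo),
      balance = list(total_triangles = census$total,
                     balanced_fraction = census$balanced_fraction),
      n_communities = length(unique(comm$partition$community)),
      n_clusters = if (!is.null(embedding)) max(c(-1L, embedding$cluster)) + 1L else NA
    ), file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA, na = "null")
  })

  artifacts <- c("removed.csv", "corr.csv",
                 if (isTRUE(cfg$pvalues$enabled)) "pval.csv",
                 if (!is.null(embedding)) "clusters.csv",
                 "net.graphml", "census.json", "report.csv", "centrality.csv",
                 "trace.csv", "summary.json", "run.log")
  invisible(list(filtered = filtered, fit = fit, embedding = embedding,
                 network = net, topology = topo, census = census,
                 communities = comm, centrality = centr, trace = trace,
                 artifacts = setNames(file.path(out_dir, artifacts), artifacts)))
}

#' Benchmark SparCC against planted correlations
#'
#' Regenerates the standard validation design — `n_taxa` taxa in
#' `n_samples` samples drawn from a multinomial log-normal community with a
#' sparse strong basis — runs SparCC, and reports the root-mean-square
#' error between estimated and planted correlations over all off-diagonal
#' pairs, overall and binned by the magnitude of the true correlation.
#'
#' @param n_taxa,n_samples,depth Community dimensions (defaults 50, 200,
#'   10000).
#' @param n_strong,strength Sparse basis: number of planted pairs and their
#'   magnitude (defaults 10 pairs at 0.8).
#' @param seeds Integer vector; one community and fit per seed.
#' @param bins Breakpoints for the `|rho|` bins.
#' @param ... Passed to [sparcc()] (e.g. `n_iterations`).
#' @return A `sparcc_validation` tibble with columns `seed`, `bin` (one row
#'   per magnitude bin plus `"overall"`), `n_pairs`, `rmse`. The median
#'   overall RMSE across seeds is reported by `glance()`.
#' @export
validate_sparcc <- function(n_taxa = 50, n_samples = 200, depth = 10000,
                            n_strong = 10, strength = 0.8, seeds = 1:5,
                            bins = c(0, 0.2, 0.4, 0.6, 0.8, 1), ...) {
  rows <- purrr::map(seeds, function(s) {
    basis <- generate_sparse_basis(n_taxa, n_strong, strength, seed = s)
    com <- generate_community(
      community_spec(n_taxa, n_samples, depth, basis_correlation = basis),
      seed = s + 500000L)
    fit <- sparcc(com$table, seed = s + 1000000L, ...)
    ut <- upper.tri(basis)
    err <- fit$correlations[ut] - com$basis[ut]
    mag <- abs(com$basis[ut])
    bin <- cut(mag, breaks = bins, include.lowest = TRUE)
    by_bin <- tibble::tibble(bin = as.character(bin), err = err) |>
      dplyr::group_by(.data$bin) |>
      dplyr::summarise(n_pairs = dplyr::n(),
                       rmse = sqrt(mean(.data$err^2)), .groups = "drop")
    dplyr::bind_rows(
      tibble::tibble(seed = s, bin = "overall", n_pairs = sum(ut),
                     rmse = sqrt(mean(err^2))),
      dplyr::bind_cols(tibble::tibble(seed = s), by_bin)
    )
  }) |> dplyr::bind_rows()
  class(rows) <- c("sparcc_validation", class(rows))
  rows
}

#' @export
glance.sparcc_validation <- function(x, ...) {
  overall <- x$rmse[x$bin == "overall"]
  tibble::tibble(n_seeds = length(overall),
                 median_rmse = median(overall),
                 max_rmse = max(overall))
}
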