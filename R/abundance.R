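#' Read an OTU/ASV abundance table
#'
#' Reads a taxa-by-samples abundance table from a delimited text file. The
#' first column must hold unique OTU/ASV identifiers; an optional second
#' column may hold `";"`-delimited taxonomy strings (e.g.
#' `"Bacteria;Cyanobacteria;..."`); every remaining column is one sample of
#' counts or relative abundances.
#'
#' @param path Path to a `.tsv` (tab-separated) or `.csv` (comma-separated)
#'   file.
#' @param has_taxonomy One of `"auto"`, `TRUE`, `FALSE`. With `"auto"` the
#'   second column is treated as taxonomy iff any of its cells contains a
#'   `";"`.
#' @param delimiter One of `"auto"`, `"tab"`, `"comma"`. With `"auto"` the
#'   delimiter is chosen from the file extension (`.tsv` vs `.csv`).
#'
#' @return A tibble with columns `taxon_id`, optionally `taxonomy`, and one
#'   numeric column per sample.
#'
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "id\ttaxonomy\ts1\ts2\ts3",
#'   "ASV1\tBacteria;Proteobacteria\t5\t0\t2",
#'   "ASV2\tBacteria;Firmicutes\t1\t3\t4"
#' ), tf)
#' read_abundance(tf)
#' @export
read_abundance <- function(path, has_taxonomy = "auto", delimiter = "auto") {
  if (!file.exists(path)) {
    abort(paste0("abundance file not found: '", path, "'"))
  }
  delim <- switch(match.arg(delimiter, c("auto", "tab", "comma")),
    tab = "\t",
    comma = ",",
    auto = if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  )
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, trim_ws = TRUE)
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    abort("empty abundance table: need at least 1 taxon row and 2 columns")
  }

  taxon_id <- as.character(raw[[1L]])
  dup <- unique(taxon_id[duplicated(taxon_id)])
  if (length(dup) > 0L) {
    abort(paste0("duplicate taxon IDs: ", paste(dup, collapse = ", ")))
  }

  if (identical(has_taxonomy, "auto")) {
    has_taxonomy <- ncol(raw) >= 3L && any(grepl(";", raw[[2L]], fixed = TRUE))
  }
  has_taxonomy <- isTRUE(has_taxonomy)

  first_sample <- if (has_taxonomy) 3L else 2L
  if (ncol(raw) - first_sample + 1L < 2L) {
    abort("need at least 2 sample columns after the ID/taxonomy columns")
  }

  sample_cols <- names(raw)[first_sample:ncol(raw)]
  dup_s <- unique(sample_cols[duplicated(sample_cols)])
  if (length(dup_s) > 0L) {
    abort(paste0("duplicate sample IDs: ", paste(dup_s, collapse = ", ")))
  }

  counts <- lapply(seq_along(sample_cols), function(k) {
    col <- raw[[first_sample + k - 1L]]
    val <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(val) & !is.na(col))
    if (length(bad) > 0L) {
      abort(paste0("non-numeric abundance value '", col[bad[1L]], "' at row ",
                   bad[1L], ", column '", sample_cols[k], "'"))
    }
    val
  })
  names(counts) <- sample_cols

  out <- tibble::tibble(taxon_id = taxon_id)
  if (has_taxonomy) out$taxonomy <- as.character(raw[[2L]])
  out <- dplyr::bind_cols(out, tibble::as_tibble(counts))
  validate_abundance(out)
}

#' Validate an abundance tibble
#'
#' Checks the abundance-table contract: a `taxon_id` column of unique IDs, an
#' optional `taxonomy` column, and at least two numeric, non-negative sample
#' columns.
#'
#' @param x A tibble as returned by [read_abundance()].
#' @return `x`, invisibly unchanged, or an error.
#' @export
validate_abundance <- function(x) {
  if (!is.data.frame(x) || !"taxon_id" %in% names(x)) {
    abort("abundance table must be a data frame with a 'taxon_id' column")
  }
  dup <- unique(x$taxon_id[duplicated(x$taxon_id)])
  if (length(dup) > 0L) abort(paste0("duplicate taxon IDs: ", paste(dup, collapse = ", ")))
  sc <- abundance_sample_cols(x)
  if (length(sc) < 2L) abort("need at least 2 sample columns")
  for (s in sc) {
    if (!is.numeric(x[[s]])) abort(paste0("sample column '", s, "' is not numeric"))
    if (anyNA(x[[s]])) abort(paste0("missing abundance values in sample '", s, "'"))
    if (any(x[[s]] < 0)) abort(paste0("negative abundance values in sample '", s, "'"))
  }
  if ("taxonomy" %in% names(x) && !is.character(x$taxonomy)) {
    abort("'taxonomy' column must be character")
  }
  x
}

abundance_sample_cols <- function(x) {
  setdiff(names(x), c("taxon_id", "taxonomy"))
}

#' Extract the numeric matrix of an abundance table
#'
#' @param x Abundance tibble (see [read_abundance()]).
#' @return A taxa-by-samples numeric matrix with taxon IDs as row names and
#'   sample IDs as column names.
#' @export
abundance_matrix <- function(x) {
  sc <- abundance_sample_cols(x)
  m <- as.matrix(as.data.frame(x[, sc, drop = FALSE]))
  rownames(m) <- x$taxon_id
  m
}

#' Split a taxonomy string into ranks
#'
#' Splits `";"`-delimited taxonomy strings into up to seven ranks
#' (kingdom to species), preserving trailing empty ranks.
#'
#' @param taxonomy Character vector of raw taxonomy strings.
#' @return A list of character vectors of ranks, one per input string.
#' @export
taxonomy_ranks <- function(taxonomy) {
  lapply(taxonomy, function(s) {
    if (is.na(s)) return(character())
    strsplit(paste0(s, ";\x01"), ";", fixed = TRUE)[[1L]] |>
      (\(v) head(v, -1L))() |>
      trimws()
  })
}

#' Phylum of a taxonomy string
#'
#' The phylum is the second `";"`-delimited field; taxonomies with fewer than
#' two fields (or missing) fall into the `"NA"` bucket.
#'
#' @param taxonomy Character vector of raw taxonomy strings.
#' @return Character vector of phylum names.
#' @export
extract_phylum <- function(taxonomy) {
  vapply(taxonomy_ranks(taxonomy), function(r) {
    if (length(r) >= 2L && nzchar(r[2L])) r[2L] else "NA"
  }, character(1))
}

#' Remove singleton and unique taxa
#'
#' Applies the standard co-occurrence pre-filter to a raw count table:
#' *singletons* (taxa with fewer than `min_total` total counts summed over all
#' samples) and *unique* taxa (non-zero in exactly one sample) are dropped.
#' A taxon with a total of exactly `min_total` survives the singleton rule.
#' Samples are never removed and surviving counts are untouched, so the
#' filter is idempotent.
#'
#' When the table holds per-sample relative abundances (every sample sums to
#' 1) the count-based singleton rule is not meaningful; only the unique rule
#' is applied and a warning is emitted.
#'
#' @param x Abundance tibble.
#' @param min_total Minimum total count a taxon needs to survive (strict
#'   `<` comparison removes; default 5).
#' @param remove_unique Also drop taxa present (count > 0) in exactly one
#'   sample? Default `TRUE`.
#'
#' @return The filtered tibble. The removal report — a tibble with columns
#'   `taxon_id` and `reason` (`"singleton"` or `"unique"`) — is attached as
#'   attribute `"removal_report"` and accessible via [removal_report()].
#' @seealso [removal_report()], [write_removal_report()]
#' @export
filter_low_abundance <- function(x, min_total = 5, remove_unique = TRUE) {
  validate_abundance(x)
  m <- abundance_matrix(x)

  compositional <- all(abs(colSums(m) - 1) < 1e-6)
  if (compositional) {
    warn("table looks compositional (samples sum to 1): skipping the count-based singleton rule")
  } else if (any(m != floor(m))) {
    warn("non-integer counts detected; singleton filtering assumes raw counts")
  }

  totals <- rowSums(m)
  n_present <- rowSums(m > 0)
  singleton <- if (compositional) rep(FALSE, nrow(m)) else totals < min_total
  unique_tax <- remove_unique & n_present == 1L

  removed <- singleton | unique_tax
  report <- tibble::tibble(
    taxon_id = x$taxon_id[removed],
    reason = unname(ifelse(singleton[removed], "singleton", "unique"))
  )
  if (all(removed)) {
    abort("all taxa removed by filtering; lower 'min_total' or disable 'remove_unique'")
  }

  out <- x[!removed, , drop = FALSE]
  attr(out, "removal_report") <- report
  out
}

#' Removal report of a filtered abundance table
#'
#' @param x A tibble returned by [filter_low_abundance()].
#' @return A tibble with columns `taxon_id` and `reason`.
#' @export
removal_report <- function(x) {
  rep <- attr(x, "removal_report", exact = TRUE)
  if (is.null(rep)) {
    abort("no removal report attached; was this table produced by filter_low_abundance()?")
  }
  rep
}

#' Write the removal report to CSV
#'
#' @param x A tibble returned by [filter_low_abundance()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_removal_report <- function(x, path) {
  readr::write_csv(removal_report(x), path)
  invisible(path)
}

#' Write an abundance table
#'
#' @param x Abundance tibble.
#' @param path Output path; `.tsv` writes tab-separated, anything else
#'   comma-separated.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(x, path) {
  validate_abundance(x)
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) {
    readr::write_tsv(x, path)
  } else {
    readr::write_csv(x, path)
  }
  invisible(path)
}

#' Write a labeled square matrix as CSV
#'
#' Writes a square numeric matrix (e.g. a correlation or p-value matrix) with
#' a header row of labels and a leading label column, so that
#' [read_matrix()] round-trips values to full double precision.
#'
#' @param m Square numeric matrix; row/column labels are taken from
#'   `dimnames` or from `labels`.
#' @param path Output CSV path.
#' @param labels Optional character vector of labels, one per row.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, labels = NULL) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) abort("'m' must be a square matrix")
  labels <- labels %||% rownames(m) %||% paste0("v", seq_len(nrow(m)))
  if (length(labels) != nrow(m)) abort("label count does not match matrix dimension")
  if (anyDuplicated(labels)) abort("matrix labels must be unique")
  df <- tibble::as_tibble(as.data.frame(m), .name_repair = "minimal")
  names(df) <- labels
  out <- dplyr::bind_cols(tibble::tibble(id = labels), df)
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a labeled square matrix from CSV
#'
#' @param path CSV path as written by [write_matrix()].
#' @return A square numeric matrix with dimnames.
#' @export
read_matrix <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  m <- as.matrix(as.data.frame(df[, -1L, drop = FALSE]))
  rownames(m) <- df[[1L]]
  if (nrow(m) != ncol(m)) abort(paste0("matrix in '", path, "' is not square"))
  m
}
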