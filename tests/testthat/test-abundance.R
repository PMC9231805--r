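write_fixture <- function(lines, ext = ".tsv") {
  tf <- tempfile(fileext = ext)
  writeLines(lines, tf)
  tf
}

test_that("reading a TSV with a taxonomy column works and the column shift contract holds", {
  tf <- write_fixture(c(
    "id\ttaxonomy\ts1\ts2\ts3\ts4",
    "ASV1\tBacteria;Proteobacteria\t5\t0\t2\t1",
    "ASV2\tBacteria;Firmicutes\t1\t3\t4\t0",
    "ASV3\tBacteria;Cyanobacteria\t0\t0\t9\t2"
  ))
  tbl <- read_abundance(tf)
  expect_equal(nrow(tbl), 3L)
  expect_equal(length(setdiff(names(tbl), c("taxon_id", "taxonomy"))), 4L)
  expect_true("taxonomy" %in% names(tbl))
  expect_equal(abundance_matrix(tbl)["ASV2", "s2"], 3)

  # column-shift contract: without the taxonomy flag the second column
  # becomes the first sample
  tf2 <- write_fixture(c(
    "id\tc1\tc2\tc3\tc4\tc5",
    "ASV1\t9\t5\t0\t2\t1",
    "ASV2\t8\t1\t3\t4\t0"
  ))
  tbl2 <- read_abundance(tf2, has_taxonomy = FALSE)
  expect_false("taxonomy" %in% names(tbl2))
  expect_equal(ncol(abundance_matrix(tbl2)), 5L)
  expect_equal(abundance_matrix(tbl2)["ASV1", "c1"], 9)
})

test_that("duplicate IDs and non-numeric cells are rejected with informative errors", {
  dup <- write_fixture(c("id,s1,s2", "A,1,2", "A,3,4", "B,5,6"), ext = ".csv")
  expect_error(read_abundance(dup, has_taxonomy = FALSE), "A")
  bad <- write_fixture(c("id\ts1\ts2", "A\t1\tx", "B\t3\t4"))
  expect_error(read_abundance(bad, has_taxonomy = FALSE), "row 1.*s2")
  empty <- write_fixture("id\ts1\ts2")
  expect_error(read_abundance(empty), "empty|taxon")
})

test_that("singleton and unique filtering match the rules exactly", {
  # t1: total 4 -> singleton; t2: total 5 in one sample -> unique;
  # t3: total 3 in one sample -> both (reported once); t4, t5 survive
  m <- rbind(
    t1 = c(1, 1, 1, 1),
    t2 = c(5, 0, 0, 0),
    t3 = c(3, 0, 0, 0),
    t4 = c(5, 1, 0, 0),
    t5 = c(2, 2, 2, 2)
  )
  f <- filter_low_abundance(abundance_tbl(m))
  expect_equal(f$taxon_id, c("t4", "t5"))
  rep <- removal_report(f)
  expect_equal(nrow(rep), 3L)
  expect_equal(rep$reason[rep$taxon_id == "t1"], "singleton")
  expect_equal(rep$reason[rep$taxon_id == "t2"], "unique")
  # total of exactly min_total survives the singleton rule
  expect_true("t4" %in% f$taxon_id)
})

test_that("filtering is idempotent and leaves surviving counts untouched", {
  m <- withr::with_seed(1, matrix(rpois(40, 3), 10, 4))
  f1 <- filter_low_abundance(abundance_tbl(m))
  f2 <- filter_low_abundance(f1)
  expect_equal(tibble::as_tibble(f2), tibble::as_tibble(f1))
  kept <- match(f1$taxon_id, paste0("t", 1:10))
  expect_equal(abundance_matrix(f1), abundance_matrix(abundance_tbl(m))[kept, , drop = FALSE])
})

test_that("compositional tables only get the unique rule, with a warning", {
  m <- cbind(c(0.99, 0.01, 0), c(0.98, 0, 0.02), c(0.97, 0.03, 0))
  expect_warning(f <- filter_low_abundance(abundance_tbl(m)), "compositional")
  # t1 and t2 are in >1 sample and survive despite tiny totals; t3 is unique
  expect_equal(f$taxon_id, c("t1", "t2"))
})

test_that("removing every taxon is an error that suggests changing the threshold", {
  m <- rbind(c(1, 0, 0), c(0, 1, 0))
  expect_error(suppressWarnings(filter_low_abundance(abundance_tbl(m))), "min_total")
})

test_that("square matrix CSV round-trips at full precision", {
  m <- diag(2); rownames(m) <- colnames(m) <- c("a", "b")
  tf <- tempfile(fileext = ".csv")
  write_matrix(m, tf)
  expect_equal(length(readLines(tf)), 3L)
  expect_equal(read_matrix(tf), m)

  r <- withr::with_seed(3, { x <- matrix(rnorm(100), 10); (x + t(x)) / 2 })
  rownames(r) <- colnames(r) <- paste0("v", 1:10)
  write_matrix(r, tf)
  expect_equal(read_matrix(tf), r, tolerance = 1e-12)

  expect_error(write_matrix(matrix(1:6, 2, 3), tf), "square")
  expect_error(write_matrix(diag(2), tf, labels = "only_one"), "label")
})

test_that("taxonomy ranks split on ';' preserving trailing empties, phylum is rank 2", {
  r <- taxonomy_ranks("Bacteria;Cyanobacteria;Cyanophyceae;Nostocales;;")
  expect_equal(r[[1]][1:2], c("Bacteria", "Cyanobacteria"))
  expect_equal(length(r[[1]]), 6L)
  expect_equal(r[[1]][5:6], c("", ""))
  expect_equal(
    extract_phylum(c("Bacteria;Cyanobacteria;Cyanophyceae", "Unassigned", NA)),
    c("Cyanobacteria", "NA", "NA")
  )
})
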