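make_expr_file <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("read_expression parses a well-formed matrix", {
  f <- make_expr_file(c("gene_id\tpA\tpB", "g1\t1.5\t2", "g2\t0\t3.25"))
  m <- read_expression(f)
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["g2", "pB"], 3.25)
})

test_that("read_expression rejects negative values naming the line", {
  f <- make_expr_file(c("gene_id\tpA", "g1\t2", "g2\t-1"))
  expect_error(read_expression(f), "line 3")
})

test_that("read_expression rejects duplicate identifiers", {
  f <- make_expr_file(c("gene_id\tpA", "g1\t2", "g1\t3"))
  expect_error(read_expression(f), "duplicate gene")
  f2 <- make_expr_file(c("gene_id\tpA\tpA", "g1\t2\t3"))
  expect_error(read_expression(f2), "duplicate patient")
})

test_that("clinical reader enforces columns, codes and subtype mapping", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("patient_id\tdiagnosis_year\tos_time\tevent\tsubtype",
               "p1\t1990\t3.5\t1\tLumA",
               "p2\t1995\t2.0\t0\tweird",
               "p3\tNA\t1.0\t1\tBasal"), f)
  expect_warning(cl <- suppressMessages(read_clinical(f)),
                 "unknown subtype")
  expect_equal(nrow(cl), 2L) # the NA-year patient is dropped
  expect_true(is.na(cl$subtype[cl$patient_id == "p2"]))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("patient_id\tdiagnosis_year\tos_time\tevent",
               "p1\t1990\t3.5\t2"), f2)
  expect_error(read_clinical(f2), "event")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("patient_id\tos_time\tevent", "p1\t3.5\t1"), f3)
  expect_error(read_clinical(f3), "diagnosis_year")
})

test_that("gene lists skip comments and warn when empty", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# catalog", "g1", "", "g2", "g1"), f)
  expect_identical(read_gene_list(f), c("g1", "g2"))
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines("# only a comment", f2)
  expect_warning(empty <- read_gene_list(f2), "empty")
  expect_length(empty, 0)
})

test_that("GMT lines parse as name, description, members", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("pathA\tdescription A\tg1\tg2",
               "pathB\tdescription B\tg3\tg4\tg5"), f)
  sets <- read_gmt(f)
  expect_setequal(sets$pathA, c("g1", "g2"))
  expect_identical(attr(sets$pathB, "description"), "description B")
  f2 <- withr::local_tempfile(fileext = ".gmt")
  writeLines("pathA\tdesc-only", f2)
  expect_error(read_gmt(f2), "fewer than 3")
})

test_that("perfectly balanceable years split evenly", {
  cl <- data.frame(patient_id = sprintf("p%d", 1:8),
                   diagnosis_year = rep(1:4, each = 2),
                   os_time = 1, event = 1L, subtype = NA_character_)
  b <- make_bins(cl, 4)
  expect_equal(unname(bin_sizes(b)), rep(2L, 4))
  expect_equal(b$n_bins, 4L)
})

test_that("binning fails when there are fewer distinct years than bins", {
  cl <- data.frame(patient_id = sprintf("p%d", 1:6),
                   diagnosis_year = rep(1:3, 2),
                   os_time = 1, event = 1L, subtype = NA_character_)
  expect_error(make_bins(cl, 8), "distinct")
})

test_that("binning is a partition and invariant to patient order", {
  set.seed(42)
  cl <- data.frame(patient_id = sprintf("p%03d", 1:200),
                   diagnosis_year = sample(1988:2011, 200, replace = TRUE),
                   os_time = 1, event = 1L, subtype = NA_character_)
  b <- make_bins(cl, 8)
  expect_equal(sum(bin_sizes(b)), nrow(cl))
  expect_setequal(names(b$assignment), cl$patient_id)
  shuffled <- cl[sample(nrow(cl)), , drop = FALSE]
  b2 <- make_bins(shuffled, 8)
  expect_identical(b$bin_edges, b2$bin_edges)
  expect_identical(b$assignment[cl$patient_id],
                   b2$assignment[cl$patient_id])
})

test_that("count-balancing binning attains the exhaustive-search optimum", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(80:300, 1)
    years <- sample(1988:2011, n, replace = TRUE,
                    prob = stats::runif(24, 0.2, 1))
    if (length(unique(years)) < 8) next
    cl <- data.frame(patient_id = sprintf("p%04d", seq_len(n)),
                     diagnosis_year = years, os_time = 1, event = 1L,
                     subtype = NA_character_)
    b <- make_bins(cl, 8)
    sizes <- bin_sizes(b)
    distinct <- sort(unique(years))
    counts <- as.integer(table(factor(years, levels = distinct)))
    opt <- oracle_partition_best_ratio(counts, 8)
    expect_lte(max(sizes) / min(sizes), opt + 1e-9)
  }
})

test_that("explicit edges are used verbatim", {
  cl <- data.frame(patient_id = sprintf("p%d", 1:9),
                   diagnosis_year = c(1988, 1990, 1992, 1994, 1996,
                                      1998, 2000, 2002, 2011),
                   os_time = 1, event = 1L, subtype = NA_character_)
  b <- make_bins(cl, mode = "explicit",
                 explicit_edges = c(1988, 1995, 2012))
  expect_equal(b$n_bins, 2L)
  expect_equal(unname(bin_sizes(b)), c(4L, 5L))
  expect_error(make_bins(cl, mode = "explicit",
                         explicit_edges = c(1990, 1990, 2012)),
               "increasing")
})
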