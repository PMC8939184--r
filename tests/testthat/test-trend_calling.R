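test_that("bin means match a naive per-bin recomputation", {
  set.seed(31)
  expr <- matrix(stats::rexp(20 * 40), nrow = 20,
                 dimnames = list(sprintf("g%02d", 1:20),
                                 sprintf("p%02d", 1:40)))
  cl <- data.frame(patient_id = colnames(expr),
                   diagnosis_year = sample(2000:2007, 40, replace = TRUE),
                   os_time = 1, event = 1L, subtype = NA_character_)
  b <- make_bins(cl, 4)
  m <- bin_means(expr, b)
  for (g in rownames(expr)) for (bin in 0:3) {
    members <- names(b$assignment)[b$assignment == bin]
    acc <- 0
    for (p in members) acc <- acc + expr[g, p]
    expect_equal(m[g, bin + 1], acc / length(members))
  }
  # trivial cases
  expect_equal(mean(c(2, 4)), 3)
  const <- matrix(5, 1, 40, dimnames = list("gc", colnames(expr)))
  expect_true(all(bin_means(const, b) == 5))
})

test_that("trend calls follow the k-of-(B-1) consecutive-comparison rule", {
  p <- trend_params(k_min = 6, epsilon = 1e-9)
  up <- call_trend(1:8, p)
  expect_identical(up$direction, "up")
  expect_equal(up$n_increase, 7)
  expect_equal(up$log2fc, 3, tolerance = 1e-6)

  dip <- call_trend(c(1, 2, 3, 2, 5, 6, 7, 8), p)
  expect_equal(dip$n_increase, 6)
  expect_equal(dip$n_decrease, 1)
  expect_identical(dip$direction, "up")
  expect_length(dip$counter_steps, 1)

  flat <- call_trend(rep(5, 8), p)
  expect_equal(flat$n_tie, 7)
  expect_identical(flat$direction, "none")
  expect_equal(flat$log2fc, 0)

  expect_error(call_trend(c(1, NA, 3), p), "NA")
})

test_that("every up/down/tie pattern agrees with the counting oracle", {
  # all 3^7 consecutive-comparison patterns at B = 8
  p <- trend_params(k_min = 6, epsilon = 1e-9)
  grid <- as.matrix(expand.grid(rep(list(c(-1, 0, 1)), 7)))
  got <- apply(grid, 1, function(steps)
    call_trend(10 + cumsum(c(0, steps)), p))
  want <- apply(grid, 1, function(steps)
    oracle_trend(10 + cumsum(c(0, steps)), 6))
  pull <- function(lst, f, what) vapply(lst, `[[`, f, what)
  expect_equal(pull(got, numeric(1), "n_increase"),
               pull(want, numeric(1), "n_increase"))
  expect_equal(pull(got, numeric(1), "n_decrease"),
               pull(want, numeric(1), "n_decrease"))
  expect_equal(pull(got, numeric(1), "n_tie"),
               pull(want, numeric(1), "n_tie"))
  expect_identical(pull(got, character(1), "direction"),
                   pull(want, character(1), "direction"))
  # a gene can never be called in both directions
  expect_false(any(pull(got, numeric(1), "n_increase") >= 6 &
                     pull(got, numeric(1), "n_decrease") >= 6))
})

test_that("reversing the bins swaps direction and negates the fold-change", {
  set.seed(7)
  p <- trend_params(k_min = 6, epsilon = 1e-9)
  for (i in 1:25) {
    means <- stats::rexp(8)
    a <- call_trend(means, p)
    b <- call_trend(rev(means), p)
    expect_equal(a$log2fc, -b$log2fc)
    expect_identical(b$direction,
                     switch(a$direction, up = "down", down = "up",
                            none = "none"))
    expect_equal(a$n_increase, b$n_decrease)
  }
})

test_that("rescaling the matrix preserves calls when epsilon scales too", {
  set.seed(8)
  means <- stats::rexp(8)
  a <- call_trend(means, trend_params(k_min = 6, epsilon = 1e-4))
  b <- call_trend(means * 1000, trend_params(k_min = 6, epsilon = 0.1))
  expect_identical(a$direction, b$direction)
  expect_equal(a$n_increase, b$n_increase)
  expect_equal(a$log2fc, b$log2fc, tolerance = 1e-12)
})

test_that("call_trends preserves gene order and resolves defaults", {
  co <- cohort_from_bin_means(rbind(
    gA = 2^seq(0, 3.5, by = 0.5),
    gB = 2^seq(3.5, 0, by = -0.5),
    gC = rep(4, 8)))
  calls <- call_trends(co$expr, co$binning)
  expect_identical(calls$gene_id, c("gA", "gB", "gC"))
  expect_identical(calls$direction, c("up", "down", "none"))
  expect_equal(attr(calls, "k_min"), 6L)
  single <- call_trends(co$expr["gA", , drop = FALSE], co$binning)
  expect_equal(nrow(single), 1L)
})

test_that("top table orders by fold-change with a lexicographic tie-break", {
  fc <- c(2.5, 2.3, 2.2, 2.1, 2.0)
  mm <- t(vapply(fc, function(f) 2^seq(0, f, length.out = 8),
                 numeric(8)))
  rownames(mm) <- c("gE", "gD", "gC", "gB", "gA")
  co <- cohort_from_bin_means(mm)
  calls <- call_trends(co$expr, co$binning,
                       trend_params(epsilon = 1e-9))
  top <- trend_top_table(calls, top_n = 5)
  expect_identical(top$gene_id, c("gE", "gD", "gC", "gB", "gA"))
  expect_equal(top$log2fc, fc, tolerance = 1e-6)

  tie <- cohort_from_bin_means(rbind(gB = 2^seq(0, 2, length.out = 8),
                                     gA = 2^seq(0, 2, length.out = 8)))
  tie_calls <- call_trends(tie$expr, tie$binning,
                           trend_params(epsilon = 1e-9))
  expect_identical(trend_top_table(tie_calls)$gene_id, c("gA", "gB"))

  truncated <- trend_top_table(calls, top_n = 2)
  expect_equal(nrow(truncated), 2L)
  expect_false(is.null(attr(truncated, "bin_means")))
})

test_that("high-expression proportions count strictly-above patients", {
  expr <- rbind(g1 = c(1, 2, 3, 10, 20, 30),
                g2 = c(5, 5, 5, 5, 5, 5))
  colnames(expr) <- sprintf("p%d", 1:6)
  cl <- data.frame(patient_id = colnames(expr),
                   diagnosis_year = rep(c(2000, 2001), each = 3),
                   os_time = 1, event = 1L, subtype = NA_character_)
  b <- make_bins(cl, 2)
  prop <- high_expression_proportion(expr, b,
                                     c(g1 = 2, g2 = 0))
  expect_equal(unname(prop["g1", ]), c(1 / 3, 1))
  expect_equal(unname(prop["g2", ]), c(1, 1)) # cutpoint below the minimum
  expect_error(high_expression_proportion(expr, b, c(gX = 1)),
               "cutpoints")
})
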