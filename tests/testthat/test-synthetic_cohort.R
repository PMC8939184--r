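test_that("identical seeds give identical cohorts, different seeds differ", {
  cfg <- sim_config(n_patients = 60, n_genes = 40, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth, b$truth)
  c <- generate_cohort(sim_config(n_patients = 60, n_genes = 40, seed = 8))
  expect_false(identical(a$expression, c$expression))
})

test_that("no drift planted means empty up/down truth and a full null set", {
  co <- generate_cohort(sim_config(n_patients = 50, n_genes = 30,
                                   frac_up = 0, frac_down = 0, delta = 0,
                                   seed = 2))
  expect_length(co$truth$up_genes, 0)
  expect_length(co$truth$down_genes, 0)
  expect_setequal(co$truth$null_genes, rownames(co$expression))
})

test_that("up/down/null truth sets partition the gene universe", {
  co <- generate_cohort(sim_config(n_patients = 50, n_genes = 200,
                                   frac_up = 0.1, frac_down = 0.2,
                                   seed = 11))
  all_genes <- rownames(co$expression)
  tr <- co$truth
  expect_setequal(c(tr$up_genes, tr$down_genes, tr$null_genes), all_genes)
  expect_length(intersect(tr$up_genes, tr$down_genes), 0)
  expect_length(intersect(tr$up_genes, tr$null_genes), 0)
  expect_true(all(tr$prognostic_genes %in% c(tr$up_genes, tr$down_genes)))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(sim_config(frac_up = 0.7, frac_down = 0.6), "frac_up")
  expect_error(sim_config(subtype_probs = c(0.5, 0.5, 0.1, 0.1)),
               "subtype_probs")
  expect_error(sim_config(n_bins = 1), "n_bins")
  expect_error(sim_config(year_range = c(2000, 2003), n_bins = 8),
               "year_range")
  expect_error(sim_config(sigma = 0), "sigma")
})

test_that("planted up-genes rise through nearly every consecutive bin pair", {
  co <- generate_cohort(sim_config(n_patients = 800, n_genes = 100,
                                   frac_up = 0.3, frac_down = 0,
                                   delta = 1.0, sigma = 0.1, seed = 5))
  binning <- make_bins(co$clinical, 8)
  means <- bin_means(co$expression, binning)
  frac_fully_monotone <- mean(vapply(co$truth$up_genes, function(g)
    all(diff(means[g, ]) > 0), logical(1)))
  expect_gte(frac_fully_monotone, 0.95)
})

test_that("per-bin log2 means recover the planted drift slope", {
  cfg <- sim_config(n_patients = 1200, n_genes = 60, frac_up = 0.5,
                    frac_down = 0, delta = 0.8, sigma = 0.3, seed = 9)
  co <- generate_cohort(cfg)
  # regress per-bin mean log2 expression on the generator's bin index
  edges <- seq(cfg$year_range[1] - 0.5, cfg$year_range[2] + 0.5,
               length.out = cfg$n_bins + 1)
  bin <- findInterval(co$clinical$diagnosis_year, edges,
                      rightmost.closed = TRUE) - 1
  slopes <- vapply(co$truth$up_genes, function(g) {
    y <- tapply(log2(co$expression[g, ]), bin, mean)
    unname(stats::coef(stats::lm(y ~ as.numeric(names(y))))[2])
  }, numeric(1))
  se <- stats::sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - cfg$delta), 2 * se + 0.02)
})

test_that("default survival settings yield moderate censoring", {
  co <- generate_cohort(sim_config(n_patients = 2000, n_genes = 20,
                                   n_pathways = 3, pathway_size = 5,
                                   seed = 13))
  cens <- mean(co$clinical$event == 0)
  expect_gt(cens, 0.15)
  expect_lt(cens, 0.45)
})

test_that("written cohort files round-trip through the readers", {
  co <- generate_cohort(sim_config(n_patients = 30, n_genes = 10,
                                   n_pathways = 4, pathway_size = 5,
                                   seed = 21))
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  # 10 data rows + 1 header
  expect_length(readLines(paths[["expression"]]), 11L)
  expect_identical(read_expression(paths[["expression"]]), co$expression)
  cl <- suppressMessages(read_clinical(paths[["clinical"]]))
  expect_equal(cl$patient_id, co$clinical$patient_id)
  expect_equal(cl$event, co$clinical$event)
  sets <- read_gmt(paths[["pathways"]])
  expect_identical(names(sets), names(co$gene_sets))
  expect_identical(sets[[1]], co$gene_sets[[1]],
                   ignore_attr = FALSE)
  # GMT line layout: name, description, then the member ids
  line1 <- strsplit(readLines(paths[["pathways"]])[1], "\t")[[1]]
  expect_identical(line1[1], names(co$gene_sets)[1])
  expect_identical(line1[-(1:2)], as.character(co$gene_sets[[1]]))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_setequal(truth$up_genes, co$truth$up_genes)
})
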