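#' Load a pipeline run configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file. The
#'   file holds either a `simulate` block ([sim_config()] fields) or an
#'   `inputs` block (paths `expression`, `clinical`, `oncogenes`, `tsgs`,
#'   `lincrnas`, `gmt`), plus any of: `n_bins`, `explicit_edges`, `k_min`,
#'   `epsilon`, `top_n`, `enrich_method`, `alpha`, `minprop`,
#'   `min_subtype_n`, `subtypes`, `out_dir`, `seed`.
#' @return The configuration list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

default_run_config <- function() {
  list(n_bins = 8L, explicit_edges = NULL,
       k_min = NULL, epsilon = NULL, top_n = 50L,
       enrich_method = "ease", alpha = 0.05, minprop = 0.1,
       min_subtype_n = 20L,
       subtypes = c("LumA", "LumB", "Basal", "Her2"),
       seed = 1L)
}

#' Run the full temporal trend analysis pipeline
#'
#' Executes, on either a simulated or a file-based cohort: diagnosis-year
#' binning, per-gene trend calling, catalog overlap, pathway
#' over-representation of the up- and down-regulated lists separately,
#' per-called-gene survival stratification at the best expression cutpoint,
#' hub-gene selection, and high-expression-proportion trajectories; then
#' repeats trend calling and enrichment within each subtype subset (using
#' the whole-cohort bin edges). All module outputs are written as TSV/JSON
#' under `out_dir` together with `run_manifest.json`.
#'
#' @param config A configuration list (see [load_run_config()]) or a path
#'   to a YAML/JSON configuration file. Exactly one of `simulate` /
#'   `inputs` must be present.
#' @param out_dir Output directory; overrides `config$out_dir`.
#' @return Invisibly, the run manifest list.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- load_run_config(config)
  cfg <- utils::modifyList(default_run_config(), config)
  if (is.null(out_dir)) out_dir <- cfg$out_dir
  if (is.null(out_dir)) stop("no output directory configured",
                             call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  has_sim <- !is.null(cfg$simulate)
  has_inp <- !is.null(cfg$inputs)
  if (has_sim == has_inp)
    stop("configuration must contain exactly one of 'simulate' or 'inputs'",
         call. = FALSE)
  t0 <- Sys.time()
  log_file <- file.path(out_dir, "run.log")
  logf <- function(...) {
    msg <- paste0(...)
    message(msg)
    cat(msg, "\n", file = log_file, append = TRUE, sep = "")
  }
  unlink(log_file)
  set.seed(cfg$seed)

  stage <- "load"
  manifest <- list(config = cfg[setdiff(names(cfg), "inputs")],
                   package_version =
                     as.character(utils::packageVersion("cohorttrend")),
                   seed = cfg$seed, stages = list(), outputs = character(0))
  res <- tryCatch({
    if (has_sim) {
      sim_args <- cfg$simulate
      if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
      cohort <- generate_cohort(do.call(sim_config, sim_args))
      expr <- cohort$expression
      clinical <- cohort$clinical
      gene_sets <- cohort$gene_sets
      catalog <- cohort$catalog
      logf("simulated cohort: ", nrow(expr), " genes x ", ncol(expr),
           " patients")
    } else {
      inp <- cfg$inputs
      for (f in c("expression", "clinical", "oncogenes", "tsgs",
                  "lincrnas", "gmt")) {
        if (is.null(inp[[f]]))
          stop("inputs block missing path: ", f, call. = FALSE)
        if (!file.exists(inp[[f]]))
          stop("input file not found: ", inp[[f]], call. = FALSE)
      }
      expr <- read_expression(inp$expression)
      clinical <- read_clinical(inp$clinical)
      gene_sets <- read_gmt(inp$gmt)
      catalog <- read_catalog(inp$oncogenes, inp$tsgs, inp$lincrnas)
      logf("loaded cohort: ", nrow(expr), " genes x ", nrow(clinical),
           " patients")
    }
    common <- intersect(clinical$patient_id, colnames(expr))
    n_drop <- (nrow(clinical) - length(common)) +
      (ncol(expr) - length(common))
    if (n_drop > 0)
      logf(n_drop, " record(s) dropped at the expression/clinical join")
    clinical <- clinical[clinical$patient_id %in% common, , drop = FALSE]
    expr <- expr[, common, drop = FALSE]
    manifest$stages$load <- "ok"

    stage <- "binning"
    binning <- if (!is.null(cfg$explicit_edges))
      make_bins(clinical, mode = "explicit",
                explicit_edges = cfg$explicit_edges)
    else make_bins(clinical, n_bins = cfg$n_bins, mode = "quantile")
    logf("bins: ", paste(binning$bin_labels, "(", bin_sizes(binning), ")",
                         collapse = ", "))
    manifest$stages$binning <- "ok"

    stage <- "trend_calling"
    tp <- trend_params(k_min = cfg$k_min, epsilon = cfg$epsilon,
                       top_n = cfg$top_n)
    calls <- call_trends(expr, binning, tp)
    n_up <- sum(calls$direction == "up")
    n_down <- sum(calls$direction == "down")
    logf(n_up, " up-regulated and ", n_down, " down-regulated genes")
    write_tsv <- function(df, name) {
      p <- file.path(out_dir, name)
      utils::write.table(df, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      manifest$outputs <<- c(manifest$outputs, name)
      p
    }
    bm <- attr(calls, "bin_means")
    calls_out <- cbind(as.data.frame(calls),
                       as.data.frame(bm)[calls$gene_id, , drop = FALSE])
    write_tsv(calls_out, "trend_calls.tsv")
    top <- trend_top_table(calls)
    top_bm <- attr(top, "bin_means")
    write_tsv(cbind(top, as.data.frame(top_bm)), "top_matrix.tsv")
    manifest$stages$trend_calling <- "ok"

    stage <- "annotation_overlap"
    ov <- annotation_overlap(calls, catalog)
    ov_rows <- do.call(rbind, lapply(names(ov), function(dir) {
      data.frame(direction = dir,
                 region = names(ov[[dir]]$region_counts),
                 count = as.integer(ov[[dir]]$region_counts),
                 stringsAsFactors = FALSE)
    }))
    write_tsv(ov_rows, "overlap_report.tsv")
    jsonlite::write_json(
      lapply(ov, function(x) list(n_called = x$n_called,
                                  regions = x$regions,
                                  lincrna_fraction = x$lincrna_fraction)),
      file.path(out_dir, "overlap_regions.json"), auto_unbox = TRUE)
    manifest$outputs <- c(manifest$outputs, "overlap_regions.json")
    manifest$stages$annotation_overlap <- "ok"

    stage <- "pathway_enrichment"
    universe <- default_universe(expr, gene_sets)
    run_enrich <- function(genes, name) {
      if (length(genes) == 0 || length(universe) == 0) {
        logf("skipping enrichment for empty list: ", name)
        return(invisible(NULL))
      }
      er <- enrich(genes, gene_sets, universe,
                   method = cfg$enrich_method, alpha = cfg$alpha)
      write_tsv(er, name)
    }
    up_genes <- calls$gene_id[calls$direction == "up"]
    down_genes <- calls$gene_id[calls$direction == "down"]
    run_enrich(up_genes, "enrichment_up.tsv")
    run_enrich(down_genes, "enrichment_down.tsv")
    manifest$stages$pathway_enrichment <- "ok"

    stage <- "survival"
    called <- c(up_genes, down_genes)
    surv_results <- list()
    surv_rows <- list()
    for (g in called) {
      fit <- tryCatch(
        suppressMessages(km_for_gene(expr, clinical, g,
                                     minprop = cfg$minprop)),
        error = function(e) NULL)
      if (is.null(fit)) {
        logf("survival skipped for gene ", g, " (no valid cutpoint)")
        next
      }
      surv_results[[g]] <- fit$cutpoint
      surv_rows[[g]] <- data.frame(
        gene_id = g, cutpoint = fit$cutpoint$cutpoint,
        n_high = fit$cutpoint$n_high, n_low = fit$cutpoint$n_low,
        logrank_chisq = fit$cutpoint$logrank_chisq,
        p_naive = fit$cutpoint$p_naive,
        median_survival_high = fit$km_high$median_survival,
        median_survival_low = fit$km_low$median_survival,
        stringsAsFactors = FALSE)
    }
    if (length(surv_rows) > 0)
      write_tsv(do.call(rbind, surv_rows), "survival.tsv")
    manifest$stages$survival <- "ok"

    stage <- "hub_selection"
    hub_cfg <- hub_criteria()
    kept <- calls
    kept <- kept[!(kept$direction %in% c("up", "down")) |
                   kept$gene_id %in% names(surv_results), , drop = FALSE]
    attr(kept, "bin_means") <- attr(calls, "bin_means")
    class(kept) <- class(calls)
    hubs <- select_hubs(kept, surv_results, catalog, hub_cfg)
    write_tsv(hubs, "hub_genes.tsv")
    logf(sum(hubs$passed), " hub gene(s) selected")
    manifest$stages$hub_selection <- "ok"

    stage <- "trajectories"
    if (length(surv_results) > 0) {
      cuts <- vapply(surv_results, `[[`, numeric(1), "cutpoint")
      prop <- high_expression_proportion(expr, binning, cuts)
      write_tsv(data.frame(gene_id = rownames(prop),
                           as.data.frame(prop), check.names = FALSE),
                "high_expression_proportion.tsv")
    }
    manifest$stages$trajectories <- "ok"

    stage <- "subtype_analysis"
    if (all(is.na(clinical$subtype))) {
      logf("no subtype labels; subtype analyses skipped")
    } else {
      for (st in cfg$subtypes) {
        sub_cl <- clinical[!is.na(clinical$subtype) &
                             clinical$subtype == st, , drop = FALSE]
        if (nrow(sub_cl) < cfg$min_subtype_n) {
          logf("subtype ", st, " skipped: ", nrow(sub_cl),
               " patients < ", cfg$min_subtype_n)
          next
        }
        sub_bin <- tryCatch({
          keep <- binning$assignment[names(binning$assignment) %in%
                                       sub_cl$patient_id]
          sb <- binning
          sb$assignment <- keep
          if (any(table(factor(keep, levels = 0:(binning$n_bins - 1L)))
                  == 0))
            stop("empty bin within subtype")
          sb
        }, error = function(e) NULL)
        if (is.null(sub_bin)) {
          logf("subtype ", st, " skipped: empty diagnosis-year bin")
          next
        }
        st_dir <- file.path(out_dir, paste0("subtype_", st))
        dir.create(st_dir, showWarnings = FALSE)
        sub_expr <- expr[, sub_cl$patient_id, drop = FALSE]
        sub_calls <- call_trends(sub_expr, sub_bin, tp)
        utils::write.table(as.data.frame(sub_calls),
                           file.path(st_dir, "trend_calls.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        manifest$outputs <- c(manifest$outputs,
                              file.path(paste0("subtype_", st),
                                        "trend_calls.tsv"))
        for (dir in c("up", "down")) {
          genes <- sub_calls$gene_id[sub_calls$direction == dir]
          if (length(genes) == 0) next
          er <- enrich(genes, gene_sets, universe,
                       method = cfg$enrich_method, alpha = cfg$alpha)
          fn <- file.path(st_dir, paste0("enrichment_", dir, ".tsv"))
          utils::write.table(er, fn, sep = "\t", quote = FALSE,
                             row.names = FALSE)
          manifest$outputs <- c(manifest$outputs,
                                file.path(paste0("subtype_", st),
                                          paste0("enrichment_", dir,
                                                 ".tsv")))
        }
        logf("subtype ", st, ": ",
             sum(sub_calls$direction == "up"), " up / ",
             sum(sub_calls$direction == "down"), " down")
      }
    }
    manifest$stages$subtype_analysis <- "ok"
    list(calls = calls, hubs = hubs, surv_results = surv_results)
  }, error = function(e) {
    manifest$stages[[stage]] <<- paste0("failed: ", conditionMessage(e))
    manifest$incomplete <<- TRUE
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  manifest$n_genes <- nrow(res$calls)
  manifest$n_up <- sum(res$calls$direction == "up")
  manifest$n_down <- sum(res$calls$direction == "down")
  manifest$n_hubs <- sum(res$hubs$passed)
  manifest$wall_time_sec <-
    as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(manifest)
}
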