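#' Configuration for the synthetic cohort generator
#'
#' Builds a validated configuration for [generate_cohort()]. Defaults emulate
#' a TCGA-BRCA-sized breast-cancer cohort: roughly a thousand patients
#' diagnosed over a 24-year window partitioned into eight diagnosis-year
#' groups, log-normal expression with monotone per-bin drifts planted on a
#' subset of genes, expression-dependent exponential overall survival with
#' administrative plus random censoring, PAM50-like subtype labels, and
#' pathway sets preferentially drawing their members from the planted genes.
#'
#' @param n_patients Number of patients.
#' @param n_genes Number of genes.
#' @param n_bins Number of diagnosis-year groups the cohort is designed for.
#' @param year_range Length-2 integer vector, first and last calendar year of
#'   diagnosis (inclusive).
#' @param frac_up,frac_down Fractions of genes with a planted monotone
#'   increase / decrease across bins. `frac_up + frac_down` must be <= 1.
#' @param delta Planted per-bin drift of mean log2 expression
#'   (log2-expression units per bin).
#' @param sigma Standard deviation of log2 expression around the gene/bin
#'   mean (multiplicative noise on the raw scale).
#' @param frac_prognostic Fraction of the planted (drifting) genes whose
#'   high/low expression status multiplies the patient hazard.
#' @param beta Log hazard ratio of above-median versus below-median
#'   expression for each prognostic gene.
#' @param baseline_hazard Baseline event rate (events per time unit; the
#'   default time unit is years since diagnosis).
#' @param censor_horizon Administrative censoring time; random censoring is
#'   drawn uniformly on (0, 2 * censor_horizon) and truncated at the horizon.
#' @param subtype_probs Length-4 probabilities for the subtype labels
#'   LumA, LumB, Basal, Her2 (must sum to 1).
#' @param n_pathways,pathway_size Number and size of simulated gene sets.
#' @param planted_enrichment_frac For the enriched pathways, the fraction of
#'   members drawn from the planted (drifting) genes; remaining members and
#'   all members of non-enriched pathways are drawn from the whole universe.
#' @param seed Integer seed; identical seeds give byte-identical cohorts.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_cohort()], [write_cohort()]
#' @export
sim_config <- function(n_patients = 1000L,
                       n_genes = 2000L,
                       n_bins = 8L,
                       year_range = c(1988L, 2011L),
                       frac_up = 0.05,
                       frac_down = 0.05,
                       delta = 1.0,
                       sigma = 0.25,
                       frac_prognostic = 0.02,
                       beta = 1.0,
                       baseline_hazard = 0.15,
                       censor_horizon = 10,
                       subtype_probs = c(LumA = 0.45, LumB = 0.242,
                                         Basal = 0.196, Her2 = 0.112),
                       n_pathways = 20L,
                       pathway_size = 25L,
                       planted_enrichment_frac = 0.6,
                       seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients), n_genes = as.integer(n_genes),
    n_bins = as.integer(n_bins), year_range = as.integer(year_range),
    frac_up = frac_up, frac_down = frac_down, delta = delta, sigma = sigma,
    frac_prognostic = frac_prognostic, beta = beta,
    baseline_hazard = baseline_hazard, censor_horizon = censor_horizon,
    subtype_probs = subtype_probs,
    n_pathways = as.integer(n_pathways),
    pathway_size = as.integer(pathway_size),
    planted_enrichment_frac = planted_enrichment_frac,
    seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stop_field <- function(field, msg) {
    stop(sprintf("invalid sim_config field '%s': %s", field, msg),
         call. = FALSE)
  }
  if (cfg$n_patients < 1L) stop_field("n_patients", "must be >= 1")
  if (cfg$n_genes < 1L) stop_field("n_genes", "must be >= 1")
  if (cfg$n_bins < 2L) stop_field("n_bins", "must be >= 2")
  if (length(cfg$year_range) != 2L || cfg$year_range[2] < cfg$year_range[1])
    stop_field("year_range", "must be two non-decreasing years")
  if (diff(cfg$year_range) + 1L < cfg$n_bins)
    stop_field("year_range", "must span at least n_bins distinct years")
  for (f in c("frac_up", "frac_down", "frac_prognostic",
              "planted_enrichment_frac")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop_field(f, "must be a fraction in [0, 1]")
  }
  if (cfg$frac_up + cfg$frac_down > 1)
    stop_field("frac_up", "frac_up + frac_down must be <= 1")
  if (cfg$sigma <= 0) stop_field("sigma", "must be > 0")
  if (cfg$baseline_hazard <= 0) stop_field("baseline_hazard", "must be > 0")
  if (cfg$censor_horizon <= 0) stop_field("censor_horizon", "must be > 0")
  if (length(cfg$subtype_probs) != 4L || any(cfg$subtype_probs < 0) ||
      abs(sum(cfg$subtype_probs) - 1) > 1e-9)
    stop_field("subtype_probs", "must be 4 probabilities summing to 1")
  if (cfg$n_pathways < 1L) stop_field("n_pathways", "must be >= 1")
  if (cfg$pathway_size < 1L || cfg$pathway_size > cfg$n_genes)
    stop_field("pathway_size", "must be in [1, n_genes]")
  invisible(cfg)
}

pad_ids <- function(prefix, n) {
  sprintf(paste0(prefix, "%0", max(2L, nchar(as.character(n))), "d"),
          seq_len(n))
}

#' Generate a synthetic expression cohort with known planted structure
#'
#' Draws a gene x patient expression matrix, a clinical table, pathway gene
#' sets and annotation catalogs, together with the ground truth used to
#' plant them. For gene g in diagnosis-year bin b (0-based), log2 expression
#' is Normal(mu_g + s_g * delta * b, sigma^2) with s_g in \{+1, -1, 0\}
#' according to whether the gene carries a planted up-drift, down-drift or no
#' drift; raw expression is 2 to that draw. Patient hazard is
#' `baseline_hazard * exp(beta * z)` where `z` counts the patient's
#' above-median statuses over the prognostic genes; survival is exponential
#' with that rate, censored at the administrative horizon or a uniform random
#' censoring time, whichever is first. Bin membership uses equal-width
#' year bins over `year_range` purely to place the drift; the analysis-side
#' binning is chosen later by [make_bins()]. Diagnosis years are redrawn
#' until at least `n_bins` distinct years are present so no bin can be empty.
#'
#' The first `floor(0.25 * n_pathways)` pathways (at least one) are enriched:
#' a `planted_enrichment_frac` share of their members is sampled from the
#' planted genes. Annotation catalogs (oncogenes, TSGs, lincRNAs) are random
#' gene subsets that deliberately include some planted genes so that overlap
#' and hub-filter logic is exercised.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `sim_cohort` with elements `expression` (numeric
#'   matrix, genes x patients), `clinical` (data.frame: patient_id,
#'   diagnosis_year, os_time, event, subtype), `gene_sets` (named list of
#'   character vectors with a `description` attribute per set), `catalog`
#'   (list with `oncogenes`, `tsgs`, `lincrnas`), and `truth` (list with
#'   `up_genes`, `down_genes`, `null_genes`, `prognostic_genes`,
#'   `enriched_pathways`).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  set.seed(config$seed)

  n_p <- config$n_patients
  n_g <- config$n_genes
  gene_ids <- pad_ids("g", n_g)
  patient_ids <- pad_ids("p", n_p)

  # planted structure
  n_up <- round(config$frac_up * n_g)
  n_down <- round(config$frac_down * n_g)
  planted <- if (n_up + n_down > 0) sample(gene_ids, n_up + n_down) else character(0)
  up_genes <- sort(planted[seq_len(n_up)])
  down_genes <- sort(planted[n_up + seq_len(n_down)])
  null_genes <- sort(setdiff(gene_ids, planted))
  s <- integer(n_g)
  names(s) <- gene_ids
  s[up_genes] <- 1L
  s[down_genes] <- -1L

  # diagnosis years: uniform over the window, redrawn until n_bins distinct
  years_pool <- seq.int(config$year_range[1], config$year_range[2])
  repeat {
    diagnosis_year <- sample(years_pool, n_p, replace = TRUE)
    if (length(unique(diagnosis_year)) >= config$n_bins) break
  }
  # drift bin index 0..n_bins-1 via equal-width year slices
  edges <- seq(config$year_range[1] - 0.5, config$year_range[2] + 0.5,
               length.out = config$n_bins + 1L)
  drift_bin <- findInterval(diagnosis_year, edges,
                            rightmost.closed = TRUE) - 1L

  # log2 expression: baseline mu_g ~ N(5, 1), drift s_g * delta * bin
  mu <- stats::rnorm(n_g, mean = 5, sd = 1)
  noise <- matrix(stats::rnorm(n_g * n_p, sd = config$sigma), n_g, n_p)
  log2_expr <- mu + outer(s * config$delta, drift_bin) + noise
  expr <- 2^log2_expr
  dimnames(expr) <- list(gene_ids, patient_ids)

  # prognostic genes: subset of planted genes; hazard multiplies per gene
  n_prog <- round(config$frac_prognostic * length(planted))
  prognostic <- if (n_prog > 0) sort(sample(planted, n_prog)) else character(0)
  beta_sign <- rep(1, length(prognostic))
  names(beta_sign) <- prognostic
  log_hr <- rep(0, n_p)
  for (g in prognostic) {
    z <- expr[g, ] > stats::median(expr[g, ])
    log_hr <- log_hr + config$beta * beta_sign[[g]] * as.numeric(z)
  }
  rate <- config$baseline_hazard * exp(log_hr)
  t_event <- stats::rexp(n_p, rate = rate)
  t_censor <- pmin(config$censor_horizon,
                   stats::runif(n_p, 0, 2 * config$censor_horizon))
  os_time <- pmin(t_event, t_censor)
  event <- as.integer(t_event <= t_censor)

  subtype <- sample(names(config$subtype_probs), n_p, replace = TRUE,
                    prob = config$subtype_probs)

  clinical <- data.frame(
    patient_id = patient_ids,
    diagnosis_year = diagnosis_year,
    os_time = os_time,
    event = event,
    subtype = subtype,
    stringsAsFactors = FALSE)

  # pathway sets: first ~25% enriched in planted genes
  n_enriched <- max(1L, as.integer(floor(0.25 * config$n_pathways)))
  n_enriched <- min(n_enriched, config$n_pathways)
  pathway_ids <- pad_ids("path", config$n_pathways)
  gene_sets <- vector("list", config$n_pathways)
  names(gene_sets) <- pathway_ids
  for (i in seq_len(config$n_pathways)) {
    if (i <= n_enriched && length(planted) > 0) {
      k_planted <- min(length(planted),
                       round(config$planted_enrichment_frac *
                               config$pathway_size))
      members <- c(sample(planted, k_planted),
                   sample(setdiff(gene_ids, planted),
                          config$pathway_size - k_planted))
    } else {
      members <- sample(gene_ids, config$pathway_size)
    }
    members <- sort(unique(members))
    attr(members, "description") <- if (i <= n_enriched)
      "simulated pathway enriched for drifting genes"
    else "simulated background pathway"
    gene_sets[[i]] <- members
  }

  # annotation catalogs: random subsets salted with planted genes
  take <- function(pool, n) sort(sample(pool, min(n, length(pool))))
  catalog <- list(
    oncogenes = take(gene_ids, max(5L, round(0.02 * n_g))),
    tsgs = take(gene_ids, max(5L, round(0.02 * n_g))),
    lincrnas = sort(unique(c(
      take(gene_ids, max(5L, round(0.05 * n_g))),
      if (length(planted) > 0) take(planted, max(1L, round(0.15 * length(planted))))
    ))))

  truth <- list(
    up_genes = up_genes,
    down_genes = down_genes,
    null_genes = null_genes,
    prognostic_genes = prognostic,
    prognostic_beta_sign = beta_sign,
    enriched_pathways = pathway_ids[seq_len(n_enriched)])

  structure(list(expression = expr, clinical = clinical,
                 gene_sets = gene_sets, catalog = catalog, truth = truth,
                 config = config),
            class = "sim_cohort")
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Emits `expression.tsv` (genes x patients), `clinical.tsv`,
#' `pathways.gmt`, `oncogenes.txt`, `tsgs.txt`, `lincrnas.txt` and
#' `truth.json`, all readable back through the package's readers.
#'
#' @param cohort A `sim_cohort` from [generate_cohort()].
#' @param out_dir Output directory, created if absent.
#' @return Invisibly, a named character vector of the files written.
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  paths <- c(
    expression = file.path(out_dir, "expression.tsv"),
    clinical = file.path(out_dir, "clinical.tsv"),
    pathways = file.path(out_dir, "pathways.gmt"),
    oncogenes = file.path(out_dir, "oncogenes.txt"),
    tsgs = file.path(out_dir, "tsgs.txt"),
    lincrnas = file.path(out_dir, "lincrnas.txt"),
    truth = file.path(out_dir, "truth.json"))

  write_expression_tsv(cohort$expression, paths[["expression"]])
  utils::write.table(cohort$clinical, paths[["clinical"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gmt(cohort$gene_sets, paths[["pathways"]])
  writeLines(cohort$catalog$oncogenes, paths[["oncogenes"]])
  writeLines(cohort$catalog$tsgs, paths[["tsgs"]])
  writeLines(cohort$catalog$lincrnas, paths[["lincrnas"]])
  jsonlite::write_json(
    list(up_genes = cohort$truth$up_genes,
         down_genes = cohort$truth$down_genes,
         prognostic_genes = cohort$truth$prognostic_genes,
         enriched_pathways = cohort$truth$enriched_pathways),
    paths[["truth"]])
  invisible(paths)
}
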