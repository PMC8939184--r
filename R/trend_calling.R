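#' Parameters for trend calling
#'
#' `k_min` is the minimum number of consecutive bin-to-bin strict increases
#' (decreases) out of the B-1 comparisons required to call a gene
#' up-regulated (down-regulated). The default reproduces the
#' at-least-6-of-7 rule used with eight diagnosis-year groups and
#' generalises to `B - 2` for other bin counts; any value must exceed
#' `(B - 1) / 2` so a gene can never be called both directions.
#' `epsilon` is the pseudocount stabilising log2 fold-changes of zero bin
#' means; when left `NULL` it resolves to half the smallest positive value
#' in the expression matrix (or 1e-6 when no positive value exists).
#'
#' @param k_min Minimum consecutive-step count for a directional call, or
#'   `NULL` to use `B - 2`.
#' @param epsilon Pseudocount added inside both log2 terms, or `NULL` for
#'   the data-driven default.
#' @param top_n Number of genes per direction retained by
#'   [trend_top_table()].
#' @return A list of class `trend_params`.
#' @export
trend_params <- function(k_min = NULL, epsilon = NULL, top_n = 50L) {
  if (!is.null(epsilon) && epsilon <= 0)
    stop("epsilon must be > 0", call. = FALSE)
  if (!is.null(top_n) && top_n < 1L)
    stop("top_n must be >= 1", call. = FALSE)
  structure(list(k_min = if (is.null(k_min)) NULL else as.integer(k_min),
                 epsilon = epsilon, top_n = as.integer(top_n)),
            class = "trend_params")
}

resolve_trend_params <- function(params, n_bins, expr = NULL) {
  if (is.null(params)) params <- trend_params()
  k_min <- params$k_min
  if (is.null(k_min)) k_min <- n_bins - 2L
  if (k_min <= (n_bins - 1L) / 2 || k_min > n_bins - 1L)
    stop(sprintf("k_min must satisfy (B-1)/2 < k_min <= B-1 (B = %d)",
                 n_bins), call. = FALSE)
  epsilon <- params$epsilon
  if (is.null(epsilon)) {
    pos <- if (!is.null(expr)) expr[expr > 0] else numeric(0)
    epsilon <- if (length(pos) > 0) min(pos) * 0.5 else 1e-6
  }
  list(k_min = as.integer(k_min), epsilon = epsilon, top_n = params$top_n)
}

#' Per-gene per-bin mean expression
#'
#' The expression change of a gene in a diagnosis-year group is summarised
#' by its arithmetic mean over the patients of that group.
#'
#' @param expr Numeric genes x patients matrix.
#' @param binning A `group_binning` from [make_bins()].
#' @return A genes x bins numeric matrix (columns named by bin label).
#' @export
bin_means <- function(expr, binning) {
  pats <- names(binning$assignment)
  missing <- setdiff(pats, colnames(expr))
  if (length(missing) > 0)
    stop("patients in binning absent from expression matrix: ",
         paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
  b <- binning$n_bins
  out <- matrix(NA_real_, nrow = nrow(expr), ncol = b,
                dimnames = list(rownames(expr), binning$bin_labels))
  for (i in seq_len(b)) {
    members <- pats[binning$assignment == i - 1L]
    if (length(members) == 0)
      stop("bin ", binning$bin_labels[i], " is empty", call. = FALSE)
    out[, i] <- rowMeans(expr[, members, drop = FALSE])
  }
  out
}

#' Call the temporal trend of one gene from its bin means
#'
#' Counts strict increases, strict decreases and ties over the B-1
#' consecutive bin comparisons. A gene is called `up` when at least `k_min`
#' comparisons are strict increases, `down` when at least `k_min` are strict
#' decreases, otherwise `none`; ties count as neither. The log2 fold-change
#' compares the last bin to the first with the epsilon pseudocount inside
#' both log terms. Counter-directional steps (a strict decrease for an
#' up-gene, a strict increase for a down-gene; for uncalled genes, steps
#' against the sign of the overall change) are reported with their log2
#' magnitudes for the downstream hub filter.
#'
#' @param means Numeric vector of B >= 2 non-negative bin means, in
#'   chronological order.
#' @param params A [trend_params()] object (or `NULL` for defaults).
#' @param gene_id Optional identifier carried through to the result.
#' @return A list of class `trend_call`: `gene_id`, `bin_means`,
#'   `n_increase`, `n_decrease`, `n_tie`, `direction`, `log2fc`,
#'   `counter_steps` (log2 magnitudes of counter-directional steps).
#' @export
call_trend <- function(means, params = NULL, gene_id = NA_character_) {
  if (length(means) < 2L) stop("need >= 2 bin means", call. = FALSE)
  if (anyNA(means)) stop("NaN/NA bin mean for gene ", gene_id, call. = FALSE)
  if (any(means < 0)) stop("negative bin mean for gene ", gene_id,
                           call. = FALSE)
  p <- resolve_trend_params(params, length(means))
  d <- diff(means)
  n_inc <- sum(d > 0)
  n_dec <- sum(d < 0)
  n_tie <- sum(d == 0)
  direction <- if (n_inc >= p$k_min) "up" else if (n_dec >= p$k_min) "down"
  else "none"
  lm <- log2(means + p$epsilon)
  log2fc <- lm[length(lm)] - lm[1]
  counter_sign <- switch(direction, up = -1, down = 1, none = -sign(log2fc))
  steps <- diff(lm)
  counter <- if (counter_sign == 0) numeric(0)
  else abs(steps[sign(d) == counter_sign])
  structure(list(gene_id = gene_id, bin_means = as.numeric(means),
                 n_increase = n_inc, n_decrease = n_dec, n_tie = n_tie,
                 direction = direction, log2fc = unname(log2fc),
                 counter_steps = counter),
            class = "trend_call")
}

#' Call trends for every gene of a binned cohort
#'
#' Applies [call_trend()] gene by gene; output rows keep the input gene
#' order.
#'
#' @param expr Numeric genes x patients matrix.
#' @param binning A `group_binning` from [make_bins()].
#' @param params A [trend_params()] object (or `NULL` for defaults;
#'   `epsilon` resolves against `expr`).
#' @return A data.frame of class `trend_calls`, one row per gene, with
#'   columns `gene_id`, `direction`, `n_increase`, `n_decrease`, `n_tie`,
#'   `log2fc`, `abs_log2fc`, `n_counter_steps`, `max_counter_step`, and the
#'   bin means as a matrix attribute `bin_means`. The resolved `k_min` and
#'   `epsilon` are attached as attributes.
#' @export
call_trends <- function(expr, binning, params = NULL) {
  means <- bin_means(expr, binning)
  p <- resolve_trend_params(params, ncol(means), expr)
  pp <- trend_params(k_min = p$k_min, epsilon = p$epsilon, top_n = p$top_n)
  calls <- lapply(seq_len(nrow(means)), function(i)
    call_trend(means[i, ], pp, gene_id = rownames(means)[i]))
  df <- data.frame(
    gene_id = vapply(calls, `[[`, character(1), "gene_id"),
    direction = vapply(calls, `[[`, character(1), "direction"),
    n_increase = vapply(calls, `[[`, numeric(1), "n_increase"),
    n_decrease = vapply(calls, `[[`, numeric(1), "n_decrease"),
    n_tie = vapply(calls, `[[`, numeric(1), "n_tie"),
    log2fc = vapply(calls, `[[`, numeric(1), "log2fc"),
    stringsAsFactors = FALSE)
  df$abs_log2fc <- abs(df$log2fc)
  df$n_counter_steps <- vapply(calls, function(x)
    length(x$counter_steps), numeric(1))
  df$max_counter_step <- vapply(calls, function(x)
    if (length(x$counter_steps) > 0) max(x$counter_steps) else 0,
    numeric(1))
  attr(df, "bin_means") <- means
  attr(df, "k_min") <- p$k_min
  attr(df, "epsilon") <- p$epsilon
  attr(df, "top_n") <- p$top_n
  class(df) <- c("trend_calls", "data.frame")
  df
}

#' Top up- and down-regulated genes ordered by log2 fold-change
#'
#' Up-regulated genes are sorted by log2 fold-change descending and
#' down-regulated genes ascending (largest decrease first), each truncated
#' to `top_n`; equal fold-changes are broken by gene id. The heatmap-ready
#' per-bin mean sub-matrix of the retained genes is attached.
#'
#' @param calls A `trend_calls` data.frame from [call_trends()].
#' @param top_n Number of genes per direction; defaults to the value
#'   resolved in `calls`.
#' @return A data.frame with columns `gene_id`, `direction`, `rank`,
#'   `log2fc`, `abs_log2fc`; the bin means of the listed genes are in the
#'   `bin_means` attribute.
#' @export
trend_top_table <- function(calls, top_n = NULL) {
  if (is.null(top_n)) top_n <- attr(calls, "top_n")
  if (is.null(top_n)) top_n <- 50L
  pick <- function(dir) {
    sub <- calls[calls$direction == dir, , drop = FALSE]
    ord <- if (dir == "up") order(-sub$log2fc, sub$gene_id)
    else order(sub$log2fc, sub$gene_id)
    utils::head(sub[ord, , drop = FALSE], top_n)
  }
  up <- pick("up")
  down <- pick("down")
  out <- rbind(up, down)
  out$rank <- c(seq_len(nrow(up)), seq_len(nrow(down)))
  out <- out[, c("gene_id", "direction", "rank", "log2fc", "abs_log2fc")]
  rownames(out) <- NULL
  bm <- attr(calls, "bin_means")
  if (!is.null(bm)) attr(out, "bin_means") <- bm[out$gene_id, , drop = FALSE]
  out
}

#' Proportion of high-expression patients per diagnosis-year bin
#'
#' For each requested gene, the fraction of patients in each bin whose
#' expression lies strictly above the gene's global cutpoint (typically the
#' maximally selected survival cutpoint). This is the trajectory behind the
#' "proportion of high expression population" line charts.
#'
#' @param expr Numeric genes x patients matrix.
#' @param binning A `group_binning` from [make_bins()].
#' @param cutpoints Named numeric vector, gene id -> expression threshold.
#' @return A genes x bins matrix of proportions in `[0, 1]`.
#' @export
high_expression_proportion <- function(expr, binning, cutpoints) {
  genes <- names(cutpoints)
  if (is.null(genes) || any(!genes %in% rownames(expr)))
    stop("cutpoints must be named by genes present in the matrix",
         call. = FALSE)
  pats <- names(binning$assignment)
  b <- binning$n_bins
  out <- matrix(NA_real_, nrow = length(genes), ncol = b,
                dimnames = list(genes, binning$bin_labels))
  for (i in seq_len(b)) {
    members <- pats[binning$assignment == i - 1L]
    if (length(members) == 0)
      stop("bin ", binning$bin_labels[i], " is empty", call. = FALSE)
    sub <- expr[genes, members, drop = FALSE]
    out[, i] <- rowMeans(sub > cutpoints)
  }
  out
}
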