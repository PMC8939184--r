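#' Criteria for hub-gene selection
#'
#' The four-part filter applied to trend-called genes: (1) the gene is not
#' a catalogued lincRNA; (2) its Kaplan-Meier log-rank p-value at the best
#' expression cutpoint is below `p_threshold`; (3) the magnitude of its
#' last-versus-first-bin log2 fold-change exceeds `abs_log2fc_threshold`;
#' (4) its trajectory has at most `max_counter_steps` counter-directional
#' steps, each with log2 magnitude below `counter_step_fraction` of the
#' total log2 change. Defaults reproduce the published rule: p < 0.05,
#' |log2FC| > 1, one drop allowed if smaller than one third of the total
#' change.
#'
#' @param require_not_lincrna Apply criterion (1) (default TRUE).
#' @param p_threshold Strict upper bound on the survival p-value.
#' @param abs_log2fc_threshold Strict lower bound on |log2FC|.
#' @param max_counter_steps Maximum number of counter-directional steps.
#' @param counter_step_fraction Each counter-step must be below this
#'   fraction of |log2FC| (in (0, 1)).
#' @return A list of class `hub_criteria`.
#' @export
hub_criteria <- function(require_not_lincrna = TRUE,
                         p_threshold = 0.05,
                         abs_log2fc_threshold = 1.0,
                         max_counter_steps = 1L,
                         counter_step_fraction = 1 / 3) {
  if (p_threshold <= 0 || abs_log2fc_threshold <= 0)
    stop("thresholds must be positive", call. = FALSE)
  if (counter_step_fraction <= 0 || counter_step_fraction >= 1)
    stop("counter_step_fraction must be in (0, 1)", call. = FALSE)
  if (max_counter_steps < 0)
    stop("max_counter_steps must be >= 0", call. = FALSE)
  structure(list(require_not_lincrna = isTRUE(require_not_lincrna),
                 p_threshold = p_threshold,
                 abs_log2fc_threshold = abs_log2fc_threshold,
                 max_counter_steps = as.integer(max_counter_steps),
                 counter_step_fraction = counter_step_fraction),
            class = "hub_criteria")
}

#' Apply the hub-gene filter to trend calls plus survival results
#'
#' Evaluates every trend-called (up or down) gene against the four hub
#' criteria (see [hub_criteria()]). The counter-step rule is applied
#' direction-symmetrically: for a down-regulated gene the counter-step is a
#' rise. A gene passes iff no criterion fails; the result lists the failed
#' criteria by name so borderline patterns (significant p but small
#' fold-change, or the converse) remain visible.
#'
#' @param calls A `trend_calls` data.frame from [call_trends()].
#' @param survival_results Named list (gene id -> `cutpoint_result`, or
#'   anything with a `p_naive` element) covering every called gene, e.g.
#'   built from [km_for_gene()] or [best_cutpoint()].
#' @param catalog Annotation catalog with a `lincrnas` element.
#' @param criteria A [hub_criteria()] object.
#' @return A data.frame ordered by |log2FC| descending with columns
#'   `gene_id`, `direction`, `log2fc`, `p_naive`, `n_counter_steps`,
#'   `max_counter_step`, `is_lincrna`, `passed`, `failed_criteria`
#'   (comma-separated names, empty when passed).
#' @export
select_hubs <- function(calls, survival_results, catalog,
                        criteria = hub_criteria()) {
  stopifnot(inherits(calls, "trend_calls"))
  cand <- calls[calls$direction %in% c("up", "down"), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    g <- cand$gene_id[i]
    sr <- survival_results[[g]]
    if (is.null(sr))
      stop("missing survival result for called gene ", g, call. = FALSE)
    p <- sr$p_naive
    failed <- character(0)
    is_linc <- g %in% catalog$lincrnas
    if (criteria$require_not_lincrna && is_linc)
      failed <- c(failed, "lincrna")
    if (!(p < criteria$p_threshold))
      failed <- c(failed, "km_p")
    if (!(cand$abs_log2fc[i] > criteria$abs_log2fc_threshold))
      failed <- c(failed, "log2fc")
    too_many <- cand$n_counter_steps[i] > criteria$max_counter_steps
    too_big <- cand$n_counter_steps[i] > 0 &&
      !(cand$max_counter_step[i] <
          criteria$counter_step_fraction * cand$abs_log2fc[i])
    if (too_many || too_big)
      failed <- c(failed, "trajectory")
    data.frame(gene_id = g,
               direction = cand$direction[i],
               log2fc = cand$log2fc[i],
               p_naive = p,
               n_counter_steps = cand$n_counter_steps[i],
               max_counter_step = cand$max_counter_step[i],
               is_lincrna = is_linc,
               passed = length(failed) == 0,
               failed_criteria = paste(failed, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0) do.call(rbind, rows)
  else data.frame(gene_id = character(0), direction = character(0),
                  log2fc = numeric(0), p_naive = numeric(0),
                  n_counter_steps = numeric(0),
                  max_counter_step = numeric(0),
                  is_lincrna = logical(0), passed = logical(0),
                  failed_criteria = character(0),
                  stringsAsFactors = FALSE)
  out <- out[order(-abs(out$log2fc), out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
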