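#' Gene-set over-representation of a query list
#'
#' Tests each gene set for over-representation in a query gene list by the
#' upper-tail hypergeometric probability of the observed overlap, in the
#' style of the DAVID web tool. With universe size N, K set members in the
#' universe, a query of n genes and overlap k, the one-sided Fisher p-value
#' is `P(X >= k)` for `X ~ Hypergeom(N, K, n)`. The default `"ease"` method
#' is DAVID's conservative EASE score: the same tail computed after
#' replacing k with `max(k - 1, 0)`, so `p_ease >= p_fisher` always. Fold
#' enrichment is `(k/n) / (K/N)`. Query genes outside the universe are
#' dropped with a message; set members outside the universe do not count
#' towards K. No multiple-testing correction is applied unless
#' `adjust = TRUE` (Benjamini-Hochberg), matching the common practice of
#' reading raw p < alpha off DAVID output.
#'
#' @param query Character vector of query gene ids.
#' @param sets Named list of gene-id vectors (see [read_gmt()]).
#' @param universe Character vector of background gene ids. A sensible
#'   default is all expression-matrix genes appearing in at least one set;
#'   see [default_universe()].
#' @param method `"ease"` (default) or `"fisher"`.
#' @param alpha Significance level for the `significant` flag.
#' @param adjust If `TRUE`, `p_adjusted` (Benjamini-Hochberg) is added and
#'   used for the `significant` flag.
#' @return A data.frame sorted by p-value (ties by pathway id) with columns
#'   `pathway_id`, `description`, `N`, `K`, `n`, `k`, `fold_enrichment`,
#'   `p_value`, `neg_log10_p`, `significant` (and `p_adjusted` if
#'   requested). Sets with no members in the universe are skipped with a
#'   message; k = 0 rows are kept with fold enrichment 0.
#' @export
enrich <- function(query, sets, universe, method = c("ease", "fisher"),
                   alpha = 0.05, adjust = FALSE) {
  method <- match.arg(method)
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  if (length(sets) == 0) stop("no gene sets supplied", call. = FALSE)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    message(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  n <- length(query)
  N <- length(universe)
  rows <- lapply(names(sets), function(id) {
    members <- intersect(sets[[id]], universe)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(query, members))
    p <- hyper_tail_p(k, N, K, n, method)
    desc <- attr(sets[[id]], "description")
    data.frame(pathway_id = id,
               description = if (is.null(desc)) id else desc,
               N = N, K = K, n = n, k = k,
               fold_enrichment = if (n > 0) (k / n) / (K / N) else 0,
               p_value = p,
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  if (skipped > 0)
    message(skipped, " gene set(s) with no members in the universe skipped")
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) stop("no gene set overlaps the universe",
                              call. = FALSE)
  out <- do.call(rbind, rows)
  out$neg_log10_p <- -log10(out$p_value)
  if (adjust) {
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- out$p_adjusted < alpha
  } else {
    out$significant <- out$p_value < alpha
  }
  out <- out[order(out$p_value, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Upper-tail hypergeometric probability P(X >= k); EASE decrements the
# observed overlap by one before taking the tail.
hyper_tail_p <- function(k, N, K, n, method = "fisher") {
  kk <- if (method == "ease") max(k - 1L, 0L) else k
  stats::phyper(kk - 1, K, N - K, n, lower.tail = FALSE)
}

#' Default enrichment background
#'
#' All genes of the expression matrix that appear in at least one gene set
#' — mirroring the behaviour of annotation tools that restrict the
#' background to annotated genes. Set `annotated_only = FALSE` for the
#' whole matrix.
#'
#' @param expr Numeric genes x patients matrix (or a character vector of
#'   gene ids).
#' @param sets Named list of gene-id vectors.
#' @param annotated_only Restrict to genes present in >= 1 set (default).
#' @return Character vector of background gene ids.
#' @export
default_universe <- function(expr, sets, annotated_only = TRUE) {
  genes <- if (is.character(expr)) expr else rownames(expr)
  if (!annotated_only) return(unique(genes))
  annotated <- unique(unlist(sets, use.names = FALSE))
  intersect(genes, annotated)
}
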