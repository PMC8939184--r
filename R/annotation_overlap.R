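#' Intersect trend-called gene lists with annotation catalogs
#'
#' Computes, for the up- and down-regulated lists separately, the exact
#' Venn regions of the called set against the oncogene, tumor-suppressor
#' and lincRNA catalogs. A gene in several catalogs lands in the
#' corresponding multi-membership region exactly once; genes in none land
#' in the `unannotated` region. The lincRNA fraction of each called set
#' (catalogued lincRNAs / called genes) is reported alongside.
#'
#' @param calls A `trend_calls` data.frame from [call_trends()], or a list
#'   with elements `up` and `down` holding gene-id character vectors.
#' @param catalog A list with gene-id vectors `oncogenes`, `tsgs`,
#'   `lincrnas` (see [read_catalog()]).
#' @return A list of class `overlap_report` with one element per direction;
#'   each holds `n_called`, `regions` (named list of gene-id vectors keyed
#'   by membership signature such as `"oncogene"`, `"oncogene+tsg"`,
#'   `"unannotated"`), `region_counts`, and `lincrna_fraction`.
#' @export
annotation_overlap <- function(calls, catalog) {
  if (inherits(calls, "trend_calls")) {
    lists <- list(up = calls$gene_id[calls$direction == "up"],
                  down = calls$gene_id[calls$direction == "down"])
  } else {
    stopifnot(is.list(calls), all(c("up", "down") %in% names(calls)))
    lists <- calls[c("up", "down")]
  }
  out <- lapply(lists, function(genes) {
    genes <- unique(genes)
    sig <- vapply(genes, function(g) {
      parts <- c(if (g %in% catalog$oncogenes) "oncogene",
                 if (g %in% catalog$tsgs) "tsg",
                 if (g %in% catalog$lincrnas) "lincrna")
      if (length(parts) == 0) "unannotated"
      else paste(parts, collapse = "+")
    }, character(1))
    regions <- split(genes, sig)
    n_linc <- sum(genes %in% catalog$lincrnas)
    list(n_called = length(genes),
         regions = regions,
         region_counts = vapply(regions, length, integer(1)),
         lincrna_fraction = if (length(genes) > 0)
           n_linc / length(genes) else NA_real_)
  })
  structure(out, class = "overlap_report")
}
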