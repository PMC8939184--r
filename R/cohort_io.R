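#' Read a gene x patient expression matrix from TSV
#'
#' Expects a header row of patient identifiers and a first column of gene
#' identifiers. Values must be non-negative and finite; identifiers must be
#' unique. Parsing is locale-independent (dot decimal separator).
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix with gene rownames and patient colnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path,
                               call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header[-1]))
    stop("duplicate patient ids in ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA)
  if (ncol(df) < 2L) stop("expression TSV needs a gene-id column plus at ",
                          "least one patient column", call. = FALSE)
  gene_ids <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- gene_ids
  validate_expression(mat, path = path)
  mat
}

validate_expression <- function(mat, path = "<matrix>") {
  if (anyDuplicated(rownames(mat)))
    stop("duplicate gene ids in ", path, call. = FALSE)
  if (anyDuplicated(colnames(mat)))
    stop("duplicate patient ids in ", path, call. = FALSE)
  bad <- which(!is.finite(mat) | mat < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    # +1 for the header line of the TSV
    stop(sprintf(
      "non-finite or negative expression value at line %d (gene %s) of %s",
      bad[1, 1] + 1L, rownames(mat)[bad[1, 1]], path), call. = FALSE)
  }
  invisible(mat)
}

write_expression_tsv <- function(mat, path) {
  # %.17g keeps full double precision so a write/read cycle is lossless
  txt <- matrix(sprintf("%.17g", mat), nrow = nrow(mat))
  df <- data.frame(gene_id = rownames(mat), txt, stringsAsFactors = FALSE)
  names(df) <- c("gene_id", colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a clinical table from TSV
#'
#' Required columns: `patient_id`, `diagnosis_year`, `os_time` (time from
#' diagnosis in the unit the file declares), `event` (1 = death,
#' 0 = censored) and optionally `subtype` (LumA, LumB, Basal, Her2; anything
#' else is mapped to NA with a warning). Patients with missing diagnosis
#' year or missing survival time are dropped with a message rather than
#' imputed.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with the columns above.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("clinical file not found: ", path,
                               call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  required <- c("patient_id", "diagnosis_year", "os_time", "event")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("clinical table missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"subtype" %in% names(df)) df$subtype <- NA_character_
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient ids in ", path, call. = FALSE)

  drop <- is.na(df$diagnosis_year) | is.na(df$os_time)
  if (any(drop)) {
    message(sum(drop), " patient(s) dropped for missing diagnosis year or ",
            "survival time")
    df <- df[!drop, , drop = FALSE]
  }
  if (any(df$os_time < 0))
    stop("negative os_time in ", path, call. = FALSE)
  if (!all(df$event %in% c(0L, 1L)))
    stop("event column must be 0 (censored) or 1 (death) in ", path,
         call. = FALSE)
  known <- c("LumA", "LumB", "Basal", "Her2")
  unknown <- !is.na(df$subtype) & !(df$subtype %in% known)
  if (any(unknown)) {
    warning(sum(unknown), " unknown subtype label(s) mapped to NA",
            call. = FALSE)
    df$subtype[unknown] <- NA_character_
  }
  rownames(df) <- NULL
  df
}

#' Read a plain-text gene list
#'
#' One identifier per line; blank lines and lines starting with `#` are
#' ignored. An empty file yields an empty set with a warning.
#'
#' @param path Path to the list file.
#' @return A character vector of unique gene identifiers.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0)
    warning("gene list is empty: ", path, call. = FALSE)
  unique(lines)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member gene ids, all
#' tab-separated.
#'
#' @param path Path to the `.gmt` file.
#' @return A named list of character vectors; each element carries its
#'   description as the `description` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L)
      stop(sprintf("GMT line %d has fewer than 3 fields", i), call. = FALSE)
    name <- parts[[1]]
    if (name %in% names(sets))
      stop("duplicate pathway id in GMT: ", name, call. = FALSE)
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0)
      stop(sprintf("GMT line %d (%s) has an empty gene set", i, name),
           call. = FALSE)
    attr(members, "description") <- parts[[2]]
    sets[[name]] <- members
  }
  sets
}

write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm) {
    set <- gene_sets[[nm]]
    desc <- attr(set, "description")
    if (is.null(desc)) desc <- nm
    paste(c(nm, desc, as.character(set)), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
}

#' Read annotation catalogs (oncogenes, TSGs, lincRNAs)
#'
#' Convenience wrapper bundling three [read_gene_list()] calls into the
#' catalog structure the overlap and hub stages consume.
#'
#' @param oncogenes,tsgs,lincrnas Paths to the three gene-list files.
#' @return A list with elements `oncogenes`, `tsgs`, `lincrnas`.
#' @export
read_catalog <- function(oncogenes, tsgs, lincrnas) {
  list(oncogenes = read_gene_list(oncogenes),
       tsgs = read_gene_list(tsgs),
       lincrnas = read_gene_list(lincrnas))
}

#' Assign patients to diagnosis-year bins
#'
#' Partitions the cohort into `n_bins` chronological groups on whole-year
#' boundaries. In `"quantile"` mode the year boundaries are chosen to balance
#' patient counts as well as whole-year boundaries allow: among all
#' contiguous partitions of the observed distinct years into `n_bins`
#' non-empty groups, the one minimising the ratio of the largest to the
#' smallest bin count is selected (dynamic programme over year boundaries).
#' In `"explicit"` mode the supplied edges are used verbatim. Years are never
#' split across bins; a year belongs to exactly one bin.
#'
#' @param clinical A clinical data.frame (see [read_clinical()]).
#' @param n_bins Number of bins (>= 2). Ignored in explicit mode.
#' @param mode `"quantile"` (count-balancing, default) or `"explicit"`.
#' @param explicit_edges In explicit mode, an increasing vector of B+1 year
#'   boundaries; bin b covers years `[edge_b, edge_{b+1})`, so the final edge
#'   is one past the last year of the last bin.
#' @return An object of class `group_binning`: list with `bin_edges`
#'   (first year of each bin plus one-past-last), `bin_labels`
#'   (`"1988-1990"` style), and `assignment` (named integer vector,
#'   patient id -> 0-based bin index).
#' @export
make_bins <- function(clinical, n_bins = 8L,
                      mode = c("quantile", "explicit"),
                      explicit_edges = NULL) {
  mode <- match.arg(mode)
  years <- clinical$diagnosis_year
  if (mode == "explicit") {
    if (is.null(explicit_edges) || length(explicit_edges) < 3L)
      stop("explicit mode requires >= 3 increasing year edges",
           call. = FALSE)
    if (any(diff(explicit_edges) <= 0))
      stop("explicit edges must be strictly increasing", call. = FALSE)
    edges <- explicit_edges
  } else {
    n_bins <- as.integer(n_bins)
    if (n_bins < 2L) stop("n_bins must be >= 2", call. = FALSE)
    distinct <- sort(unique(years))
    if (length(distinct) < n_bins)
      stop(sprintf("only %d distinct diagnosis years for %d bins",
                   length(distinct), n_bins), call. = FALSE)
    counts <- as.integer(table(factor(years, levels = distinct)))
    cut_idx <- balance_year_partition(counts, n_bins)
    # cut_idx: indices into distinct years marking first year of bins 2..B
    edges <- c(distinct[1], distinct[cut_idx], distinct[length(distinct)] + 1L)
  }
  b <- length(edges) - 1L
  # half-open year intervals [edge_i, edge_{i+1}); the top edge is one past
  # the last year of the final bin
  idx <- findInterval(years, edges) - 1L
  in_range <- idx >= 0L & idx <= b - 1L & years < edges[length(edges)]
  assignment <- idx[in_range]
  names(assignment) <- clinical$patient_id[in_range]
  labels <- vapply(seq_len(b), function(i) {
    lo <- ceiling(edges[i])
    hi <- ceiling(edges[i + 1]) - 1L
    if (lo == hi) as.character(lo) else paste0(lo, "-", hi)
  }, character(1))
  if (any(table(factor(assignment, levels = 0:(b - 1L))) == 0))
    stop("binning produced an empty bin; use fewer bins or explicit edges",
         call. = FALSE)
  structure(list(bin_edges = edges, bin_labels = labels,
                 assignment = assignment, n_bins = b),
            class = "group_binning")
}

# Choose B-1 cut positions over distinct-year counts so the max/min bin
# occupancy ratio is minimal. For each candidate cap M on the largest bin,
# a DP computes the best achievable smallest bin; the (M, min) pair with the
# smallest ratio wins. Returns the distinct-year indices that start bins 2..B.
balance_year_partition <- function(counts, n_bins) {
  y <- length(counts)
  cs <- c(0L, cumsum(counts))
  seg <- function(i, j) cs[j + 1L] - cs[i] # sum of counts[i..j]
  # all achievable contiguous segment sums are candidate maxima
  cands <- sort(unique(unlist(lapply(seq_len(y), function(i)
    vapply(i:y, function(j) seg(i, j), integer(1))))))
  best <- NULL
  for (M in cands) {
    # f[i, b]: partitioning years 1..i into b bins each with count <= M,
    # the largest achievable minimum bin count (-Inf if infeasible)
    f <- matrix(-Inf, nrow = y, ncol = n_bins)
    trace <- matrix(NA_integer_, nrow = y, ncol = n_bins)
    for (i in seq_len(y)) if (seg(1L, i) <= M) f[i, 1L] <- seg(1L, i)
    if (n_bins > 1L) {
      for (b in 2:n_bins) {
        for (i in b:y) {
          for (j in (b - 1L):(i - 1L)) {
            s <- seg(j + 1L, i)
            if (s > M) next
            v <- min(f[j, b - 1L], s)
            if (v > f[i, b]) {
              f[i, b] <- v
              trace[i, b] <- j
            }
          }
        }
      }
    }
    if (is.finite(f[y, n_bins]) && f[y, n_bins] > 0) {
      ratio <- M / f[y, n_bins]
      if (is.null(best) || ratio < best$ratio) {
        cuts <- integer(0)
        i <- y
        for (b in n_bins:2) {
          j <- trace[i, b]
          cuts <- c(j + 1L, cuts)
          i <- j
        }
        best <- list(ratio = ratio, cuts = cuts)
      }
    }
  }
  if (is.null(best)) stop("no feasible year partition", call. = FALSE)
  best$cuts
}

#' Per-bin patient counts of a binning
#' @param binning A `group_binning` object.
#' @return Integer vector of length B, named by bin label.
#' @export
bin_sizes <- function(binning) {
  sizes <- as.integer(table(factor(binning$assignment,
                                   levels = 0:(binning$n_bins - 1L))))
  names(sizes) <- binning$bin_labels
  sizes
}
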