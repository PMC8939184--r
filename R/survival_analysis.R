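#' Kaplan-Meier product-limit fit
#'
#' Fits the product-limit estimator S(t) = prod over event times t_i <= t of
#' (1 - d_i / n_i). Censored-only times reduce the at-risk counts but add no
#' factor. The reported median is the smallest event time with S <= 0.5
#' (NA when the curve never reaches 0.5).
#'
#' @param times Non-negative follow-up times.
#' @param events 0/1 event indicators (1 = death).
#' @return A list of class `km_curve`: `event_times`, `at_risk`, `events`
#'   (counts at each distinct event time), `survival` (estimate after each
#'   event time), `median_survival`, `n`.
#' @export
km_fit <- function(times, events) {
  if (length(times) == 0) stop("empty survival input", call. = FALSE)
  if (length(times) != length(events))
    stop("times and events lengths differ", call. = FALSE)
  if (any(times < 0)) stop("negative survival time", call. = FALSE)
  if (!all(events %in% c(0, 1))) stop("events must be 0/1", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  keep <- fit$n.event > 0
  surv <- fit$surv[keep]
  event_times <- fit$time[keep]
  med <- if (any(surv <= 0.5)) min(event_times[surv <= 0.5]) else NA_real_
  structure(list(event_times = event_times,
                 at_risk = fit$n.risk[keep],
                 events = fit$n.event[keep],
                 survival = surv,
                 median_survival = med,
                 n = length(times)),
            class = "km_curve")
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank: over the distinct event times,
#' U = sum(d_1i - e_1i) with e_1i the expected group-1 events and V the
#' hypergeometric variance; the statistic is U^2 / V with a 1-df chi-square
#' upper-tail p-value. With no events (V = 0) the statistic is 0 and p = 1.
#'
#' @param times Non-negative follow-up times.
#' @param events 0/1 event indicators.
#' @param group Two-level grouping (logical, factor or vector); both groups
#'   must be non-empty.
#' @return A list with `chisq` and `p`.
#' @export
logrank_test <- function(times, events, group) {
  g <- as.factor(group)
  if (nlevels(droplevels(g)) != 2L)
    stop("log-rank test needs exactly two non-empty groups", call. = FALSE)
  if (sum(events) == 0) return(list(chisq = 0, p = 1))
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  chisq <- unname(sd$chisq)
  if (!is.finite(chisq)) chisq <- 0
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Maximally selected log-rank cutpoint for one expression vector
#'
#' The "auto best cutoff": every midpoint between consecutive distinct
#' expression values is a candidate threshold; candidates leaving fewer
#' than `minprop` of the cohort on either side are discarded; the log-rank
#' chi-square of high (strictly above threshold) versus low is computed at
#' each remaining candidate and the maximiser is returned (ties go to the
#' lower cutpoint). `p_naive` is the uncorrected 1-df chi-square tail at
#' the maximum; because the cutpoint is chosen to maximise the statistic
#' this p-value is anti-conservative under the null, exactly as when
#' reading it off a best-cutoff KM plot.
#'
#' The scan is vectorised: subjects are ordered by decreasing expression so
#' successive candidates differ by adding subjects to the high group, and
#' the per-event-time at-risk and event counts of the high group are
#' cumulative sums along that order.
#'
#' @param expr_values Numeric expression values, one per subject.
#' @param times,events Survival outcome, aligned with `expr_values`.
#' @param minprop Minimum fraction of subjects in each group (default 0.1).
#' @param gene_id Optional identifier carried into the result.
#' @return A list of class `cutpoint_result`: `gene_id`, `cutpoint`,
#'   `n_high`, `n_low`, `logrank_chisq`, `p_naive`, `minprop`,
#'   `candidates_evaluated`.
#' @export
best_cutpoint <- function(expr_values, times, events, minprop = 0.1,
                          gene_id = NA_character_) {
  n <- length(expr_values)
  if (length(times) != n || length(events) != n)
    stop("expression and survival vectors differ in length", call. = FALSE)
  if (n < ceiling(1 / minprop))
    stop("too few subjects for minprop = ", minprop, call. = FALSE)
  if (sum(events) < 1) stop("no events; cutpoint selection undefined",
                            call. = FALSE)
  v <- sort(unique(expr_values))
  if (length(v) < 2L)
    stop("constant expression vector: no valid split for gene ", gene_id,
         call. = FALSE)
  cand <- (v[-length(v)] + v[-1]) / 2
  # high group size for each candidate: subjects strictly above the midpoint
  n_above <- n - findInterval(cand, sort(expr_values))
  ok <- n_above >= minprop * n & (n - n_above) >= minprop * n
  if (!any(ok))
    stop("no candidate split satisfies minprop for gene ", gene_id,
         call. = FALSE)
  cand <- cand[ok]
  m <- n_above[ok]

  stats_all <- logrank_scan(expr_values, times, events, m)
  chisq <- stats_all$chisq
  best <- which.max(chisq) # first max = lowest cutpoint on ties
  structure(list(gene_id = gene_id,
                 cutpoint = cand[best],
                 n_high = as.integer(m[best]),
                 n_low = as.integer(n - m[best]),
                 logrank_chisq = chisq[best],
                 p_naive = stats::pchisq(chisq[best], df = 1,
                                         lower.tail = FALSE),
                 minprop = minprop,
                 candidates_evaluated = length(cand)),
            class = "cutpoint_result")
}

# Log-rank chi-square for every "top-m subjects by expression" split.
# m is a vector of high-group sizes; returns chisq aligned with m.
logrank_scan <- function(expr_values, times, events, m) {
  ord <- order(expr_values, decreasing = TRUE)
  t_ord <- times[ord]
  e_ord <- events[ord]
  tt <- sort(unique(times[events == 1]))
  at_risk <- outer(tt, t_ord, FUN = function(a, b) a <= b) # T x n
  ev_here <- outer(tt, t_ord, FUN = "==") *
    matrix(e_ord, nrow = length(tt), ncol = length(t_ord), byrow = TRUE)
  n_t <- rowSums(at_risk)
  d_t <- rowSums(ev_here)
  n1_cum <- t(apply(at_risk, 1, cumsum))
  d1_cum <- t(apply(ev_here, 1, cumsum))
  n1 <- n1_cum[, m, drop = FALSE]
  d1 <- d1_cum[, m, drop = FALSE]
  U <- colSums(d1) - colSums(n1 * (d_t / n_t))
  w <- ifelse(n_t > 1, d_t * (n_t - d_t) / (n_t - 1), 0)
  frac <- n1 / n_t
  V <- colSums(frac * (1 - frac) * w)
  chisq <- ifelse(V > 0, U^2 / V, 0)
  list(chisq = chisq, U = U, V = V)
}

#' Survival stratification of one gene at its best cutpoint
#'
#' Joins the expression row of `gene_id` with the clinical table on patient
#' id, selects the maximally selected log-rank cutpoint, and returns the
#' Kaplan-Meier curves of the high (strictly above cutpoint) and low
#' groups together with the cutpoint result. Patients missing survival data
#' are excluded with a message.
#'
#' @param expr Numeric genes x patients matrix.
#' @param clinical Clinical data.frame (see [read_clinical()]).
#' @param gene_id Gene to stratify.
#' @param minprop Minimum group proportion for the cutpoint scan.
#' @return A list with `cutpoint` (a `cutpoint_result`), `km_high`,
#'   `km_low` (both `km_curve`), and `n_excluded`.
#' @export
km_for_gene <- function(expr, clinical, gene_id, minprop = 0.1) {
  if (!gene_id %in% rownames(expr))
    stop("gene not in expression matrix: ", gene_id, call. = FALSE)
  common <- intersect(colnames(expr), clinical$patient_id)
  cl <- clinical[match(common, clinical$patient_id), , drop = FALSE]
  keep <- !is.na(cl$os_time) & !is.na(cl$event)
  n_excl <- sum(!keep) + (ncol(expr) - length(common))
  if (n_excl > 0)
    message(n_excl, " patient(s) excluded for missing survival data")
  cl <- cl[keep, , drop = FALSE]
  x <- expr[gene_id, cl$patient_id]
  cp <- best_cutpoint(x, cl$os_time, cl$event, minprop = minprop,
                      gene_id = gene_id)
  high <- x > cp$cutpoint
  list(cutpoint = cp,
       km_high = km_fit(cl$os_time[high], cl$event[high]),
       km_low = km_fit(cl$os_time[!high], cl$event[!high]),
       n_excluded = n_excl)
}
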