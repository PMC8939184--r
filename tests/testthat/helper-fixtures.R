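# Small fixtures built in code.

# A cohort with one patient per bin so per-bin means equal the raw values:
# each row of `mean_matrix` becomes one gene's eight bin means.
cohort_from_bin_means <- function(mean_matrix) {
  b <- ncol(mean_matrix)
  if (is.null(rownames(mean_matrix)))
    rownames(mean_matrix) <- sprintf("g%02d", seq_len(nrow(mean_matrix)))
  patients <- sprintf("p%02d", seq_len(b))
  expr <- mean_matrix
  colnames(expr) <- patients
  clinical <- data.frame(patient_id = patients,
                         diagnosis_year = seq_len(b),
                         os_time = rep(5, b), event = rep(1L, b),
                         subtype = rep("LumA", b),
                         stringsAsFactors = FALSE)
  binning <- make_bins(clinical, mode = "explicit",
                       explicit_edges = seq_len(b + 1))
  list(expr = expr, clinical = clinical, binning = binning)
}

# A genuine trend_calls object from bin-mean trajectories on the log2
# scale, plus matching survival-result stubs for the hub filter.
calls_from_log2 <- function(traj, p_values) {
  mm <- t(vapply(traj, function(v) 2^v, numeric(length(traj[[1]]))))
  rownames(mm) <- names(traj)
  co <- cohort_from_bin_means(mm)
  calls <- call_trends(co$expr, co$binning, trend_params(epsilon = 1e-9))
  surv <- lapply(p_values, function(p) list(p_naive = p))
  list(calls = calls, surv = surv)
}

random_survival_fixture <- function(n, seed, frac_events = 0.7) {
  set.seed(seed)
  list(times = round(stats::rexp(n, 0.2), 3),
       events = stats::rbinom(n, 1, frac_events),
       x = stats::rnorm(n))
}
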