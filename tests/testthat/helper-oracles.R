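# Independent oracles used across the suite. Deliberately naive: explicit
# loops and exact integer arithmetic, sharing no code with the package.

# ---- exact big-integer arithmetic (base 1e7 little-endian digit vectors) ----

bi <- function(x) {
  stopifnot(x >= 0, x < 1e7)
  as.numeric(x)
}

bi_norm <- function(a) {
  i <- 1
  while (i <= length(a)) {
    if (a[i] >= 1e7) {
      carry <- floor(a[i] / 1e7)
      a[i] <- a[i] - carry * 1e7
      if (i == length(a)) a <- c(a, 0)
      a[i + 1] <- a[i + 1] + carry
    }
    i <- i + 1
  }
  while (length(a) > 1 && a[length(a)] == 0) a <- a[-length(a)]
  a
}

bi_add <- function(a, b) {
  n <- max(length(a), length(b))
  bi_norm(c(a, rep(0, n - length(a))) + c(b, rep(0, n - length(b))))
}

bi_mul <- function(a, b) {
  out <- rep(0, length(a) + length(b))
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    for (j in seq_along(b)) {
      out[i + j - 1] <- out[i + j - 1] + a[i] * b[j]
      if (out[i + j - 1] >= 1e14) out <- bi_norm(out)
    }
  }
  bi_norm(out)
}

bi_to_double <- function(a) {
  v <- 0
  for (i in rev(seq_along(a))) v <- v * 1e7 + a[i]
  v
}

# Pascal's triangle of exact binomial coefficients up to n
bi_choose_table <- function(n) {
  tab <- vector("list", n + 1)
  tab[[1]] <- list(bi(1))
  for (r in seq_len(n)) {
    row <- vector("list", r + 1)
    row[[1]] <- bi(1)
    row[[r + 1]] <- bi(1)
    if (r > 1) for (c in 2:r)
      row[[c]] <- bi_add(tab[[r]][[c - 1]], tab[[r]][[c]])
    tab[[r + 1]] <- row
  }
  tab
}

.bi_table_cache <- new.env(parent = emptyenv())

# exact upper-tail hypergeometric p via big-integer sums
oracle_hyper_p <- function(k, N, K, n, method = c("fisher", "ease")) {
  method <- match.arg(method)
  if (method == "ease") k <- max(k - 1, 0)
  key <- as.character(N)
  if (is.null(.bi_table_cache[[key]]))
    .bi_table_cache[[key]] <- bi_choose_table(N)
  tab <- .bi_table_cache[[key]]
  ch <- function(a, b) if (b < 0 || b > a) bi(0) else tab[[a + 1]][[b + 1]]
  num <- bi(0)
  for (i in k:min(K, n)) num <- bi_add(num, bi_mul(ch(K, i), ch(N - K, n - i)))
  bi_to_double(num) / bi_to_double(ch(N, n))
}

# ---- trend oracle: direct counting over consecutive comparisons ----

oracle_trend <- function(means, k_min) {
  n_inc <- 0; n_dec <- 0; n_tie <- 0
  for (i in 2:length(means)) {
    if (means[i] > means[i - 1]) n_inc <- n_inc + 1
    else if (means[i] < means[i - 1]) n_dec <- n_dec + 1
    else n_tie <- n_tie + 1
  }
  dir <- "none"
  if (n_inc >= k_min) dir <- "up"
  if (n_dec >= k_min) dir <- "down"
  list(n_increase = n_inc, n_decrease = n_dec, n_tie = n_tie,
       direction = dir)
}

# exchangeable-null call rate: exhaustive enumeration over all orderings
# of B iid-continuous bin means (built by the insertion construction)
oracle_null_call_rate <- function(B, k_min) {
  perms <- matrix(1L, nrow = 1, ncol = 1)
  for (n in 2:B) {
    rows <- nrow(perms)
    out <- matrix(0L, nrow = rows * n, ncol = n)
    r <- 0
    for (pos in seq_len(n)) {
      idx <- r + seq_len(rows)
      if (pos > 1) out[idx, seq_len(pos - 1)] <-
          perms[, seq_len(pos - 1), drop = FALSE]
      out[idx, pos] <- n
      if (pos < n) out[idx, (pos + 1):n] <-
          perms[, pos:(n - 1), drop = FALSE]
      r <- r + rows
    }
    perms <- out
  }
  asc <- rowSums(perms[, -1, drop = FALSE] >
                   perms[, -ncol(perms), drop = FALSE])
  mean(asc >= k_min)
}

# ---- naive log-rank: explicit per-event-time summation ----

oracle_logrank <- function(times, events, group) {
  g <- as.integer(as.factor(group)) - 1L
  tt <- sort(unique(times[events == 1]))
  U <- 0; V <- 0
  for (t in tt) {
    at <- times >= t
    n_t <- sum(at)
    d_t <- sum(events == 1 & times == t)
    n1 <- sum(at & g == 1)
    d1 <- sum(events == 1 & times == t & g == 1)
    U <- U + d1 - d_t * n1 / n_t
    if (n_t > 1)
      V <- V + d_t * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d_t) / (n_t - 1)
  }
  chisq <- if (V > 0) U^2 / V else 0
  list(chisq = chisq,
       p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

# ---- brute-force maximally selected cutpoint ----

oracle_best_cutpoint <- function(x, times, events, minprop = 0.1) {
  n <- length(x)
  v <- sort(unique(x))
  cand <- (v[-length(v)] + v[-1]) / 2
  best <- NULL
  for (c in cand) {
    high <- x > c
    if (sum(high) < minprop * n || sum(!high) < minprop * n) next
    chisq <- oracle_logrank(times, events, high)$chisq
    if (is.null(best) || chisq > best$chisq + 1e-12)
      best <- list(cutpoint = c, chisq = chisq)
  }
  best
}

# ---- manual product-limit estimator ----

oracle_km <- function(times, events) {
  tt <- sort(unique(times[events == 1]))
  s <- 1
  out <- numeric(length(tt))
  for (i in seq_along(tt)) {
    n_i <- sum(times >= tt[i])
    d_i <- sum(events == 1 & times == tt[i])
    s <- s * (1 - d_i / n_i)
    out[i] <- s
  }
  list(event_times = tt, survival = out)
}

# ---- exhaustive search over whole-year bin partitions ----

oracle_partition_best_ratio <- function(year_counts, n_bins) {
  y <- length(year_counts)
  cuts <- utils::combn(y - 1, n_bins - 1)
  best <- Inf
  for (j in seq_len(ncol(cuts))) {
    bounds <- c(0, cuts[, j], y)
    sizes <- vapply(seq_len(n_bins), function(b)
      sum(year_counts[(bounds[b] + 1):bounds[b + 1]]), numeric(1))
    if (any(sizes == 0)) next
    best <- min(best, max(sizes) / min(sizes))
  }
  best
}
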