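# Independent brute-force reference implementations used as oracles.
# These deliberately avoid the package's own code paths (prefix sums,
# boundary index, step-up shortcuts) so that agreement is informative.

naive_segment_mean <- function(values, start, end) {
  mean(values[(start + 1):end])
}

naive_overlaps <- function(accepted, start, end) {
  any(accepted$start < end & accepted$end > start)
}

# O(k^2) greedy selection: repeatedly take the most significant
# remaining candidate, drop everything overlapping it
naive_greedy <- function(pool) {
  ord <- order(pool$p, -abs(pool$z), -pool$n, pool$start)
  pool <- pool[ord, , drop = FALSE]
  acc <- pool[0, , drop = FALSE]
  for (i in seq_len(nrow(pool))) {
    if (!nrow(acc) || !naive_overlaps(acc, pool$start[i], pool$end[i]))
      acc <- rbind(acc, pool[i, , drop = FALSE])
  }
  acc <- acc[order(acc$start), , drop = FALSE]
  rownames(acc) <- NULL
  acc
}

naive_mad_sigma <- function(x) 1.4826 * median(abs(x - median(x)))

naive_confusion_f1 <- function(pred, truth, N) {
  in_set <- function(iv, i) any(iv$start <= i & i < iv$end)
  tp <- fp <- fn <- 0
  for (i in 0:(N - 1)) {
    p <- in_set(pred, i); t <- in_set(truth, i)
    if (p && t) tp <- tp + 1
    else if (p) fp <- fp + 1
    else if (t) fn <- fn + 1
  }
  pr <- if (tp + fp > 0) tp / (tp + fp) else 0
  re <- if (tp + fn > 0) tp / (tp + fn) else 0
  list(precision = pr, recall = re,
       f1 = if (pr + re > 0) 2 * pr * re / (pr + re) else 0)
}

# random disjoint intervals in [0, N)
random_disjoint_intervals <- function(n, N, max_len = 20) {
  starts <- sort(sample.int(N - max_len, n))
  ends <- pmin(starts + sample.int(max_len, n, replace = TRUE), N)
  keep <- c(TRUE, starts[-1] >= cummax(ends[-n]))
  data.frame(start = starts[keep], end = ends[keep])
}

# random candidate pool (intervals may overlap) with synthetic scores
random_pool <- function(k, N) {
  start <- sample.int(N, k, replace = TRUE) - 1
  len <- sample.int(30, k, replace = TRUE)
  end <- pmin(start + len, N)
  ok <- start < end
  start <- start[ok]; end <- end[ok]
  z <- rnorm(length(start), 0, 4)
  data.frame(start = start, end = end, n = end - start,
             mean = z / sqrt(end - start), z = z,
             p = 2 * pnorm(-abs(z)))
}

null_spec <- function(length, seed) {
  simulation_spec(length,
                  data.frame(start = integer(0), end = integer(0),
                             base_mean = numeric(0)),
                  snr = 0, seed = seed)
}

known_noise <- function(sigma = 1, mu0 = 0) {
  estimate_noise(c(0, 0), mu0 = mu0, sigma = sigma)
}
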