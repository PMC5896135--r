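.check_disjoint <- function(iv, what, N) {
  if (!nrow(iv)) return(invisible())
  if (any(iv$start < 0) || any(iv$end > N) || any(iv$start >= iv$end))
    stop(what, " intervals must satisfy 0 <= start < end <= N",
         call. = FALSE)
  o <- order(iv$start)
  if (nrow(iv) > 1L && any(iv$start[o][-1L] < iv$end[o][-nrow(iv)]))
    stop(what, " intervals overlap", call. = FALSE)
  invisible()
}

.coverage <- function(iv, N) {
  cov <- logical(N)
  for (i in seq_len(nrow(iv)))
    cov[(iv$start[i] + 1L):iv$end[i]] <- TRUE
  cov
}

#' Bin-level precision, recall and F1
#'
#' Classification is per bin: a bin is a true positive when covered by
#' both a predicted and a truth interval, a false positive when
#' predicted only, a false negative when truth only. Precision
#' `p = TP / (TP + FP)`, recall `r = TP / (TP + FN)`, and
#' `F1 = 2pr / (p + r)` (0 when `p + r = 0`).
#'
#' @param predicted,truth data frames of disjoint 0-based half-open
#'   intervals (`start`, `end` columns); a `segscan_result` is accepted
#'   for `predicted`.
#' @param N profile length in bins.
#' @return Named list with `precision`, `recall`, `f1`, and the raw
#'   `tp`, `fp`, `fn` counts.
#' @examples
#' f1_score(data.frame(start = 0, end = 10),
#'          data.frame(start = 2, end = 12), N = 20)
#' @export
f1_score <- function(predicted, truth, N) {
  if (inherits(predicted, "segscan_result")) predicted <- predicted$segments
  predicted <- as.data.frame(predicted)
  truth <- as.data.frame(truth)
  .check_disjoint(predicted, "predicted", N)
  .check_disjoint(truth, "truth", N)
  pc <- .coverage(predicted, N)
  tc <- .coverage(truth, N)
  tp <- sum(pc & tc); fp <- sum(pc & !tc); fn <- sum(!pc & tc)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f1 = f1, tp = tp, fp = fp, fn = fn)
}

#' Consensus gold standard from pooled candidate segment sets
#'
#' Builds reference annotations the way consensus benchmarks for
#' copy-number segmentation are constructed: candidate interval sets
#' from any number of sources (methods, parameter settings) are pooled
#' and deduplicated, each unique interval is scored on the profile with
#' the shared Gaussian z-test, and the Benjamini-Hochberg procedure at
#' the given level (0.05 by default) selects the retained set. Retained
#' intervals may overlap — the gold standard is a set of annotated
#' regions, not a segmentation; set `flatten = TRUE` to union-flatten
#' them for bin-level scoring.
#'
#' @param candidate_sets list of interval data frames (`start`, `end`).
#' @param profile the `segscan_profile` the candidates refer to.
#' @param noise a `noise_model`; estimated from the profile if `NULL`.
#' @param alpha B-H adjusted-p cutoff (default 0.05).
#' @param flatten union-flatten overlapping retained intervals.
#' @return Data frame of retained intervals with their scores (columns
#'   as [score_segment()]), sorted by start; flattened output has only
#'   `start`/`end`.
#' @export
consensus_gold_standard <- function(candidate_sets, profile, noise = NULL,
                                    alpha = 0.05, flatten = FALSE) {
  pool <- unique(do.call(rbind, lapply(candidate_sets, function(d)
    data.frame(start = as.numeric(d$start), end = as.numeric(d$end)))))
  if (is.null(pool) || !nrow(pool)) return(.empty_segments())
  if (is.null(noise)) noise <- estimate_noise(profile)
  ps <- build_prefix_sums(profile)
  scored <- score_segment(ps, noise, pool$start, pool$end)
  kept <- bh_filter(scored, alpha, m = nrow(scored))$segments
  kept <- kept[order(kept$start, kept$end), , drop = FALSE]
  rownames(kept) <- NULL
  if (!flatten || !nrow(kept)) return(kept)
  flatten_intervals(kept)
}

#' Union-flatten a set of intervals
#'
#' @param iv interval data frame (`start`, `end`), possibly overlapping.
#' @return Disjoint sorted data frame covering the same bins.
#' @export
flatten_intervals <- function(iv) {
  if (!nrow(iv)) return(data.frame(start = numeric(0), end = numeric(0)))
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  s <- iv$start[1L]; e <- iv$end[1L]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_len(nrow(iv))[-1L]) {
    if (iv$start[i] <= e) e <- max(e, iv$end[i])
    else { out_s <- c(out_s, s); out_e <- c(out_e, e)
           s <- iv$start[i]; e <- iv$end[i] }
  }
  data.frame(start = c(out_s, s), end = c(out_e, e))
}

#' Write a per-profile metrics report
#'
#' @param metrics data frame with one row per profile (e.g. columns
#'   `profile`, `precision`, `recall`, `f1`).
#' @param path output path for the tab-delimited report.
#' @return Invisibly, `path`.
#' @export
write_metrics <- function(metrics, path) {
  utils::write.table(metrics, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
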