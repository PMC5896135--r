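# scalar z for [s, e) without data.frame overhead; refinement loops are
# bin-at-a-time so this is on the hot path
.z_of <- function(ps, noise, s, e) {
  n <- e - s
  ((ps$cumulative[e + 1L] - ps$cumulative[s + 1L]) / n - noise$mu0) *
    sqrt(n) / noise$sigma_hat
}

.key_of <- function(ps, noise, s, e, alternative) {
  .z_score_key(.z_of(ps, noise, s, e), alternative)
}

.as_interval <- function(segment) {
  if (is.data.frame(segment)) c(segment$start[1L], segment$end[1L])
  else as.numeric(segment[1:2])
}

# neighbor-imposed expansion limits for a segment among disjoint others
.neighbor_bounds <- function(s, e, others_start, others_end, N) {
  lower <- 0
  upper <- N
  if (length(others_end)) {
    left <- others_end[others_end <= s]
    if (length(left)) lower <- max(left)
    right <- others_start[others_start >= e]
    if (length(right)) upper <- min(right)
  }
  c(lower, upper)
}

#' Expand a segment while its p-value strictly decreases
#'
#' Grows the left boundary one bin at a time while each grown segment is
#' strictly more significant than the last, then the right boundary
#' likewise. Growth never crosses the profile ends or another accepted
#' segment, so the accepted set stays disjoint.
#'
#' @param segment a `c(start, end)` pair or one-row segment data frame.
#' @param profile the `segscan_profile` (or a precomputed `prefix_sums`
#'   via `ps`).
#' @param noise a `noise_model`.
#' @param others boundaries the expansion must not touch: an
#'   [accepted_index()], a data frame with `start`/`end` columns, or
#'   `NULL`.
#' @param config a [scan_config()] (supplies the test sidedness).
#' @param ps optional precomputed `prefix_sums`.
#' @return One-row data frame with the expanded, re-scored segment.
#' @export
expand_segment <- function(segment, profile, noise, others = NULL,
                           config = scan_config(), ps = NULL) {
  if (is.null(ps)) ps <- build_prefix_sums(profile)
  iv <- .as_interval(segment)
  s <- iv[1L]; e <- iv[2L]
  if (inherits(others, "accepted_index"))
    others <- data.frame(start = others$starts, end = others$ends)
  os <- others$start; oe <- others$end
  if (!is.null(others)) {  # drop the segment itself if present
    self <- which(os == s & oe == e)
    if (length(self)) { os <- os[-self[1L]]; oe <- oe[-self[1L]] }
  }
  b <- .neighbor_bounds(s, e, os, oe, ps$n)
  alt <- config$alternative
  key <- .key_of(ps, noise, s, e, alt)
  while (s - 1L >= b[1L]) {
    k2 <- .key_of(ps, noise, s - 1L, e, alt)
    if (k2 > key) { s <- s - 1L; key <- k2 } else break
  }
  while (e + 1L <= b[2L]) {
    k2 <- .key_of(ps, noise, s, e + 1L, alt)
    if (k2 > key) { e <- e + 1L; key <- k2 } else break
  }
  score_segment(ps, noise, s, e, alternative = alt)
}

#' Shrink a segment while its p-value strictly decreases
#'
#' Repeatedly drops the boundary bin (left or right, whichever removal
#' lowers the p-value most) while the shrunken segment is strictly more
#' significant, never below length 1.
#'
#' @inheritParams expand_segment
#' @return One-row data frame with the shrunken, re-scored segment.
#' @export
shrink_segment <- function(segment, profile, noise,
                           config = scan_config(), ps = NULL) {
  if (is.null(ps)) ps <- build_prefix_sums(profile)
  iv <- .as_interval(segment)
  s <- iv[1L]; e <- iv[2L]
  alt <- config$alternative
  key <- .key_of(ps, noise, s, e, alt)
  while (e - s > 1L) {
    kL <- .key_of(ps, noise, s + 1L, e, alt)
    kR <- .key_of(ps, noise, s, e - 1L, alt)
    if (max(kL, kR) > key) {
      if (kL >= kR) s <- s + 1L else e <- e - 1L
      key <- max(kL, kR)
    } else break
  }
  score_segment(ps, noise, s, e, alternative = alt)
}

#' Refine accepted segments by expansion and shrinkage
#'
#' Processes segments in significance order (most significant first, so
#' the strongest segments claim contested territory) and, for each,
#' loops expand-left, expand-right, shrink until a fixed point. Every
#' single-bin move strictly increases significance, so the loop
#' terminates and no state repeats; disjointness is preserved because
#' expansion is bounded by the current boundaries of the other segments.
#'
#' @param segments disjoint segment data frame from [select_segments()].
#' @param profile the `segscan_profile`.
#' @param noise a `noise_model`.
#' @param config a [scan_config()].
#' @param ps optional precomputed `prefix_sums`.
#' @return Refined, re-scored, disjoint segment data frame sorted by
#'   start.
#' @export
refine_segments <- function(segments, profile, noise,
                            config = scan_config(), ps = NULL) {
  if (is.null(ps)) ps <- build_prefix_sums(profile)
  if (nrow(segments) == 0L) return(segments)
  segs <- segments[order(segments$start), , drop = FALSE]
  rownames(segs) <- NULL
  alt <- config$alternative
  for (j in .pool_order(segs, alt)) {
    others <- segs[-j, , drop = FALSE]
    cur <- segs[j, , drop = FALSE]
    repeat {
      before <- c(cur$start, cur$end)
      cur <- expand_segment(cur, profile, noise, others, config, ps)
      cur <- shrink_segment(cur, profile, noise, config, ps)
      if (cur$start == before[1L] && cur$end == before[2L]) break
    }
    segs[j, ] <- cur
  }
  segs <- segs[order(segs$start), , drop = FALSE]
  rownames(segs) <- NULL
  segs
}

#' Iteratively merge adjacent significant segments
#'
#' Walks the sorted segment list and merges an adjacent pair whenever
#' the gap between them is at most `max_gap` bins and the union span
#' (left boundary of the first to right boundary of the second,
#' including any gap bins) is strictly more significant than both
#' members. A freshly merged segment is immediately re-tested against
#' its neighbors; passes repeat until no merge fires, so the result is
#' a fixed point (running the operation twice equals running it once).
#'
#' @param segments disjoint sorted segment data frame.
#' @param profile the `segscan_profile`.
#' @param noise a `noise_model`.
#' @param max_gap largest bin gap across which merging is considered.
#' @param config a [scan_config()]; its `merge_same_sign_only` flag
#'   restricts merging to segments deviating from `mu0` in the same
#'   direction.
#' @param ps optional precomputed `prefix_sums`.
#' @return Merged, re-scored, disjoint segment data frame.
#' @export
merge_segments <- function(segments, profile, noise,
                           max_gap = config$max_merge_gap,
                           config = scan_config(), ps = NULL) {
  if (is.null(ps)) ps <- build_prefix_sums(profile)
  if (nrow(segments) <= 1L) return(segments)
  segs <- segments[order(segments$start), , drop = FALSE]
  rownames(segs) <- NULL
  if (any(segs$start[-1L] < segs$end[-nrow(segs)]))
    stop("merge_segments requires disjoint input segments", call. = FALSE)
  alt <- config$alternative
  repeat {
    merged_any <- FALSE
    i <- 1L
    while (i < nrow(segs)) {
      gap <- segs$start[i + 1L] - segs$end[i]
      sign_ok <- !config$merge_same_sign_only ||
        sign(segs$mean[i] - noise$mu0) == sign(segs$mean[i + 1L] - noise$mu0)
      if (gap <= max_gap && sign_ok) {
        u <- score_segment(ps, noise, segs$start[i], segs$end[i + 1L],
                           alternative = alt)
        k_pair <- max(.z_score_key(segs$z[i], alt),
                      .z_score_key(segs$z[i + 1L], alt))
        if (.z_score_key(u$z, alt) > k_pair) {
          segs[i, ] <- u
          segs <- segs[-(i + 1L), , drop = FALSE]
          rownames(segs) <- NULL
          merged_any <- TRUE
          i <- max(1L, i - 1L)  # re-test the new segment with its left neighbor
          next
        }
      }
      i <- i + 1L
    }
    if (!merged_any) break
  }
  segs
}
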