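#' Boundary index over accepted segments
#'
#' An ordered store of the boundaries of accepted (pairwise disjoint)
#' segments supporting logarithmic-time overlap queries via binary search
#' on the sorted start positions. This plays the role of the boundary
#' tree in the coupled ordered-structure selection scheme: the candidate
#' pool supplies entries in significance order, and the boundary index
#' answers "does this interval touch anything already accepted?".
#'
#' @return An empty `accepted_index` (an environment holding parallel
#'   sorted vectors of starts and ends).
#' @export
accepted_index <- function() {
  idx <- new.env(parent = emptyenv())
  idx$starts <- numeric(0)
  idx$ends <- numeric(0)
  class(idx) <- "accepted_index"
  idx
}

#' Query overlap against accepted segments
#'
#' @param index an [accepted_index()].
#' @param start,end half-open query interval, `start < end`.
#' @return `TRUE` iff `[start, end)` intersects any accepted segment.
#'   Half-open adjacency (query starting exactly at an accepted end) is
#'   not an overlap.
#' @export
overlaps_accepted <- function(index, start, end) {
  if (start >= end) stop("need start < end", call. = FALSE)
  k <- findInterval(start, index$starts)
  # segment whose start is the greatest <= query start
  if (k >= 1L && index$ends[k] > start) return(TRUE)
  # next segment to the right
  if (k < length(index$starts) && index$starts[k + 1L] < end) return(TRUE)
  FALSE
}

#' Insert a segment into the boundary index
#'
#' @param index an [accepted_index()].
#' @param start,end half-open interval; must not overlap any accepted
#'   segment.
#' @return The index, invisibly.
#' @export
insert_accepted <- function(index, start, end) {
  if (overlaps_accepted(index, start, end))
    stop("segment overlaps an accepted segment", call. = FALSE)
  k <- findInterval(start, index$starts)
  index$starts <- append(index$starts, start, after = k)
  index$ends <- append(index$ends, end, after = k)
  invisible(index)
}

# deterministic significance order for a candidate pool: p ascending,
# then |z| descending (breaks ties among underflowed p-values), then
# longer first, then smaller start
.pool_order <- function(cand, alternative = "two.sided") {
  order(cand$p, -.z_score_key(cand$z, alternative), -cand$n, cand$start)
}

#' Greedy selection of non-overlapping segments
#'
#' Orders the candidate pool by significance (p ascending; ties broken by
#' larger |z|, then longer length, then smaller start — a deterministic
#' total order) and walks it once, accepting each candidate iff it does
#' not overlap any previously accepted segment. The result is exactly
#' the greedy-by-p-value independent set: the most significant segment
#' is kept and anything overlapping a more significant acceptance is
#' discarded.
#'
#' @param pool data frame of candidates from [scan_candidates()] (the
#'   input order is irrelevant; the significance order is re-derived).
#' @param alternative test sidedness used for tie-breaking on `z`.
#' @return data frame of accepted segments, sorted by `start`.
#' @export
select_segments <- function(pool, alternative = "two.sided") {
  if (is.null(pool) || nrow(pool) == 0L)
    return(.empty_segments())
  ord <- .pool_order(pool, alternative)
  idx <- accepted_index()
  keep <- logical(nrow(pool))
  for (i in ord) {
    if (!overlaps_accepted(idx, pool$start[i], pool$end[i])) {
      insert_accepted(idx, pool$start[i], pool$end[i])
      keep[i] <- TRUE
    }
  }
  res <- pool[keep, , drop = FALSE]
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.empty_segments <- function() {
  data.frame(start = integer(0), end = integer(0), n = integer(0),
             mean = numeric(0), z = numeric(0), p = numeric(0))
}
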