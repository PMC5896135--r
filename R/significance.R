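#' Benjamini-Hochberg filter over segment p-values
#'
#' Standard step-up procedure: sort the p-values ascending, find the
#' largest `k` with `p(k) <= k * alpha / m`, and retain every segment
#' with `p <= p(k)`. The denominator `m` may exceed the number of
#' segments supplied — e.g. the number of windows actually tested during
#' the scan — in which case the filter accounts for the tests whose
#' p-values were discarded along the way.
#'
#' @param segments segment data frame with a `p` column (may be empty).
#' @param alpha target false discovery rate, in (0, 1].
#' @param m number of tests; defaults to `nrow(segments)` and must be at
#'   least that.
#' @return List with `segments` (the retained rows, input order
#'   preserved) and `bh_cutoff` (the largest retained p-value, or 0 when
#'   nothing is retained).
#' @examples
#' s <- data.frame(p = c(0.01, 0.02, 0.03, 0.04))
#' bh_filter(s, alpha = 0.05)$bh_cutoff  # 0.04: all retained
#' @export
bh_filter <- function(segments, alpha, m = nrow(segments)) {
  if (!(alpha > 0 && alpha <= 1))
    stop("alpha must be in (0, 1]", call. = FALSE)
  k_seg <- nrow(segments)
  if (k_seg == 0L) return(list(segments = segments, bh_cutoff = 0))
  if (m < k_seg)
    stop("m must be at least the number of segments", call. = FALSE)
  p <- sort(segments$p)
  k <- which(p <= seq_along(p) * alpha / m)
  if (!length(k))
    return(list(segments = segments[0, , drop = FALSE], bh_cutoff = 0))
  cutoff <- p[max(k)]
  list(segments = segments[segments$p <= cutoff, , drop = FALSE],
       bh_cutoff = cutoff)
}

#' Biological-cutoff tier membership
#'
#' A segment passes tier `bc` iff its height exceeds `bc` data SDs:
#' `|mean - mu0| > bc * sigma_hat`, strictly, regardless of segment
#' length. Tiers are nested by construction: passing 3.0 implies passing
#' 2.0, 1.5 and 1.0.
#'
#' @param segments segment data frame with a `mean` column.
#' @param noise a `noise_model`.
#' @param tiers strictly increasing positive cutoffs (default
#'   `c(1, 1.5, 2, 3)`).
#' @return Logical matrix, one row per segment, one column per tier
#'   (columns named `bc<tier>`).
#' @export
apply_biological_cutoff <- function(segments, noise,
                                    tiers = c(1, 1.5, 2, 3)) {
  if (length(tiers) && any(diff(tiers) <= 0))
    stop("tiers must be strictly increasing", call. = FALSE)
  height <- abs(segments$mean - noise$mu0)
  out <- vapply(tiers, function(bc) height > bc * noise$sigma_hat,
                logical(nrow(segments)))
  out <- matrix(out, nrow = nrow(segments), ncol = length(tiers))
  colnames(out) <- paste0("bc", format(tiers, trim = TRUE))
  out
}
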