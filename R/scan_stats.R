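#' Robust noise estimation
#'
#' Estimates the background noise SD from the whole profile with the
#' median absolute deviation, MAD = median(|x_i - median(x)|), scaled by
#' the normal-consistency constant 1.4826 so that `sigma_hat` estimates
#' the SD of the Gaussian background. The estimate is global: it is
#' computed once per profile and shared by every segment test, which is
#' what makes the length-1 z-test consistent with longer segments.
#'
#' @param profile a `segscan_profile` (or plain numeric vector).
#' @param mu0 null (background) mean.
#' @param sigma optional known noise SD; when supplied, MAD estimation is
#'   skipped. Required for degenerate profiles whose MAD is 0.
#' @return A `noise_model`: list with `sigma_hat` and `mu0`.
#' @examples
#' estimate_noise(c(1, 2, 3, 4, 100))$sigma_hat  # 1.4826
#' @export
estimate_noise <- function(profile, mu0 = 0, sigma = NULL) {
  x <- if (inherits(profile, "segscan_profile")) profile$values else
    as.numeric(profile)
  if (!is.null(sigma)) {
    if (!(sigma > 0)) stop("sigma must be positive", call. = FALSE)
    return(structure(list(sigma_hat = as.numeric(sigma),
                          mu0 = as.numeric(mu0)), class = "noise_model"))
  }
  if (length(x) < 2L)
    stop("need at least 2 values to estimate noise", call. = FALSE)
  s <- stats::mad(x)  # 1.4826 * median(|x - median(x)|)
  if (s == 0)
    stop("MAD of the profile is 0 (more than half the values are ",
         "identical); supply the noise SD explicitly via `sigma`",
         call. = FALSE)
  structure(list(sigma_hat = s, mu0 = as.numeric(mu0)),
            class = "noise_model")
}

#' Running sums for constant-time segment means
#'
#' Builds cumulative sums (and sums of squares, kept for diagnostics) so
#' that the mean of any segment `[i, j)` is retrievable in constant time
#' as `(cumulative[j+1] - cumulative[i+1]) / (j - i)`. This is the
#' dynamic-programming backbone of the scan: the running sum of a longer
#' window extends that of a shorter one instead of being recomputed.
#'
#' @param profile a `segscan_profile` or numeric vector.
#' @return A `prefix_sums` object: list with `cumulative` and
#'   `cumulative_sq`, both of length N+1 with leading 0, and `n`.
#' @export
build_prefix_sums <- function(profile) {
  x <- if (inherits(profile, "segscan_profile")) profile$values else
    as.numeric(profile)
  structure(list(cumulative = c(0, cumsum(x)),
                 cumulative_sq = c(0, cumsum(x * x)),
                 n = length(x)),
            class = "prefix_sums")
}

#' Geometric ladder of scan window lengths
#'
#' Window lengths are the deduplicated ceilings of `w_min * rho^i`,
#' generated while the un-rounded length stays within `w_max`, each
#' capped at the profile length. Scanning a length-`W` ladder rung uses
#' overlapping windows spaced `ceiling(W/5)` bins apart (minimum 1).
#'
#' @param config a [scan_config()].
#' @param N profile length in bins.
#' @return data frame with columns `length` (ascending) and `step`.
#' @examples
#' window_ladder(scan_config(w_min = 1, w_max = 4, rho = 1.1), N = 100)
#' @export
window_ladder <- function(config, N) {
  stopifnot(N >= 1)
  w <- as.numeric(config$w_min)
  raw <- numeric(0)
  while (w <= config$w_max) {
    raw <- c(raw, w)
    w <- w * config$rho
  }
  len <- sort(unique(pmin(as.integer(ceiling(raw)), as.integer(N))))
  data.frame(length = len, step = pmax(1L, as.integer(ceiling(len / 5))))
}

#' Score a segment with the robust z-test
#'
#' With the noise SD treated as known (the global MAD estimate), the
#' one-sample test statistic is `z = (mean - mu0) * sqrt(n) / sigma_hat`,
#' which evaluates segments of any length down to a single bin under the
#' same model. The default p-value is the two-sided normal tail
#' `2 * (1 - Phi(|z|))`, so enriched and depleted segments are detected
#' in one pass.
#'
#' @param ps a `prefix_sums` object.
#' @param noise a `noise_model`.
#' @param start,end 0-based half-open bin interval(s); vectorized.
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @return data frame with columns `start`, `end`, `n`, `mean`, `z`, `p`.
#' @examples
#' ps <- build_prefix_sums(c(3, 0, 0))
#' noise <- estimate_noise(sigma = 1, c(0, 0, 0), mu0 = 0)
#' score_segment(ps, noise, 0, 1)$p  # ~0.0027
#' @export
score_segment <- function(ps, noise, start, end,
                          alternative = "two.sided") {
  if (length(start) != length(end))
    stop("start and end must have equal length", call. = FALSE)
  if (any(start < 0L) || any(end > ps$n) || any(start >= end))
    stop("invalid segment: need 0 <= start < end <= N", call. = FALSE)
  n <- end - start
  m <- (ps$cumulative[end + 1L] - ps$cumulative[start + 1L]) / n
  z <- (m - noise$mu0) * sqrt(n) / noise$sigma_hat
  p <- switch(alternative,
    two.sided = 2 * stats::pnorm(-abs(z)),
    greater = stats::pnorm(z, lower.tail = FALSE),
    less = stats::pnorm(z),
    stop("unknown alternative: ", alternative, call. = FALSE))
  # p-values beyond double underflow are clamped to the smallest positive
  # double; ranking among them falls back on |z| downstream
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  data.frame(start = start, end = end, n = n, mean = m, z = z, p = p)
}

# signed score whose increase always means a smaller p-value, immune to
# p underflow; used by refinement and merging comparisons
.z_score_key <- function(z, alternative) {
  switch(alternative,
         two.sided = abs(z),
         greater = z,
         less = -z)
}

#' Scan a profile for candidate segments
#'
#' Slides every ladder window across the profile (windows start at
#' multiples of the step, plus one flush window against the right edge so
#' trailing bins are always scanned), scores each window with
#' [score_segment()], and keeps windows with `p <= p_s`.
#'
#' @param profile a `segscan_profile`.
#' @param config a [scan_config()].
#' @param noise a `noise_model`.
#' @param ps optional precomputed `prefix_sums`.
#' @return data frame of candidates (columns as [score_segment()]), with
#'   attribute `n_tests` giving the total number of windows scored.
#' @export
scan_candidates <- function(profile, config, noise,
                            ps = build_prefix_sums(profile)) {
  N <- ps$n
  ladder <- window_ladder(config, N)
  out <- vector("list", nrow(ladder))
  n_tests <- 0
  for (k in seq_len(nrow(ladder))) {
    W <- ladder$length[k]
    starts <- seq.int(0L, N - W, by = ladder$step[k])
    if (starts[length(starts)] != N - W) starts <- c(starts, N - W)
    sc <- score_segment(ps, noise, starts, starts + W,
                        alternative = config$alternative)
    n_tests <- n_tests + nrow(sc)
    out[[k]] <- sc[sc$p <= config$p_s, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_tests") <- n_tests
  res
}
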