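#' Segment a signal profile end to end
#'
#' Runs the full pipeline on one profile: robust noise estimation
#' (global MAD) -> prefix sums -> multi-scale window scan -> greedy
#' selection of non-overlapping candidates by p-value -> boundary
#' refinement (expansion/shrinkage) -> iterative merging of adjacent
#' segments -> Benjamini-Hochberg FDR filter -> biological-cutoff tiers.
#'
#' @param profile a `segscan_profile` (or numeric vector, coerced).
#' @param config a [scan_config()].
#' @param noise optional `noise_model`; estimated from the profile by
#'   default. Supply one (via [estimate_noise()] with explicit `sigma`)
#'   for degenerate profiles or when the noise SD is known.
#' @param verbose log stage-by-stage counts to stderr.
#' @return A `segscan_result`: list with `segments` (disjoint, sorted,
#'   re-scored data frame), `tier_membership` (logical matrix from
#'   [apply_biological_cutoff()]), `bh_cutoff`, `n_tests` (windows
#'   scored), `noise`, and `config`.
#' @examples
#' sim <- simulate_profile(short_profile_spec(snr = 2, seed = 1))
#' res <- segment_profile(sim$profile)
#' nrow(res$segments)
#' @export
segment_profile <- function(profile, config = scan_config(), noise = NULL,
                            verbose = FALSE) {
  if (!inherits(profile, "segscan_profile"))
    profile <- signal_profile(profile)
  if (is.null(noise))
    noise <- estimate_noise(profile, mu0 = config$mu0)
  say <- function(...) if (verbose) message(sprintf(...))
  ps <- build_prefix_sums(profile)
  cand <- scan_candidates(profile, config, noise, ps)
  n_tests <- attr(cand, "n_tests")
  say("scan: %d windows scored, %d candidates at p_s = %g",
      n_tests, nrow(cand), config$p_s)
  segs <- select_segments(cand, config$alternative)
  say("selection: %d non-overlapping segments", nrow(segs))
  segs <- refine_segments(segs, profile, noise, config, ps)
  segs <- merge_segments(segs, profile, noise, config$max_merge_gap,
                         config, ps)
  say("refine+merge: %d segments", nrow(segs))
  m <- switch(config$bh_denominator,
              scanned = max(n_tests, nrow(segs)),
              segments = nrow(segs))
  bh <- bh_filter(segs, config$fdr_alpha, m)
  segs <- bh$segments
  rownames(segs) <- NULL
  say("B-H filter: %d segments at alpha = %g (m = %d, cutoff = %.3g)",
      nrow(segs), config$fdr_alpha, m, bh$bh_cutoff)
  tiers <- apply_biological_cutoff(segs, noise, config$bc_tiers)
  if (verbose)
    for (j in seq_along(config$bc_tiers))
      say("  bc %.1f: %d segments", config$bc_tiers[j], sum(tiers[, j]))
  structure(
    list(segments = segs, tier_membership = tiers,
         bh_cutoff = bh$bh_cutoff, n_tests = n_tests, noise = noise,
         config = config, profile_name = profile$name),
    class = "segscan_result"
  )
}

#' @export
print.segscan_result <- function(x, ...) {
  cat(sprintf("<segscan_result%s: %d segments>\n",
              if (nzchar(x$profile_name))
                paste0(" '", x$profile_name, "'") else "",
              nrow(x$segments)))
  cat(sprintf("  sigma_hat = %.4g, mu0 = %g, %d windows scored, B-H cutoff %.3g\n",
              x$noise$sigma_hat, x$noise$mu0, x$n_tests, x$bh_cutoff))
  if (nrow(x$segments)) {
    counts <- colSums(x$tier_membership)
    cat("  tier counts:",
        paste(sprintf("%s=%d", colnames(x$tier_membership), counts),
              collapse = ", "), "\n")
    print(utils::head(x$segments, 10))
    if (nrow(x$segments) > 10) cat("  ...\n")
  }
  invisible(x)
}

#' Segments of a result as a plain data frame
#'
#' @param x a `segscan_result`.
#' @param bc optional biological-cutoff tier; only segments passing it
#'   are returned.
#' @param ... unused.
#' @return Segment data frame.
#' @export
as.data.frame.segscan_result <- function(x, bc = NULL, ...) {
  if (is.null(bc)) return(x$segments)
  col <- paste0("bc", format(bc, trim = TRUE))
  if (!col %in% colnames(x$tier_membership))
    stop("no such tier: ", bc, call. = FALSE)
  x$segments[x$tier_membership[, col], , drop = FALSE]
}
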