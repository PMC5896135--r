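#' Construct a signal profile
#'
#' A profile is an ordered sequence of per-bin signal values along (part of)
#' a genome, optionally anchored to genomic coordinates by a chromosome
#' label, the genomic start of the first bin, and a fixed bin width. Values
#' may be negative (e.g. light-minus-heavy differential nuclease-sensitivity
#' tracks, aCGH log-ratios). Bin index `i` (0-based) maps to the half-open
#' genomic interval `[bin_start + i * bin_width, bin_start + (i+1) * bin_width)`.
#'
#' @param values numeric vector of per-bin signal values; must be finite.
#' @param chrom optional chromosome label (single string).
#' @param bin_start integer genomic start (bp) of bin 0. Default 0.
#' @param bin_width positive integer bin width in bp. Default 1.
#' @param name free-text profile name.
#' @return An object of class `segscan_profile`.
#' @examples
#' p <- signal_profile(c(0.5, -1.2, 3.0), chrom = "chr1", bin_width = 20)
#' length(p$values)
#' @export
signal_profile <- function(values, chrom = NULL, bin_start = 0L,
                           bin_width = 1L, name = "") {
  values <- as.numeric(values)
  if (length(values) < 1L)
    stop("profile must contain at least one value", call. = FALSE)
  if (!all(is.finite(values)))
    stop("profile values must be finite; remove or impute missing bins ",
         "before construction (see `na_action` in read_profile())",
         call. = FALSE)
  if (!is.null(chrom)) chrom <- as.character(chrom)[1L]
  bin_start <- as.integer(bin_start)
  bin_width <- as.integer(bin_width)
  if (is.na(bin_width) || bin_width < 1L)
    stop("bin_width must be a positive integer", call. = FALSE)
  structure(
    list(values = values, chrom = chrom, bin_start = bin_start,
         bin_width = bin_width, name = as.character(name)[1L]),
    class = "segscan_profile"
  )
}

#' @export
print.segscan_profile <- function(x, ...) {
  cat(sprintf("<segscan_profile%s: %d bins%s, bin width %d bp>\n",
              if (nzchar(x$name)) paste0(" '", x$name, "'") else "",
              length(x$values),
              if (!is.null(x$chrom)) paste0(" on ", x$chrom) else "",
              x$bin_width))
  invisible(x)
}

#' @export
length.segscan_profile <- function(x) length(x$values)

#' Scan configuration
#'
#' Bundles every tunable of the segmentation scan. Defaults follow the
#' published parameterization of the scan: window lengths from 1 to 300
#' bins growing by power factor 1.1, candidate pre-filter p-value 0.001,
#' FDR level 0.01, biological-cutoff tiers 1.0/1.5/2.0/3.0 data SDs, and
#' merging restricted to strictly adjacent segments (gap 0).
#'
#' @param w_min minimum scan window length in bins (default 1).
#' @param w_max maximum scan window length in bins (default 300).
#' @param rho power factor: multiplicative growth rate of the window-length
#'   ladder; must be > 1 (default 1.1).
#' @param p_s pre-filter threshold: only windows with p-value <= `p_s` enter
#'   the candidate pool (default 0.001, the per-test Bonferroni level for
#'   100 simultaneous tests at family-wise level 0.1).
#' @param fdr_alpha Benjamini-Hochberg false discovery rate (default 0.01).
#' @param bc_tiers strictly increasing biological-cutoff tiers, in units of
#'   the robust data SD (default `c(1, 1.5, 2, 3)`).
#' @param max_merge_gap largest gap, in bins, across which two adjacent
#'   segments may merge (default 0: strictly consecutive segments only).
#' @param mu0 background (null) mean (default 0).
#' @param alternative sidedness of the z-test: `"two.sided"` (default;
#'   detects both enriched and depleted segments), `"greater"`, or `"less"`.
#' @param bh_denominator what the Benjamini-Hochberg `m` counts:
#'   `"scanned"` (default) uses the number of windows actually tested
#'   during the scan, so the FDR level refers to the family of tests
#'   performed; `"segments"` uses only the number of final segments
#'   entering the filter.
#' @param merge_same_sign_only if `TRUE`, only segments whose means deviate
#'   from `mu0` in the same direction may merge (useful for signed
#'   difference tracks).
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(w_min = 1L, w_max = 300L, rho = 1.1, p_s = 0.001,
                        fdr_alpha = 0.01, bc_tiers = c(1, 1.5, 2, 3),
                        max_merge_gap = 0L, mu0 = 0,
                        alternative = c("two.sided", "greater", "less"),
                        bh_denominator = c("scanned", "segments"),
                        merge_same_sign_only = FALSE) {
  w_min <- as.integer(w_min); w_max <- as.integer(w_max)
  if (w_min < 1L) stop("w_min must be >= 1", call. = FALSE)
  if (w_min > w_max) stop("w_min must be <= w_max", call. = FALSE)
  if (!(rho > 1)) stop("rho must be > 1", call. = FALSE)
  if (!(p_s > 0 && p_s <= 1)) stop("p_s must be in (0, 1]", call. = FALSE)
  if (!(fdr_alpha > 0 && fdr_alpha <= 1))
    stop("fdr_alpha must be in (0, 1]", call. = FALSE)
  if (length(bc_tiers) && any(diff(bc_tiers) <= 0))
    stop("bc_tiers must be strictly increasing", call. = FALSE)
  if (any(bc_tiers <= 0)) stop("bc_tiers must be positive", call. = FALSE)
  max_merge_gap <- as.integer(max_merge_gap)
  if (max_merge_gap < 0L) stop("max_merge_gap must be >= 0", call. = FALSE)
  structure(
    list(w_min = w_min, w_max = w_max, rho = rho, p_s = p_s,
         fdr_alpha = fdr_alpha, bc_tiers = as.numeric(bc_tiers),
         max_merge_gap = max_merge_gap, mu0 = as.numeric(mu0),
         alternative = match.arg(alternative),
         bh_denominator = match.arg(bh_denominator),
         merge_same_sign_only = isTRUE(merge_same_sign_only)),
    class = "scan_config"
  )
}

#' @export
print.scan_config <- function(x, ...) {
  cat("<scan_config>\n")
  cat(sprintf("  windows %d..%d bins, power factor %g; p_s = %g\n",
              x$w_min, x$w_max, x$rho, x$p_s))
  cat(sprintf("  FDR alpha = %g (m = %s), bc tiers = %s, max merge gap = %d\n",
              x$fdr_alpha, x$bh_denominator,
              paste(x$bc_tiers, collapse = "/"), x$max_merge_gap))
  cat(sprintf("  mu0 = %g, test = %s\n", x$mu0, x$alternative))
  invisible(x)
}
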