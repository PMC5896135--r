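#' Specification of a synthetic profile
#'
#' Describes a simulated signal profile: Gaussian background with mean 0
#' and SD `noise_sd`, plus planted disjoint segments whose bins are
#' drawn from `N(base_mean * snr, noise_sd^2)`. The signal-to-noise
#' ratio is the planted mean in units of the noise SD, applied as a
#' multiplier on the base means with the noise SD fixed at 1, so
#' `snr = 2` doubles every planted mean relative to the unit-SD
#' background.
#'
#' @param length profile length in bins.
#' @param planted data frame with columns `start`, `end` (0-based
#'   half-open bin intervals, pairwise disjoint) and `base_mean`.
#' @param snr signal-to-noise ratio (>= 0; 0 gives pure noise).
#' @param noise_sd background noise SD (default 1).
#' @param seed RNG seed; fixed seed gives a byte-identical profile.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(length, planted, snr = 1, noise_sd = 1,
                            seed = 1L) {
  length <- as.integer(length)
  stopifnot(length >= 1L, snr >= 0, noise_sd > 0)
  planted <- as.data.frame(planted)
  if (nrow(planted)) {
    stopifnot(all(c("start", "end", "base_mean") %in% names(planted)))
    planted <- planted[order(planted$start), , drop = FALSE]
    rownames(planted) <- NULL
    if (any(planted$start < 0) || any(planted$end > length) ||
        any(planted$start >= planted$end))
      stop("planted intervals must satisfy 0 <= start < end <= length",
           call. = FALSE)
    if (nrow(planted) > 1L &&
        any(planted$start[-1L] < planted$end[-nrow(planted)]))
      stop("planted intervals must be pairwise disjoint", call. = FALSE)
  }
  structure(list(length = length, planted = planted, snr = snr,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "simulation_spec")
}

# default short-profile design: length 5000 with six planted segments.
# The base means are the six published example means; locations and
# lengths are implementation-chosen (the originals are not printed),
# spanning a single bin up to several hundred bins so that single-point
# and long-segment detection are both exercised, with the two largest
# means on the two longest segments.
.short_planted <- function() {
  data.frame(
    start = c(500L, 1200L, 2000L, 2800L, 3700L, 4400L),
    end = c(600L, 1400L, 2150L, 3100L, 3750L, 4401L),
    base_mean = c(0.72, 0.83, 0.76, 0.9, 0.7, 0.6)
  )
}

# default long-profile design: length 100,000 with seven sparse planted
# segments (~1.5% of bins carry signal), the sparse-signal regime the
# multi-scale scan is built for
.long_planted <- function() {
  data.frame(
    start = c(5000L, 15000L, 30000L, 45000L, 60000L, 75000L, 90000L),
    end = c(5100L, 15200L, 30150L, 45300L, 60050L, 75400L, 90250L),
    base_mean = c(0.72, 0.83, 0.76, 0.9, 0.7, 0.6, 0.8)
  )
}

#' Default short simulated profile (length 5000, six planted segments)
#'
#' @param snr signal-to-noise ratio.
#' @param seed RNG seed.
#' @return A `simulation_spec`.
#' @export
short_profile_spec <- function(snr = 1, seed = 1L) {
  simulation_spec(5000L, .short_planted(), snr = snr, seed = seed)
}

#' Default long simulated profile (length 100,000, seven planted segments)
#'
#' @inheritParams short_profile_spec
#' @return A `simulation_spec`.
#' @export
long_profile_spec <- function(snr = 1, seed = 1L) {
  simulation_spec(100000L, .long_planted(), snr = snr, seed = seed)
}

#' Generate a synthetic profile with ground truth
#'
#' Background bins are drawn from `N(0, noise_sd^2)` and each planted
#' interval's bins from `N(base_mean * snr, noise_sd^2)`. Ground-truth
#' intervals are returned in the same 0-based half-open bin convention
#' as segment calls, so evaluation needs no re-mapping. The caller's RNG
#' state is left untouched.
#'
#' @param spec a [simulation_spec()].
#' @return A `simulated_profile`: list with `profile`
#'   (a `segscan_profile`) and `truth` (the planted intervals with their
#'   realized means `base_mean * snr`).
#' @export
simulate_profile <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  values <- stats::rnorm(spec$length, 0, spec$noise_sd)
  for (i in seq_len(nrow(spec$planted))) {
    s <- spec$planted$start[i]; e <- spec$planted$end[i]
    values[(s + 1L):e] <- stats::rnorm(e - s,
                                       spec$planted$base_mean[i] * spec$snr,
                                       spec$noise_sd)
  }
  truth <- spec$planted
  if (nrow(truth)) truth$mean <- truth$base_mean * spec$snr
  structure(
    list(profile = signal_profile(values,
                                  name = sprintf("sim_n%d_snr%g_seed%d",
                                                 spec$length, spec$snr,
                                                 spec$seed)),
         truth = truth, spec = spec),
    class = "simulated_profile"
  )
}

#' Generate the default long synthetic profile
#'
#' Convenience wrapper: [simulate_profile()] on [long_profile_spec()].
#'
#' @inheritParams short_profile_spec
#' @return A `simulated_profile`.
#' @export
simulate_long_profile <- function(snr = 1, seed = 1L) {
  simulate_profile(long_profile_spec(snr = snr, seed = seed))
}
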