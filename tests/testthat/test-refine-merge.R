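noise1 <- known_noise(sigma = 1)

test_that("expansion absorbs adjacent signal and refuses null bins", {
  vals <- rep(0, 50)
  vals[10:20] <- 5  # bins 9..20 in 0-based terms: signal on [9, 20)
  prof <- signal_profile(vals)

  # accepted [10,20): bin 9 carries the same mean, so growing absorbs it
  ex <- expand_segment(c(10, 20), prof, noise1)
  expect_equal(c(ex$start, ex$end), c(9, 20))
  expect_lt(ex$p, score_segment(build_prefix_sums(prof), noise1, 10, 20)$p)

  # flat-zero neighbors: adding a null bin raises p, so nothing moves
  vals2 <- rep(0, 50); vals2[11:20] <- 5
  ex2 <- expand_segment(c(10, 20), signal_profile(vals2), noise1)
  expect_equal(c(ex2$start, ex2$end), c(10, 20))
})

test_that("expansion stops at an accepted neighbor even when p would improve", {
  vals <- rep(0, 50)
  vals[9:20] <- 5  # signal on [8, 20)
  prof <- signal_profile(vals)
  others <- data.frame(start = 8, end = 9)
  ex <- expand_segment(c(10, 20), prof, noise1, others = others)
  expect_equal(ex$start, 9)  # bin 8 is claimed; growth stops at its end
})

test_that("shrinkage trims null boundary bins and respects length 1", {
  vals <- rep(0, 50)
  vals[11:20] <- 5  # signal on [10, 20)
  prof <- signal_profile(vals)
  sh <- shrink_segment(c(9, 21), prof, noise1)
  expect_equal(c(sh$start, sh$end), c(10, 20))

  # homogeneous segment: no improving move
  vals3 <- rep(5, 30)
  sh2 <- shrink_segment(c(5, 15), signal_profile(vals3), noise1)
  expect_equal(c(sh2$start, sh2$end), c(5, 15))

  # length-1 segments cannot shrink to empty
  sh3 <- shrink_segment(c(10, 11), prof, noise1)
  expect_equal(c(sh3$start, sh3$end), c(10, 11))
})

test_that("refinement recovers exact boundaries of a clean high-SNR segment", {
  vals <- rep(0, 400)
  vals[101:200] <- 5  # planted [100, 200), background exactly at mu0
  prof <- signal_profile(vals)
  segs <- data.frame(start = 95, end = 190, n = 95,
                     mean = naive_segment_mean(vals, 95, 190), z = 0, p = 1)
  segs$z <- segs$mean * sqrt(95); segs$p <- 2 * pnorm(-abs(segs$z))
  out <- refine_segments(segs, prof, noise1)
  expect_equal(c(out$start, out$end), c(100, 200))
})

test_that("merging follows the union-significance rule", {
  ps_of <- function(vals) build_prefix_sums(vals)
  mkseg <- function(vals, s, e)
    score_segment(ps_of(vals), noise1, s, e)

  # two adjacent n=10 segments of mean 1: union z = sqrt(20) beats sqrt(10)
  vals <- c(rep(1, 20), rep(0, 10))
  segs <- rbind(mkseg(vals, 0, 10), mkseg(vals, 10, 20))
  out <- merge_segments(segs, signal_profile(vals), noise1, max_gap = 0)
  expect_equal(nrow(out), 1)
  expect_equal(c(out$start, out$end), c(0, 20))
  expect_equal(out$z, sqrt(20), tolerance = 1e-9)
  expect_lt(out$p, min(segs$p))

  # opposite means cancel: union is never more significant
  vals2 <- c(rep(2, 10), rep(-2, 10), rep(0, 10))
  segs2 <- rbind(mkseg(vals2, 0, 10), mkseg(vals2, 10, 20))
  out2 <- merge_segments(segs2, signal_profile(vals2), noise1, max_gap = 0)
  expect_equal(nrow(out2), 2)

  # a gap above max_gap blocks merging regardless of significance
  vals3 <- rep(5, 40)
  segs3 <- rbind(mkseg(vals3, 0, 10), mkseg(vals3, 13, 23))
  out3 <- merge_segments(segs3, signal_profile(vals3), noise1, max_gap = 0)
  expect_equal(nrow(out3), 2)
  out3b <- merge_segments(segs3, signal_profile(vals3), noise1, max_gap = 3)
  expect_equal(nrow(out3b), 1)  # gap bins included in the union span
  expect_equal(c(out3b$start, out3b$end), c(0, 23))
})

test_that("merging chains through adjacent segments and is idempotent", {
  vals <- c(rep(1, 30), rep(0, 10))
  prof <- signal_profile(vals)
  ps <- build_prefix_sums(vals)
  segs <- score_segment(ps, noise1, c(0, 10, 20), c(10, 20, 30))
  once <- merge_segments(segs, prof, noise1, max_gap = 0)
  expect_equal(nrow(once), 1)
  expect_equal(c(once$start, once$end), c(0, 30))
  twice <- merge_segments(once, prof, noise1, max_gap = 0)
  expect_equal(once, twice)
})

test_that("same-sign-only merging still allows qualifying same-sign pairs", {
  # means 3 and 2: union z = 50/sqrt(20) = 11.18 beats both members
  vals <- c(rep(3, 10), rep(2, 10), rep(0, 10))
  prof <- signal_profile(vals)
  ps <- build_prefix_sums(vals)
  segs <- score_segment(ps, noise1, c(0, 10), c(10, 20))
  cfg <- scan_config(merge_same_sign_only = TRUE)
  out <- merge_segments(segs, prof, noise1, max_gap = 0, config = cfg)
  expect_equal(nrow(out), 1)  # same sign: flag does not interfere

  # opposite signs partially cancel, so the union can never beat the
  # stronger member under the two-sided test; no merge with or without
  # the flag
  vals2 <- c(rep(3, 10), rep(-2, 10), rep(0, 10))
  segs2 <- score_segment(build_prefix_sums(vals2), noise1, c(0, 10), c(10, 20))
  for (c2 in list(cfg, scan_config())) {
    out2 <- merge_segments(segs2, signal_profile(vals2), noise1,
                           max_gap = 0, config = c2)
    expect_equal(nrow(out2), 2)
  }
})

test_that("refinement and merging preserve disjointness and never raise p", {
  set.seed(19)
  for (r in 1:5) {
    sim <- simulate_profile(short_profile_spec(snr = 1, seed = 100 + r))
    prof <- sim$profile
    noise <- estimate_noise(prof)
    ps <- build_prefix_sums(prof)
    cfg <- scan_config()
    cand <- scan_candidates(prof, cfg, noise, ps)
    sel <- select_segments(cand)
    ref <- refine_segments(sel, prof, noise, cfg, ps)
    expect_equal(nrow(ref), nrow(sel))
    if (nrow(ref) > 1)
      expect_true(all(ref$start[-1] >= ref$end[-nrow(ref)]))
    # per-segment refinement never increases the p-value
    expect_true(all(sort(ref$p) <= sort(sel$p)))
    mer <- merge_segments(ref, prof, noise, 0, cfg, ps)
    if (nrow(mer) > 1)
      expect_true(all(mer$start[-1] >= mer$end[-nrow(mer)]))
    expect_lte(min(mer$p), min(ref$p))
    expect_equal(mer, merge_segments(mer, prof, noise, 0, cfg, ps))
  }
})
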