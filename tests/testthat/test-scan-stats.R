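test_that("MAD noise estimation matches the direct definition", {
  # median 3, absolute deviations {2,1,0,1,97}, MAD 1 -> sigma 1.4826
  x <- c(1, 2, 3, 4, 100)
  expect_equal(estimate_noise(x)$sigma_hat, 1.4826)
  expect_equal(estimate_noise(x)$sigma_hat, naive_mad_sigma(x))

  set.seed(42)
  for (i in 1:5) {
    y <- rnorm(200, sample(-5:5, 1), runif(1, 0.5, 3))
    expect_equal(estimate_noise(y)$sigma_hat, naive_mad_sigma(y))
  }
})

test_that("sigma_hat is consistent for the Gaussian background", {
  set.seed(7)
  x <- rnorm(10000)
  expect_lt(abs(estimate_noise(x)$sigma_hat - 1), 0.05)
})

test_that("degenerate (zero-MAD) profiles raise an actionable error", {
  expect_error(estimate_noise(c(1, 1, 1, 1, 5)), "MAD.*0|sigma")
  # explicit sigma bypasses estimation
  nm <- estimate_noise(c(1, 1, 1, 1, 5), sigma = 2)
  expect_equal(nm$sigma_hat, 2)
})

test_that("prefix sums reproduce naive means on random segments", {
  expect_equal(build_prefix_sums(c(1, 2, 3))$cumulative, c(0, 1, 3, 6))

  set.seed(1)
  vals <- rnorm(5000)
  ps <- build_prefix_sums(vals)
  starts <- sample.int(4999, 1000) - 1
  ends <- pmin(starts + sample.int(400, 1000, replace = TRUE), 5000)
  noise <- known_noise()
  sc <- score_segment(ps, noise, starts, ends)
  for (i in seq_len(1000)) {
    nv <- naive_segment_mean(vals, starts[i], ends[i])
    expect_lt(abs(sc$mean[i] - nv) / max(abs(nv), 1e-12), 1e-9)
  }
})

test_that("window ladder follows the geometric ceiling/dedup rule", {
  lad <- window_ladder(scan_config(w_min = 1, w_max = 4, rho = 1.1), 100)
  expect_equal(lad$length, c(1, 2, 3, 4))  # ceilings of 1, 1.1, ..., 3.797

  expect_equal(window_ladder(scan_config(w_min = 7, w_max = 7), 100)$step, 2)

  lad <- window_ladder(scan_config(), 100000)
  expect_lte(max(lad$length), 300)
  expect_false(is.unsorted(lad$length, strictly = TRUE))
  expect_equal(lad$step, pmax(1, ceiling(lad$length / 5)))
  # every raw generator of a kept length stayed within w_max
  expect_lte(max(lad$length), ceiling(1 * 1.1^floor(log(300) / log(1.1))))

  # lengths are capped at the profile length
  expect_lte(max(window_ladder(scan_config(), 50)$length), 50)
})

test_that("ladder windows cover every bin at every length", {
  cfg <- scan_config(w_max = 40)
  N <- 137
  lad <- window_ladder(cfg, N)
  for (k in seq_len(nrow(lad))) {
    W <- lad$length[k]
    starts <- seq.int(0, N - W, by = lad$step[k])
    if (starts[length(starts)] != N - W) starts <- c(starts, N - W)
    covered <- logical(N)
    for (s in starts) covered[(s + 1):(s + W)] <- TRUE
    expect_true(all(covered))
  }
})

test_that("the z-test scores single points and respects symmetry", {
  noise <- known_noise()
  ps <- build_prefix_sums(c(3, 0, 0, 0))
  one <- score_segment(ps, noise, 0, 1)
  expect_equal(one$z, 3)
  expect_equal(one$p, 2 * pnorm(-3), tolerance = 1e-12)  # ~0.0027

  # mean equal to the null mean -> z = 0, p = 1
  ps0 <- build_prefix_sums(c(1, -1, 2, -2))
  expect_equal(score_segment(ps0, noise, 0, 4)$p, 1)

  # two-sided symmetry: mean +1 and -1 over n = 4 give the same p, z = +-2
  psp <- build_prefix_sums(rep(1, 4))
  psm <- build_prefix_sums(rep(-1, 4))
  sp <- score_segment(psp, noise, 0, 4)
  sm <- score_segment(psm, noise, 0, 4)
  expect_equal(sp$z, 2)
  expect_equal(sm$z, -2)
  expect_equal(sp$p, sm$p)

  expect_error(score_segment(psp, noise, 2, 2), "start < end")
})

test_that("candidate scan finds planted signal and honors the p_s filter", {
  vals <- rep(0, 50)
  vals[11:20] <- 10  # bins [10, 20)
  set.seed(3)
  vals <- vals + rnorm(50, 0, 0.1)
  prof <- signal_profile(vals)
  cfg <- scan_config(w_max = 30)
  noise <- known_noise()
  cand <- scan_candidates(prof, cfg, noise)
  expect_true(all(cand$p <= cfg$p_s))
  hit <- cand[cand$start < 20 & cand$end > 10, ]
  expect_true(any(hit$p < 1e-6))
  expect_true(attr(cand, "n_tests") > nrow(cand))
})

test_that("a pure-noise profile yields an empty candidate list", {
  set.seed(5)
  prof <- signal_profile(rnorm(60, 0, 0.01))
  # strict pre-filter: nothing should clear p_s = 1e-8 in 60 quiet bins
  cand <- scan_candidates(prof, scan_config(p_s = 1e-8, w_max = 10),
                          known_noise(sigma = 1))
  expect_equal(nrow(cand), 0)
})

test_that("scores are invariant to negation and to joint mean shifts", {
  set.seed(9)
  vals <- rnorm(300)
  vals[100:140] <- vals[100:140] + 2
  cfg <- scan_config(w_max = 60)

  n1 <- estimate_noise(vals, mu0 = 0)
  c1 <- scan_candidates(signal_profile(vals), cfg, n1)
  # sign symmetry: negating the profile leaves all p-values unchanged
  n2 <- estimate_noise(-vals, mu0 = 0)
  c2 <- scan_candidates(signal_profile(-vals), cfg, n2)
  expect_equal(c1[, c("start", "end")], c2[, c("start", "end")])
  expect_equal(c1$p, c2$p, tolerance = 1e-12)
  expect_equal(c1$z, -c2$z, tolerance = 1e-12)

  # shifting all values by c while moving mu0 by c changes nothing
  n3 <- estimate_noise(vals + 5, mu0 = 5)
  c3 <- scan_candidates(signal_profile(vals + 5), cfg, n3)
  expect_equal(c1[, c("start", "end")], c3[, c("start", "end")])
  expect_equal(c1$z, c3$z, tolerance = 1e-9)
})
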