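# Time-domain feature extractors: RMS, Weight Peaks, DFA.

test_that("rms_features: counts, constants, and the hand-computed window", {
  set.seed(30)
  x <- abs(rnorm(1000))
  expect_equal(n_ticks(rms_features(x)), 40)

  expect_true(all(abs(rms_features(rep(-2, 500))$values - 2) < 1e-12))

  one <- rms_features(c(3, 4), rms_config(window = 2, step = 2))
  expect_equal(as.numeric(one$values), sqrt(12.5), tolerance = 1e-12)
  expect_equal(n_ticks(one), 1)

  expect_error(rms_features(numeric(0)), "input error")
  expect_error(rms_config(window = 10, step = 20), "window >= step")
})

test_that("rms feature count is ceil(length / step) for every length", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(1:400, 1)
    step <- sample(1:50, 1)
    window <- step + sample(0:100, 1)
    s <- rms_features(rnorm(n), rms_config(window = window, step = step))
    expect_equal(n_ticks(s), ceiling(n / step))
    expect_true(all(diff(s$tick_times) > 0))
  }
})

test_that("zero_crossings applies both the sign and amplitude gates", {
  expect_equal(zero_crossings(c(1, -1, 1, -1), 0.5), c(1, 2, 3))
  expect_equal(length(zero_crossings(c(0.1, -0.1, 0.1), 0.5)), 0)
  expect_equal(length(zero_crossings(abs(rnorm(100)) + 0.1, 0.01)), 0)
  expect_error(zero_crossings(1, 0.5), "input error")
})

test_that("zero-crossing count equals a brute-force pairwise scan", {
  set.seed(32)
  for (i in 1:1000) {
    n <- sample(2:40, 1)
    s <- round(rnorm(n), 2)
    thr <- runif(1, 0, 1)
    brute <- 0L
    for (k in 1:(n - 1)) {
      if (sign(s[k] * s[k + 1]) < 0 && abs(s[k] - s[k + 1]) >= thr) {
        brute <- brute + 1L
      }
    }
    expect_equal(length(zero_crossings(s, thr)), brute)
  }
})

test_that("extract_peaks follows the max/min rule with valleys made positive", {
  # positive segment between crossings at 1 and 5: max + min >= 0
  s <- c(-1, 0.2, 0.8, 0.3, -1, -0.5)
  pk <- extract_peaks(s, zero_crossings(s, 0.1))
  expect_equal(pk$value[1], 0.8)
  # negative segment: valley returned as positive magnitude
  s2 <- c(1, -0.2, -0.9, -0.1, 1, 0.5)
  pk2 <- extract_peaks(s2, zero_crossings(s2, 0.1))
  expect_equal(pk2$value[1], 0.9)
  # boundary: max + min exactly 0 takes the max branch
  s3 <- c(-1, 0.5, -0.5, 1, -1)
  pk3 <- extract_peaks(s3, c(1, 3))  # segment {0.5, -0.5}
  expect_equal(pk3$value[1], 0.5)
  expect_equal(pk3$peak_at[1], 2)
  # fewer than two crossings -> empty, not an error
  expect_equal(nrow(extract_peaks(c(1, -1), 1L)), 0)
})

test_that("extracted peaks are nonnegative actual segment samples", {
  set.seed(33)
  for (i in 1:200) {
    s <- rnorm(sample(10:80, 1))
    zc <- zero_crossings(s, 0.05)
    pk <- extract_peaks(s, zc)
    expect_true(all(pk$value >= 0))
    if (nrow(pk) > 0) {
      for (r in seq_len(nrow(pk))) {
        seg <- s[(zc[r] + 1):zc[r + 1]]
        expect_true(any(abs(abs(seg) - pk$value[r]) < 1e-12))
        expect_equal(abs(s[pk$peak_at[r]]), pk$value[r])
      }
    }
  }
})

test_that("weight_peaks is the stated recursion", {
  expect_equal(weight_peaks(rep(2, 10), 5), rep(2, 10))
  expect_equal(weight_peaks(c(1, 3), 3), c(1, 5 / 3), tolerance = 1e-12)
  expect_equal(weight_peaks(c(4, 1, 7), 1), c(4, 1, 7))
  expect_equal(weight_peaks(numeric(0), 5), numeric(0))
  # matches a literal element-by-element recursion
  set.seed(34)
  p <- abs(rnorm(50))
  for (n in c(2, 5, 11)) {
    ref <- p
    for (i in 2:length(p)) ref[i] <- (n - 1) / n * ref[i - 1] + p[i] / n
    expect_equal(weight_peaks(p, n), ref, tolerance = 1e-12)
  }
})

test_that("weight_peaks smooths more strongly as n grows", {
  set.seed(35)
  p <- abs(rnorm(300))
  tv <- vapply(c(1, 3, 10, 50), function(n) {
    sum(abs(diff(weight_peaks(p, n))))
  }, numeric(1))
  expect_true(all(diff(tv) < 0))
  # n -> infinity tends to holding the first element
  expect_lt(max(abs(weight_peaks(p, 1e6) - p[1])), 1e-3)
})

test_that("wp_features merges per-node peak streams causally", {
  expect_equal(n_ticks(wp_features(numeric(600))), 0)

  set.seed(36)
  rec <- condition(generate_trial(trial_spec(5, ramp_s = 0.3, hold_s = 1,
                                             rest_s = 0.3, seed = 36)))
  s <- wp_features(rec$samples[1, ])
  expect_gt(n_ticks(s), 0.5 * n_samples(rec))
  expect_true(all(diff(s$tick_times) > 0))
  expect_true(all(s$values >= 0))
})

test_that("peak count of a pure sinusoid matches the analytic rate", {
  # one peak per half-period: 2 f T - 1 intervals between 2 f T crossings
  f <- 50
  t <- (0:999) / 1000
  s <- sin(2 * pi * f * t)
  zc <- zero_crossings(s, 0.01)
  pk <- extract_peaks(s, zc)
  expect_equal(nrow(pk), 2 * f * 1 - 1, tolerance = 0.03)
  expect_true(all(abs(pk$value - 1) < 0.01))
})

test_that("dfa_profile integrates around the segment mean", {
  expect_equal(dfa_profile(rep(3, 7)), rep(0, 7))
  expect_equal(dfa_profile(c(1, 2, 4)), c(-4 / 3, -5 / 3, 0),
               tolerance = 1e-12)
  set.seed(37)
  for (i in 1:50) {
    x <- rnorm(sample(2:200, 1))
    prof <- dfa_profile(x)
    expect_lt(abs(prof[length(prof)]), 1e-9)
  }
  expect_error(dfa_profile(numeric(0)), "input error")
})

test_that("dfa_fluctuation is the RMS residual of the in-window line fit", {
  expect_lt(dfa_fluctuation(3 * (1:50) + 2), 1e-9)
  expect_equal(dfa_fluctuation(c(0, 1, 0)), sqrt(2 / 9), tolerance = 1e-12)
  set.seed(38)
  x <- cumsum(rnorm(100))
  expect_equal(dfa_fluctuation(x), dfa_fluctuation(x + 42),
               tolerance = 1e-9)
  expect_error(dfa_fluctuation(c(1, 2)), "parameter error")
  expect_error(dfa_config(window_l = 2), ">= 3")
})

test_that("dfa_features: window partitioning and homogeneity", {
  set.seed(39)
  x <- abs(rnorm(1000))
  expect_equal(n_ticks(dfa_features(x)), 10)
  expect_equal(n_ticks(dfa_features(abs(rnorm(250)))), 2)
  expect_error(dfa_features(rnorm(50)), "input error")

  f1 <- dfa_features(x)$values
  f3 <- dfa_features(3 * x)$values
  expect_equal(f3, 3 * f1, tolerance = 1e-9)

  # floor(N/L) property across random lengths
  for (i in 1:20) {
    n <- sample(100:2000, 1)
    l <- sample(10:150, 1)
    expect_equal(n_ticks(dfa_features(rnorm(n), dfa_config(l))), n %/% l)
  }
})
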