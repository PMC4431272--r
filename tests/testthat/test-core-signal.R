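# core_signal: recording I/O, conditioning chain, accuracy accounting.

test_that("read_recording round-trips CSV recordings with and without labels", {
  rec <- emg_recording(matrix(rnorm(6 * 100), 6, 100),
                       labels = rep(9L, 100))
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(dim(back$samples), c(6, 100))
  expect_equal(back$channels, EMG_CHANNELS)
  expect_equal(back$samples, rec$samples, tolerance = 1e-12)
  expect_true(all(back$labels == 9L))

  # no label column -> labels absent
  df <- as.data.frame(t(rec$samples))
  names(df) <- EMG_CHANNELS
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path2, row.names = FALSE)
  expect_null(read_recording(path2)$labels)

  # columns can arrive in any order; schema restores canonical order
  df_shuffled <- df[, rev(EMG_CHANNELS)]
  path3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df_shuffled, path3, row.names = FALSE)
  expect_equal(read_recording(path3)$samples, rec$samples,
               tolerance = 1e-12)
})

test_that("read_recording rejects bad cells and missing channels", {
  df <- as.data.frame(matrix(rnorm(60), 10, 6))
  names(df) <- EMG_CHANNELS
  df$FCU[4] <- "NaN"
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  expect_error(read_recording(path), "parse error.*FCU.*4")

  df2 <- df[, 1:5]
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df2, path2, row.names = FALSE)
  expect_error(read_recording(path2), "schema error")
})

test_that("emg_recording validates invariants", {
  m <- matrix(0, 6, 10)
  expect_error(emg_recording(m, rate_hz = 0), "rate_hz")
  expect_error(emg_recording(m, labels = rep(1, 9)), "one entry per")
  expect_error(emg_recording(m, labels = rep(10L, 10)), "1..9")
  expect_error(emg_recording(m, mvc = c(1, 1, 1, 1, 1, 0)), "positive")
  expect_error(emg_recording(m, channels = c("a", "b")), "channel count")
})

test_that("motion labels form a bijection over 9 classes", {
  expect_length(MOTION_LABELS, 9)
  expect_equal(sort(unname(MOTION_LABELS)), 1:9)
  expect_equal(motion_code(motion_name(1:9)), 1:9)
  expect_equal(motion_name(9), "relax")
  expect_error(motion_name(10), "1..9")
  expect_error(motion_code("shrug"), "unknown")
})

test_that("condition removes DC, rectifies and normalizes by MVC", {
  const <- emg_recording(matrix(2.5, 6, 1000))
  out <- condition(const)
  # DC removed away from the filter's edge transients
  expect_lt(max(out$samples[, 300:700]), 1e-6)

  # ~100 Hz sinusoid, mvc = amplitude -> rectified peak ~ 1 away from edges
  # (97 Hz so the sample phases sweep the true peak of the sine)
  a <- 3
  x <- a * sin(2 * pi * 97 * (0:1999) / 1000)
  rec <- emg_recording(matrix(rep(x, each = 6), 6, byrow = FALSE),
                       mvc = rep(a, 6))
  cond <- condition(rec)
  interior <- cond$samples[1, 200:1800]
  expect_equal(max(interior), 1, tolerance = 0.01)
  expect_true(all(cond$samples >= 0))
  expect_equal(ncol(cond$samples), 2000)

  expect_error(condition(rec, mvc = c(rep(1, 5), 0)), "parameter error")
  expect_error(condition(rec, highpass_hz = 600), "Nyquist")
})

test_that("conditioning stages are idempotent", {
  # rectification + MVC normalization: applying them to an already
  # conditioned recording is the identity (mvc = 1, samples >= 0)
  rec <- generate_trial(trial_spec(5, seed = 4))
  once <- condition(rec)
  expect_identical(abs(once$samples) / once$mvc, once$samples)
  # the high-pass stage is idempotent up to transient/band-edge tolerance:
  # a second zero-phase pass changes an already high-passed broadband
  # signal only marginally (the full chain is NOT idempotent because
  # rectification demodulates energy below the cutoff; see the vignette)
  set.seed(3)
  hp <- butter2(20, 1000, "high")
  interior <- 500:5500
  # content above the transition band: second pass is essentially identity
  x <- bandlimited_noise(6000, 1000, band = c(40, 450))
  y1 <- filtfilt2(hp, x)
  y2 <- filtfilt2(hp, y1)
  expect_lt(mean(abs(y2 - y1)[interior]), 0.01 * mean(abs(y1)[interior]))
  # full 10-450 Hz band: band-edge content is attenuated twice, so the
  # deviation is larger but still a small fraction of the signal
  xf <- bandlimited_noise(6000, 1000)
  z1 <- filtfilt2(hp, xf)
  z2 <- filtfilt2(hp, z1)
  expect_lt(mean(abs(z2 - z1)[interior]), 0.06 * mean(abs(z1)[interior]))
})

test_that("accuracy matches its definition and exposes the confusion matrix", {
  truth <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 1)
  pred <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 2)
  res <- accuracy(pred, truth)
  expect_equal(res$accuracy, 0.9)
  expect_equal(accuracy(truth, truth)$accuracy, 1.0)
  expect_equal(accuracy(rep(1, 5), rep(2, 5))$accuracy, 0.0)
  expect_error(accuracy(1:3, 1:4), "input error")
  expect_error(accuracy(integer(0), integer(0)), "input error")

  # confusion-derived accuracy equals direct counting on random sequences
  set.seed(11)
  for (i in 1:20) {
    t <- sample(1:9, 50, replace = TRUE)
    p <- sample(1:9, 50, replace = TRUE)
    res <- accuracy(p, t)
    expect_equal(sum(diag(res$confusion)), sum(p == t))
    expect_equal(rowSums(res$confusion),
                 as.numeric(table(factor(t, levels = 1:9))),
                 ignore_attr = TRUE)
  }
})

test_that("butter2 matches reference bilinear-transform coefficients", {
  # frozen from an independent filter-design implementation
  hp <- butter2(20, 1000, "high")
  expect_equal(hp$b, c(0.9149691441130827, -1.8299382882261654,
                       0.9149691441130827), tolerance = 1e-12)
  expect_equal(hp$a, c(1, -1.8226949251963085, 0.837181651256023),
               tolerance = 1e-12)
  lp <- butter2(4, 1000, "low")
  expect_equal(lp$b, c(0.0001551484234756991, 0.0003102968469513982,
                       0.0001551484234756991), tolerance = 1e-12)
  expect_equal(lp$a, c(1, -1.9644605802052324, 0.9650811738991353),
               tolerance = 1e-12)
})

test_that("zero-phase filtering introduces no group delay", {
  t <- (0:2999) / 1000
  x <- sin(2 * pi * 5 * t)
  lp <- butter2(40, 1000, "low")
  y <- filtfilt2(lp, x)
  # 5 Hz passes a 40 Hz low-pass nearly untouched and unshifted
  expect_lt(max(abs(y - x)[300:2700]), 0.01)
  # causal pass of the same filter does lag
  yc <- biquad_filter(lp, x)
  expect_gt(max(abs(yc - x)[300:2700]), 0.02)
})
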