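test_that("the 1-8 Hz bandpass keeps the passband, kills drift and DC, zero phase", {
  fs <- 250
  t <- (0:(fs * 20 - 1)) / fs
  tone4 <- sin(2 * pi * 4 * t)
  out <- eeg_bandpass(tone4, fs)
  mid <- out[(5 * fs):(15 * fs)]
  expect_lt(abs(max(mid) - 1), 0.05)

  drift <- sin(2 * pi * 0.1 * t)
  att <- max(abs(eeg_bandpass(drift, fs)[(5 * fs):(15 * fs)]))
  expect_lt(20 * log10(att), -20)

  dc <- eeg_bandpass(tone4 + 5, fs)
  expect_lt(abs(mean(dc[(5 * fs):(15 * fs)])), 0.01)

  # zero-phase: a symmetric pulse stays symmetric about its centre sample
  pulse <- exp(-((t - 10)^2) / (2 * 0.2^2))
  fp <- eeg_bandpass(pulse, fs)
  ctr <- 10 * fs + 1
  k <- 1:1000
  expect_lt(max(abs(fp[ctr + k] - fp[ctr - k])), 1e-6)

  expect_invalid(eeg_bandpass(tone4, 10))
})

test_that("bad channels are flagged by flatline, correlation and amplitude criteria", {
  fs <- 100
  set.seed(3)
  n <- 30 * fs
  base <- smooth_regressor(n, fs)
  # correlated clean channels: shared signal + small noise; enough channels
  # that a single outlier can exceed 3 SD of the scalp distribution
  eeg <- sapply(1:16, function(i) base + 0.2 * smooth_regressor(n, fs))

  q0 <- flag_bad_channels(eeg, fs)
  expect_false(any(q0$bad))

  # 6 s of constant signal -> flatline flag
  eeg_flat <- eeg
  eeg_flat[1000:1600, 3] <- eeg_flat[1000, 3]
  q1 <- flag_bad_channels(eeg_flat, fs)
  expect_true(q1$flatline[3])
  expect_gt(q1$flat_run_s[3], 5)

  # independent large-amplitude noise -> amplitude and correlation flags
  eeg_noisy <- eeg
  eeg_noisy[, 5] <- rnorm(n) * 10 * sd(eeg[, 5])
  q2 <- flag_bad_channels(eeg_noisy, fs)
  expect_true(q2$amplitude_outlier[5])
  expect_true(q2$low_correlation[5])
  expect_true(q2$bad[5])

  expect_invalid(flag_bad_channels(eeg[, 1:3], fs))
})

test_that("common average referencing excludes bad channels and is idempotent", {
  set.seed(4)
  eeg <- matrix(rnorm(500 * 6), 500, 6)
  same <- matrix(rep(rnorm(500), 6), 500, 6)
  expect_equal(max(abs(rereference_car(same))), 0)

  out <- rereference_car(eeg, bad = 6)
  expect_lt(max(abs(rowMeans(out[, 1:5]))), 1e-10)

  # bad channel's noise does not shift the reference
  eeg2 <- eeg; eeg2[, 6] <- eeg2[, 6] + 1000
  expect_equal(rereference_car(eeg2, bad = 6)[, 1:5],
               rereference_car(eeg, bad = 6)[, 1:5])

  # idempotent on already-referenced data
  car1 <- rereference_car(eeg)
  expect_equal(rereference_car(car1), car1, tolerance = 1e-12)
  expect_error(rereference_car(eeg, bad = 1:6), "good channels")
})

test_that("interpolation respects the neighborhood radius", {
  # toy layout: bad electrode at origin, neighbours at 15/18/25 mm
  lay <- data.frame(label = c("bad", "n1", "n2", "far"),
                    x = c(0, 15, 0, 25), y = c(0, 0, 18, 0), z = 0)
  eeg <- cbind(bad = rep(99, 100),
               n1 = seq_len(100),
               n2 = seq_len(100) * 2,
               far = rep(1000, 100))
  out <- interpolate_bad(eeg, bad = 1, lay)
  expect_equal(out[, 1], (seq_len(100) + seq_len(100) * 2) / 2)  # 25 mm ignored

  # identical neighbours -> exact copy
  eeg2 <- cbind(rep(0, 50), rep(7, 50), rep(7, 50), rep(7, 50))
  lay2 <- data.frame(label = c("a", "b", "c", "d"),
                     x = c(0, 10, 0, 40), y = c(0, 0, 10, 0), z = 0)
  expect_equal(interpolate_bad(eeg2, 1, lay2)[, 1], rep(7, 50))

  # no neighbour in radius: widen to nearest with warning
  lay3 <- data.frame(label = c("a", "b"), x = c(0, 30), y = 0, z = 0)
  eeg3 <- cbind(rep(0, 10), rep(3, 10))
  expect_warning(out3 <- interpolate_bad(eeg3, 1, lay3), "nearest")
  expect_equal(out3[, 1], rep(3, 10))
})

test_that("the full preprocessing chain runs and downsamples", {
  fs <- 250
  set.seed(5)
  lay <- layout_1010_64()[1:8, ]
  base <- smooth_regressor(fs * 20, fs, cutoff = 6)
  eeg <- sapply(1:8, function(i)
    base + 0.2 * smooth_regressor(fs * 20, fs, cutoff = 6))
  res <- preprocess_eeg(eeg, fs, lay, fs_out = 100)
  expect_equal(res$fs, 100)
  expect_equal(nrow(res$eeg), 2000)
  expect_equal(ncol(res$eeg), 8)
})
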