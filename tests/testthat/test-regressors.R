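test_that("spectral flux is zero for silence and peaks at a tone onset", {
  fs <- 16000
  expect_equal(max(abs(spectral_flux(numeric(fs * 2), fs))), 0)

  t_on <- 0.8
  a <- tone_burst(1000, t_on = t_on, burst_s = 0.2, total_s = 2, fs = fs)
  fl <- spectral_flux(a, fs)
  expect_true(all(fl >= 0))
  t_max <- (which.max(fl) - 1) / 100
  expect_lt(abs(t_max - t_on), 0.020)

  # default filterbank configuration: 128 log-spaced bands, 100-8000 Hz
  fm <- formals(spectral_flux)
  expect_equal(eval(fm$n_bands), 128)
  expect_equal(eval(fm$f_lo), 100)
  expect_equal(eval(fm$f_hi), 8000)

  expect_invalid(spectral_flux(a, 8000))
  expect_invalid(spectral_flux(numeric(10), fs))
})

test_that("velocity magnitude matches closed forms", {
  expect_equal(velocity_magnitude(rep(3, 100), 100), numeric(100))
  fs <- 100
  t <- (0:999) / fs
  expect_equal(velocity_magnitude(t, fs), rep(1, 1000), tolerance = 1e-9)

  # |d/dt A sin(2 pi f t)| has mean 4 f A over whole periods
  f <- 2; A <- 1.5
  v <- velocity_magnitude(A * sin(2 * pi * f * t), fs)
  expect_equal(mean(v[1:1000]), 4 * f * A, tolerance = 0.01 * 4 * f * A)
  expect_invalid(velocity_magnitude(1, 100))
})

test_that("coordination sign product is exact and carries zeros forward", {
  expect_true(all(coordination_signal(runif(50) + 1, runif(50) + 2) == 1))
  v <- sin(seq(0, 20, by = 0.01)) + 0.2
  expect_true(all(coordination_signal(v, -v) == -1))

  # quadrature sines: square wave at double frequency
  t <- (0:1999) / 100
  co <- coordination_signal(sin(2 * pi * t), sin(2 * pi * t + pi / 2))
  expect_true(all(co %in% c(-1, 1)))
  flips <- sum(diff(co) != 0)
  expect_equal(flips, 4 * 20, tolerance = 2)  # 4 flips per 1 Hz cycle, 20 s

  expect_equal(sign_series(c(0, 2, 0, -3, 0, 0, 5)),
               c(1, 1, 1, -1, -1, -1, 1))
  expect_invalid(coordination_signal(1:5, 1:4))
})

test_that("principal movements are orthonormal with nonincreasing variance", {
  set.seed(9)
  v <- smooth_regressor(1200)
  fb <- make_fullbody(v, seed = 4)
  pm <- pca_movements(fb)
  B <- pm$basis
  expect_lt(max(abs(crossprod(B) - diag(ncol(B)))), 1e-8)
  expect_true(all(diff(pm$variance_explained) <= 1e-12))
  expect_lte(sum(pm$variance_explained), 1 + 1e-12)

  # rank-deficient input yields fewer components with a warning
  lowrank <- matrix(rnorm(500), 500, 1) %*% t(rnorm(66))
  expect_warning(pm2 <- pca_movements(lowrank, n_keep = 5), "rank")
  expect_equal(ncol(pm2$basis), 1)
  expect_invalid(pca_movements(fb[1:50, ]))
})

test_that("standardization yields unit pooled SD per participant and is scale invariant", {
  set.seed(2)
  make_p <- function(mult) lapply(1:3, function(i)
    list(a = rnorm(200) * mult, b = runif(200) * mult))
  trials <- list(make_p(1), make_p(5))
  std <- standardize_regressors(trials)
  for (p in 1:2) for (nm in c("a", "b")) {
    pooled <- unlist(lapply(std$trials[[p]], `[[`, nm))
    expect_equal(sd(pooled), 1, tolerance = 1e-12)
  }
  # scaling the input by 7 changes nothing
  scaled <- lapply(trials, function(pp) lapply(pp, function(tr)
    lapply(tr, `*`, 7)))
  expect_equal(standardize_regressors(scaled)$trials, std$trials,
               tolerance = 1e-12)

  trials[[1]][[1]]$a <- rep(1, 200); trials[[1]][[2]]$a <- rep(1, 200)
  trials[[1]][[3]]$a <- rep(1, 200)
  expect_error(standardize_regressors(trials), "'a'")
})

test_that("resampling preserves band-limited content and trims exactly", {
  x <- sin(2 * pi * 3 * (0:9999) / 250)
  expect_identical(resample_trim(x, 250, 250), x)
  y <- resample_trim(x, 250, 100)
  expect_length(y, 4000)
  interior <- y[200:3800]
  expect_lt(abs(max(interior) - 1), 0.01)
  expect_lt(abs(min(interior) + 1), 0.01)

  # trimming
  z <- resample_trim(x, 250, 100, t_start = 10, t_end = 30)
  expect_length(z, 2000)
  expect_equal(z, y[1001:3000], tolerance = 1e-6)
  expect_invalid(resample_trim(x, 250, 100, t_start = 5, t_end = 5))
  expect_invalid(resample_trim(x, 100, 250))
})

test_that("WAV files round-trip", {
  fs <- 16000
  x <- 0.8 * sin(2 * pi * 440 * (0:(fs - 1)) / fs)
  p <- tempfile(fileext = ".wav")
  write_wav(x, p, fs)
  w <- read_wav(p)
  expect_equal(w$fs, fs)
  expect_equal(w$x, x, tolerance = 1e-4)  # 16-bit quantization
  unlink(p)
})
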