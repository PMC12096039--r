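test_that("event trains have beat spacing, seeded determinism and lognormal amplitudes", {
  x <- make_event_train(120, 10, seed = 1)
  expect_length(x, 1000)
  expect_equal(sum(x > 0), 20)                      # 2 beats/s for 10 s
  idx <- which(x > 0)
  expect_true(all(diff(idx) == 50))                 # 0.5 s spacing at 100 Hz
  expect_true(all(x >= 0))
  expect_identical(x, make_event_train(120, 10, seed = 1))
  expect_false(identical(x, make_event_train(120, 10, seed = 2)))
  expect_invalid(make_event_train(-1, 10, 1))
  expect_invalid(make_event_train(120, 0, 1))

  # amplitude moments vs the lognormal closed form, 1e4 impulses
  y <- make_event_train(6000, 100, seed = 3, sdlog = 0.5)
  amp <- y[y > 0]
  expect_gte(length(amp), 1e4 - 1)
  mu_true <- exp(0 + 0.5^2 / 2)
  sd_true <- sqrt((exp(0.5^2) - 1) * exp(0.5^2))
  se <- sd_true / sqrt(length(amp))
  expect_lt(abs(mean(amp) - mu_true), 3 * se)
})

test_that("bounce pairs lock, detune by 8.5%, and alternate coordination states", {
  # phase-locked limit: no jitter, in-phase target only, common start
  bp <- make_bounce_pair(120, 120, "coupled", 10, seed = 1, phase_sd = 0,
                         targets = 0, init_phase = c(0, 0))
  expect_true(all(coordination_signal(bp$v_a, bp$v_b) == 1))

  expect_equal(diff(tempo_pair(120)) / 120, 0.085)
  expect_equal(diff(tempo_pair(104)) / 104, 0.085)

  bp2 <- make_bounce_pair(120, 120, "coupled", 40, seed = 7)
  co <- coordination_signal(bp2$v_a, bp2$v_b)
  expect_gte(coordination_episode_count(co, bp2$fs), 3)

  expect_invalid(make_bounce_pair(120, 120, "coupled", 0.3, seed = 1))
})

test_that("full-body kinematics decompose into the injected primitives", {
  v <- make_bounce_pair(120, 120, "uncoupled", 20, seed = 2)$v_a

  fb1 <- make_fullbody(v, n_primitives = 1, noise_frac = 0, seed = 1)
  pm1 <- suppressWarnings(pca_movements(fb1, n_keep = 1))
  expect_gt(pm1$variance_explained[1], 0.999)

  fb <- make_fullbody(v, seed = 3)
  expect_equal(dim(fb), c(2000L, 66L))
  pm0 <- pca_movements(fb)
  expect_gte(sum(pm0$variance_explained), 0.95)

  # the bounce score is recoverable from the PCA decomposition when data are
  # pooled at study scale (PCA runs on trial-concatenated kinematics, so the
  # near-degenerate small-variance components decouple)
  vlong <- make_bounce_pair(120, 120, "uncoupled", 160, seed = 5)$v_a
  fb <- make_fullbody(vlong, seed = 3)
  pm <- pca_movements(fb)
  b <- attr(fb, "basis")[, 1]
  match_pc <- which.max(abs(as.vector(t(b) %*% pm$basis)))
  r <- cor(pm$scores[, match_pc], attr(fb, "scores")[, 1])
  expect_gte(abs(r), 0.95)

  expect_invalid(make_fullbody(v, noise_frac = 1))
  expect_invalid(make_fullbody(v, n_primitives = 70))
})

test_that("the forward model is an exact, linear, gated convolution", {
  nchan <- 4
  topo <- c(1, 0.5, -0.25, 0)
  topo[4] <- 1e-9  # keep topography nonzero everywhere it must be
  k <- toy_kernel("music", c(60, 200), c(1, -0.5), topo)
  win <- lag_window()
  n <- 400
  imp <- numeric(n); imp[200] <- 2
  tr <- simulate_trial(list(music = imp), list(music = k),
                       condition_label("yes", "same"), snr = Inf)
  wave <- kernel_waveform(k, win)
  expect_equal(tr$eeg[200 + win$lags, 1], 2 * wave * topo[1], tolerance = 1e-12)
  expect_equal(tr$eeg[200 + win$lags, 2], 2 * wave * topo[2], tolerance = 1e-12)

  # linearity: doubled amplitude doubles the contribution
  k2 <- toy_kernel("music", c(60, 200), 2 * c(1, -0.5), topo)
  tr2 <- simulate_trial(list(music = imp), list(music = k2),
                        condition_label("yes", "same"), snr = Inf)
  expect_equal(tr2$eeg, 2 * tr$eeg, tolerance = 1e-12)

  # gating: without visual contact, other/coordination contribute nothing
  set.seed(42)
  regs <- list(other = smooth_regressor(n), coordination = smooth_regressor(n))
  ks <- list(other = toy_kernel("other", 70, 1, topo),
             coordination = toy_kernel("coordination", 160, 1, topo))
  tr3 <- simulate_trial(regs, ks, condition_label("no", "same"), snr = Inf)
  expect_equal(max(abs(tr3$eeg)), 0)

  # mismatched regressor lengths are rejected
  expect_invalid(simulate_trial(list(other = rnorm(100),
                                     coordination = rnorm(99)),
                                ks, condition_label("no", "same"), snr = Inf))
})

test_that("artifact kernels dominate neural kernels by the configured factor", {
  ks <- kernel_presets(artifact_gain = 100)
  win <- lag_window()
  expect_equal(max(abs(kernel_waveform(ks$eog_left, win))) /
               max(abs(kernel_waveform(ks$music, win))), 100, tolerance = 1e-6)
})

test_that("sessions are balanced, deterministic and structurally coordinated", {
  cfg <- small_config()
  s1 <- make_session(cfg, seed = 5)
  s2 <- make_session(cfg, seed = 5)
  expect_identical(s1$participants, s2$participants)

  tab <- table(s1$conditions$vision, s1$conditions$music)
  expect_true(all(tab == cfg$blocks * cfg$trials_per_cond_block))
  expect_true(all(vapply(s1$participants[[1]], function(tr)
    !anyNA(tr$eeg) && tr$fs == 100, logical(1))))
  # both participants share condition labels trial by trial
  expect_identical(lapply(s1$participants[[1]], `[[`, "condition"),
                   lapply(s1$participants[[2]], `[[`, "condition"))

  # default design: 8 trials per condition
  full <- make_session(session_config(duration_s = 5), seed = 1)
  expect_true(all(table(full$conditions$vision, full$conditions$music) == 8))

  # coordination structure: more in/anti-phase alternation with shared music
  sess <- make_session(session_config(), seed = 11)
  tc <- paste(sess$conditions$vision, sess$conditions$music, sep = "/")
  eps <- vapply(sess$participants[[1]], function(tr)
    coordination_episode_count(tr$regressors$coordination, 100), numeric(1))
  means <- tapply(eps, tc, mean)
  expect_gt(means["yes/same"], means["yes/different"])
})

test_that("pink noise is 1/f-shaped and unit variance", {
  set.seed(1)
  x <- pink_noise(2^14)
  expect_equal(sd(x), 1, tolerance = 1e-6)
  sp <- Mod(fft(x))^2
  f <- seq_len(2^13)
  lo <- mean(sp[2:200]); hi <- mean(sp[4000:8000])
  expect_gt(lo / hi, 5)  # strong low-frequency dominance
})
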