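test_that("the design matrix implements lagged copies with an intercept", {
  win <- lag_window()
  x <- rnorm(200)
  D <- build_design(list(music = x), win)
  expect_equal(ncol(D), 57)            # 56 lags + intercept
  expect_true(all(D[, 57] == 1))

  # impulse at sample s appears at row s + l in the lag-l column
  imp <- numeric(200); imp[100] <- 1
  Di <- build_design(list(a = imp), win)
  for (l in c(-25L, -7L, 0L, 13L, 30L)) {
    col <- which(win$lags == l)
    expect_equal(which(Di[, col] == 1), 100L + l)
  }

  # stacked per-trial designs carry the multi-trial fit
  x2 <- rnorm(150)
  D2 <- build_design(list(music = x2), win)
  stacked <- rbind(D, D2)
  expect_equal(crossprod(stacked), crossprod(D) + crossprod(D2))

  expect_invalid(build_design(list(a = rnorm(10)), win))
})

test_that("ridge_fit matches the hand-solved normal equations and ridge limits", {
  # 3 samples x 2 columns, solved by hand:
  # D'D = [[2,1],[1,2]], D'y = [3,4]  =>  w = [2/3, 5/3]
  D <- matrix(c(1, 1, 0, 0, 1, 1), 3, 2)
  colnames(D) <- c("a@0", "(intercept)")
  y <- c(1, 2, 2)
  m <- ridge_fit(D, y, lambda = 0)
  expect_equal(as.vector(m$weights), c(2 / 3, 5 / 3), tolerance = 1e-12)

  # lambda -> infinity: slopes vanish, intercept -> channel mean
  set.seed(1)
  x <- rnorm(300)
  Dd <- build_design(list(a = x), lag_window())
  yy <- 3 + rnorm(300)
  mInf <- ridge_fit(Dd, yy, lambda = 1e12)
  w <- as.vector(mInf$weights)
  expect_lt(max(abs(w[1:56])), 1e-8)
  expect_equal(w[57], mean(yy), tolerance = 1e-3)

  expect_invalid(ridge_fit(Dd, yy, lambda = -1))
})

test_that("ridge matches a direct normal-equation solve on small systems", {
  set.seed(7)
  for (k in 2:5) {
    for (lm in c(0, 1e-4, 1, 1e4)) {
      D <- matrix(rnorm(20 * k), 20, k)
      colnames(D) <- c(paste0("r", seq_len(k - 1), "@0"), "(intercept)")
      D[, k] <- 1
      y <- rnorm(20)
      m <- ridge_fit(D, y, lm)
      pen <- diag(rep(lm, k)); pen[k, k] <- 0
      w_direct <- solve(t(D) %*% D + pen, t(D) %*% y)
      expect_lt(max(abs(m$weights - w_direct)), 1e-10)
    }
  }
})

test_that("a noiseless simulated trial is recovered exactly at lambda 0", {
  set.seed(11)
  topo <- c(1, -0.4)
  k <- toy_kernel("music", c(-100, 60, 200), c(-0.5, 1, 0.8), topo)
  x <- rnorm(2000)  # broadband regressor keeps the system well conditioned
  tr <- simulate_trial(list(music = x), list(music = k),
                       condition_label("yes", "same"), snr = Inf)
  D <- build_design(tr$regressors, lag_window())
  m <- ridge_fit(D, tr$eeg, lambda = 0)
  est <- trf_weights(m, "music")
  truth <- outer(kernel_waveform(k, lag_window()), topo)
  expect_lt(max(abs(est - truth)), 1e-6)
})

test_that("lambda selection spans the printed grid and adapts to noise", {
  # unregularized option plus the 13 powers of ten from 1e-4 to 1e8
  expect_equal(lambda_grid(), c(0, 10^seq(-4, 8)))
  expect_length(setdiff(lambda_grid(), 0), 13)

  win <- lag_window()
  k <- toy_kernel("music", 60, 1, 1)
  noiseless <- lapply(1:3, function(i) {
    set.seed(i)
    simulate_trial(list(music = rnorm(600)), list(music = k),
                   condition_label("yes", "same"), snr = Inf)
  })
  lam <- select_lambda(noiseless, "music", win)
  expect_true(all(lam == 0))

  picked <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    trials <- lapply(1:3, function(i)
      simulate_trial(list(music = smooth_regressor(400)), list(music = k),
                     condition_label("yes", "same"), snr = 0.05,
                     seed = s * 37 + i))
    any(select_lambda(trials, "music", win) > 0)
  }, logical(1))
  expect_gte(mean(picked), 0.9)

  expect_invalid(select_lambda(noiseless, "music", win, grid = numeric()))
  expect_invalid(select_lambda(noiseless[1], "music", win))
})

test_that("subject TRFs average the fold fits", {
  k <- toy_kernel("music", 60, 1, 1)
  tr <- toy_trial(list(music = k), n = 600, seed = 3)
  trials <- list(tr, tr, tr)
  m_avg <- fit_subject_trf(trials, "music", lambdas = rep(1, 3))
  # identical trials: every fold fits the same two stacked copies, so the
  # fold average equals any single fold fit
  D <- build_design(tr$regressors, lag_window())
  m_fold <- ridge_fit(rbind(D, D), rbind(tr$eeg, tr$eeg), 1)
  expect_equal(m_avg$weights, m_fold$weights, tolerance = 1e-9)
  expect_invalid(fit_subject_trf(trials[1], "music"))
})

test_that("generic prediction is exact for identical participants and null for shuffled regressors", {
  win <- lag_window()
  k <- toy_kernel("music", c(60, 200), c(1, -1), c(1, 0.5))
  set.seed(5)
  regs <- list(music = rnorm(800))
  tr <- simulate_trial(regs, list(music = k), condition_label("yes", "same"),
                       snr = Inf)
  model <- ridge_fit(build_design(tr$regressors, win), tr$eeg, 0)
  res <- generic_predict(list(model, model), 2, list(tr, tr))
  expect_equal(unname(res$r), c(1, 1), tolerance = 1e-8)
  expect_true(all(res$r >= -1 & res$r <= 1))

  # shuffled-regressor control: predicting the original EEG from a
  # time-shuffled regressor gives r centred on zero
  rs <- vapply(1:20, function(s) {
    set.seed(200 + s)
    tr_sh <- tr
    tr_sh$regressors$music <- sample(tr$regressors$music)
    mean(generic_predict(list(model, model), 2, list(tr_sh))$r)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 2 * sd(rs) / sqrt(length(rs)))

  expect_error(generic_predict(list(model), 1, list(tr)), "2 participants")
})

test_that("delta r is the elementwise model difference", {
  r1 <- structure(list(r = c(0.4, 0.2), participant = 1),
                  class = "prediction_result")
  expect_equal(delta_r(r1, r1), c(0, 0))
  expect_equal(delta_r(c(0.5, 0.3), c(0.2, 0.4)), c(0.3, -0.1))
  expect_error(delta_r(c(0.1, 0.2), c(0.1, 0.2, 0.3)), "mismatch")
})

test_that("TRF peak reading honors sign, order and the amplitude floor", {
  lag_ms <- lag_window()$lag_ms
  w <- kernel_waveform(toy_kernel("music", c(60, 120, 200), c(1, -1, 1), 1),
                       lag_window())
  pos <- trf_peaks(w, lag_ms, sign = 1)
  expect_equal(pos$lag_ms, c(60, 200))
  neg <- trf_peaks(w, lag_ms, sign = -1)
  expect_equal(neg$lag_ms, 120)
  # small wiggles below the floor are ignored
  w2 <- w; w2[1] <- 0; w2[2] <- 0.05; w2[3] <- 0
  expect_equal(trf_peaks(w2, lag_ms, sign = 1)$lag_ms, c(60, 200))
})
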