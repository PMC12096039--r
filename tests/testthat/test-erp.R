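test_that("onset detection finds local maxima with salience filtering", {
  expect_equal(nrow(detect_onsets(1:100, 100)), 0)

  # three impulses, one salient beyond 3 SD
  x <- numeric(500); x[c(100, 250, 400)] <- c(1, 1, 30)
  on3 <- detect_onsets(x, 100, salience_sd = 3)
  expect_equal(on3$sample, 400)
  on0 <- detect_onsets(x, 100)
  expect_equal(on0$sample, c(100, 250, 400))

  # sine at f Hz: f peaks per second
  f <- 3
  s <- sin(2 * pi * f * (0:999) / 100)
  expect_equal(nrow(detect_onsets(s, 100)), f * 10, tolerance = 1)

  # plateaus report their first sample
  p <- c(0, 1, 2, 2, 2, 1, 0)
  expect_equal(detect_onsets(p, 1)$sample, 3)
  expect_invalid(detect_onsets(c(1, 2), 1))
})

test_that("coordination transitions are labelled and attributed", {
  expect_equal(nrow(coordination_transitions(rep(1, 100), rnorm(100),
                                             rnorm(100), 100)), 0)

  # quadrature sines: alternating transition labels at each flip
  t <- (0:799) / 100
  va <- sin(2 * pi * t); vb <- sin(2 * pi * t + pi / 2)
  co <- coordination_signal(va, vb)
  tr <- coordination_transitions(co, va, vb, 100)
  expect_gt(nrow(tr), 10)
  expect_true(all(tr$transition %in% c("to_inphase", "to_antiphase")))
  expect_true(all(abs(diff(as.integer(factor(tr$transition)))) == 1))

  # a flip caused only by the partner is attributed to "other"
  vs <- rep(1, 100)                       # self never changes direction
  vo <- c(rep(1, 50), rep(-1, 50))
  co2 <- coordination_signal(vs, vo)
  tr2 <- coordination_transitions(co2, vs, vo, 100)
  expect_equal(tr2$attribution, "other")
  expect_equal(tr2$transition, "to_antiphase")

  expect_invalid(coordination_transitions(c(0.5, 1), vs[1:2], vo[1:2], 100))
})

test_that("epoching applies the two baseline regimes exactly", {
  win <- lag_window()
  eeg <- matrix(5, 600, 3)
  on <- c(100, 300, 500)
  for (mode in c("prestim", "whole_epoch")) {
    ep <- epoch_eeg(eeg, on, win, mode)
    expect_equal(dim(ep$epochs), c(3L, 56L, 3L))
    expect_equal(max(abs(ep$epochs)), 0)  # constant input -> zero epochs
  }

  set.seed(8)
  eeg2 <- matrix(rnorm(600 * 2), 600, 2)
  pre <- epoch_eeg(eeg2, on, win, "prestim")
  base_idx <- which(win$lag_ms <= 0)
  for (e in 1:3) for (ch in 1:2)
    expect_lt(abs(mean(pre$epochs[e, base_idx, ch])), 1e-12)
  whole <- epoch_eeg(eeg2, on, win, "whole_epoch")
  for (e in 1:3) for (ch in 1:2)
    expect_lt(abs(mean(whole$epochs[e, , ch])), 1e-12)

  # events too close to the edges are dropped
  ep2 <- epoch_eeg(eeg2, c(10, 300, 595), win)
  expect_equal(ep2$kept, 2L)
  expect_equal(ep2$dropped, 2L)
  expect_warning(epoch_eeg(eeg2, c(3, 598), win), "no events")
})

test_that("extreme splits take the 20% tails and stay disjoint", {
  s <- split_extremes(1:100)
  expect_length(s$low, 20); expect_length(s$high, 20)
  expect_length(intersect(s$low, s$high), 0)

  s2 <- split_extremes(1:10)
  expect_equal(sort(s2$low), 1:2)
  expect_equal(sort(s2$high), 9:10)
  expect_invalid(split_extremes(1:9))
})

test_that("the cluster permutation test detects real effects and bounds p", {
  nlag <- 56
  # identical groups: no suprathreshold clusters
  set.seed(10)
  a <- matrix(rnorm(12 * nlag), 12, nlag)
  res0 <- cluster_perm_test(a, a, n_perm = 200, seed = 1)
  expect_equal(nrow(res0$clusters), 0)
  expect_equal(cluster_min_p(res0), 1)

  # injected 50 ms, 3 SD difference across 20 participants: near-sure detection
  hits <- vapply(1:20, function(s) {
    set.seed(3000 + s)
    ga <- matrix(rnorm(20 * nlag), 20, nlag)
    gb <- matrix(rnorm(20 * nlag), 20, nlag)
    ga[, 25:29] <- ga[, 25:29] + 3
    res <- cluster_perm_test(ga, gb, n_perm = 500, seed = s)
    nrow(res$clusters) >= 1 && min(res$clusters$p) < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  # p never drops below the estimator bound 1/(n_perm + 1)
  set.seed(30)
  ga <- matrix(rnorm(8 * nlag), 8, nlag); ga[, 10:20] <- ga[, 10:20] + 5
  res <- cluster_perm_test(ga, matrix(rnorm(8 * nlag), 8, nlag),
                           n_perm = 100, seed = 2)
  expect_true(all(res$clusters$p >= 1 / 101))

  expect_error(cluster_perm_test(a[1:4, ], a[1:4, ]), "5 participants")
})
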