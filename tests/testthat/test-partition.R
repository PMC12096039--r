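# helper: participants whose EEG is driven by a known subset of regressors
partition_fixture <- function(n_part = 3, n_trials = 4, n = 800,
                              kernels, reg_names, snr = 1, seed = 1) {
  lapply(seq_len(n_part), function(p) {
    lapply(seq_len(n_trials), function(ti) {
      set.seed(seed + 97 * p + ti)
      regs <- setNames(lapply(reg_names, function(nm) rnorm(n)), reg_names)
      simulate_trial(regs, kernels, condition_label("yes", "same"),
                     snr = snr, seed = seed + 1000 * p + ti)
    })
  })
}

test_that("delta r isolates the regressor that carries a kernel", {
  topo <- c(1, 0.6, 0.2, 1e-9)
  kern <- list(a = toy_kernel("a", c(60, 160), c(1, -1), topo))
  parts <- partition_fixture(kernels = kern, reg_names = c("a", "b"))
  res <- trf_partition(parts, conditions = NULL, reg_names = c("a", "b"),
                       reduced_sets = list(a = "a", b = "b"))
  dr_a <- mean(res$delta_r[1:2, , , "a"])
  dr_b <- mean(res$delta_r[, , , "b"])
  expect_gt(dr_a, 0.05)
  expect_lt(abs(dr_b), 0.02)
  expect_true(all(res$r_full >= -1 & res$r_full <= 1))
  expect_true(all(abs(res$delta_r) <= 2))
})

test_that("unknown exclusions and missing markers are rejected", {
  kern <- list(a = toy_kernel("a", 60, 1, c(1, 0.5)))
  parts <- partition_fixture(n_part = 2, n_trials = 2, n = 300,
                             kernels = kern, reg_names = c("a", "b"))
  expect_error(trf_partition(parts, reg_names = c("a", "b"),
                             reduced_sets = list(zz = "zz")), "zz")
  expect_error(bodypart_models(parts), "missing marker")
})

test_that("body-part models lateralize hand contributions and localize head ones", {
  sets <- bodypart_marker_sets()
  regs <- c(sets$full, "emg_neck")
  # channel layout: 1 = left central, 2 = right central, 3/4 = occipital
  kern <- list(
    `L Hand` = toy_kernel("L Hand", c(0, 80), c(1, -1), c(1e-9, 1, 1e-9, 1e-9)),
    `LF Head` = toy_kernel("LF Head", 70, 1, c(1e-9, 1e-9, 1, 0.8)))
  parts <- partition_fixture(n_part = 2, n_trials = 3, n = 600,
                             kernels = kern, reg_names = regs, snr = 2)
  res <- bodypart_models(parts)
  dr <- res$delta_r
  # left-hand kernel with right-central topography: contralateral peak
  expect_gt(mean(dr[2, , , "L Hand"]), mean(dr[1, , , "L Hand"]))
  expect_gt(mean(dr[2, , , "L Hand"]), 0.02)
  # head kernel appears at its occipital sites, not the hand site
  expect_gt(mean(dr[3:4, , , "head"]), 0.02)
  expect_gt(mean(dr[3:4, , , "head"]), mean(dr[1:2, , , "head"]))
  # empty effective exclusion: feet carried no kernel
  expect_lt(abs(mean(dr[, , , "L Foot"])), 0.02)
})

test_that("coordination encoding survives the velocity-sign control", {
  regs <- c("music", "self", "other", "coordination",
            "velocity_sign_self", "velocity_sign_other")
  topo <- c(1, 0.5)
  kc <- list(coordination = toy_kernel("coordination", c(30, 160), c(-1, 1),
                                       topo))
  parts <- partition_fixture(n_part = 2, n_trials = 3, n = 600,
                             kernels = kc, reg_names = regs, snr = 2)
  res <- coordination_control(parts)
  expect_gt(mean(res$delta_r[, , , "coordination"]), 0.02)

  # negative control: only the sign regressors carry kernels
  ks <- list(velocity_sign_self = toy_kernel("velocity_sign_self", 0, 1, topo),
             velocity_sign_other = toy_kernel("velocity_sign_other", 50, 1,
                                              topo))
  parts0 <- partition_fixture(n_part = 2, n_trials = 3, n = 600,
                              kernels = ks, reg_names = regs, snr = 2)
  res0 <- coordination_control(parts0)
  expect_lt(abs(mean(res0$delta_r[, , , "coordination"])), 0.02)

  expect_error(coordination_control(
    partition_fixture(n_part = 2, n_trials = 2, n = 300,
                      kernels = kc, reg_names = c("music", "coordination"))),
    "velocity sign")
})
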