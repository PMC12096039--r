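# shared fixtures built in code ---------------------------------------------

# small layout-independent kernel on a given number of channels
toy_kernel <- function(name, lat, amp, topo, width = 30) {
  kernel_spec(name, data.frame(latency_ms = lat, amplitude = amp,
                               width_ms = width), topo)
}

# smooth band-limited random regressor (unit variance)
smooth_regressor <- function(n, fs = 100, cutoff = 8) {
  bf <- signal::butter(2, cutoff / (fs / 2), "low")
  x <- signal::filtfilt(bf, rnorm(n))
  (x - mean(x)) / sd(x)
}

# a tiny trial_record with known kernels on nchan channels
toy_trial <- function(kernels, n = 1500, snr = Inf, seed = 1, fs = 100,
                      regressors = NULL, condition = condition_label("yes", "same")) {
  window <- lag_window(fs = fs)
  if (is.null(regressors)) {
    set.seed(seed * 131 + 7)
    regressors <- setNames(
      lapply(seq_along(kernels), function(i) smooth_regressor(n, fs)),
      names(kernels))
  }
  simulate_trial(regressors, kernels, condition, snr = snr, seed = seed,
                 window = window)
}

# scaled-down session config used by simulation-heavy tests
small_config <- function(...) {
  session_config(duration_s = 15, blocks = 2, ...)
}

# participants list (flattened) for a set of dyads
flatten_sessions <- function(sessions) {
  unlist(lapply(sessions, `[[`, "participants"), recursive = FALSE)
}

expect_invalid <- function(expr) {
  expect_error(expr, class = "dyadtrf_invalid_argument")
}
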