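# Ground-truth response kernels for the simulator ---------------------------

#' TRF lag window
#'
#' The default window spans -250 to +300 ms at 100 Hz, i.e. integer sample
#' lags -25..30 (56 lags). Negative lags let the model capture anticipatory
#' (pre-event) EEG activity.
#'
#' @param t_min_ms,t_max_ms window bounds in ms.
#' @param fs sampling rate, Hz.
#' @return list with `t_min_ms`, `t_max_ms`, `fs`, `lags` (samples),
#'   `lag_ms` (lag times in ms).
#' @export
lag_window <- function(t_min_ms = -250, t_max_ms = 300, fs = 100) {
  if (t_max_ms <= t_min_ms) stop_invalid("t_max_ms must exceed t_min_ms")
  lags <- seq.int(round(t_min_ms * fs / 1000), round(t_max_ms * fs / 1000))
  list(t_min_ms = t_min_ms, t_max_ms = t_max_ms, fs = fs,
       lags = lags, lag_ms = lags * 1000 / fs)
}

#' Specify a ground-truth temporal kernel
#'
#' A kernel is a sum of Gaussian lobes, each with a latency (ms), a signed
#' amplitude and a width (FWHM, ms), plus a scalp topography that projects
#' it onto the channel array.
#'
#' @param name regressor name the kernel responds to.
#' @param peaks data.frame with columns `latency_ms`, `amplitude`, `width_ms`.
#' @param topography numeric channel-weight vector.
#' @return object of class `kernel_spec`.
#' @export
kernel_spec <- function(name, peaks, topography) {
  stopifnot(is.data.frame(peaks),
            all(c("latency_ms", "amplitude", "width_ms") %in% names(peaks)))
  if (any(peaks$latency_ms < -250 | peaks$latency_ms > 300))
    stop_invalid("kernel '", name, "': peak latency outside [-250, 300] ms")
  if (all(topography == 0))
    stop_invalid("kernel '", name, "': topography is all zero")
  structure(list(name = name, peaks = peaks, topography = topography),
            class = "kernel_spec")
}

#' Sample a kernel's waveform on the lag grid
#' @param spec a [kernel_spec()].
#' @param window a [lag_window()].
#' @return numeric vector, one value per lag.
#' @export
kernel_waveform <- function(spec, window = lag_window()) {
  sigma <- spec$peaks$width_ms / (2 * sqrt(2 * log(2)))
  w <- numeric(length(window$lag_ms))
  for (i in seq_len(nrow(spec$peaks)))
    w <- w + spec$peaks$amplitude[i] *
      exp(-(window$lag_ms - spec$peaks$latency_ms[i])^2 / (2 * sigma[i]^2))
  w
}

peak_df <- function(lat, amp, width = 30) {
  data.frame(latency_ms = lat, amplitude = amp, width_ms = width)
}

#' Default ground-truth kernel set
#'
#' Latencies follow the canonical evoked-response morphologies the encoding
#' model is expected to recover: music (auditory P50-N100-P200 analogue at
#' Fz) +60/+120/+200 ms; self-movement (movement-related cortical potential
#' at C3/C4) -100/0/+80 ms; other-movement (occipital visual response, Oz)
#' +70/+160 ms; coordination (occipital quadriphasic, Oz) -180/-90/+30/+160
#' ms. Ocular and muscular leakage channels are zero-lag impulses whose
#' amplitude is `artifact_gain` times the neural kernels, reflecting the
#' orders-of-magnitude dominance of peripheral signals over brain signals.
#'
#' @param layout electrode layout data.frame.
#' @param artifact_gain amplitude multiplier for EOG/EMG impulse kernels.
#' @param lobe_width_ms FWHM of each Gaussian lobe, ms.
#' @return named list of `kernel_spec` objects.
#' @export
kernel_presets <- function(layout = layout_1010_64(), artifact_gain = 100,
                           lobe_width_ms = 30) {
  topo <- function(centers, signs = 1) gaussian_topography(layout, centers,
                                                           signs = signs)
  imp <- function(amp) peak_df(0, amp, 12)  # near-impulse at lag 0
  list(
    music = kernel_spec("music",
      peak_df(c(60, 120, 200), c(1, -1, 1), lobe_width_ms), topo("Fz")),
    self = kernel_spec("self",
      peak_df(c(-100, 0, 80), c(-1, 1, -1), lobe_width_ms),
      topo(c("C3", "C4"))),
    other = kernel_spec("other",
      peak_df(c(70, 160), c(1, -1), lobe_width_ms), topo("Oz")),
    coordination = kernel_spec("coordination",
      peak_df(c(-180, -90, 30, 160), c(-1, 1, -1, 1), lobe_width_ms),
      topo("Oz")),
    eog_left = kernel_spec("eog_left", imp(artifact_gain), topo("AF7")),
    eog_right = kernel_spec("eog_right", imp(artifact_gain), topo("AF8")),
    emg_cheek = kernel_spec("emg_cheek", imp(artifact_gain),
      topo(c("T7", "T8"))),
    emg_neck = kernel_spec("emg_neck", imp(artifact_gain),
      topo(c("O1", "O2", "Iz", "P9", "P10")))
  )
}

#' Convolve a regressor with a lagged kernel
#'
#' Returns the time series `sum_l k(l) * x(t - l)` evaluated on the same
#' sample grid as `x` (edges zero-padded), i.e. the noiseless single-channel
#' contribution of one regressor under the forward model.
#'
#' @param x regressor series.
#' @param kernel numeric kernel sampled on `window$lags`.
#' @param window a [lag_window()].
#' @return numeric vector, `length(x)`.
#' @export
convolve_kernel <- function(x, kernel, window = lag_window()) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_along(window$lags)) {
    l <- window$lags[i]
    if (kernel[i] == 0) next
    src <- seq_len(n) - l
    ok <- src >= 1L & src <= n
    out[ok] <- out[ok] + kernel[i] * x[src[ok]]
  }
  out
}
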