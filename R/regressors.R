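# Model input variables ("Step 1"-style feature extraction) -----------------

#' Broadband spectral flux of an audio waveform
#'
#' The waveform is passed through a bank of 128 fourth-order gammatone
#' filters with log-spaced centre frequencies from 100 to 8000 Hz. Per band,
#' the envelope is the analytic-signal magnitude; its first time derivative
#' is (by default) half-wave rectified, then averaged across bands and
#' resampled to the EEG rate. Filtering is done in the frequency domain:
#' the complex gammatone response (1 + i(f - fc)/b)^-4, b = 1.019 ERB(fc),
#' is applied to the analytic spectrum, so each band's inverse FFT yields
#' the band envelope directly.
#'
#' @param audio numeric waveform.
#' @param fs_audio audio sampling rate, Hz (>= 16 kHz).
#' @param n_bands number of gammatone bands.
#' @param f_lo,f_hi band centre-frequency range, Hz.
#' @param rectify half-wave rectify the envelope derivative (track increases
#'   in spectral power only); set `FALSE` for the signed derivative.
#' @param fs_out output sampling rate, Hz.
#' @return nonnegative (when `rectify`) series at `fs_out`.
#' @export
spectral_flux <- function(audio, fs_audio, n_bands = 128, f_lo = 100,
                          f_hi = 8000, rectify = TRUE, fs_out = 100) {
  if (fs_audio < 16000) stop_invalid("fs_audio must be at least 16 kHz")
  n <- length(audio)
  if (n < 0.05 * fs_audio)
    stop_invalid("audio shorter than the filter startup time")
  nfft <- 2^ceiling(log2(n))
  X <- stats::fft(c(audio, numeric(nfft - n)))
  # analytic spectrum: keep positive frequencies (doubled), zero the rest
  Xa <- X
  half <- nfft %/% 2
  Xa[2:half] <- 2 * Xa[2:half]
  Xa[(half + 2):nfft] <- 0
  freqs <- (seq_len(nfft) - 1) * fs_audio / nfft

  fc <- exp(seq(log(f_lo), log(f_hi), length.out = n_bands))
  flux <- numeric(n)
  for (b in seq_len(n_bands)) {
    bw <- 1.019 * (24.7 + fc[b] / 9.265)  # ERB-rate bandwidth
    H <- (1 + 1i * (freqs - fc[b]) / bw)^(-4)
    env <- Mod(stats::fft(Xa * H, inverse = TRUE))[seq_len(n)] / nfft
    d <- diff(env) * fs_audio
    d <- c(d[1], d)
    if (rectify) d <- pmax(d, 0)
    flux <- flux + d
  }
  flux <- flux / n_bands
  out <- resample_trim(flux, fs_audio, fs_out, 0, n / fs_audio)
  if (rectify) out <- pmax(out, 0)  # clip resampling overshoot
  out
}

#' Velocity magnitude of a 1-D position series
#'
#' First difference scaled by the sampling rate, absolute value; the first
#' value is repeated so the output length matches the input.
#'
#' @param position position series.
#' @param fs sampling rate, Hz.
#' @return nonnegative series of the same length.
#' @export
velocity_magnitude <- function(position, fs) {
  if (length(position) < 2) stop_invalid("position needs at least 2 samples")
  v <- abs(diff(position)) * fs
  c(v[1], v)
}

#' 3-D speed of a marker
#' @param xyz time x 3 matrix of positions.
#' @param fs sampling rate, Hz.
#' @return nonnegative series, same number of rows.
#' @export
marker_speed <- function(xyz, fs) {
  stopifnot(ncol(xyz) == 3)
  d <- diff(xyz) * fs
  v <- sqrt(rowSums(d^2))
  c(v[1], v)
}

#' Sign series with zero carry-forward
#'
#' `sign()` of a velocity series where exact zeros inherit the previous
#' nonzero sign (+1 at the start), so the output stays in {-1, +1}.
#'
#' @param v numeric series.
#' @return series of -1/+1.
#' @export
sign_series <- function(v) {
  s <- sign(v)
  if (s[1] == 0) s[1] <- 1
  z <- which(s == 0)
  for (i in z) s[i] <- s[i - 1]
  s
}

#' Interpersonal coordination sign product
#'
#' +1 when the two dancers' bounce velocities share a sign (in-phase), -1
#' when they oppose (anti-phase).
#'
#' @param v_self,v_other bounce velocity series of the two dancers.
#' @return series in {-1, +1}.
#' @export
coordination_signal <- function(v_self, v_other) {
  if (length(v_self) != length(v_other))
    stop_invalid("velocity series must have equal length")
  sign_series(v_self) * sign_series(v_other)
}

#' Count in-/anti-phase episode transitions
#'
#' The raw coordination sign product chatters briefly whenever the two
#' dancers' zero crossings are slightly offset; sustained coordination
#' states are recovered by smoothing the product over `smooth_s` seconds
#' and counting sign changes of the smoothed series.
#'
#' @param coordination series in {-1, +1}.
#' @param fs sampling rate, Hz.
#' @param smooth_s smoothing window, s.
#' @return integer count of episode transitions.
#' @export
coordination_episode_count <- function(coordination, fs, smooth_s = 0.5) {
  k <- max(1L, round(smooth_s * fs))
  sm <- stats::filter(coordination, rep(1 / k, k), sides = 2)
  s <- sign(sm[!is.na(sm)])
  s <- s[s != 0]
  sum(diff(s) != 0)
}

#' Principal movements of full-body kinematics
#'
#' Mean-centred PCA over the pooled posture series; component scores are
#' low-pass filtered below 6 Hz (Butterworth order 2, zero-phase) to improve
#' their signal-to-noise ratio.
#'
#' @param postures time x 66 posture matrix (rows pooled across trials and
#'   participants).
#' @param n_keep number of principal movements to return.
#' @param fs sampling rate, Hz.
#' @param lp_hz score low-pass cutoff, Hz (`NULL` to skip).
#' @return list of class `principal_movements` with `basis` (66 x k,
#'   orthonormal columns), `scores` (time x k), `variance_explained`
#'   (proportions, nonincreasing).
#' @export
pca_movements <- function(postures, n_keep = 15, fs = 100, lp_hz = 6) {
  if (nrow(postures) <= ncol(postures))
    stop_invalid("need more time samples than posture dimensions")
  pc <- stats::prcomp(postures, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  rank <- sum(pc$sdev > pc$sdev[1] * 1e-10)
  if (rank < n_keep) {
    warning("input rank ", rank, " < n_keep; returning ", rank, " components")
    n_keep <- rank
  }
  scores <- pc$x[, seq_len(n_keep), drop = FALSE]
  if (!is.null(lp_hz) && lp_hz < fs / 2) {
    bf <- signal::butter(2, lp_hz / (fs / 2), "low")
    for (k in seq_len(ncol(scores)))
      scores[, k] <- signal::filtfilt(bf, scores[, k])
  }
  structure(list(basis = pc$rotation[, seq_len(n_keep), drop = FALSE],
                 scores = scores,
                 variance_explained = ve[seq_len(n_keep)]),
            class = "principal_movements")
}

#' Standardize regressor series per participant
#'
#' Divides every series by its participant-level standard deviation computed
#' across all of that participant's concatenated trials; means are left
#' untouched. This is the per-participant normalization applied to all model
#' variables before fitting.
#'
#' @param trials_by_participant list (participants) of lists (trials) of
#'   named series lists.
#' @return list with `trials` (same structure, scaled) and `scales`
#'   (participant x series matrix of the SDs divided out).
#' @export
standardize_regressors <- function(trials_by_participant) {
  out <- trials_by_participant
  nms <- names(trials_by_participant[[1]][[1]])
  scales <- matrix(NA_real_, length(trials_by_participant), length(nms),
                   dimnames = list(NULL, nms))
  for (p in seq_along(trials_by_participant)) {
    for (nm in nms) {
      pooled <- unlist(lapply(trials_by_participant[[p]], `[[`, nm),
                       use.names = FALSE)
      s <- stats::sd(pooled)
      if (!is.finite(s) || s == 0)
        stop("series '", nm, "' has zero SD for participant ", p)
      scales[p, nm] <- s
      for (ti in seq_along(trials_by_participant[[p]]))
        out[[p]][[ti]][[nm]] <- trials_by_participant[[p]][[ti]][[nm]] / s
    }
  }
  list(trials = out, scales = scales)
}

#' Standardize all regressors of a dyad session
#' @param session a `dyad_session`.
#' @return the session with per-participant standardized regressors and a
#'   `scales` element.
#' @export
standardize_session <- function(session) {
  regs <- lapply(session$participants, function(tr) lapply(tr, `[[`, "regressors"))
  std <- standardize_regressors(regs)
  for (p in seq_along(session$participants))
    for (ti in seq_along(session$participants[[p]]))
      session$participants[[p]][[ti]]$regressors <- std$trials[[p]][[ti]]
  session$scales <- std$scales
  session
}

#' Resample a series and trim it to a time span
#'
#' Fourier-domain resampling (exact for band-limited content) with
#' reflection padding to suppress edge ringing, then trimming to
#' `[t_start, t_end)`; output length is `round((t_end - t_start) * fs_out)`.
#'
#' @param x numeric series.
#' @param fs_in input rate, Hz (>= `fs_out`).
#' @param fs_out output rate, Hz.
#' @param t_start,t_end span to keep, s (relative to the first sample).
#' @return resampled, trimmed series.
#' @export
resample_trim <- function(x, fs_in, fs_out = 100, t_start = 0,
                          t_end = length(x) / fs_in) {
  if (fs_out > fs_in) stop_invalid("fs_in must be >= fs_out")
  if (t_end <= t_start) stop_invalid("t_end must exceed t_start")
  n <- length(x)
  if (fs_in == fs_out) {
    y <- x
  } else {
    pad <- min(n - 1L, ceiling(fs_in))  # ~1 s reflection padding
    xp <- c(rev(x[2:(pad + 1)]), x, rev(x[(n - pad):(n - 1)]))
    np <- length(xp)
    m <- round(np * fs_out / fs_in)
    X <- stats::fft(xp)
    Y <- complex(length.out = m)
    keep <- min(np, m)
    kh <- keep %/% 2
    Y[1:(kh + 1)] <- X[1:(kh + 1)]
    if (kh > 0) Y[(m - kh + 1):m] <- X[(np - kh + 1):np]
    y_full <- Re(stats::fft(Y, inverse = TRUE)) / np
    pad_out <- round(pad * fs_out / fs_in)
    y <- y_full[(pad_out + 1):(pad_out + round(n * fs_out / fs_in))]
  }
  i0 <- round(t_start * fs_out)
  len <- round((t_end - t_start) * fs_out)
  if (i0 + len > length(y)) len <- length(y) - i0
  y[(i0 + 1):(i0 + len)]
}

#' Synthesize a tone burst
#'
#' A pure tone with raised-cosine on/off ramps embedded in silence; the
#' simulator's stand-in for a musical note.
#'
#' @param freq_hz tone frequency.
#' @param t_on burst onset time, s.
#' @param burst_s burst duration, s.
#' @param total_s total waveform duration, s.
#' @param fs sampling rate, Hz.
#' @param ramp_s ramp duration, s.
#' @return numeric waveform.
#' @export
tone_burst <- function(freq_hz = 1000, t_on = 0.5, burst_s = 0.1,
                       total_s = 2, fs = 16000, ramp_s = 0.005) {
  t <- (seq_len(round(total_s * fs)) - 1) / fs
  env <- numeric(length(t))
  inb <- t >= t_on & t < t_on + burst_s
  env[inb] <- 1
  ramp_in <- t >= t_on & t < t_on + ramp_s
  env[ramp_in] <- 0.5 * (1 - cos(pi * (t[ramp_in] - t_on) / ramp_s))
  ramp_out <- t >= t_on + burst_s - ramp_s & t < t_on + burst_s
  env[ramp_out] <- 0.5 * (1 - cos(pi * (t_on + burst_s - t[ramp_out]) / ramp_s))
  env * sin(2 * pi * freq_hz * t)
}

# Minimal 16-bit PCM WAV I/O -------------------------------------------------

#' Write a mono waveform as 16-bit PCM WAV
#' @param x waveform in [-1, 1] (clipped otherwise).
#' @param path output path.
#' @param fs sampling rate, Hz.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, fs) {
  pcm <- as.integer(round(pmax(-1, pmin(1, x)) * 32767))
  con <- file(path, "wb"); on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#' @param path file path.
#' @return list with `x` (waveform in [-1, 1], channels averaged if stereo)
#'   and `fs`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, integer(), 1, size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  fs <- NULL; n_chan <- 1L; bits <- 16L; x <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), 2, size = 2, endian = "little")
      n_chan <- fmt[2]
      fs <- readBin(con, integer(), 1, size = 4, endian = "little")
      readBin(con, integer(), 1, size = 4, endian = "little")
      readBin(con, integer(), 1, size = 2, endian = "little")
      bits <- readBin(con, integer(), 1, size = 2, endian = "little")
      if (sz > 16) readBin(con, raw(), sz - 16)
    } else if (id == "data") {
      if (bits != 16L) stop("only 16-bit PCM supported")
      pcm <- readBin(con, integer(), sz / 2, size = 2, endian = "little",
                     signed = TRUE)
      if (length(pcm) * 2L < sz)
        stop("truncated WAV data chunk in ", path)
      x <- pcm / 32768
      if (n_chan > 1) {
        x <- rowMeans(matrix(x, ncol = n_chan, byrow = TRUE))
      }
      break
    } else readBin(con, raw(), sz + sz %% 2)
  }
  if (is.null(x) || is.null(fs)) stop("no PCM data found in ", path)
  list(x = x, fs = fs)
}
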