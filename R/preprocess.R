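# EEG cleaning steps ---------------------------------------------------------

#' Zero-phase 1-8 Hz bandpass
#'
#' Butterworth order 3, applied forward and backward (zero phase), the
#' passband used throughout the analysis; the caller downsamples to 100 Hz
#' afterwards with [resample_trim()].
#'
#' @param eeg time x channel matrix (or vector).
#' @param fs sampling rate, Hz (> 16).
#' @param band passband edges, Hz.
#' @param order filter order.
#' @return filtered matrix of the same shape.
#' @export
eeg_bandpass <- function(eeg, fs, band = c(1, 8), order = 3) {
  if (fs <= 16) stop_invalid("fs must exceed 16 Hz for a 1-8 Hz passband")
  bf <- signal::butter(order, band / (fs / 2), "pass")
  if (is.null(dim(eeg))) return(signal::filtfilt(bf, eeg))
  apply(eeg, 2, function(ch) signal::filtfilt(bf, ch))
}

#' Flag faulty or noisy channels
#'
#' A channel is flagged when any of three criteria fires: a flat line
#' longer than `flat_s` seconds (successive differences below `flat_eps`
#' times the channel SD), a best interchannel correlation below `corr_min`
#' (max absolute correlation with any other channel, median across windows
#' of `corr_window_s` seconds), or any amplitude metric (mean, SD,
#' peak-to-peak) more than `z_max` SDs from the scalp average.
#'
#' @param eeg time x channel matrix.
#' @param fs sampling rate, Hz.
#' @param labels optional channel labels.
#' @param flat_s flatline duration threshold, s.
#' @param corr_min minimum acceptable neighbor correlation.
#' @param z_max amplitude z-score threshold.
#' @param flat_eps flatness tolerance relative to channel SD.
#' @param corr_window_s correlation window length, s.
#' @return data.frame, one row per channel: `label`, the three logical
#'   flags, `bad`, and the metrics behind them.
#' @export
flag_bad_channels <- function(eeg, fs, labels = NULL, flat_s = 5,
                              corr_min = 0.8, z_max = 3, flat_eps = 1e-8,
                              corr_window_s = 5) {
  nch <- ncol(eeg)
  if (nch < 4) stop_invalid("need at least 4 channels")
  if (is.null(labels)) labels <- paste0("ch", seq_len(nch))

  # flat runs
  flat_run <- vapply(seq_len(nch), function(c) {
    s <- stats::sd(eeg[, c])
    thr <- if (s > 0) flat_eps * s else Inf
    r <- rle(c(abs(diff(eeg[, c])) <= thr, FALSE))
    if (any(r$values)) max(r$lengths[r$values]) / fs else 0
  }, numeric(1))
  flat_flag <- flat_run > flat_s
  # an all-constant channel has sd 0: count as fully flat
  allflat <- apply(eeg, 2, function(x) stats::sd(x) == 0)
  flat_run[allflat] <- nrow(eeg) / fs
  flat_flag <- flat_flag | (allflat & nrow(eeg) / fs > flat_s)

  # windowed max-abs interchannel correlation, median over windows
  win <- max(2L, round(corr_window_s * fs))
  starts <- seq(1L, max(1L, nrow(eeg) - win + 1L), by = win)
  best_cor <- matrix(NA_real_, length(starts), nch)
  for (w in seq_along(starts)) {
    seg <- eeg[starts[w]:min(nrow(eeg), starts[w] + win - 1L), , drop = FALSE]
    cc <- abs(suppressWarnings(stats::cor(seg)))
    diag(cc) <- NA
    best_cor[w, ] <- apply(cc, 2, function(col) {
      m <- suppressWarnings(max(col, na.rm = TRUE))
      if (is.finite(m)) m else 0
    })
  }
  med_cor <- apply(best_cor, 2, stats::median, na.rm = TRUE)
  med_cor[!is.finite(med_cor)] <- 0
  corr_flag <- med_cor < corr_min

  # amplitude metrics vs scalp distribution
  met <- cbind(mean = colMeans(eeg),
               sd = apply(eeg, 2, stats::sd),
               p2p = apply(eeg, 2, function(x) diff(range(x))))
  z <- abs(scale(met))
  amp_flag <- apply(z > z_max, 1, any)

  data.frame(label = labels, flatline = flat_flag, low_correlation = corr_flag,
             amplitude_outlier = amp_flag,
             bad = flat_flag | corr_flag | amp_flag,
             flat_run_s = flat_run, max_neighbor_cor = med_cor,
             z_mean = z[, "mean"], z_sd = z[, "sd"], z_p2p = z[, "p2p"],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Common average reference
#'
#' Subtracts the mean over good channels from every channel; bad channels
#' are excluded from the reference so their noise does not leak into it.
#'
#' @param eeg time x channel matrix.
#' @param bad integer or logical index of bad channels (optional).
#' @return rereferenced matrix.
#' @export
rereference_car <- function(eeg, bad = integer()) {
  nch <- ncol(eeg)
  good <- setdiff(seq_len(nch), which(if (is.logical(bad)) bad else
    seq_len(nch) %in% bad))
  if (length(good) < 2) stop("need at least 2 good channels for CAR")
  eeg - rowMeans(eeg[, good, drop = FALSE])
}

#' Interpolate bad channels from spatial neighbors
#'
#' Each bad channel is replaced by the average of the good channels within
#' `radius_mm` on the layout; if none lies within the radius, the radius is
#' widened to the nearest good channel with a warning.
#'
#' @param eeg time x channel matrix (columns ordered as `layout`).
#' @param bad indices of bad channels.
#' @param layout layout data.frame ([layout_1010_64()]).
#' @param radius_mm neighborhood radius, mm.
#' @return matrix with bad channels replaced.
#' @export
interpolate_bad <- function(eeg, bad, layout, radius_mm = 20) {
  if (!length(bad)) return(eeg)
  d <- layout_distances(layout)
  good <- setdiff(seq_len(ncol(eeg)), bad)
  if (!length(good)) stop("no good channels available for interpolation")
  for (b in bad) {
    nb <- good[d[b, good] <= radius_mm]
    if (!length(nb)) {
      nearest <- good[which.min(d[b, good])]
      warning("no good neighbor within ", radius_mm, " mm of ",
              layout$label[b], "; using nearest (",
              round(d[b, nearest], 1), " mm)")
      nb <- nearest
    }
    eeg[, b] <- rowMeans(eeg[, nb, drop = FALSE])
  }
  eeg
}

#' Preprocess a continuous EEG recording
#'
#' Bandpass (1-8 Hz), bad-channel flagging, common average reference over
#' good channels, downsampling to `fs_out`, and spatial interpolation of
#' the flagged channels. A `hook` function applied after rereferencing
#' accommodates external artifact-correction stages (e.g. subspace
#' reconstruction or ICA-based ocular cleaning), which are out of scope
#' here.
#'
#' @param eeg time x channel matrix.
#' @param fs input sampling rate, Hz.
#' @param layout electrode layout.
#' @param fs_out output rate, Hz.
#' @param hook optional `function(eeg, fs)` applied after rereferencing.
#' @return list with `eeg` (time x channel at `fs_out`), `fs`, `quality`
#'   (the [flag_bad_channels()] table).
#' @export
preprocess_eeg <- function(eeg, fs, layout = layout_1010_64(), fs_out = 100,
                           hook = NULL) {
  eeg <- eeg_bandpass(eeg, fs)
  quality <- flag_bad_channels(eeg, fs, labels = layout$label)
  bad <- which(quality$bad)
  eeg <- rereference_car(eeg, bad)
  if (!is.null(hook)) eeg <- hook(eeg, fs)
  if (fs_out != fs)
    eeg <- apply(eeg, 2, resample_trim, fs_in = fs, fs_out = fs_out)
  eeg <- interpolate_bad(eeg, bad, layout)
  list(eeg = eeg, fs = fs_out, quality = quality)
}
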