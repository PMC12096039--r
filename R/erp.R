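# Event-related potentials and cluster statistics ---------------------------

#' Detect event onsets as local maxima of a feature series
#'
#' Interior samples strictly greater than their left neighbor and greater
#' than or equal to the right one (plateaus keep their first sample, the
#' following samples of the plateau are not reported). With `salience_sd`
#' set, only peaks exceeding `mean + salience_sd * SD` of the trial series
#' are kept (the acoustic onsets use 3).
#'
#' @param series feature series (spectral flux, velocity magnitude, ...).
#' @param fs sampling rate, Hz.
#' @param salience_sd salience threshold in trial SDs, or NULL for none.
#' @return data.frame with `sample`, `time_s`, `amplitude` (possibly empty).
#' @export
detect_onsets <- function(series, fs, salience_sd = NULL) {
  n <- length(series)
  if (n <= 2) stop_invalid("series too short for peak detection")
  peaks <- integer()
  i <- 2L
  while (i <= n - 1L) {
    if (series[i] > series[i - 1L]) {
      j <- i
      while (j < n && series[j + 1L] == series[i]) j <- j + 1L
      if (j < n && series[j + 1L] < series[i]) peaks <- c(peaks, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!is.null(salience_sd) && length(peaks)) {
    thr <- mean(series) + salience_sd * stats::sd(series)
    peaks <- peaks[series[peaks] > thr]
  }
  data.frame(sample = peaks, time_s = (peaks - 1) / fs,
             amplitude = series[peaks])
}

#' Transitions of the coordination signal, with self/other attribution
#'
#' Onsets are the sign flips of the in-/anti-phase coordination series. A
#' flip is attributed to the dancer whose bounce velocity changes sign
#' within `tol_samples` of it: `self`, `other`, `both` (excluded from
#' self/other contrasts) or `none`.
#'
#' @param coordination series in {-1, +1}.
#' @param v_self,v_other the two bounce velocity series.
#' @param fs sampling rate, Hz.
#' @param tol_samples attribution alignment tolerance, samples.
#' @return data.frame with `sample`, `time_s`, `transition`
#'   (`to_inphase`/`to_antiphase`), `attribution`.
#' @export
coordination_transitions <- function(coordination, v_self, v_other, fs,
                                     tol_samples = 1L) {
  if (!all(coordination %in% c(-1, 1)))
    stop_invalid("coordination must be a -1/+1 series")
  flips <- which(diff(coordination) != 0) + 1L
  if (!length(flips))
    return(data.frame(sample = integer(), time_s = numeric(),
                      transition = character(), attribution = character()))
  ss <- sign_series(v_self); so <- sign_series(v_other)
  fs_self <- which(diff(ss) != 0) + 1L
  fs_other <- which(diff(so) != 0) + 1L
  near <- function(i, set) length(set) && min(abs(set - i)) <= tol_samples
  attribution <- vapply(flips, function(i) {
    s <- near(i, fs_self); o <- near(i, fs_other)
    if (s && o) "both" else if (s) "self" else if (o) "other" else "none"
  }, character(1))
  data.frame(sample = flips, time_s = (flips - 1) / fs,
             transition = ifelse(coordination[flips] > 0,
                                 "to_inphase", "to_antiphase"),
             attribution = attribution)
}

#' Epoch EEG around event onsets
#'
#' Cuts epochs spanning the TRF lag window around each onset and baseline
#' corrects them: `prestim` subtracts the mean of the pre-onset interval
#' (external stimuli: music, partner movement), `whole_epoch` subtracts the
#' mean of the entire epoch (internally initiated events: self movement,
#' coordination). Events too close to the trial edges are dropped.
#'
#' @param eeg time x channel matrix.
#' @param onset_samples event sample indices.
#' @param window a [lag_window()].
#' @param baseline "prestim" or "whole_epoch".
#' @return object of class `epoch_set`: list with `epochs` (event x time x
#'   channel array), `lag_ms`, `baseline`, `kept` (indices of retained
#'   events), `dropped` (count).
#' @export
epoch_eeg <- function(eeg, onset_samples, window = lag_window(),
                      baseline = c("prestim", "whole_epoch")) {
  baseline <- match.arg(baseline)
  if (is.null(dim(eeg))) eeg <- matrix(eeg, ncol = 1)
  n <- nrow(eeg); L <- length(window$lags)
  ok <- onset_samples + min(window$lags) >= 1 &
        onset_samples + max(window$lags) <= n
  kept <- which(ok)
  if (!length(kept)) {
    warning("no events leave room for a full epoch window")
    return(structure(list(epochs = array(0, c(0, L, ncol(eeg))),
                          lag_ms = window$lag_ms, baseline = baseline,
                          kept = integer(), dropped = length(onset_samples)),
                     class = "epoch_set"))
  }
  ep <- array(NA_real_, c(length(kept), L, ncol(eeg)))
  base_idx <- if (baseline == "prestim") which(window$lag_ms <= 0) else
    seq_len(L)
  for (e in seq_along(kept)) {
    rows <- onset_samples[kept[e]] + window$lags
    seg <- eeg[rows, , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg[base_idx, , drop = FALSE]))
    ep[e, , ] <- seg
  }
  structure(list(epochs = ep, lag_ms = window$lag_ms, baseline = baseline,
                 kept = kept, dropped = sum(!ok)),
            class = "epoch_set")
}

#' Split events into lowest- and highest-amplitude quantile groups
#'
#' The soft/loud and slow/fast contrasts use the events whose evoking
#' amplitude falls at or below the `q` quantile and at or above the `1 - q`
#' quantile.
#'
#' @param amplitudes event amplitudes.
#' @param q quantile (default 0.20).
#' @return list with `low` and `high` integer index vectors (disjoint).
#' @export
split_extremes <- function(amplitudes, q = 0.20) {
  if (length(amplitudes) < 10) stop_invalid("need at least 10 events")
  lo <- stats::quantile(amplitudes, q, names = FALSE)
  hi <- stats::quantile(amplitudes, 1 - q, names = FALSE)
  list(low = which(amplitudes <= lo), high = which(amplitudes >= hi))
}

# contiguous sign-coherent suprathreshold clusters of a t series
t_clusters <- function(tvals, thr) {
  code <- sign(tvals) * (abs(tvals) > thr)
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0
  if (!any(keep)) return(data.frame(start = integer(), end = integer(),
                                    mass = numeric()))
  cs <- cumsum(tvals)
  s <- starts[keep]; e <- ends[keep]
  data.frame(start = s, end = e,
             mass = cs[e] - ifelse(s > 1, cs[s - 1], 0))
}

# fast path for permutations: only the maximum absolute cluster mass
max_cluster_mass <- function(tvals, thr) {
  code <- sign(tvals) * (abs(tvals) > thr)
  r <- rle(code)
  keep <- r$values != 0
  if (!any(keep)) return(0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cs <- cumsum(tvals)
  s <- starts[keep]; e <- ends[keep]
  max(abs(cs[e] - ifelse(s > 1, cs[s - 1], 0)))
}

#' Cluster-based permutation test for a paired ERP contrast
#'
#' Two-stage statistics at a single channel: per time point, a paired
#' t-statistic across participants (group A mean epoch minus group B mean
#' epoch); clusters are contiguous sign-coherent runs where |t| exceeds the
#' two-sided pointwise threshold (p < `cluster_alpha` at n-1 df); the
#' cluster mass is the summed t. The null distribution is the maximum
#' absolute cluster mass over random sign flips of the participant-wise
#' differences; corrected p = (1 + #{null >= observed}) / (1 + n_perm).
#'
#' @param group_a,group_b participant x time matrices of per-participant
#'   mean epochs at the channel of interest.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @param cluster_alpha pointwise two-sided cluster-forming alpha.
#' @param lag_ms optional time axis for reporting, ms.
#' @return object of class `cluster_result`: list with `clusters`
#'   (data.frame: start/end sample, start/end ms, mass, p), `t` (observed
#'   series), `threshold`, `n_perm`, `null_max` (permutation distribution).
#' @export
cluster_perm_test <- function(group_a, group_b, n_perm = 1000, seed = 1,
                              cluster_alpha = 0.05, lag_ms = NULL) {
  stopifnot(all(dim(group_a) == dim(group_b)))
  n <- nrow(group_a)
  if (n < 5) stop("need at least 5 participants with both groups")
  d <- group_a - group_b
  nt <- ncol(d)
  thr <- stats::qt(1 - cluster_alpha / 2, df = n - 1)

  t_of <- function(means, ssq) {
    v <- (ssq - n * means^2) / (n - 1)
    means / sqrt(pmax(v, .Machine$double.eps) / n)
  }
  ssq <- colSums(d^2)
  t_obs <- t_of(colMeans(d), ssq)
  obs <- t_clusters(t_obs, thr)

  old <- local_seed(seed); on.exit(restore_seed(old), add = TRUE)
  signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  perm_means <- signs %*% d / n
  null_max <- vapply(seq_len(n_perm), function(k)
    max_cluster_mass(t_of(perm_means[k, ], ssq), thr), numeric(1))

  if (nrow(obs)) {
    obs$p <- vapply(obs$mass, function(m)
      (1 + sum(null_max >= abs(m))) / (1 + n_perm), numeric(1))
    if (!is.null(lag_ms)) {
      obs$start_ms <- lag_ms[obs$start]; obs$end_ms <- lag_ms[obs$end]
    }
  } else {
    obs$p <- numeric(0)
  }
  structure(list(clusters = obs, t = t_obs, threshold = thr,
                 n_perm = n_perm, null_max = null_max),
            class = "cluster_result")
}

#' Run-level permutation p-value
#'
#' The corrected p-value of the largest observed cluster, or 1 when no
#' suprathreshold cluster forms (observed maximum mass 0).
#'
#' @param result a `cluster_result`.
#' @return scalar p in (0, 1].
#' @export
cluster_min_p <- function(result) {
  obs_max <- if (nrow(result$clusters)) max(abs(result$clusters$mass)) else 0
  (1 + sum(result$null_max >= obs_max)) / (1 + result$n_perm)
}
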