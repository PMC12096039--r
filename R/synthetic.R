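# Synthetic dyadic-dance sessions with known ground truth -------------------

#' Beat-locked acoustic event train
#'
#' Impulses at the inter-beat interval `60/tempo_bpm` s with i.i.d.
#' lognormal amplitudes, so a loud/soft 20% amplitude split is meaningful.
#'
#' @param tempo_bpm tempo in beats per minute.
#' @param duration_s series duration, s.
#' @param seed RNG seed.
#' @param fs sampling rate, Hz.
#' @param meanlog,sdlog lognormal amplitude parameters.
#' @return numeric vector of length `duration_s * fs`, nonnegative.
#' @export
make_event_train <- function(tempo_bpm, duration_s, seed, fs = 100,
                             meanlog = 0, sdlog = 0.5) {
  check_positive(tempo_bpm, "tempo_bpm")
  check_positive(duration_s, "duration_s")
  n <- round(duration_s * fs)
  beat_times <- seq(0, duration_s - 1e-9, by = 60 / tempo_bpm)
  idx <- pmin(n, 1L + round(beat_times * fs))
  old <- local_seed(seed); on.exit(restore_seed(old), add = TRUE)
  amp <- stats::rlnorm(length(idx), meanlog, sdlog)
  x <- numeric(n)
  x[idx] <- amp
  x
}

# Ornstein-Uhlenbeck phase noise, stationary sd `sd`, correlation time `tau`.
ou_noise <- function(n, dt, sd, tau) {
  if (sd <= 0) return(numeric(n))
  a <- exp(-dt / tau)
  innov_sd <- sd * sqrt(1 - a^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  eps <- stats::rnorm(n - 1, 0, innov_sd)
  for (i in 2:n) x[i] <- a * x[i - 1] + eps[i - 1]
  x
}

#' Simulate the bounce velocities of a dancing dyad
#'
#' Each dancer bounces near-sinusoidally at half their musical beat rate
#' (one bounce per two beats is replaced by one bounce per beat; i.e. bounce
#' frequency = tempo/60 Hz), with Ornstein-Uhlenbeck phase jitter. When
#' `coupling = "coupled"` (partners can see each other) dancer B's phase is
#' additionally attracted to dancer A's phase plus a target offset that is
#' reset at seeded random intervals of 2-6 s, alternating between relative
#' phase 0 (in-phase) and pi (anti-phase); this guarantees both coordination
#' states occur and yields at least one in/anti-phase transition per 10 s on
#' average. With unequal tempos the attraction is too weak to lock, so the
#' relative phase drifts at a rate set by the tempo difference (default
#' 8.5%).
#'
#' @param tempo_a,tempo_b tempos in bpm.
#' @param coupling "coupled" or "uncoupled".
#' @param duration_s duration, s.
#' @param seed RNG seed.
#' @param fs sampling rate, Hz.
#' @param phase_sd,phase_tau OU phase-jitter sd (rad) and time constant (s).
#' @param kappa attraction strength, rad/s (coupled only).
#' @param reset_range_s range of intervals between coupling-target resets, s.
#' @param targets relative-phase targets cycled at each reset (rad).
#' @param amp_mod relative depth of each dancer's slow independent
#'   amplitude modulation (movement vigor varies over seconds; this also
#'   keeps the two dancers' velocity magnitudes linearly separable, since
#'   |sin| is pi-periodic and equal-tempo dancers would otherwise produce
#'   nearly identical speed profiles at any relative phase).
#' @param amp_tau correlation time of the amplitude modulation, s.
#' @param init_phase optional length-2 initial phases (rad); random if NULL.
#' @return list with `v_a`, `v_b` (velocity series), `phase_a`, `phase_b`,
#'   `fs`.
#' @export
make_bounce_pair <- function(tempo_a, tempo_b, coupling = c("coupled", "uncoupled"),
                             duration_s, seed, fs = 100,
                             phase_sd = 0.15, phase_tau = 1,
                             kappa = 1.5, reset_range_s = c(2, 6),
                             targets = c(0, pi), amp_mod = 0.3,
                             amp_tau = 5, init_phase = NULL) {
  coupling <- match.arg(coupling)
  check_positive(tempo_a, "tempo_a"); check_positive(tempo_b, "tempo_b")
  check_positive(duration_s, "duration_s")
  if (duration_s < 60 / min(tempo_a, tempo_b))
    stop_invalid("duration_s is shorter than one beat period")
  n <- round(duration_s * fs); dt <- 1 / fs
  f_a <- tempo_a / 60; f_b <- tempo_b / 60
  old <- local_seed(seed); on.exit(restore_seed(old), add = TRUE)
  if (is.null(init_phase)) init_phase <- stats::runif(2, 0, 2 * pi)

  # target-offset schedule for coupled runs
  target_at <- rep(targets[1], n)
  if (coupling == "coupled" && length(targets) >= 1) {
    t_reset <- 0; k <- 0L
    while (t_reset < duration_s) {
      k <- k + 1L
      t_next <- t_reset + stats::runif(1, reset_range_s[1], reset_range_s[2])
      i0 <- max(1L, 1L + round(t_reset * fs)); i1 <- min(n, round(t_next * fs))
      if (i1 >= i0) target_at[i0:i1] <- targets[1L + (k - 1L) %% length(targets)]
      t_reset <- t_next
    }
  }

  jit_a <- ou_noise(n, dt, phase_sd, phase_tau)
  jit_b <- ou_noise(n, dt, phase_sd, phase_tau)
  env_a <- pmax(0.2, 1 + ou_noise(n, dt, amp_mod, amp_tau))
  env_b <- pmax(0.2, 1 + ou_noise(n, dt, amp_mod, amp_tau))

  ph_a <- init_phase[1] + 2 * pi * f_a * (seq_len(n) - 1) * dt + jit_a
  ph_b <- init_phase[2] + 2 * pi * f_b * (seq_len(n) - 1) * dt + jit_b
  if (coupling == "coupled" && kappa > 0) {
    # accumulated attraction correction on top of the free-running phase,
    # so an exactly locked pair stays exactly locked
    pull <- numeric(n)
    for (i in 2:n) {
      pull[i] <- pull[i - 1] +
        kappa * sin(ph_a[i - 1] + target_at[i - 1] - ph_b[i - 1] -
                      pull[i - 1]) * dt
    }
    ph_b <- ph_b + pull
  }
  list(v_a = env_a * sin(ph_a), v_b = env_b * sin(ph_b),
       phase_a = ph_a, phase_b = ph_b, fs = fs)
}

#' Default tempo pair for the different-music condition
#'
#' The two songs differ in tempo by exactly the configured relative amount
#' (default 8.5%).
#' @param base_bpm tempo of dancer A's song.
#' @param rel_diff relative tempo difference.
#' @return length-2 numeric vector of tempos.
#' @export
tempo_pair <- function(base_bpm = 120, rel_diff = 0.085) {
  c(base_bpm, base_bpm * (1 + rel_diff))
}

#' Full-body posture series built from movement primitives
#'
#' Generates a 66-dimensional posture time series (22 markers x xyz) as a
#' sum of orthonormal movement primitives: the first primitive is the bounce
#' (vertical displacement of all markers, score = integral of the supplied
#' bounce velocity) and the rest carry band-limited noise scores with
#' geometrically decaying variance. Isotropic Gaussian sensor noise
#' contributes `noise_frac` of the total variance.
#'
#' @param bounce_velocity bounce velocity series.
#' @param n_primitives number of primitives (including bounce), 1..66.
#' @param noise_frac proportion of total variance that is sensor noise.
#' @param seed RNG seed.
#' @param fs sampling rate, Hz.
#' @param bounce_var_frac fraction of primitive variance carried by bounce
#'   (the bounce is a small-variance but neurally dominant primitive).
#' @param decay geometric decay ratio of the remaining primitive variances.
#' @return time x 66 matrix with marker-coordinate column names; attributes
#'   `basis` (66 x n), `scores` (time x n), `markers`.
#' @export
make_fullbody <- function(bounce_velocity, n_primitives = 15, noise_frac = 0.04,
                          seed = 1, fs = 100, bounce_var_frac = 0.01,
                          decay = 0.7) {
  if (n_primitives < 1 || n_primitives > 66)
    stop_invalid("n_primitives must be in 1..66")
  check_fraction(noise_frac, "noise_frac")
  n <- length(bounce_velocity)
  markers <- marker_names_22()
  cols <- as.vector(t(outer(markers, c("x", "y", "z"), paste, sep = "_")))

  # bounce primitive: uniform vertical displacement of all markers
  b <- rep(c(0, 0, 1), times = 22); b <- b / sqrt(sum(b^2))
  old <- local_seed(seed); on.exit(restore_seed(old), add = TRUE)
  basis <- b
  if (n_primitives > 1) {
    q <- qr.Q(qr(cbind(b, matrix(stats::rnorm(66 * (n_primitives - 1)), 66))))
    basis <- q[, seq_len(n_primitives), drop = FALSE]
    basis[, 1] <- b * sign(sum(q[, 1] * b))
  } else basis <- matrix(b, ncol = 1)

  bounce_score <- cumsum(bounce_velocity) / fs
  bounce_score <- bounce_score - mean(bounce_score)
  scores <- matrix(0, n, n_primitives)
  if (n_primitives > 1) {
    bf <- signal::butter(2, min(0.99, 5 / (fs / 2)), "low")
    for (k in 2:n_primitives) {
      s <- signal::filtfilt(bf, stats::rnorm(n))
      s <- s - mean(s)
      scores[, k] <- s / stats::sd(s) * sqrt(decay^(k - 2))
    }
    other_var <- sum(decay^(0:(n_primitives - 2)))
    target_bounce_var <- bounce_var_frac / (1 - bounce_var_frac) * other_var
    scores[, 1] <- bounce_score / stats::sd(bounce_score) *
      sqrt(target_bounce_var)
  } else scores[, 1] <- bounce_score

  postures <- scores %*% t(basis)
  signal_var <- sum(apply(scores, 2, stats::var))
  if (noise_frac > 0) {
    noise_var <- noise_frac / (1 - noise_frac) * signal_var
    postures <- postures + matrix(stats::rnorm(n * 66, 0, sqrt(noise_var / 66)),
                                  n, 66)
  }
  colnames(postures) <- cols
  attr(postures, "basis") <- basis
  attr(postures, "scores") <- scores
  attr(postures, "markers") <- markers
  attr(postures, "fs") <- fs
  postures
}

#' Marker set of the motion-capture model
#' @return character vector of 22 marker names.
#' @export
marker_names_22 <- function() {
  c("LB Head", "LF Head", "RF Head", "RB Head", "Sternum",
    "L Shoulder", "R Shoulder", "L Elbow", "R Elbow", "L Wrist", "R Wrist",
    "L Hand", "R Hand", "Pelvis", "L Hip", "R Hip",
    "L Knee", "R Knee", "L Ankle", "R Ankle", "L Foot", "R Foot")
}

#' 1/f (pink) background noise
#'
#' Spectrally shaped Gaussian noise with power ~ 1/f, the standard model of
#' ongoing EEG background activity; normalized to unit variance.
#'
#' @param n series length.
#' @return numeric vector of length `n`.
#' @export
pink_noise <- function(n) {
  nfft <- 2^ceiling(log2(max(n, 2)))
  x <- stats::rnorm(nfft)
  X <- stats::fft(x)
  f <- c(1, seq_len(nfft - 1))  # avoid DC blow-up
  f <- pmin(f, nfft - f + 1)
  X <- X / sqrt(f)
  y <- Re(stats::fft(X, inverse = TRUE))[seq_len(n)]
  (y - mean(y)) / stats::sd(y)
}

#' Condition label of the 2x2 design
#' @param vision "yes" or "no" (visual contact).
#' @param music "same" or "different" (musical input).
#' @return list with `vision`, `music`.
#' @export
condition_label <- function(vision = c("yes", "no"),
                            music = c("same", "different")) {
  list(vision = match.arg(vision), music = match.arg(music))
}

#' All four conditions of the 2x2 design
#' @return data.frame with columns `vision`, `music`.
#' @export
condition_grid <- function() {
  expand.grid(vision = c("yes", "no"), music = c("same", "different"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Gating factor of each kernel under a condition
#'
#' Partner-movement responses require visual contact (gain 0 without
#' vision); coordination tracking is full with vision and shared music,
#' reduced with vision and different music, absent without vision.
#'
#' @param condition a [condition_label()].
#' @param gating named list of gating factors (config).
#' @return named numeric vector of per-kernel gains.
#' @export
condition_gains <- function(condition,
                            gating = list(other_novision = 0,
                                          coord_vision_same = 1,
                                          coord_vision_diff = 0.25,
                                          coord_novision = 0)) {
  g <- c(music = 1, self = 1, other = 1, coordination = 1,
         eog_left = 1, eog_right = 1, emg_cheek = 1, emg_neck = 1)
  if (condition$vision == "no") {
    g["other"] <- gating$other_novision
    g["coordination"] <- gating$coord_novision
  } else {
    g["coordination"] <- if (condition$music == "same")
      gating$coord_vision_same else gating$coord_vision_diff
  }
  g
}

#' Noiseless forward model: project kernel responses onto the scalp
#'
#' EEG(t, c) = sum over kernels k of gain_k * topo_k(c) * (kernel_k *
#' regressor_k)(t). Kernels whose regressor is missing are skipped.
#'
#' @param regressors named list of equal-length series.
#' @param kernels named list of [kernel_spec()] objects.
#' @param window a [lag_window()].
#' @param gains named per-kernel multipliers (default all 1).
#' @param exclude kernel names to leave out.
#' @return time x channel matrix.
#' @export
simulate_eeg_clean <- function(regressors, kernels, window = lag_window(),
                               gains = NULL, exclude = character()) {
  n <- length(regressors[[1]])
  nchan <- length(kernels[[1]]$topography)
  eeg <- matrix(0, n, nchan)
  for (nm in setdiff(names(kernels), exclude)) {
    if (!nm %in% names(regressors)) next
    g <- if (!is.null(gains) && nm %in% names(gains)) gains[[nm]] else 1
    if (g == 0) next
    contrib <- convolve_kernel(regressors[[nm]], kernel_waveform(kernels[[nm]],
                                                                window), window)
    eeg <- eeg + (g * contrib) %*% t(kernels[[nm]]$topography)
  }
  eeg
}

#' Simulate one trial of dyadic-dance EEG
#'
#' Adds channel-independent pink noise to the noiseless forward model,
#' scaled so that the ratio of mean neural signal variance (music, self,
#' other, coordination contributions) to noise variance equals `snr`.
#' Artifact (EOG/EMG) contributions are excluded from the SNR reference:
#' they ride on top at their own, much larger, amplitude.
#'
#' @param regressors named list of series (see [make_session()] for names).
#' @param kernels named list of [kernel_spec()].
#' @param condition a [condition_label()].
#' @param snr neural signal-to-noise variance ratio; `Inf` for noiseless.
#' @param seed RNG seed.
#' @param window a [lag_window()].
#' @param gating gating config, see [condition_gains()].
#' @return object of class `trial_record`: list with `eeg` (time x channel),
#'   `regressors`, `condition`, `fs`, `gains`.
#' @export
simulate_trial <- function(regressors, kernels, condition, snr = 0.25,
                           seed = 1, window = lag_window(),
                           gating = NULL) {
  lens <- vapply(regressors, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop_invalid("regressor series must have equal length")
  gains <- if (is.null(gating)) condition_gains(condition)
           else condition_gains(condition, gating)
  artifact <- c("eog_left", "eog_right", "emg_cheek", "emg_neck")
  neural <- simulate_eeg_clean(regressors, kernels, window, gains,
                               exclude = artifact)
  art <- simulate_eeg_clean(regressors, kernels, window, gains,
                            exclude = setdiff(names(kernels), artifact))
  eeg <- neural + art
  if (is.finite(snr)) {
    check_positive(snr, "snr")
    sig_var <- mean(apply(neural, 2, stats::var))
    noise_sd <- sqrt(sig_var / snr)
    old <- local_seed(seed); on.exit(restore_seed(old), add = TRUE)
    for (ch in seq_len(ncol(eeg)))
      eeg[, ch] <- eeg[, ch] + noise_sd * pink_noise(nrow(eeg))
  }
  structure(list(eeg = eeg, regressors = regressors, condition = condition,
                 fs = window$fs, gains = gains),
            class = "trial_record")
}

#' Default configuration of the synthetic dyad session
#'
#' Defaults mirror the study conditions: 4 blocks x (2 trials x 4
#' conditions) = 32 trials of ~40 s at 100 Hz on 64 channels; tempo around
#' 120 bpm with an exact 8.5% tempo difference in the different-music
#' condition; neural SNR 0.25; artifact gain 100.
#'
#' @param ... overrides of the listed defaults.
#' @return list of class `session_config`.
#' @export
session_config <- function(...) {
  cfg <- list(
    fs = 100, duration_s = 40, blocks = 4, trials_per_cond_block = 2,
    tempo_bpm = 120, tempo_jitter_bpm = 10, tempo_rel_diff = 0.085,
    snr = 0.25, artifact_gain = 100, lobe_width_ms = 30,
    gating = list(other_novision = 0, coord_vision_same = 1,
                  coord_vision_diff = 0.25, coord_novision = 0),
    phase_sd = 0.15, kappa = 1.5, reset_range_s = c(2, 6),
    amp_mod = 0.3, event_sdlog = 0.5
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop_invalid("unknown config field(s): ",
                                paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "session_config")
}

# smooth artifact source series (unit variance, low-frequency)
artifact_source <- function(n, fs, cutoff_hz) {
  bf <- signal::butter(2, min(0.99, cutoff_hz / (fs / 2)), "low")
  s <- signal::filtfilt(bf, stats::rnorm(n))
  s <- s - mean(s)
  s / stats::sd(s)
}

#' Generate a complete synthetic dyad session
#'
#' Two participants, `blocks` x 4 conditions x `trials_per_cond_block`
#' trials each, with shared condition labels, known ground-truth kernels,
#' and per-trial seeds derived deterministically from the session seed.
#'
#' @param config a [session_config()].
#' @param seed session seed.
#' @param layout electrode layout (default 64-channel 10-10).
#' @return object of class `dyad_session`: list with `participants` (each a
#'   list of `trial_record`s), `conditions` (one row per trial), `kernels`,
#'   `config`, `seed`, `layout`.
#' @export
make_session <- function(config = session_config(), seed = 1,
                         layout = layout_1010_64()) {
  stopifnot(inherits(config, "session_config"))
  window <- lag_window(fs = config$fs)
  kernels <- kernel_presets(layout, artifact_gain = config$artifact_gain,
                            lobe_width_ms = config$lobe_width_ms)
  grid <- condition_grid()
  cond_rows <- do.call(rbind, replicate(config$blocks * config$trials_per_cond_block,
                                        grid, simplify = FALSE))
  n_trials <- nrow(cond_rows)
  cond_rows$block <- rep(seq_len(config$blocks),
                         each = 4 * config$trials_per_cond_block)
  cond_rows$trial <- seq_len(n_trials)

  seeds <- matrix(derive_seeds(seed, n_trials * 8L), nrow = n_trials)
  n <- round(config$duration_s * config$fs)
  participants <- list(vector("list", n_trials), vector("list", n_trials))

  for (ti in seq_len(n_trials)) {
    cond <- condition_label(cond_rows$vision[ti], cond_rows$music[ti])
    old <- local_seed(seeds[ti, 1]); base <- config$tempo_bpm +
      stats::runif(1, -config$tempo_jitter_bpm, config$tempo_jitter_bpm)
    restore_seed(old)
    tempos <- if (cond$music == "same") c(base, base)
              else tempo_pair(base, config$tempo_rel_diff)
    coupling <- if (cond$vision == "yes") "coupled" else "uncoupled"
    # with a shared beat, partners deliberately alternate in-/anti-phase
    # play; with conflicting beats they only try to fall in phase, and
    # anti-phase episodes arise from tempo-difference phase slips
    targets <- if (cond$music == "same") c(0, pi) else 0
    bounce <- make_bounce_pair(tempos[1], tempos[2], coupling,
                               config$duration_s, seed = seeds[ti, 2],
                               fs = config$fs, phase_sd = config$phase_sd,
                               kappa = config$kappa,
                               reset_range_s = config$reset_range_s,
                               targets = targets, amp_mod = config$amp_mod)
    coord <- coordination_signal(bounce$v_a, bounce$v_b)
    trains <- list(
      make_event_train(tempos[1], config$duration_s, seeds[ti, 3],
                       fs = config$fs, sdlog = config$event_sdlog),
      make_event_train(tempos[2], config$duration_s, seeds[ti, 4],
                       fs = config$fs, sdlog = config$event_sdlog))
    vel <- list(abs(bounce$v_a), abs(bounce$v_b))
    vsign <- list(sign_series(bounce$v_a), sign_series(bounce$v_b))

    for (p in 1:2) {
      o <- 3 - p
      old <- local_seed(seeds[ti, 4 + 2 * (p - 1) + 1])
      art <- list(eog_left = artifact_source(n, config$fs, 3),
                  eog_right = artifact_source(n, config$fs, 3),
                  emg_cheek = artifact_source(n, config$fs, 12),
                  emg_neck = artifact_source(n, config$fs, 12))
      restore_seed(old)
      regs <- c(list(music = trains[[p]], self = vel[[p]], other = vel[[o]],
                     coordination = coord), art,
                list(velocity_sign_self = vsign[[p]],
                     velocity_sign_other = vsign[[o]]))
      participants[[p]][[ti]] <- simulate_trial(
        regs, kernels, cond, snr = config$snr,
        seed = seeds[ti, 4 + 2 * (p - 1) + 2], window = window,
        gating = config$gating)
    }
  }
  structure(list(participants = participants, conditions = cond_rows,
                 kernels = kernels, config = config, seed = seed,
                 layout = layout),
            class = "dyad_session")
}

#' @export
print.dyad_session <- function(x, ...) {
  cat("<dyad_session> 2 participants,", nrow(x$conditions), "trials each,",
      x$config$duration_s, "s @", x$config$fs, "Hz, seed", x$seed, "\n")
  invisible(x)
}
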