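# Study-level model fitting and variance partitioning -----------------------

# condition id string per trial
condition_id <- function(vision, music) paste(vision, music, sep = "/")

#' Fit subject TRFs for a cohort of synthetic dyads
#'
#' Generates `n_dyads` sessions (seeds derived from `seed`), standardizes
#' regressors per participant, and fits the full-model subject TRF for
#' every participant and condition (leave-one-trial lambda selection, fold
#' averaging). EEG is discarded as soon as each participant is fitted, so
#' memory stays bounded.
#'
#' @param n_dyads number of dyads (2 participants each).
#' @param config a [session_config()].
#' @param seed cohort seed.
#' @param reg_names regressors of the full model.
#' @param window a [lag_window()].
#' @param progress print one line per dyad.
#' @return list with `trfs` (participant-indexed list of condition-named
#'   `trf_model` lists), `conditions` (the 4 condition ids), `layout`,
#'   `window`, `kernels` (ground truth of the first session).
#' @export
cohort_subject_trfs <- function(n_dyads = 10, config = session_config(),
                                seed = 1, reg_names = main_regressors(),
                                window = lag_window(fs = config$fs),
                                progress = FALSE) {
  seeds <- derive_seeds(seed, n_dyads)
  cond_ids <- condition_id(condition_grid()$vision, condition_grid()$music)
  trfs <- list(); layout <- NULL; kernels <- NULL
  for (d in seq_len(n_dyads)) {
    sess <- make_session(config, seeds[d])
    sess <- standardize_session(sess)
    if (is.null(layout)) { layout <- sess$layout; kernels <- sess$kernels }
    trial_cond <- condition_id(sess$conditions$vision, sess$conditions$music)
    for (p in 1:2) {
      models <- lapply(cond_ids, function(cid) {
        fit_subject_trf(sess$participants[[p]][trial_cond == cid],
                        reg_names, window)
      })
      names(models) <- cond_ids
      trfs[[length(trfs) + 1L]] <- models
    }
    if (progress) message("dyad ", d, "/", n_dyads, " fitted")
  }
  list(trfs = trfs, conditions = cond_ids, layout = layout, window = window,
       kernels = kernels)
}

#' Grand-average TRF weights across participants and conditions
#' @param cohort result of [cohort_subject_trfs()].
#' @param conditions condition ids to average (default all).
#' @return a `trf_model` with grand-average weights.
#' @export
grand_average_trf <- function(cohort, conditions = cohort$conditions) {
  models <- unlist(lapply(cohort$trfs, function(m) m[conditions]),
                   recursive = FALSE)
  average_trfs(models)
}

#' Recovered peak latencies of the four neural TRFs
#'
#' Reads the canonical deflection latencies off the grand-average recovered
#' TRFs: music = last positive peak at Fz (all conditions); self = earliest
#' pre-onset negative peak averaged over C3/C4 (all conditions); other =
#' first post-onset positive peak at Oz (vision conditions); coordination =
#' last positive peak at Oz (vision + same music).
#'
#' @param cohort result of [cohort_subject_trfs()].
#' @return named numeric vector of latencies in ms (music, self, other,
#'   coordination).
#' @export
kernel_latency_report <- function(cohort) {
  lay <- cohort$layout; win <- cohort$window
  chan <- function(lbl) match(lbl, lay$label)
  wave <- function(model, reg, labels) {
    w <- trf_weights(model, reg)[, chan(labels), drop = FALSE]
    rowMeans(w)
  }
  vis <- grep("^yes/", cohort$conditions, value = TRUE)
  vis_same <- "yes/same"

  music_w <- wave(grand_average_trf(cohort), "music", "Fz")
  p <- trf_peaks(music_w, win$lag_ms, sign = 1)
  music_lat <- p$lag_ms[nrow(p)]

  self_w <- wave(grand_average_trf(cohort), "self", c("C3", "C4"))
  p <- trf_peaks(self_w, win$lag_ms, sign = -1)
  p <- p[p$lag_ms < 0, , drop = FALSE]
  self_lat <- p$lag_ms[1]

  other_w <- wave(grand_average_trf(cohort, vis), "other", "Oz")
  p <- trf_peaks(other_w, win$lag_ms, sign = 1)
  p <- p[p$lag_ms > 0, , drop = FALSE]
  other_lat <- p$lag_ms[1]

  coord_w <- wave(grand_average_trf(cohort, vis_same), "coordination", "Oz")
  p <- trf_peaks(coord_w, win$lag_ms, sign = 1)
  coord_lat <- p$lag_ms[nrow(p)]

  c(music = music_lat, self = self_lat, other = other_lat,
    coordination = coord_lat)
}

#' Full-versus-reduced variance partitioning across a study
#'
#' For every participant and condition, fits the full model and one reduced
#' model per entry of `reduced_sets` (each a set of regressors to exclude),
#' then computes generic (leave-one-participant-out) prediction accuracies
#' and the unique contributions delta r = r_full - r_reduced per channel.
#' Lambdas are selected by leave-one-trial cross-validation independently
#' for each model.
#'
#' @param participants list over participants of lists of `trial_record`s.
#' @param conditions data.frame with `vision`, `music` per trial (shared by
#'   all participants), or NULL to pool all trials into one cell.
#' @param reg_names regressors of the full model.
#' @param reduced_sets named list of character vectors (regressors excluded
#'   by each reduced model).
#' @param window a [lag_window()].
#' @param grid lambda grid.
#' @return list with `r_full` (channel x participant x condition) and
#'   `delta_r` (channel x participant x condition x reduced set).
#' @export
trf_partition <- function(participants, conditions = NULL,
                          reg_names = main_regressors(),
                          reduced_sets = list(other = "other",
                                              coordination = "coordination"),
                          window = lag_window(), grid = lambda_grid()) {
  for (s in reduced_sets)
    if (!all(s %in% reg_names))
      stop("reduced set excludes unknown regressor(s): ",
           paste(setdiff(s, reg_names), collapse = ", "))
  n_part <- length(participants)
  if (n_part < 2) stop("need at least 2 participants for generic prediction")
  cond_ids <- if (is.null(conditions)) "all" else
    unique(condition_id(conditions$vision, conditions$music))
  trial_cond <- if (is.null(conditions))
    rep("all", length(participants[[1]])) else
    condition_id(conditions$vision, conditions$music)
  model_names <- c("full", names(reduced_sets))
  model_regs <- c(list(full = reg_names),
                  lapply(reduced_sets, function(s) setdiff(reg_names, s)))
  nchan <- ncol(participants[[1]][[1]]$eeg)

  # pass 1: subject TRFs for every model, participant, condition
  fits <- array(vector("list", 1),
                dim = c(n_part, length(cond_ids), length(model_names)),
                dimnames = list(NULL, cond_ids, model_names))
  crosses <- array(vector("list", 1), dim = c(n_part, length(cond_ids)))
  for (p in seq_len(n_part)) {
    for (ci in seq_along(cond_ids)) {
      trials <- participants[[p]][trial_cond == cond_ids[ci]]
      cross_full <- trial_crossprods(trials, reg_names, window)
      crosses[[p, ci]] <- cross_full
      for (m in model_names) {
        cols <- design_columns(model_regs[[m]], reg_names, window)
        cross_m <- if (identical(model_regs[[m]], reg_names)) cross_full else
          lapply(cross_full, function(cp)
            list(XtX = cp$XtX[cols, cols], Xty = cp$Xty[cols, , drop = FALSE],
                 d = cp$d[cols], n = cp$n, y_sum = cp$y_sum,
                 y_ssq = cp$y_ssq))
        fits[[p, ci, m]] <- fit_subject_trf(
          trials, model_regs[[m]], window, cross = cross_m, grid = grid)
      }
    }
  }

  # pass 2: generic predictions from the cached sufficient statistics
  r_full <- array(NA_real_, c(nchan, n_part, length(cond_ids)),
                  dimnames = list(NULL, NULL, cond_ids))
  dr <- array(NA_real_,
              c(nchan, n_part, length(cond_ids), length(reduced_sets)),
              dimnames = list(NULL, NULL, cond_ids, names(reduced_sets)))
  for (p in seq_len(n_part)) {
    for (ci in seq_along(cond_ids)) {
      r_model <- sapply(model_names, function(m) {
        generic <- average_trfs(lapply(seq_len(n_part)[-p],
                                       function(q) fits[[q, ci, m]]))
        cols <- design_columns(model_regs[[m]], reg_names, window)
        mom <- NULL
        for (cp in crosses[[p, ci]]) {
          st <- list(XtX = cp$XtX[cols, cols], Xty = cp$Xty[cols, , drop = FALSE],
                     d = cp$d[cols], n = cp$n, y_sum = cp$y_sum,
                     y_ssq = cp$y_ssq)
          mom <- add_moments(mom, pred_moments(generic$weights, st))
        }
        moments_cor(mom)
      })
      r_full[, p, ci] <- r_model[, "full"]
      for (m in names(reduced_sets))
        dr[, p, ci, m] <- r_model[, "full"] - r_model[, m]
    }
  }
  list(r_full = r_full, delta_r = dr, conditions = cond_ids)
}

#' Body-part-specific variance partitioning
#'
#' Full model: velocity magnitudes of the 16 major body markers plus the
#' neck EMG control; reduced models exclude the left hand, right hand, left
#' foot, right foot, or the four head markers together.
#'
#' @param participants list over participants of `trial_record` lists whose
#'   regressors contain one series per marker (names as in
#'   [bodypart_marker_sets()]) plus `emg_neck`.
#' @param window a [lag_window()].
#' @param grid lambda grid.
#' @return [trf_partition()] result (conditions pooled).
#' @export
bodypart_models <- function(participants, window = lag_window(),
                            grid = lambda_grid()) {
  sets <- bodypart_marker_sets()
  full <- c(unlist(sets$full), "emg_neck")
  have <- names(participants[[1]][[1]]$regressors)
  miss <- setdiff(full, have)
  if (length(miss)) stop("missing marker regressor(s): ",
                         paste(miss, collapse = ", "))
  trf_partition(participants, conditions = NULL, reg_names = full,
                reduced_sets = sets$reduced, window = window, grid = grid)
}

#' Marker sets of the body-part analysis
#' @return list with `full` (16 marker names) and `reduced` (named list of
#'   exclusion sets).
#' @export
bodypart_marker_sets <- function() {
  head4 <- c("LB Head", "LF Head", "RF Head", "RB Head")
  full <- c(head4, "Sternum", "L Shoulder", "R Shoulder", "L Hand", "R Hand",
            "Pelvis", "L Hip", "R Hip", "L Knee", "L Foot", "R Knee", "R Foot")
  list(full = full,
       reduced = list(`L Hand` = "L Hand", `R Hand` = "R Hand",
                      `L Foot` = "L Foot", `R Foot` = "R Foot",
                      head = head4))
}

#' Coordination unique contribution controlling for movement direction
#'
#' Delta r for the coordination regressor computed against a full model
#' that also carries the velocity-sign series of both dancers, so any gain
#' attributable to spatial direction alone is absorbed by the controls.
#'
#' @param participants list over participants of `trial_record` lists whose
#'   regressors include `velocity_sign_self` and `velocity_sign_other`.
#' @param conditions per-trial condition data.frame or NULL.
#' @param window a [lag_window()].
#' @param grid lambda grid.
#' @return [trf_partition()] result with a single `coordination` set.
#' @export
coordination_control <- function(participants, conditions = NULL,
                                 window = lag_window(), grid = lambda_grid()) {
  regs <- c("music", "self", "other", "coordination",
            "velocity_sign_self", "velocity_sign_other")
  have <- names(participants[[1]][[1]]$regressors)
  if (!all(c("velocity_sign_self", "velocity_sign_other") %in% have))
    stop("velocity sign regressors are required for the coordination control")
  trf_partition(participants, conditions, reg_names = regs,
                reduced_sets = list(coordination = "coordination"),
                window = window, grid = grid)
}
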