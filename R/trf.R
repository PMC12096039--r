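# Multivariate lagged ridge regression (mTRF core) --------------------------

#' Regularization grid for TRF estimation
#'
#' Zero plus powers of ten from 1e-4 to 1e8: 13 candidate values searched by
#' leave-one-trial cross-validation.
#' @return numeric vector of 13 lambda values.
#' @export
lambda_grid <- function() c(0, 10^seq(-4, 8))

#' Names of the regressors entering the main full model
#' @return character vector of 8 names.
#' @export
main_regressors <- function() {
  c("music", "self", "other", "coordination",
    "eog_left", "eog_right", "emg_cheek", "emg_neck")
}

#' Build the lagged design matrix
#'
#' One column block per regressor (lags ascending, zero-padded at trial
#' edges) plus a trailing constant intercept column; row `t` of the lag-`l`
#' column holds `x[t - l]`.
#'
#' @param regressors named list of equal-length series.
#' @param window a [lag_window()].
#' @return time x (n_regressors * n_lags + 1) matrix.
#' @export
build_design <- function(regressors, window = lag_window()) {
  n <- length(regressors[[1]])
  L <- length(window$lags)
  if (n < L) stop_invalid("regressor series shorter than the lag window")
  D <- matrix(0, n, length(regressors) * L + 1L)
  col <- 0L
  for (x in regressors) {
    if (length(x) != n) stop_invalid("regressor series must have equal length")
    for (l in window$lags) {
      col <- col + 1L
      if (l >= 0) {
        if (l < n) D[(l + 1L):n, col] <- x[1:(n - l)]
      } else {
        D[1:(n + l), col] <- x[(1L - l):n]
      }
    }
  }
  D[, ncol(D)] <- 1
  colnames(D) <- c(as.vector(t(outer(names(regressors), window$lags,
                                     paste, sep = "@"))), "(intercept)")
  D
}

# column indices of given regressors (plus intercept) in the design
design_columns <- function(reg_names, all_names, window, intercept = TRUE) {
  L <- length(window$lags)
  idx <- unlist(lapply(match(reg_names, all_names), function(j)
    ((j - 1L) * L + 1L):(j * L)))
  if (intercept) idx <- c(idx, length(all_names) * L + 1L)
  idx
}

# ridge solve from cross-products; intercept column unpenalized
ridge_solve <- function(XtX, Xty, lambda, intercept_col = ncol(XtX)) {
  pen <- rep(lambda, ncol(XtX))
  pen[intercept_col] <- 0
  A <- XtX + diag(pen, ncol(XtX))
  w <- tryCatch(solve(A, Xty), error = function(e) NULL)
  if (is.null(w)) {
    warning("singular system; returning minimum-norm solution")
    s <- svd(A)
    tol <- max(s$d) * 1e-12
    dinv <- ifelse(s$d > tol, 1 / s$d, 0)
    w <- s$v %*% (dinv * (t(s$u) %*% Xty))
  }
  w
}

new_trf_model <- function(weights, reg_names, window, lambda) {
  L <- length(window$lags)
  structure(list(weights = weights, regressors = reg_names, window = window,
                 lambda = lambda, n_lags = L),
            class = "trf_model")
}

#' Fit a TRF by ridge regression
#'
#' Solves `(D'D + lambda I*) w = D'y` per channel, with the identity zeroed
#' at the intercept column so the offset is never penalized; `lambda = 0`
#' reduces to ordinary least squares (minimum-norm with a warning if the
#' system is singular).
#'
#' @param design design matrix from [build_design()].
#' @param eeg time x channel matrix (or vector).
#' @param lambda ridge parameter, >= 0.
#' @param reg_names regressor names (defaults recovered from column names).
#' @param window a [lag_window()].
#' @return object of class `trf_model`: `weights` is a (n_regressors *
#'   n_lags + 1) x channel matrix whose last row is the intercept.
#' @export
ridge_fit <- function(design, eeg, lambda, reg_names = NULL,
                      window = lag_window()) {
  if (lambda < 0) stop_invalid("lambda must be >= 0")
  if (is.null(dim(eeg))) eeg <- matrix(eeg, ncol = 1)
  if (is.null(reg_names))
    reg_names <- unique(sub("@.*$", "", utils::head(colnames(design), -1L)))
  w <- ridge_solve(crossprod(design), crossprod(design, eeg), lambda)
  new_trf_model(w, reg_names, window, lambda)
}

#' Extract one regressor's lag x channel weights from a TRF model
#' @param model a `trf_model`.
#' @param regressor regressor name.
#' @return n_lags x channel matrix.
#' @export
trf_weights <- function(model, regressor) {
  j <- match(regressor, model$regressors)
  if (is.na(j)) stop_invalid("model has no regressor '", regressor, "'")
  L <- model$n_lags
  model$weights[((j - 1L) * L + 1L):(j * L), , drop = FALSE]
}

#' Predict EEG from a TRF model
#' @param model a `trf_model`.
#' @param regressors named list of series (must cover `model$regressors`).
#' @return time x channel matrix of predictions.
#' @export
predict_trf <- function(model, regressors) {
  D <- build_design(regressors[model$regressors], model$window)
  D %*% model$weights
}

# Per-trial sufficient statistics. Prediction accuracy never needs the
# predicted time series itself: with w the weights, sum(pred*y) = diag(w'
# D'y), sum(pred^2) = diag(w' D'D w) and sum(pred) = w' colSums(D), so
# Pearson r per channel follows from the cached cross-products alone.
trial_crossprods <- function(trials, reg_names, window, keep_design = FALSE) {
  lapply(trials, function(tr) {
    D <- build_design(tr$regressors[reg_names], window)
    y <- tr$eeg
    out <- list(XtX = crossprod(D), Xty = crossprod(D, y), d = colSums(D),
                n = nrow(D), y_sum = colSums(y), y_ssq = colSums(y^2))
    if (keep_design) out$D <- D
    out
  })
}

# accumulate the prediction-vs-actual moment sums of one trial
pred_moments <- function(w, st) {
  list(a = colSums(w * st$Xty),
       q = colSums(w * (st$XtX %*% w)),
       pm = as.vector(crossprod(w, st$d)),
       n = st$n, y_sum = st$y_sum, y_ssq = st$y_ssq)
}

# Pearson r per channel from accumulated moments
moments_cor <- function(m) {
  num <- m$a - m$pm * m$y_sum / m$n
  vp <- pmax(m$q - m$pm^2 / m$n, 0)
  vy <- pmax(m$y_ssq - m$y_sum^2 / m$n, 0)
  r <- num / sqrt(vp * vy)
  r[!is.finite(r)] <- 0
  pmin(1, pmax(-1, r))
}

add_moments <- function(x, y) {
  if (is.null(x)) return(y)
  Map(`+`, x, y)
}

#' Select the ridge parameter by leave-one-trial cross-validation
#'
#' For each held-out trial, TRFs are fitted on the remaining trials at every
#' grid value and the lambda maximizing the mean-over-channels Pearson
#' correlation between predicted and actual EEG of the held-out trial is
#' chosen (ties broken toward smaller lambda).
#'
#' @param trials list of `trial_record`s (>= 2).
#' @param reg_names regressors to include.
#' @param window a [lag_window()].
#' @param grid candidate lambdas.
#' @param cross internal: precomputed [trial_crossprods()] with designs.
#' @return numeric vector, one selected lambda per trial.
#' @export
select_lambda <- function(trials, reg_names = main_regressors(),
                          window = lag_window(), grid = lambda_grid(),
                          cross = NULL) {
  if (!length(grid)) stop_invalid("empty lambda grid")
  if (length(trials) < 2) stop_invalid("need at least 2 trials")
  grid <- sort(grid)
  if (is.null(cross))
    cross <- trial_crossprods(trials, reg_names, window)
  XtX_all <- Reduce(`+`, lapply(cross, `[[`, "XtX"))
  Xty_all <- Reduce(`+`, lapply(cross, `[[`, "Xty"))
  vapply(seq_along(trials), function(i) {
    XtX <- XtX_all - cross[[i]]$XtX
    Xty <- Xty_all - cross[[i]]$Xty
    scores <- vapply(grid, function(lm) {
      # the grid probe legitimately visits singular lambda = 0 systems;
      # their minimum-norm fits simply score poorly
      w <- suppressWarnings(ridge_solve(XtX, Xty, lm))
      mean(moments_cor(pred_moments(w, cross[[i]])))
    }, numeric(1))
    grid[which.max(scores)]  # which.max returns the first (smallest) maximum
  }, numeric(1))
}

#' Fit a participant- and condition-specific TRF
#'
#' The subject TRF is the average of n leave-one-trial fold fits: for each
#' fold, a TRF is fitted on the other n-1 trials at that fold's selected
#' lambda, and the n fold TRFs are averaged elementwise.
#'
#' @param trials list of `trial_record`s for one condition (>= 2).
#' @param reg_names regressors to include.
#' @param window a [lag_window()].
#' @param lambdas per-fold lambdas; selected by [select_lambda()] if NULL.
#' @param grid lambda grid used when selecting.
#' @param cross internal: precomputed crossproducts with designs.
#' @return a `trf_model` (with `lambda` the per-fold vector).
#' @export
fit_subject_trf <- function(trials, reg_names = main_regressors(),
                            window = lag_window(), lambdas = NULL,
                            grid = lambda_grid(), cross = NULL) {
  if (length(trials) < 2) stop_invalid("need at least 2 trials")
  if (is.null(cross))
    cross <- trial_crossprods(trials, reg_names, window)
  if (is.null(lambdas))
    lambdas <- select_lambda(trials, reg_names, window, grid, cross = cross)
  XtX_all <- Reduce(`+`, lapply(cross, `[[`, "XtX"))
  Xty_all <- Reduce(`+`, lapply(cross, `[[`, "Xty"))
  w_sum <- 0
  for (i in seq_along(trials)) {
    w_sum <- w_sum + ridge_solve(XtX_all - cross[[i]]$XtX,
                                 Xty_all - cross[[i]]$Xty, lambdas[i])
  }
  new_trf_model(w_sum / length(trials), reg_names, window, lambdas)
}

#' Average several TRF models elementwise
#' @param models list of `trf_model`s with identical structure.
#' @return a `trf_model`.
#' @export
average_trfs <- function(models) {
  w <- Reduce(`+`, lapply(models, `[[`, "weights")) / length(models)
  new_trf_model(w, models[[1]]$regressors, models[[1]]$window,
                lambda = NA_real_)
}

#' Generic (leave-one-participant-out) prediction
#'
#' Predicts one participant's trials with the average of the other
#' participants' subject TRFs; Pearson r per channel is computed on the
#' trial-concatenated series.
#'
#' @param subject_trfs list of `trf_model`s, one per participant.
#' @param target index of the participant to predict.
#' @param trials that participant's trials.
#' @return list of class `prediction_result` with `r` (per channel),
#'   `participant`.
#' @export
generic_predict <- function(subject_trfs, target, trials) {
  if (length(subject_trfs) < 2) stop("need at least 2 participants")
  generic <- average_trfs(subject_trfs[-target])
  cross <- trial_crossprods(trials, generic$regressors, generic$window)
  mom <- NULL
  for (st in cross) mom <- add_moments(mom, pred_moments(generic$weights, st))
  structure(list(r = moments_cor(mom), participant = target),
            class = "prediction_result")
}

#' Unique contribution of a regressor (delta r)
#'
#' Elementwise difference in prediction accuracy between the full and a
#' reduced model: the EEG variance uniquely attributable to the excluded
#' regressor.
#'
#' @param full,reduced `prediction_result`s (or plain r vectors) with
#'   matching channels.
#' @return numeric vector of r_full - r_reduced.
#' @export
delta_r <- function(full, reduced) {
  rf <- if (inherits(full, "prediction_result")) full$r else full
  rr <- if (inherits(reduced, "prediction_result")) reduced$r else reduced
  if (length(rf) != length(rr)) stop("channel mismatch between models")
  rf - rr
}

# peak picking ---------------------------------------------------------------

#' Signed local extrema of a TRF waveform
#'
#' Interior local maxima (of `w` for positive deflections, of `-w` for
#' negative ones) whose absolute value exceeds `min_frac` of the waveform's
#' maximum absolute value; the amplitude floor suppresses spurious
#' noise-level wiggles.
#'
#' @param w weight series over lags.
#' @param lag_ms lag times, ms.
#' @param sign +1 for positive peaks, -1 for negative.
#' @param min_frac amplitude floor as a fraction of `max(abs(w))`; the
#'   default 0.3 keeps only deflections comparable in size to the main
#'   response, suppressing residual estimation noise.
#' @return data.frame with `lag_ms`, `value`, ordered by lag.
#' @export
trf_peaks <- function(w, lag_ms, sign = 1, min_frac = 0.3) {
  v <- sign * w
  n <- length(v)
  idx <- which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
  idx <- idx[v[idx] > 0 & abs(w[idx]) >= min_frac * max(abs(w))]
  data.frame(lag_ms = lag_ms[idx], value = w[idx])
}
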