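# Electrode selection and condition statistics ------------------------------

#' Select the electrodes showing a prediction gain
#'
#' Channels whose grand-average unique contribution (delta r) across
#' participants and the conditions where the process is expected to occur
#' exceeds zero. All four conditions are expected for music and
#' self-movement; the two visual-contact conditions for partner movement
#' and coordination. Falls back to the single best channel (with a warning)
#' when no channel shows a gain.
#'
#' @param delta_r channel x participant x condition array (one regressor's
#'   slice of a [trf_partition()] result).
#' @param expected_conditions condition ids (dimnames of the third axis) to
#'   average over.
#' @return integer vector of selected channel indices.
#' @export
select_electrodes <- function(delta_r, expected_conditions = NULL) {
  conds <- dimnames(delta_r)[[3]]
  if (is.null(expected_conditions)) expected_conditions <- conds
  if (!length(expected_conditions)) stop("expected_conditions is empty")
  miss <- setdiff(expected_conditions, conds)
  if (length(miss)) stop("unknown condition(s): ", paste(miss, collapse = ", "))
  ga <- apply(delta_r[, , expected_conditions, drop = FALSE], 1, mean)
  sel <- which(ga > 0)
  if (!length(sel)) {
    warning("no channel shows a positive grand-average delta r; ",
            "falling back to the best channel")
    sel <- which.max(ga)
  }
  sel
}

#' Average delta r over selected electrodes, per participant and condition
#' @param delta_r channel x participant x condition array.
#' @param channels channel indices from [select_electrodes()].
#' @return participant x condition matrix.
#' @export
average_over_electrodes <- function(delta_r, channels) {
  apply(delta_r[channels, , , drop = FALSE], c(2, 3), mean)
}

#' 2x2 repeated-measures ANOVA (visual contact x musical input)
#'
#' Within-subject F tests computed from per-subject effect contrasts (each
#' effect has 1 numerator df, so F equals the squared paired t on the
#' contrast, df (1, n-1)). When the interaction is significant at
#' `followup_alpha`, follow-up paired comparisons of musical input within
#' each visual-contact level are reported (difference, SE, p).
#'
#' @param values participant x 4 condition matrix; column names must be the
#'   condition ids "vision/music" (e.g. "yes/same").
#' @param bonferroni_n family size for the Bonferroni correction (the study
#'   tests four regressors, so 4).
#' @param followup_alpha significance level gating the follow-ups.
#' @return list of class `anova_2x2` with `effects` (data.frame: effect, F,
#'   df1, df2, p, p_bonf) and `followups` (data.frame or NULL).
#' @export
rm_anova_2x2 <- function(values, bonferroni_n = 4, followup_alpha = 0.05) {
  need <- c("yes/same", "yes/different", "no/same", "no/different")
  if (!all(need %in% colnames(values)))
    stop("values must have columns ", paste(need, collapse = ", "))
  if (any(!is.finite(values))) stop("missing cells in the condition matrix")
  n <- nrow(values)
  if (n < 3) stop("need at least 3 participants")
  ys <- values[, "yes/same"]; yd <- values[, "yes/different"]
  ns <- values[, "no/same"]; nd <- values[, "no/different"]
  contrasts <- list(
    vision = (ys + yd) / 2 - (ns + nd) / 2,
    music = (ys + ns) / 2 - (yd + nd) / 2,
    interaction = (ys - yd) - (ns - nd))
  eff <- do.call(rbind, lapply(names(contrasts), function(e) {
    cvec <- contrasts[[e]]
    s <- stats::sd(cvec)
    Fv <- if (s == 0) {
      if (mean(cvec) == 0) 0 else Inf  # no error variance
    } else (mean(cvec) / (s / sqrt(n)))^2
    p <- stats::pf(Fv, 1, n - 1, lower.tail = FALSE)
    data.frame(effect = e, F = Fv, df1 = 1, df2 = n - 1, p = p,
               p_bonf = min(1, p * bonferroni_n))
  }))
  followups <- NULL
  if (eff$p_bonf[eff$effect == "interaction"] < followup_alpha) {
    fu <- function(label, a, b) {
      d <- a - b
      tt <- stats::t.test(d)
      data.frame(comparison = label, delta = mean(d),
                 se = stats::sd(d) / sqrt(n), p = tt$p.value)
    }
    followups <- rbind(
      fu("same - different | vision", ys, yd),
      fu("same - different | no vision", ns, nd))
  }
  structure(list(effects = eff, followups = followups, n = n),
            class = "anova_2x2")
}

#' @export
print.anova_2x2 <- function(x, ...) {
  cat("2x2 repeated-measures ANOVA (n =", x$n, ")\n")
  print(x$effects, row.names = FALSE)
  if (!is.null(x$followups)) {
    cat("follow-up paired comparisons:\n")
    print(x$followups, row.names = FALSE)
  }
  invisible(x)
}

#' Condition-wise ANOVA over every regressor of a partition result
#'
#' Electrode selection per regressor (all conditions for music/self, visual
#' conditions for other/coordination), averaging of delta r over the
#' selected electrodes, and the 2x2 repeated-measures ANOVA with Bonferroni
#' correction across the regressor family.
#'
#' @param partition result of [trf_partition()] whose reduced sets are the
#'   regressors of interest.
#' @return list per regressor: `channels`, `values` (participant x
#'   condition), `anova` (an `anova_2x2`).
#' @export
partition_anovas <- function(partition) {
  regs <- dimnames(partition$delta_r)[[4]]
  vis <- grep("^yes/", partition$conditions, value = TRUE)
  out <- lapply(regs, function(rg) {
    expected <- if (rg %in% c("other", "coordination")) vis else
      partition$conditions
    dr <- partition$delta_r[, , , rg, drop = FALSE]
    dim(dr) <- dim(partition$delta_r)[1:3]
    dimnames(dr) <- dimnames(partition$delta_r)[1:3]
    ch <- select_electrodes(dr, expected)
    vals <- average_over_electrodes(dr, ch)
    list(channels = ch, values = vals,
         anova = rm_anova_2x2(vals, bonferroni_n = length(regs)))
  })
  names(out) <- regs
  out
}
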