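#' IPCW time-dependent AUC
#'
#' Cumulative-case / dynamic-control area under the time-dependent ROC
#' curve at a fixed horizon, with inverse-probability-of-censoring weights.
#' Cases are subjects with an event by the horizon, controls those still
#' under observation beyond it. The censoring survival function `G` is
#' estimated by Kaplan-Meier on the flipped event indicator; cases are
#' weighted `1/G(T_i-)` and controls `1/G(t)`. Marker ties between a case
#' and a control count one half. With no censoring before the horizon the
#' weights are all 1 and the estimator reduces to plain case-control pair
#' counting.
#'
#' @param time Follow-up times (months).
#' @param event Event indicators (0/1).
#' @param marker Numeric risk marker; higher values are taken to indicate
#'   higher event risk (use a negated marker for a protective score).
#' @param horizon Evaluation time `t` in months, within follow-up.
#'
#' @return Object of class `td_auc`: `auc`, `horizon`, `n_cases`,
#'   `n_controls`.
#' @examples
#' set.seed(1)
#' t <- rexp(100, 0.05)
#' td_auc_ipcw(pmin(t, 40), as.integer(t <= 40), rank(t) * -1, horizon = 24)
#' @export
td_auc_ipcw <- function(time, event, marker, horizon) {
  event <- check_surv_input(time, event)
  if (length(marker) != length(time) || !is.numeric(marker) || anyNA(marker)) {
    stop("`marker` must be numeric, no missing values, matching `time`",
         call. = FALSE)
  }
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0 ||
      horizon > max(time)) {
    stop("`horizon` must be a single time within follow-up (0, ",
         max(time), "]", call. = FALSE)
  }
  cens_fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  g_right <- stats::stepfun(cens_fit$time, c(1, cens_fit$surv), right = FALSE)
  g_left  <- stats::stepfun(cens_fit$time, c(1, cens_fit$surv), right = TRUE)

  is_case <- time <= horizon & event == 1L
  is_ctrl <- time > horizon
  if (sum(is_case) < 1L || sum(is_ctrl) < 1L) {
    stop("need at least one case and one control at the horizon", call. = FALSE)
  }
  w_case <- 1 / g_left(time[is_case])
  w_ctrl <- rep(1 / g_right(horizon), sum(is_ctrl))
  if (any(!is.finite(w_case)) || any(!is.finite(w_ctrl))) {
    stop("censoring survival reaches zero before the horizon; ",
         "reduce `horizon`", call. = FALSE)
  }
  a <- marker[is_case]
  b <- marker[is_ctrl]
  conc <- outer(a, b, ">") + 0.5 * outer(a, b, "==")
  num <- as.numeric(t(w_case) %*% conc %*% w_ctrl)
  auc <- num / (sum(w_case) * sum(w_ctrl))
  structure(
    list(auc = auc, horizon = horizon,
         n_cases = sum(is_case), n_controls = sum(is_ctrl)),
    class = "td_auc"
  )
}

#' @export
print.td_auc <- function(x, ...) {
  cat(sprintf("IPCW time-dependent AUC at t = %g months: %.4f (%d cases, %d controls)\n",
              x$horizon, x$auc, x$n_cases, x$n_controls))
  invisible(x)
}
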