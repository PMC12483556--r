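check_surv_input <- function(time, event) {
  if (!is.numeric(time) || length(time) == 0L || anyNA(time)) {
    stop("`time` must be non-empty numeric without missing values", call. = FALSE)
  }
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("survival times must be finite and non-negative; offending value(s): ",
         paste(utils::head(time[!is.finite(time) | time < 0], 3), collapse = ", "),
         call. = FALSE)
  }
  if (is.logical(event)) event <- as.integer(event)
  if (!is.numeric(event) || length(event) != length(time) || anyNA(event) ||
      !all(event %in% c(0, 1))) {
    stop("`event` must be 0/1 (or logical) and match `time` in length",
         call. = FALSE)
  }
  as.integer(event)
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator with Greenwood standard errors, delegated to
#' [survival::survfit()] and repackaged as a light `km_curve` object whose
#' step function can be evaluated with [survival_at()].
#'
#' @param time Follow-up times (months), >= 0.
#' @param event Event indicator (1 = death, 0 = censored).
#' @param conf_level Confidence level for the Greenwood (log-scale) CI.
#'
#' @return Object of class `km_curve`: `time`, `surv`, `n_risk`, `n_event`,
#'   `n_censor`, `lower`, `upper`, `n`, `events`.
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 1, 1))
#' @export
km_estimate <- function(time, event, conf_level = 0.95) {
  event <- check_surv_input(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log", conf.int = conf_level)
  structure(
    list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
         n_event = fit$n.event, n_censor = fit$n.censor,
         lower = fit$lower, upper = fit$upper,
         n = length(time), events = sum(event), conf_level = conf_level),
    class = "km_curve"
  )
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: n =", x$n, ", events =", x$events, "\n")
  cat("  last observed time:", max(x$time), "; S =",
      signif(utils::tail(x$surv, 1), 4), "\n")
  invisible(x)
}

#' Evaluate a survival curve or model at given times
#'
#' Step-function evaluation for Kaplan-Meier curves (with a flagged
#' last-value extrapolation beyond the final observed time) and closed-form
#' evaluation for Weibull models.
#'
#' @param object A `km_curve` or `weibull_model`.
#' @param t Times (months), >= 0.
#' @param ... Method arguments; for `km_curve`, `conf = TRUE` returns a data
#'   frame with Greenwood CI bounds.
#' @return Survival probabilities (or a data frame when `conf = TRUE`).
#' @export
survival_at <- function(object, t, ...) UseMethod("survival_at")

#' @rdname survival_at
#' @param conf Return Greenwood CI columns as well.
#' @export
survival_at.km_curve <- function(object, t, conf = FALSE, ...) {
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  step <- function(y) stats::stepfun(object$time, c(1, y), right = FALSE)
  s <- step(object$surv)(t)
  extrapolated <- t > max(object$time)
  if (any(extrapolated)) {
    warning("evaluation beyond the last observed time (",
            max(object$time), "); returning last value (extrapolation)",
            call. = FALSE)
  }
  if (conf) {
    lo <- step(ifelse(is.na(object$lower), object$surv, object$lower))(t)
    hi <- step(ifelse(is.na(object$upper), object$surv, object$upper))(t)
    return(data.frame(t = t, surv = s, lower = lo, upper = hi,
                      extrapolated = extrapolated))
  }
  attr(s, "extrapolated") <- extrapolated
  s
}

# risk-set components at the distinct event times, for the group indicator g2
logrank_components <- function(time, event, g2) {
  ut <- sort(unique(time[event == 1L]))
  d  <- vapply(ut, function(u) sum(event[time == u]), numeric(1))
  d1 <- vapply(ut, function(u) sum(event[time == u & g2]), numeric(1))
  n  <- vapply(ut, function(u) sum(time >= u), numeric(1))
  n1 <- vapply(ut, function(u) sum(time >= u & g2), numeric(1))
  e1 <- d * n1 / n
  v  <- ifelse(n > 1, d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1), 0)
  list(time = ut, d = d, d1 = d1, n = n, n1 = n1, e1 = e1, v = v)
}

#' Two-sample log-rank test
#'
#' Standardized two-sample log-rank statistic `(O - E) / sqrt(V)` for the
#' second group level, with the hypergeometric variance, and the chi-square
#' p-value from its square (1 df). When no informative events exist the
#' statistic is flagged undefined rather than propagating NaN.
#'
#' @param time Follow-up times.
#' @param event Event indicators (0/1).
#' @param group Two-level grouping vector; the statistic is oriented to the
#'   second level (positive = more events than expected in that group).
#'
#' @return Object of class `logrank_test`: `statistic` (z), `chisq`,
#'   `p_value`, `observed`, `expected`, `variance`, `n`, `undefined`.
#' @examples
#' logrank_statistic(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
#' @export
logrank_statistic <- function(time, event, group) {
  event <- check_surv_input(time, event)
  group <- as.factor(group)
  if (nlevels(group) != 2L || length(group) != length(time)) {
    stop("`group` must have exactly 2 levels and match `time` in length",
         call. = FALSE)
  }
  if (min(table(group)) == 0L) stop("both groups must be non-empty", call. = FALSE)
  comp <- logrank_components(time, event, group == levels(group)[2L])
  o <- sum(comp$d1); e <- sum(comp$e1); v <- sum(comp$v)
  undefined <- v <= 0
  if (undefined) {
    warning("log-rank variance is zero (no informative events); ",
            "statistic undefined", call. = FALSE)
    z <- NA_real_
  } else {
    z <- (o - e) / sqrt(v)
  }
  structure(
    list(statistic = z, chisq = z^2,
         p_value = if (undefined) NA_real_ else stats::pchisq(z^2, 1, lower.tail = FALSE),
         observed = o, expected = e, variance = v,
         n = as.vector(table(group)), levels = levels(group),
         undefined = undefined),
    class = "logrank_test"
  )
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("Two-sample log-rank test (", paste(x$levels, collapse = " vs "), ")\n",
      sep = "")
  cat(sprintf("  z = %.4f, chisq = %.4f (1 df), p = %.4g\n",
              x$statistic, x$chisq, x$p_value))
  cat(sprintf("  O = %g, E = %.3f, V = %.3f in group %s\n",
              x$observed, x$expected, x$variance, x$levels[2]))
  invisible(x)
}
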