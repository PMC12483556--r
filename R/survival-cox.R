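#' Cox proportional hazards fit
#'
#' Thin wrapper around [survival::coxph()] that returns a tidy coefficient
#' table with hazard ratios, Wald confidence intervals and p-values.
#' Monotone-likelihood / non-convergent fits are turned into explicit
#' errors rather than silent warnings.
#'
#' @param data Data frame containing the survival columns and covariates.
#' @param covariates Character vector of covariate column names.
#' @param time,event Names of the follow-up time and event columns
#'   (defaults `time_months`, `event`).
#' @param ties Tie handling, default `"efron"`.
#' @param conf_level Confidence level for the Wald CIs.
#'
#' @return Object of class `cox_result`: `coefficients` (data frame with
#'   `term`, `estimate`, `se`, `hr`, `conf_low`, `conf_high`, `p_value`),
#'   `loglik`, `n`, `events`, `ties`, and the underlying `fit`.
#' @examples
#' d <- data.frame(time_months = c(5, 8, 12, 20, 33, 40),
#'                 event = c(1, 1, 0, 1, 0, 1),
#'                 x = c(1.2, 0.8, 0.1, -0.4, -1, 0.3))
#' fit_cox(d, "x")
#' @export
fit_cox <- function(data, covariates, time = "time_months", event = "event",
                    ties = "efron", conf_level = 0.95) {
  stopifnot(is.data.frame(data), is.character(covariates), length(covariates) > 0)
  missing_cols <- setdiff(c(time, event, covariates), names(data))
  if (length(missing_cols)) {
    stop("column(s) missing from `data`: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ev <- check_surv_input(data[[time]], data[[event]])
  if (sum(ev) < 1L) stop("Cox fit requires at least one event", call. = FALSE)
  fml <- stats::reformulate(covariates,
                            response = sprintf("survival::Surv(%s, %s)", time, event))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite", conditionMessage(w))) {
        stop("Cox fit failed (monotone likelihood or non-convergence): ",
             conditionMessage(w), call. = FALSE)
      }
      invokeRestart("muffleWarning")
    }
  )
  if (any(!is.finite(stats::coef(fit)))) {
    stop("Cox fit produced non-finite coefficients", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  tab <- data.frame(
    term = names(cf),
    estimate = unname(cf),
    se = unname(se),
    hr = unname(exp(cf)),
    conf_low = unname(exp(cf - z * se)),
    conf_high = unname(exp(cf + z * se)),
    p_value = unname(2 * stats::pnorm(-abs(cf / se))),
    stringsAsFactors = FALSE
  )
  structure(
    list(coefficients = tab, loglik = fit$loglik[length(fit$loglik)],
         n = fit$n, events = fit$nevent, ties = ties,
         conf_level = conf_level, fit = fit),
    class = "cox_result"
  )
}

#' @export
print.cox_result <- function(x, digits = 4, ...) {
  cat("Cox proportional hazards (ties =", x$ties, "): n =", x$n,
      ", events =", x$events, "\n")
  tab <- x$coefficients
  tab[-1] <- lapply(tab[-1], signif, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
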