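#' Weibull survival model
#'
#' Constructor for a two-parameter Weibull survival model
#' `S(t) = exp(-(t/scale)^shape)`, either specified directly or produced by
#' [fit_weibull()]. A degenerate "plateau" model (`S(t) = 1` over the
#' observed horizon) represents groups with zero observed events.
#'
#' @param shape Shape `k > 0` (dimensionless).
#' @param scale Scale `lambda > 0` (months).
#' @param n,events Optional fit metadata.
#' @param method Provenance label (`"specified"`, `"mle"`, `"km"`).
#' @param degenerate Zero-event plateau flag.
#' @param horizon Last observed time for a degenerate model.
#'
#' @return Object of class `weibull_model`.
#' @examples
#' weibull_model(shape = 2, scale = 50)
#' @export
weibull_model <- function(shape, scale, n = NA_integer_, events = NA_integer_,
                          method = "specified", degenerate = FALSE,
                          horizon = Inf) {
  if (!degenerate) {
    if (!is.numeric(shape) || length(shape) != 1L || !is.finite(shape) || shape <= 0) {
      stop("`shape` must be a single positive number", call. = FALSE)
    }
    if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0) {
      stop("`scale` must be a single positive number (months)", call. = FALSE)
    }
  }
  structure(
    list(shape = shape, scale = scale, n = n, events = events,
         method = method, degenerate = degenerate, horizon = horizon),
    class = "weibull_model"
  )
}

#' @export
print.weibull_model <- function(x, ...) {
  if (x$degenerate) {
    cat("Degenerate Weibull plateau: S(t) = 1 on [0, ", x$horizon,
        "] (zero events)\n", sep = "")
  } else {
    cat(sprintf("Weibull survival model (%s): shape = %.4g, scale = %.4g months\n",
                x$method, x$shape, x$scale))
    cat(sprintf("  median survival = %.2f months\n", weibull_median(x)))
  }
  invisible(x)
}

#' @rdname survival_at
#' @export
survival_at.weibull_model <- function(object, t, ...) {
  if (any(t < 0)) stop("`t` must be >= 0", call. = FALSE)
  if (object$degenerate) return(rep(1, length(t)))
  exp(-(t / object$scale)^object$shape)
}

#' Median of a Weibull survival model
#'
#' `scale * log(2)^(1/shape)`; `Inf` for a degenerate plateau model.
#'
#' @param model A `weibull_model`.
#' @return Median survival time in months.
#' @export
weibull_median <- function(model) {
  stopifnot(inherits(model, "weibull_model"))
  if (model$degenerate) return(Inf)
  model$scale * log(2)^(1 / model$shape)
}

#' Weibull model through two survival anchors
#'
#' Closed-form shape/scale such that `S(t1) = s1` and `S(t2) = s2`
#' (`0 < s2 < s1 < 1`, `t2 > t1`). Used to specify group outcome models
#' from printed survival proportions.
#'
#' @param t1,s1,t2,s2 Anchor times (months) and survival probabilities.
#' @return A `weibull_model`.
#' @examples
#' m <- weibull_from_survival(36, 0.90, 60, 0.80)
#' survival_at(m, c(36, 60))
#' @export
weibull_from_survival <- function(t1, s1, t2, s2) {
  stopifnot(t2 > t1, t1 > 0, s1 < 1, s1 > 0, s2 < s1, s2 > 0)
  k <- log(log(s2) / log(s1)) / log(t2 / t1)
  lambda <- t1 / (-log(s1))^(1 / k)
  weibull_model(shape = k, scale = lambda, method = "anchored")
}

weibull_negloglik <- function(par, time, event) {
  k <- exp(par[1]); lam <- exp(par[2])
  tt <- pmax(time, .Machine$double.eps)
  ll <- sum(event * (log(k) - log(lam) + (k - 1) * (log(tt) - log(lam)))) -
    sum((tt / lam)^k)
  -ll
}

#' Fit a Weibull survival model to right-censored data
#'
#' Two estimation routes: `"mle"` (default) maximizes the right-censored
#' Weibull likelihood; `"km"` least-squares fits the Weibull survival
#' function to the Kaplan-Meier steps at the observed event times. Groups
#' with zero events cannot identify a proper Weibull: the default returns a
#' flagged degenerate plateau model (`S = 1` over the observed horizon),
#' and `zero_events = "pseudo"` instead places a single pseudo-event at the
#' last follow-up time and fits by MLE.
#'
#' @param time Follow-up times (months).
#' @param event Event indicators (0/1).
#' @param method `"mle"` or `"km"`.
#' @param zero_events `"plateau"` (default) or `"pseudo"`.
#'
#' @return A `weibull_model`.
#' @examples
#' set.seed(1)
#' t <- rweibull(200, 1.5, 80); c <- runif(200, 0, 120)
#' fit_weibull(pmin(t, c), as.integer(t <= c))
#' @export
fit_weibull <- function(time, event, method = c("mle", "km"),
                        zero_events = c("plateau", "pseudo")) {
  method <- match.arg(method)
  zero_events <- match.arg(zero_events)
  event <- check_surv_input(time, event)
  pseudo <- FALSE
  if (sum(event) == 0L) {
    if (zero_events == "plateau") {
      warning("no events observed; returning degenerate plateau model S(t) = 1",
              call. = FALSE)
      return(weibull_model(NA_real_, NA_real_, n = length(time), events = 0L,
                           method = paste0(method, "/plateau"),
                           degenerate = TRUE, horizon = max(time)))
    }
    event[which.max(time)] <- 1L
    pseudo <- TRUE
  }
  if (method == "mle") {
    init <- c(0, log(sum(time) / max(sum(event), 1)))
    opt <- stats::optim(init, weibull_negloglik, time = time, event = event,
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (opt$convergence != 0) {
      stop("Weibull MLE did not converge (optim code ", opt$convergence, ")",
           call. = FALSE)
    }
    out <- weibull_model(exp(opt$par[1]), exp(opt$par[2]),
                         n = length(time), events = sum(event),
                         method = if (pseudo) "mle/pseudo-event" else "mle")
    attr(out, "loglik") <- -opt$value
  } else {
    km <- km_estimate(time, event)
    steps <- km$n_event > 0
    tt <- km$time[steps]; ss <- km$surv[steps]
    keep <- ss > 0 & tt > 0
    if (sum(keep) < 2L) {
      stop("KM curve-fit requires at least 2 positive-survival event steps",
           call. = FALSE)
    }
    tt <- tt[keep]; ss <- ss[keep]
    # initialize from the linearized Weibull plot, then polish
    y <- log(-log(ss)); x <- log(tt)
    b <- stats::coef(stats::lm(y ~ x))
    init <- c(log(max(b[2], 0.05)), -b[1] / max(b[2], 0.05))
    sse <- function(par) {
      k <- exp(par[1]); lam <- exp(par[2])
      sum((exp(-(tt / lam)^k) - ss)^2)
    }
    opt <- stats::optim(init, sse, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    out <- weibull_model(exp(opt$par[1]), exp(opt$par[2]),
                         n = length(time), events = sum(event),
                         method = if (pseudo) "km/pseudo-event" else "km")
    attr(out, "sse") <- opt$value
  }
  out
}
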