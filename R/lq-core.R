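#' Linear-quadratic model parameters
#'
#' Container for the radiobiological constants used throughout the package.
#' The genomic linear coefficient `alpha_g` is defined relative to a single
#' reference fraction of 2 Gy (the dose at which RSI estimates the surviving
#' fraction), with the quadratic coefficient `beta` held fixed across
#' patients.
#'
#' @param beta Quadratic coefficient of the linear-quadratic model, in
#'   Gy^-2. Fixed across patients; default 0.05.
#' @param alpha_beta_eqd2 Alpha/beta ratio used for EQD2 conversion, in Gy.
#'   Default 10, the standard tumor assumption.
#'
#' @return An object of class `lq_params` with fields `beta`,
#'   `reference_dose` (2 Gy), `reference_fractions` (1) and
#'   `alpha_beta_eqd2`.
#' @examples
#' lq_params()
#' @export
lq_params <- function(beta = 0.05, alpha_beta_eqd2 = 10) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0) {
    stop("`beta` must be a single positive number (Gy^-2), got ",
         deparse(beta), call. = FALSE)
  }
  if (!is.numeric(alpha_beta_eqd2) || length(alpha_beta_eqd2) != 1L ||
      !is.finite(alpha_beta_eqd2) || alpha_beta_eqd2 <= 0) {
    stop("`alpha_beta_eqd2` must be a single positive number (Gy), got ",
         deparse(alpha_beta_eqd2), call. = FALSE)
  }
  structure(
    list(beta = beta, reference_dose = 2, reference_fractions = 1L,
         alpha_beta_eqd2 = alpha_beta_eqd2),
    class = "lq_params"
  )
}

#' @export
print.lq_params <- function(x, ...) {
  cat("Linear-quadratic parameters\n")
  cat("  beta:              ", x$beta, "Gy^-2\n")
  cat("  reference:         ", x$reference_fractions, "fraction(s) of",
      x$reference_dose, "Gy\n")
  cat("  alpha/beta (EQD2): ", x$alpha_beta_eqd2, "Gy\n")
  invisible(x)
}

#' Fractionation schedule
#'
#' A (vectorized) radiotherapy fractionation schedule: `n_fractions` daily
#' fractions of `dose_per_fraction` Gy each.
#'
#' @param n_fractions Positive integer number of fractions (recycled).
#' @param dose_per_fraction Dose per fraction in Gy, > 0 (recycled).
#'
#' @return An object of class `fx_schedule` with fields `n_fractions`,
#'   `dose_per_fraction` and the derived `total_dose` in Gy.
#' @examples
#' fx_schedule(35, 2)      # 70 Gy standard of care
#' fx_schedule(33, 2.12)   # 69.96 Gy moderate hypofractionation
#' @export
fx_schedule <- function(n_fractions, dose_per_fraction) {
  if (length(n_fractions) == 0L || length(dose_per_fraction) == 0L) {
    stop("`n_fractions` and `dose_per_fraction` must be non-empty", call. = FALSE)
  }
  len <- max(length(n_fractions), length(dose_per_fraction))
  n <- rep_len(as.numeric(n_fractions), len)
  d <- rep_len(as.numeric(dose_per_fraction), len)
  if (anyNA(n) || any(!is.finite(n)) || any(n < 1) || any(n != round(n))) {
    stop("`n_fractions` must be whole numbers >= 1; got ",
         paste(utils::head(n[is.na(n) | n < 1 | n != round(n)], 3), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(d) || any(!is.finite(d)) || any(d <= 0)) {
    stop("`dose_per_fraction` must be positive and finite; got ",
         paste(utils::head(d[is.na(d) | d <= 0], 3), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(n_fractions = as.integer(n), dose_per_fraction = d, total_dose = n * d),
    class = "fx_schedule"
  )
}

#' @export
length.fx_schedule <- function(x) length(x$n_fractions)

#' @export
`[.fx_schedule` <- function(x, i) {
  fx_schedule(x$n_fractions[i], x$dose_per_fraction[i])
}

#' @export
print.fx_schedule <- function(x, ...) {
  k <- length(x)
  cat("Fractionation schedule (", k, " plan", if (k != 1) "s", ")\n", sep = "")
  show <- utils::head(seq_len(k), 6)
  for (i in show) {
    cat(sprintf("  %g Gy = %d x %g Gy\n", x$total_dose[i], x$n_fractions[i],
                x$dose_per_fraction[i]))
  }
  if (k > 6) cat("  ...\n")
  invisible(x)
}

#' Genomic linear coefficient from RSI
#'
#' Back-solves the patient-specific linear coefficient `alpha_g` of the
#' linear-quadratic survival model from the radiosensitivity index, which
#' estimates the surviving fraction after a single 2 Gy fraction:
#' `alpha_g = -log(rsi) / (n * d) - beta * d` with `n = 1`, `d = 2` Gy.
#' With the default `beta = 0.05` this is `-log(rsi)/2 - 0.1`.
#'
#' Tumors with RSI above `exp(-0.2)` imply a negative `alpha_g`; this is
#' admissible in the GARD framework (GARD stays non-negative for doses per
#' fraction >= 2 Gy) but is flagged with a warning.
#'
#' @param rsi Radiosensitivity index, surviving fraction in (0, 1].
#' @param params [lq_params()].
#'
#' @return Numeric vector of `alpha_g` values in Gy^-1.
#' @examples
#' alpha_g_from_rsi(exp(-0.2))  # exactly 0
#' @export
alpha_g_from_rsi <- function(rsi, params = lq_params()) {
  stopifnot(inherits(params, "lq_params"))
  if (!is.numeric(rsi) || length(rsi) == 0L || anyNA(rsi)) {
    stop("`rsi` must be numeric without missing values", call. = FALSE)
  }
  bad <- rsi <= 0 | rsi > 1
  if (any(bad)) {
    stop("RSI must lie in (0, 1]; offending value(s): ",
         paste(utils::head(signif(rsi[bad], 6), 5), collapse = ", "),
         call. = FALSE)
  }
  nd <- params$reference_fractions * params$reference_dose
  alpha <- -log(rsi) / nd - params$beta * params$reference_dose
  if (any(alpha < 0)) {
    warning(sum(alpha < 0), " RSI value(s) > exp(-",
            params$beta * params$reference_dose * nd,
            ") imply negative alpha_g", call. = FALSE)
  }
  alpha
}

#' Invert alpha_g back to RSI
#'
#' @param alpha_g Genomic linear coefficient, Gy^-1.
#' @param params [lq_params()].
#' @return RSI values, `exp(-(n*d) * (alpha_g + beta*d))`.
#' @export
rsi_from_alpha_g <- function(alpha_g, params = lq_params()) {
  stopifnot(inherits(params, "lq_params"), is.numeric(alpha_g))
  nd <- params$reference_fractions * params$reference_dose
  exp(-nd * (alpha_g + params$beta * params$reference_dose))
}

#' GARD for a fractionation schedule
#'
#' The genomic adjusted radiation dose: the biological treatment effect of
#' delivering `n_c` fractions of `d_c` Gy to a tumor with genomic linear
#' coefficient `alpha_g`, computed as `GARD = n_c * d_c * (alpha_g + beta * d_c)`.
#' At 2 Gy per fraction this equals `-n_c * log(rsi)` exactly.
#'
#' @param alpha_g Genomic linear coefficient(s), Gy^-1 (recycled against the
#'   schedule).
#' @param schedule [fx_schedule()].
#' @param params [lq_params()].
#'
#' @return Numeric vector of GARD values (dimensionless). GARD can only be
#'   negative when `dose_per_fraction < 2` Gy and `alpha_g` is strongly
#'   negative; such values are flagged with a warning, never clipped.
#' @examples
#' a <- alpha_g_from_rsi(0.4)
#' gard_from_schedule(a, fx_schedule(35, 2))
#' @export
gard_from_schedule <- function(alpha_g, schedule, params = lq_params()) {
  stopifnot(inherits(params, "lq_params"), inherits(schedule, "fx_schedule"))
  if (!is.numeric(alpha_g) || length(alpha_g) == 0L || any(!is.finite(alpha_g))) {
    stop("`alpha_g` must be finite numeric", call. = FALSE)
  }
  len <- max(length(alpha_g), length(schedule))
  a <- rep_len(alpha_g, len)
  n <- rep_len(schedule$n_fractions, len)
  d <- rep_len(schedule$dose_per_fraction, len)
  g <- n * d * (a + params$beta * d)
  if (any(g < 0)) {
    warning(sum(g < 0), " negative GARD value(s) (dose per fraction < 2 Gy ",
            "with negative alpha_g); values returned unclipped", call. = FALSE)
  }
  g
}

#' Recover alpha_g from a delivered GARD value
#'
#' Inverse of [gard_from_schedule()]: `alpha_g = gard / (n_c * d_c) - beta * d_c`.
#' Useful when only summary GARD values at a known schedule are available.
#'
#' @param gard GARD value(s).
#' @param schedule [fx_schedule()] at which `gard` was achieved.
#' @param params [lq_params()].
#' @return Numeric `alpha_g` in Gy^-1.
#' @examples
#' alpha_g_from_gard(71.7, fx_schedule(35, 2))
#' @export
alpha_g_from_gard <- function(gard, schedule, params = lq_params()) {
  stopifnot(inherits(params, "lq_params"), inherits(schedule, "fx_schedule"))
  len <- max(length(gard), length(schedule))
  g <- rep_len(as.numeric(gard), len)
  n <- rep_len(schedule$n_fractions, len)
  d <- rep_len(schedule$dose_per_fraction, len)
  g / (n * d) - params$beta * d
}

#' Equivalent dose in 2 Gy fractions
#'
#' Standard fractionation correction:
#' `EQD2 = D * (d + alpha/beta) / (2 + alpha/beta)` where `D` is total dose
#' and `d` dose per fraction. A schedule delivered at exactly 2 Gy per
#' fraction has `EQD2 = D`.
#'
#' @param schedule [fx_schedule()].
#' @param alpha_beta Alpha/beta ratio in Gy (default 10).
#' @return EQD2 in Gy.
#' @examples
#' eqd2(fx_schedule(33, 2.12))  # 70.66 Gy
#' @export
eqd2 <- function(schedule, alpha_beta = 10) {
  stopifnot(inherits(schedule, "fx_schedule"))
  if (!is.numeric(alpha_beta) || length(alpha_beta) != 1L ||
      !is.finite(alpha_beta) || alpha_beta <= 0) {
    stop("`alpha_beta` must be a single positive number (Gy)", call. = FALSE)
  }
  schedule$total_dose * (schedule$dose_per_fraction + alpha_beta) / (2 + alpha_beta)
}

#' Minimum dose to reach a target GARD
#'
#' Inverse GARD solver: the minimum continuous total dose, delivered at
#' `dose_per_fraction` Gy per fraction, for a patient with genomic
#' coefficient `alpha_g` to achieve `target_gard`:
#' `D = target_gard / (alpha_g + beta * d)`. The fraction count is rounded
#' up so the achieved GARD never undershoots the target, while the
#' whole-Gy display dose uses the integer part of the continuous dose.
#'
#' @param alpha_g Genomic linear coefficient(s), Gy^-1.
#' @param target_gard Target GARD (> 0); default 32, an iso-curative target.
#' @param dose_per_fraction Prescription dose per fraction in Gy (default 2).
#' @param params [lq_params()].
#' @param delivered Optional [fx_schedule()] actually delivered, used to
#'   compute dose deltas and the underdosed flag.
#' @param reference_fractions Fraction count of the reference plan used for
#'   `fraction_delta` (default 35, i.e. 70 Gy at 2 Gy/fraction).
#' @param unreachable How to treat patients with `alpha_g + beta*d <= 0`,
#'   for whom no finite dose reaches the target: `"error"` (default) or
#'   `"na"` (flagged per patient).
#' @param patient_id Optional identifiers carried into the result.
#'
#' @return A data frame of class `gard_prescription` with columns
#'   `patient_id`, `alpha_g`, `target_gard`, `dose_per_fraction`,
#'   `required_dose_continuous`, `required_dose_gy` (integer part),
#'   `required_fractions` (ceiling), `achieved_gard`, `fraction_delta`
#'   (`reference_fractions - required_fractions`; positive = fractions
#'   spared) and `unreachable`; plus `delivered_dose`, `dose_delta`
#'   (`delivered - required`, Gy) and `underdosed` when `delivered` is given.
#' @examples
#' a <- alpha_g_from_gard(c(71.7, 19.7), fx_schedule(35, 2))
#' dose_for_target_gard(a, target_gard = 32)
#' @export
dose_for_target_gard <- function(alpha_g, target_gard = 32,
                                 dose_per_fraction = 2,
                                 params = lq_params(),
                                 delivered = NULL,
                                 reference_fractions = 35,
                                 unreachable = c("error", "na"),
                                 patient_id = NULL) {
  stopifnot(inherits(params, "lq_params"))
  unreachable <- match.arg(unreachable)
  if (!is.numeric(target_gard) || length(target_gard) != 1L || target_gard < 0 ||
      !is.finite(target_gard)) {
    stop("`target_gard` must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(dose_per_fraction) || length(dose_per_fraction) != 1L ||
      dose_per_fraction <= 0) {
    stop("`dose_per_fraction` must be a single positive dose in Gy", call. = FALSE)
  }
  d <- dose_per_fraction
  k <- length(alpha_g)
  id <- if (is.null(patient_id)) seq_len(k) else rep_len(patient_id, k)
  denom <- alpha_g + params$beta * d
  bad <- denom <= 0 & target_gard > 0
  if (any(bad) && unreachable == "error") {
    stop("target GARD ", target_gard, " unreachable at ", d,
         " Gy/fraction for patient(s): ",
         paste(utils::head(id[bad], 5), collapse = ", "),
         " (alpha_g + beta*d <= 0)", call. = FALSE)
  }
  dose <- ifelse(bad, NA_real_, target_gard / denom)
  # round before ceiling/floor so exact inverse round trips are not pushed
  # to the next integer by floating noise
  fx <- as.integer(ceiling(round(dose / d, 9)))
  fx[!bad & target_gard == 0] <- 0L
  out <- data.frame(
    patient_id = id,
    alpha_g = alpha_g,
    target_gard = target_gard,
    dose_per_fraction = d,
    required_dose_continuous = dose,
    required_dose_gy = floor(round(dose, 9)),
    required_fractions = fx,
    achieved_gard = fx * d * denom,
    fraction_delta = as.integer(reference_fractions) - fx,
    unreachable = bad,
    stringsAsFactors = FALSE
  )
  if (!is.null(delivered)) {
    stopifnot(inherits(delivered, "fx_schedule"))
    out$delivered_dose <- rep_len(delivered$total_dose, k)
    out$dose_delta <- out$delivered_dose - out$required_dose_continuous
    out$underdosed <- !bad & out$required_dose_continuous > out$delivered_dose + 1e-9
  }
  class(out) <- c("gard_prescription", "data.frame")
  out
}

#' Dichotomize GARD at a cut point
#'
#' @param gard GARD value(s).
#' @param cutpoint Cut point; the boundary belongs to the high group
#'   (`high` iff `gard >= cutpoint`). Default 42.
#' @return Factor with levels `low`, `high`.
#' @examples
#' classify_gard_group(c(41.999, 42))
#' @export
classify_gard_group <- function(gard, cutpoint = 42) {
  if (!is.numeric(cutpoint) || length(cutpoint) != 1L || !is.finite(cutpoint)) {
    stop("`cutpoint` must be a single finite number", call. = FALSE)
  }
  factor(ifelse(gard >= cutpoint, "high", "low"), levels = c("low", "high"))
}

#' Fractions spared relative to a reference plan
#'
#' @param prescription A `gard_prescription` from [dose_for_target_gard()].
#' @param reference_fractions Reference fraction count (default 35).
#' @return Signed integer vector: positive = fractions spared, negative =
#'   fractions added.
#' @export
fraction_delta <- function(prescription, reference_fractions = 35) {
  stopifnot(inherits(prescription, "gard_prescription"))
  as.integer(reference_fractions) - prescription$required_fractions
}
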