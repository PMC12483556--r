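#' Smoothed bootstrap of an RSI distribution
#'
#' Draws virtual-patient RSI values by sampling the source values with
#' replacement and adding independent Gaussian kernel noise — i.e. sampling
#' from a Gaussian kernel density estimate of the source distribution. The
#' default bandwidth is Silverman's rule-of-thumb
#' (`0.9 * min(sd, IQR/1.349) * m^(-1/5)`, R's `nrd0`). Values pushed
#' outside the open unit interval by the noise are clipped to
#' `(0.001, 0.999)` and the clip count is recorded.
#'
#' @param rsi Source RSI values (each in (0, 1)).
#' @param n Number of virtual patients to draw.
#' @param bandwidth `"nrd0"` (default) or a non-negative number; 0 gives a
#'   plain bootstrap.
#' @param seed Optional seed.
#' @param bounds Clip bounds, default `c(0.001, 0.999)`.
#'
#' @return Numeric vector of length `n` with attribute `n_clipped`.
#' @examples
#' smoothed_bootstrap_rsi(runif(50, 0.2, 0.6), 10, seed = 1)
#' @export
smoothed_bootstrap_rsi <- function(rsi, n, bandwidth = "nrd0", seed = NULL,
                                   bounds = c(0.001, 0.999)) {
  if (!is.numeric(rsi) || length(rsi) == 0L || anyNA(rsi) ||
      any(rsi <= 0 | rsi >= 1)) {
    stop("`rsi` must be a non-empty numeric vector with values in (0, 1)",
         call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a single count >= 1", call. = FALSE)
  }
  if (identical(bandwidth, "nrd0")) {
    if (length(rsi) < 2L || stats::sd(rsi) == 0) {
      stop("bandwidth rule `nrd0` is degenerate for a source with fewer than ",
           "2 distinct values; supply a numeric bandwidth", call. = FALSE)
    }
    bw <- stats::bw.nrd0(rsi)
    if (!is.finite(bw) || bw <= 0) {
      stop("bandwidth rule `nrd0` yielded a non-positive bandwidth", call. = FALSE)
    }
  } else {
    if (!is.numeric(bandwidth) || length(bandwidth) != 1L || bandwidth < 0) {
      stop("`bandwidth` must be \"nrd0\" or a single non-negative number",
           call. = FALSE)
    }
    bw <- bandwidth
  }
  if (!is.null(seed)) set.seed(seed)
  out <- sample(rsi, n, replace = TRUE)
  if (bw > 0) out <- out + stats::rnorm(n, 0, bw)
  clipped <- sum(out < bounds[1] | out > bounds[2])
  out <- pmin(pmax(out, bounds[1]), bounds[2])
  attr(out, "bandwidth") <- bw
  attr(out, "n_clipped") <- clipped
  out
}

#' Mixture survival curve over GARD groups
#'
#' Weighted average of component survival curves,
#' `S(t) = sum_g p_g * S_g(t)`, used to predict arm-level outcomes from
#' GARD-group composition.
#'
#' @param models List of survival models (each supporting [survival_at()]),
#'   e.g. `list(low = ..., high = ...)`.
#' @param proportions Non-negative weights matching `models`, summing to 1
#'   (within 1e-9).
#' @param times Evaluation times.
#' @return Numeric vector `S(times)`.
#' @examples
#' ms <- list(low = weibull_from_survival(36, 0.90, 60, 0.80),
#'            high = weibull_from_survival(36, 0.995, 60, 0.99))
#' predict_survival_mixture(ms, c(low = 0.5, high = 0.5), 36)
#' @export
predict_survival_mixture <- function(models, proportions, times) {
  stopifnot(is.list(models), length(models) == length(proportions))
  if (any(proportions < 0)) stop("proportions must be >= 0", call. = FALSE)
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must sum to 1 (got ", sum(proportions), ")", call. = FALSE)
  }
  if (!is.null(names(proportions)) && !is.null(names(models))) {
    proportions <- proportions[names(models)]
  }
  s <- rep(0, length(times))
  for (i in seq_along(models)) {
    s <- s + proportions[[i]] * survival_at(models[[i]], times)
  }
  unname(s)
}

#' In silico trial design
#'
#' Configuration for the simulated de-escalation trials: control and
#' experimental fractionation, the GARD risk cut point, the iso-curative
#' equipoise target, arm size and replicate count.
#'
#' @param design One of `"unselected_deescalation"`,
#'   `"gard_selected_deescalation"`, `"personalized_iso_gard"`.
#' @param control_schedule Control-arm [fx_schedule()] (default 70 Gy in 35
#'   fractions).
#' @param experimental_schedule De-escalated [fx_schedule()] (default 60 Gy
#'   in 30 fractions of 2 Gy).
#' @param gard_cutpoint Risk-group cut point (default 42).
#' @param target_gard Iso-curative equipoise target (default 32).
#' @param n_per_arm Virtual patients per arm (default 200).
#' @param replicates Trial replicates (default 100).
#' @param lq [lq_params()].
#' @return Object of class `trial_design`.
#' @export
trial_design <- function(design = c("unselected_deescalation",
                                    "gard_selected_deescalation",
                                    "personalized_iso_gard"),
                         control_schedule = fx_schedule(35, 2),
                         experimental_schedule = fx_schedule(30, 2),
                         gard_cutpoint = 42, target_gard = 32,
                         n_per_arm = 200, replicates = 100,
                         lq = lq_params()) {
  design <- match.arg(design)
  stopifnot(inherits(control_schedule, "fx_schedule"),
            inherits(experimental_schedule, "fx_schedule"),
            inherits(lq, "lq_params"))
  if (n_per_arm < 2) stop("`n_per_arm` must be >= 2", call. = FALSE)
  if (replicates < 1) stop("`replicates` must be >= 1", call. = FALSE)
  structure(
    list(design = design, control_schedule = control_schedule,
         experimental_schedule = experimental_schedule,
         gard_cutpoint = gard_cutpoint, target_gard = target_gard,
         n_per_arm = n_per_arm, replicates = replicates, lq = lq),
    class = "trial_design"
  )
}

arm_outcome <- function(gard, cutpoint, group_models, times) {
  grp <- classify_gard_group(gard, cutpoint)
  p_high <- mean(grp == "high")
  props <- c(low = 1 - p_high, high = p_high)
  curve <- predict_survival_mixture(group_models, props, times)
  list(n_low = sum(grp == "low"), n_high = sum(grp == "high"),
       p_high = p_high, curve = curve,
       os36 = predict_survival_mixture(group_models, props, 36))
}

summarize_trial <- function(design, reps, curves, times, extra = list(),
                            seed = NA) {
  arms <- split(reps, reps$arm)
  arm_summ <- lapply(arms, function(a) {
    list(os36_mean = mean(a$os36),
         os36_ci = unname(stats::quantile(a$os36, c(0.025, 0.975))),
         mean_n_low = mean(a$n_low), mean_n_high = mean(a$n_high))
  })
  mean_curves <- lapply(split(curves, curves$arm), function(cc) {
    stats::aggregate(surv ~ time, data = cc, FUN = mean)
  })
  structure(
    c(list(design = design, arms = arm_summ, replicates = reps,
           curves = mean_curves, times = times, seed = seed), extra),
    class = "trial_summary"
  )
}

#' @export
print.trial_summary <- function(x, ...) {
  cat("In silico trial:", x$design$design, "\n")
  cat("  n per arm:", x$design$n_per_arm, "; replicates:",
      x$design$replicates, "\n")
  for (arm in names(x$arms)) {
    a <- x$arms[[arm]]
    cat(sprintf("  %s arm: 36-month OS %.1f%% (replicate 95%% CI %.1f-%.1f%%); mean groups low/high = %.1f/%.1f\n",
                arm, 100 * a$os36_mean, 100 * a$os36_ci[1], 100 * a$os36_ci[2],
                a$mean_n_low, a$mean_n_high))
  }
  if (!is.null(x$eligibility_fraction)) {
    cat(sprintf("  mean de-escalation eligibility: %.1f%%\n",
                100 * x$eligibility_fraction))
  }
  invisible(x)
}

#' Unselected dose de-escalation trial
#'
#' Simulates a two-arm trial comparing uniform standard dosing (control)
#' with uniform de-escalation (experimental). Each replicate draws
#' `n_per_arm` virtual patients per arm by smoothed bootstrap of the source
#' RSI values, computes GARD at the arm's schedule, classifies patients at
#' the GARD cut point, and predicts arm survival as the GARD-group mixture
#' of the supplied Weibull models. Replicate 36-month OS values yield
#' 2.5/97.5 percentile intervals.
#'
#' @param rsi_source Source RSI values defining the virtual-patient
#'   distribution.
#' @param group_models `list(low = , high = )` of survival models for the
#'   GARD groups (fit once on the source cohort).
#' @param design [trial_design()].
#' @param seed Seed for the whole run (reproducible bit for bit).
#' @param times Curve evaluation grid in months.
#' @param bandwidth Kernel bandwidth passed to [smoothed_bootstrap_rsi()];
#'   the default computes `nrd0` once on the source.
#' @return A `trial_summary`.
#' @export
run_unselected_deescalation_trial <- function(rsi_source, group_models,
                                              design = trial_design("unselected_deescalation"),
                                              seed = 1,
                                              times = seq(0, 60, by = 1),
                                              bandwidth = "nrd0") {
  stopifnot(inherits(design, "trial_design"))
  bw <- if (identical(bandwidth, "nrd0")) stats::bw.nrd0(rsi_source) else bandwidth
  set.seed(seed)
  schedules <- list(control = design$control_schedule,
                    experimental = design$experimental_schedule)
  reps <- list(); curves <- list()
  for (r in seq_len(design$replicates)) {
    for (arm in names(schedules)) {
      rsi <- smoothed_bootstrap_rsi(rsi_source, design$n_per_arm, bandwidth = bw)
      alpha <- suppressWarnings(alpha_g_from_rsi(rsi, design$lq))
      gard <- gard_from_schedule(alpha, schedules[[arm]], design$lq)
      out <- arm_outcome(gard, design$gard_cutpoint, group_models, times)
      reps[[length(reps) + 1L]] <- data.frame(
        replicate = r, arm = arm, os36 = out$os36,
        n_low = out$n_low, n_high = out$n_high)
      curves[[length(curves) + 1L]] <- data.frame(
        replicate = r, arm = arm, time = times, surv = out$curve)
    }
  }
  summarize_trial(design, do.call(rbind, reps), do.call(rbind, curves),
                  times, seed = seed)
}

#' GARD-selected dose de-escalation trial
#'
#' Control arm: uniform standard dosing. Experimental arm: only patients
#' who are GARD-high at the de-escalated schedule (and hence remain in the
#' high-risk-free group after de-escalation) receive the de-escalated dose;
#' everyone else stays at the control schedule. Because de-escalated
#' patients remain GARD-high by construction, the arm's group composition
#' matches the control arm in distribution and the design predicts
#' equivalent survival.
#'
#' @inheritParams run_unselected_deescalation_trial
#' @return A `trial_summary` with an `eligibility_fraction` element (mean
#'   fraction of the experimental arm eligible for de-escalation).
#' @export
run_gard_selected_trial <- function(rsi_source, group_models,
                                    design = trial_design("gard_selected_deescalation"),
                                    seed = 1, times = seq(0, 60, by = 1),
                                    bandwidth = "nrd0") {
  stopifnot(inherits(design, "trial_design"))
  bw <- if (identical(bandwidth, "nrd0")) stats::bw.nrd0(rsi_source) else bandwidth
  set.seed(seed)
  reps <- list(); curves <- list(); elig <- numeric(0)
  for (r in seq_len(design$replicates)) {
    # control arm
    rsi_c <- smoothed_bootstrap_rsi(rsi_source, design$n_per_arm, bandwidth = bw)
    alpha_c <- suppressWarnings(alpha_g_from_rsi(rsi_c, design$lq))
    gard_c <- gard_from_schedule(alpha_c, design$control_schedule, design$lq)
    out_c <- arm_outcome(gard_c, design$gard_cutpoint, group_models, times)
    # experimental arm: de-escalate only patients still high at the lower dose
    rsi_e <- smoothed_bootstrap_rsi(rsi_source, design$n_per_arm, bandwidth = bw)
    alpha_e <- suppressWarnings(alpha_g_from_rsi(rsi_e, design$lq))
    g_ctl <- gard_from_schedule(alpha_e, design$control_schedule, design$lq)
    g_exp <- gard_from_schedule(alpha_e, design$experimental_schedule, design$lq)
    eligible <- g_exp >= design$gard_cutpoint
    g_assigned <- ifelse(eligible, g_exp, g_ctl)
    out_e <- arm_outcome(g_assigned, design$gard_cutpoint, group_models, times)
    elig <- c(elig, mean(eligible))
    reps[[length(reps) + 1L]] <- data.frame(
      replicate = r, arm = "control", os36 = out_c$os36,
      n_low = out_c$n_low, n_high = out_c$n_high)
    reps[[length(reps) + 1L]] <- data.frame(
      replicate = r, arm = "experimental", os36 = out_e$os36,
      n_low = out_e$n_low, n_high = out_e$n_high)
    curves[[length(curves) + 1L]] <- data.frame(
      replicate = r, arm = "control", time = times, surv = out_c$curve)
    curves[[length(curves) + 1L]] <- data.frame(
      replicate = r, arm = "experimental", time = times, surv = out_e$curve)
  }
  summarize_trial(design, do.call(rbind, reps), do.call(rbind, curves), times,
                  extra = list(eligibility_fraction = mean(elig),
                               eligibility_by_replicate = elig),
                  seed = seed)
}

#' Personalized iso-GARD dose prescription
#'
#' For each patient, computes the minimum dose (at a fixed dose per
#' fraction) achieving the target GARD, compares it with the delivered
#' plan, and summarizes the population-level dose and fraction savings.
#' Patients whose required dose exceeds the delivered dose are flagged
#' underdosed. When outcome columns are present, Kaplan-Meier curves are
#' produced for the subgroup whose delivered GARD met the target versus the
#' whole cohort (the equipoise comparison).
#'
#' @param cohort Cohort data frame with columns `rsi` (or `alpha_g`),
#'   `n_fractions`, `dose_per_fraction`, optionally `patient_id`,
#'   `time_months`, `event`.
#' @param target_gard Target GARD (default 32).
#' @param dose_per_fraction Prescription dose per fraction in Gy (default 2).
#' @param reference_fractions Reference fraction count (default 35).
#' @param params [lq_params()].
#'
#' @return Object of class `iso_gard_report`: `prescriptions` (per-patient
#'   data frame), `mean_fraction_delta`, `total_dose_delta`,
#'   `prop_underdosed`, `prop_requiring_60_70`, `n_unreachable`, and (when
#'   outcomes are available) `km_achieved` / `km_all`.
#' @export
run_personalized_iso_gard <- function(cohort, target_gard = 32,
                                      dose_per_fraction = 2,
                                      reference_fractions = 35,
                                      params = lq_params()) {
  stopifnot(is.data.frame(cohort))
  if (!all(c("n_fractions", "dose_per_fraction") %in% names(cohort))) {
    stop("`cohort` must contain `n_fractions` and `dose_per_fraction`",
         call. = FALSE)
  }
  alpha <- if ("alpha_g" %in% names(cohort)) {
    cohort$alpha_g
  } else if ("rsi" %in% names(cohort)) {
    suppressWarnings(alpha_g_from_rsi(cohort$rsi, params))
  } else {
    stop("`cohort` must contain `rsi` or `alpha_g`", call. = FALSE)
  }
  delivered <- fx_schedule(cohort$n_fractions, cohort$dose_per_fraction)
  delivered_gard <- gard_from_schedule(alpha, delivered, params)
  id <- if ("patient_id" %in% names(cohort)) cohort$patient_id else seq_len(nrow(cohort))
  presc <- dose_for_target_gard(alpha, target_gard = target_gard,
                                dose_per_fraction = dose_per_fraction,
                                params = params, delivered = delivered,
                                reference_fractions = reference_fractions,
                                unreachable = "na", patient_id = id)
  presc$delivered_gard <- delivered_gard
  ok <- !presc$unreachable
  req <- presc$required_dose_continuous
  out <- list(
    prescriptions = presc,
    target_gard = target_gard,
    mean_fraction_delta = mean(presc$fraction_delta[ok]),
    total_dose_delta = sum(presc$dose_delta[ok]),
    prop_underdosed = mean(presc$underdosed[ok]),
    prop_requiring_60_70 = mean(req[ok] > 60 & req[ok] <= 70),
    n_unreachable = sum(!ok)
  )
  if (all(c("time_months", "event") %in% names(cohort))) {
    achieved <- delivered_gard >= target_gard
    out$km_all <- km_estimate(cohort$time_months, cohort$event)
    if (sum(achieved) >= 2) {
      out$km_achieved <- km_estimate(cohort$time_months[achieved],
                                     cohort$event[achieved])
    }
    out$n_achieved <- sum(achieved)
  }
  class(out) <- "iso_gard_report"
  out
}

#' @export
print.iso_gard_report <- function(x, ...) {
  cat("Personalized iso-GARD prescription report (target GARD =",
      x$target_gard, ")\n")
  cat(sprintf("  patients: %d (%d with unreachable target)\n",
              nrow(x$prescriptions), x$n_unreachable))
  cat(sprintf("  mean fractions spared vs reference: %.2f\n",
              x$mean_fraction_delta))
  cat(sprintf("  underdosed at delivered plan: %.1f%%; requiring 60-70 Gy: %.1f%%\n",
              100 * x$prop_underdosed, 100 * x$prop_requiring_60_70))
  invisible(x)
}

#' Smallest GARD threshold achieving equipoise with the whole cohort
#'
#' Scans the observed GARD values in ascending order and returns the
#' smallest threshold `g` such that the Kaplan-Meier OS at the horizon for
#' the subgroup `{GARD >= g}` is at least the whole-cohort OS. Under a
#' positive GARD-survival association every subgroup satisfies this in
#' expectation; in finite samples the returned threshold is where sampling
#' noise first favors the subgroup, so it should be read as a
#' hypothesis-generating equipoise candidate.
#'
#' @param cohort Cohort with `gard` (or `rsi` + schedule columns),
#'   `time_months`, `event`.
#' @param horizon Horizon in months (default 36).
#' @param min_size Minimum subgroup size considered (default 10).
#' @param params [lq_params()].
#' @return List: `threshold`, `n_subgroup`, `os_subgroup`, `os_cohort`,
#'   `horizon`.
#' @export
find_equipoise_threshold <- function(cohort, horizon = 36, min_size = 10,
                                     params = lq_params()) {
  stopifnot(is.data.frame(cohort),
            all(c("time_months", "event") %in% names(cohort)))
  gard <- if ("gard" %in% names(cohort)) {
    cohort$gard
  } else {
    alpha <- suppressWarnings(alpha_g_from_rsi(cohort$rsi, params))
    gard_from_schedule(alpha, fx_schedule(cohort$n_fractions,
                                          cohort$dose_per_fraction), params)
  }
  km_all <- km_estimate(cohort$time_months, cohort$event)
  os_all <- suppressWarnings(as.numeric(survival_at(km_all, horizon)))
  for (g in sort(unique(gard))) {
    sub <- gard >= g
    if (sum(sub) < min_size) break
    km_sub <- km_estimate(cohort$time_months[sub], cohort$event[sub])
    os_sub <- suppressWarnings(as.numeric(survival_at(km_sub, horizon)))
    if (os_sub >= os_all - 1e-12) {
      return(list(threshold = g, n_subgroup = sum(sub), os_subgroup = os_sub,
                  os_cohort = os_all, horizon = horizon))
    }
  }
  stop("no GARD threshold achieves subgroup OS >= cohort OS at the horizon",
       call. = FALSE)
}
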