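test_that("zero-bandwidth smoothed bootstrap is a plain bootstrap", {
  src <- runif(30, 0.2, 0.7)
  out <- smoothed_bootstrap_rsi(src, 500, bandwidth = 0, seed = 1)
  expect_true(all(out %in% src))
  expect_equal(attr(out, "n_clipped"), 0)
})

test_that("degenerate sources and bad bandwidths are rejected", {
  expect_error(smoothed_bootstrap_rsi(0.3, 10), "degenerate")
  expect_error(smoothed_bootstrap_rsi(rep(0.3, 5), 10), "degenerate")
  expect_error(smoothed_bootstrap_rsi(c(0.2, 0.4), 10, bandwidth = -1),
               "non-negative")
  expect_error(smoothed_bootstrap_rsi(c(0, 0.5), 10), "in \\(0, 1\\)")
})

test_that("smoothed bootstrap reproduces the kernel density distribution", {
  set.seed(61)
  src <- pmin(pmax(rnorm(200, 0.42, 0.1), 0.05), 0.9)
  n <- 50000
  draws <- smoothed_bootstrap_rsi(src, n, seed = 62)
  # mean matches the source mean within 3 SE (kernel noise has mean 0)
  se <- sqrt(stats::var(src) + stats::bw.nrd0(src)^2) / sqrt(n)
  expect_lt(abs(mean(draws) - mean(src)), 3 * se)
  # KS distance to the exact smoothed-bootstrap CDF (mixture of normals)
  grid <- seq(0.05, 0.95, by = 0.01)
  kde_cdf <- vapply(grid, function(x) {
    mean(stats::pnorm(x, mean = src, sd = stats::bw.nrd0(src)))
  }, numeric(1))
  emp_cdf <- ecdf(draws)(grid)
  expect_lt(max(abs(emp_cdf - kde_cdf)), 0.02)
})

test_that("boundary clipping is applied and counted", {
  src <- c(rep(0.0015, 50), rep(0.9985, 50))
  out <- smoothed_bootstrap_rsi(src, 2000, bandwidth = 0.05, seed = 63)
  expect_gt(attr(out, "n_clipped"), 0)
  expect_true(all(out >= 0.001 & out <= 0.999))
})

test_that("mixture survival is the weighted average of its components", {
  low <- weibull_from_survival(36, 0.90, 60, 0.80)
  high <- weibull_from_survival(36, 0.995, 60, 0.99)
  ms <- list(low = low, high = high)
  expect_equal(predict_survival_mixture(ms, c(low = 0, high = 1), c(10, 36)),
               survival_at(high, c(10, 36)))
  expect_equal(predict_survival_mixture(ms, c(low = 0.5, high = 0.5), 36),
               0.5 * survival_at(low, 36) + 0.5 * survival_at(high, 36))
  expect_error(predict_survival_mixture(ms, c(low = 0.6, high = 0.5), 36),
               "sum to 1")
  # mixture bounded by its components at any time
  set.seed(64)
  for (i in 1:20) {
    p <- runif(1); t <- runif(1, 0, 120)
    s <- predict_survival_mixture(ms, c(low = p, high = 1 - p), t)
    comp <- c(survival_at(low, t), survival_at(high, t))
    expect_gte(s, min(comp)); expect_lte(s, max(comp))
  }
})

test_that("identical arms differ only by Monte Carlo noise", {
  set.seed(65)
  src <- runif(100, 0.25, 0.6)
  models <- list(low = weibull_from_survival(36, 0.90, 60, 0.80),
                 high = weibull_from_survival(36, 0.995, 60, 0.99))
  des <- trial_design("unselected_deescalation",
                      experimental_schedule = fx_schedule(35, 2),
                      n_per_arm = 100, replicates = 30)
  tr <- run_unselected_deescalation_trial(src, models, des, seed = 66)
  d <- tr$arms$control$os36_mean - tr$arms$experimental$os36_mean
  reps <- tr$replicates
  diffs <- reps$os36[reps$arm == "control"] - reps$os36[reps$arm == "experimental"]
  expect_lt(abs(d), 3 * stats::sd(diffs) / sqrt(length(diffs)) + 1e-12)
})

test_that("trial runs are reproducible bit for bit under a fixed seed", {
  src <- runif(60, 0.3, 0.6)
  models <- list(low = weibull_from_survival(36, 0.90, 60, 0.80),
                 high = weibull_from_survival(36, 0.995, 60, 0.99))
  des <- trial_design("unselected_deescalation", n_per_arm = 50, replicates = 5)
  t1 <- run_unselected_deescalation_trial(src, models, des, seed = 7)
  t2 <- run_unselected_deescalation_trial(src, models, des, seed = 7)
  expect_identical(t1$replicates, t2$replicates)
  t3 <- run_unselected_deescalation_trial(src, models, des, seed = 8)
  expect_false(identical(t1$replicates, t3$replicates))
})

test_that("an unreachable cut point de-escalates nobody", {
  set.seed(67)
  src <- runif(80, 0.3, 0.6)
  models <- list(low = weibull_from_survival(36, 0.90, 60, 0.80),
                 high = weibull_from_survival(36, 0.995, 60, 0.99))
  des <- trial_design("gard_selected_deescalation", gard_cutpoint = 1e6,
                      n_per_arm = 50, replicates = 5)
  tr <- run_gard_selected_trial(src, models, des, seed = 68)
  expect_equal(tr$eligibility_fraction, 0)
  # nobody high, so both arms are pure low-group mixtures: identical OS
  reps <- tr$replicates
  expect_equal(unique(reps$os36), survival_at(models$low, 36))
})

test_that("GARD-selected de-escalation preserves group composition and OS", {
  set.seed(69)
  dist <- default_dist()
  src <- exp(-gardose:::rgd(dist, 191) / 35)
  models <- list(low = weibull_from_survival(36, 0.90, 60, 0.80),
                 high = weibull_from_survival(36, 0.995, 60, 0.99))
  des <- trial_design("gard_selected_deescalation", n_per_arm = 200,
                      replicates = 50)
  tr <- run_gard_selected_trial(src, models, des, seed = 70)
  reps <- tr$replicates
  nh_c <- reps$n_high[reps$arm == "control"]
  nh_e <- reps$n_high[reps$arm == "experimental"]
  # same composition in distribution: mean counts within MC noise
  se <- sqrt(stats::var(nh_c) / length(nh_c) + stats::var(nh_e) / length(nh_e))
  expect_lt(abs(mean(nh_c) - mean(nh_e)), 3 * se + 1e-12)
  os_c <- reps$os36[reps$arm == "control"]
  os_e <- reps$os36[reps$arm == "experimental"]
  se_os <- sqrt(stats::var(os_c) / length(os_c) + stats::var(os_e) / length(os_e))
  expect_lt(abs(mean(os_c) - mean(os_e)), 3 * se_os + 1e-12)
  # eligibility tracks P(GARD at 60 Gy >= cut) in the source population
  p60 <- mean(gard_from_schedule(suppressWarnings(alpha_g_from_rsi(src)),
                                 fx_schedule(30, 2)) >= 42)
  expect_lt(abs(tr$eligibility_fraction - p60),
            2 * sqrt(p60 * (1 - p60) / 200) + 0.03)
  # group sizes always partition the arm
  expect_true(all(reps$n_low + reps$n_high == 200))
})

test_that("personalized iso-GARD prescriptions behave at the boundaries", {
  co <- data.frame(patient_id = c("A", "B"), rsi = c(0.3, 0.5),
                   n_fractions = 35, dose_per_fraction = 2)
  # target 0: everyone over-dosed, zero dose required
  r0 <- run_personalized_iso_gard(co, target_gard = 0)
  expect_equal(r0$prescriptions$required_dose_continuous, c(0, 0))
  expect_equal(r0$prop_underdosed, 0)
  # target equal to delivered GARD: zero dose delta
  g <- gard_from_schedule(alpha_g_from_rsi(0.3), fx_schedule(35, 2))
  r1 <- run_personalized_iso_gard(co[1, ], target_gard = g)
  expect_equal(r1$prescriptions$dose_delta, 0, tolerance = 1e-9)
  expect_equal(r1$prescriptions$required_fractions, 35)
})

test_that("calibrated cohorts spare fractions on average with a 60-70 Gy minority", {
  spec <- cohort_spec(n = 2000, seed = 71)
  co <- generate_cohort(spec)
  rep <- run_personalized_iso_gard(co, target_gard = 32)
  expect_gt(rep$mean_fraction_delta, 0)
  expect_gt(rep$prop_requiring_60_70, 0.10)
  expect_lt(rep$prop_requiring_60_70, 0.40)
  expect_gt(rep$prop_underdosed, 0.05)  # a nontrivial minority needs > 70 Gy
})

test_that("equipoise threshold search is self-consistent", {
  spec <- cohort_spec(n = 1000, seed = 72)
  co <- generate_cohort(spec)
  eq <- find_equipoise_threshold(co, horizon = 36)
  km_sub <- km_estimate(co$time_months[co$gard >= eq$threshold],
                        co$event[co$gard >= eq$threshold])
  km_all <- km_estimate(co$time_months, co$event)
  expect_gte(as.numeric(survival_at(km_sub, 36)),
             as.numeric(survival_at(km_all, 36)))
  expect_equal(eq$n_subgroup, sum(co$gard >= eq$threshold))
  # survival independent of GARD: the smallest grid value qualifies
  co2 <- co
  co2$gard <- sample(co2$gard)
  set.seed(73)
  eq2 <- find_equipoise_threshold(co2, horizon = 36)
  expect_equal(eq2$threshold, min(co2$gard))
})
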