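test_that("a lone median constraint pins the lognormal location exactly", {
  d <- calibrate_rsi_distribution(targets = list(median = 39.1))
  expect_equal(d$params$meanlog, log(39.1))
  expect_equal(gardose:::qgd(d, 0.5), 39.1, tolerance = 1e-12)
})

test_that("full calibration reproduces every population target within 10%", {
  d <- default_dist()
  rel <- d$fit$relative_error
  expect_true(all(abs(rel) < 0.10))
  expect_equal(gardose:::qgd(d, 0.5), 39.1, tolerance = 39.1 * 0.1)
  expect_equal(1 - gardose:::pgd(d, 42), 0.37, tolerance = 0.037)
  expect_equal(1 - gardose:::pgd(d, 49), 0.16, tolerance = 0.016)
})

test_that("sampling from the calibrated fit reproduces the constraint quantiles", {
  d <- default_dist()
  set.seed(81)
  x <- gardose:::rgd(d, 1e5)
  expect_equal(stats::median(x), gardose:::qgd(d, 0.5), tolerance = 0.01)
  expect_equal(stats::IQR(x), gardose:::qgd(d, 0.75) - gardose:::qgd(d, 0.25),
               tolerance = 0.02)
  expect_equal(mean(x >= 42), 1 - gardose:::pgd(d, 42), tolerance = 0.01)
})

test_that("alternative families calibrate to the same targets", {
  for (fam in c("gamma", "truncnorm")) {
    d <- calibrate_rsi_distribution(family = fam)
    expect_true(all(abs(d$fit$relative_error) < 0.15))
  }
})

test_that("generated cohorts are internally consistent with the dose math", {
  spec <- cohort_spec(n = 400, seed = 82)
  co <- generate_cohort(spec)
  expect_s3_class(co, "gard_cohort")
  expect_silent(validate_cohort(co))
  recomputed <- gard_from_schedule(
    suppressWarnings(alpha_g_from_rsi(co$rsi)),
    fx_schedule(co$n_fractions, co$dose_per_fraction))
  expect_equal(co$gard, recomputed, tolerance = 1e-9)
  expect_true(all(co$time_months <= 60))
  gt <- attr(co, "ground_truth")
  expect_equal(exp(-gt$gard_reference / 35), co$rsi, tolerance = 1e-12)
})

test_that("cohort generation is seed-deterministic and n = 0 is valid", {
  expect_identical(generate_cohort(cohort_spec(n = 50, seed = 5)),
                   generate_cohort(cohort_spec(n = 50, seed = 5)))
  expect_false(identical(generate_cohort(cohort_spec(n = 50, seed = 5))$rsi,
                         generate_cohort(cohort_spec(n = 50, seed = 6))$rsi))
  empty <- generate_cohort(cohort_spec(n = 0))
  expect_equal(nrow(empty), 0)
  expect_true(all(c("patient_id", "rsi", "time_months", "event") %in% names(empty)))
})

test_that("grouped outcomes hit their group survival targets at large n", {
  spec <- cohort_spec(n = 5000, seed = 83)
  co <- generate_cohort(spec)
  grp <- classify_gard_group(co$gard, spec$outcome$cutpoint)
  for (g in c("low", "high")) {
    idx <- grp == g
    km <- km_estimate(co$time_months[idx], co$event[idx])
    target <- survival_at(spec$outcome[[g]], 36)
    est <- as.numeric(survival_at(km, 36))
    # Greenwood SE at 36 months
    se <- (survival_at(km, 36, conf = TRUE)$upper - est) / stats::qnorm(0.975)
    expect_lt(abs(est - target), 2.5 * se + 0.005)
  }
})

test_that("continuous outcome model plants the requested log hazard ratio", {
  cont <- list(model = "continuous", shape = 1.6, scale_ref = 155,
               gard_ref = 39.1, log_hr = -0.06)
  spec <- cohort_spec(n = 4000, outcome = cont, seed = 84)
  co <- generate_cohort(spec)
  fit <- fit_cox(co, "gard")
  expect_lt(abs(fit$coefficients$estimate - (-0.06)),
            3 * fit$coefficients$se)
})

test_that("degenerate all-censored generation exercises zero-event paths", {
  spec <- cohort_spec(n = 30, censoring = list(admin = 0, accrual = c(0, 0)),
                      seed = 85)
  co <- generate_cohort(spec)
  expect_true(all(co$event == 0))
  expect_warning(m <- fit_weibull(co$time_months, co$event), "plateau")
  expect_true(m$degenerate)
})

test_that("cohort tables round trip through delimited text", {
  co <- generate_cohort(cohort_spec(n = 25, seed = 86))
  for (ext in c(".csv", ".tsv")) {
    tf <- tempfile(fileext = ext)
    write_cohort(co, tf)
    back <- read_cohort(tf)
    expect_equal(as.data.frame(back)[names(co)], as.data.frame(co),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("schema violations are itemized", {
  co <- generate_cohort(cohort_spec(n = 10, seed = 87))
  co$rsi[2] <- 1.4
  co$time_months[3] <- -1
  err <- tryCatch(validate_cohort(co), error = conditionMessage)
  expect_match(err, "rsi outside")
  expect_match(err, "time_months")
  expect_error(validate_cohort(co[, -2]), "missing column")
})
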