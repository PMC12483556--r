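test_that("KM estimate matches hand product-limit computations", {
  # no events: flat at 1
  km0 <- km_estimate(c(3, 6, 9, 12, 15), rep(0, 5))
  expect_true(all(km0$surv == 1))
  # no censoring: empirical survival
  km1 <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km1$surv, c(2 / 3, 1 / 3, 0))
  # censoring at 1 and 3, events at 2 and 4: S(2) = 2/3, S(4) = 0
  km2 <- km_estimate(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(suppressWarnings(as.numeric(survival_at(km2, c(2, 2.5, 4)))),
               c(2 / 3, 2 / 3, 0))
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "non-negative")
})

test_that("survival_at is a right-continuous step function with flagged extrapolation", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(as.numeric(survival_at(km, 0)), 1)
  expect_equal(as.numeric(survival_at(km, c(1, 1.99, 2))), c(2/3, 2/3, 1/3))
  expect_warning(s <- survival_at(km, 10), "extrapolation")
  expect_equal(as.numeric(s), 0)
  ci <- survival_at(km, 1.5, conf = TRUE)
  expect_true(ci$lower <= ci$surv && ci$surv <= ci$upper)
})

test_that("log-rank statistic matches the hand-computed 2v2 risk-set table", {
  toy <- toy_two_groups()
  lr <- logrank_statistic(toy$time, toy$event, toy$group)
  # risk sets at t=1..4: E_B = 1/2 + 2/3 + 1 + 1, V = 1/4 + 2/9
  expect_equal(lr$observed - lr$expected, 2 - (0.5 + 2 / 3 + 2), tolerance = 1e-12)
  expect_equal(lr$variance, 1 / 4 + 2 / 9, tolerance = 1e-12)
  expect_equal(lr$statistic, (-7 / 6) / sqrt(17 / 36), tolerance = 1e-12)
  # independent cross-check against survival::survdiff chi-square
  sd <- survival::survdiff(
    survival::Surv(toy$time, toy$event) ~ toy$group)
  expect_equal(lr$chisq, sd$chisq, tolerance = 1e-10)
})

test_that("log-rank is symmetric, antisymmetric under swap, scale-invariant", {
  set.seed(8)
  time <- rexp(40, 0.1); event <- rbinom(40, 1, 0.7)
  grp <- rep(c("A", "B"), 20)
  # identical event/censoring patterns in both groups: statistic 0
  lr0 <- logrank_statistic(rep(time[1:20], 2), rep(event[1:20], 2),
                           rep(c("A", "B"), each = 20))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  lr <- logrank_statistic(time, event, grp)
  swapped <- logrank_statistic(time, event, factor(grp, levels = c("B", "A")))
  expect_equal(lr$statistic, -swapped$statistic, tolerance = 1e-12)
  rescaled <- logrank_statistic(time * 12, event, grp)
  expect_equal(lr$statistic, rescaled$statistic, tolerance = 1e-12)
})

test_that("zero-variance log-rank is flagged undefined, not NaN", {
  expect_warning(
    lr <- logrank_statistic(c(1, 2, 3, 4), c(0, 0, 0, 0), c("A", "A", "B", "B")),
    "undefined")
  expect_true(lr$undefined)
  expect_true(is.na(lr$statistic))
})

test_that("KM without censoring equals the empirical survival function", {
  set.seed(11)
  t <- sample(1:100, 60, replace = TRUE)
  km <- km_estimate(t, rep(1, 60))
  ecdf_surv <- 1 - ecdf(t)(km$time)
  expect_equal(km$surv, ecdf_surv, tolerance = 1e-12)
})
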