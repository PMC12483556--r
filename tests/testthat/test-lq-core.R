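test_that("alpha_g back-solve matches the LQ relation and flags its domain", {
  expect_equal(alpha_g_from_rsi(exp(-0.2)), 0)
  expect_warning(a1 <- alpha_g_from_rsi(1), "negative alpha_g")
  expect_equal(a1, -0.1)
  # hand evaluation of -log(rsi)/2 - 0.1 at the RSI implied by median GARD
  expect_equal(alpha_g_from_rsi(0.32730), -log(0.32730) / 2 - 0.1)
  expect_error(alpha_g_from_rsi(0), "0")
  expect_error(alpha_g_from_rsi(1.5), "1.5")
  # custom beta propagates
  expect_equal(alpha_g_from_rsi(0.5, lq_params(beta = 0.1)),
               -log(0.5) / 2 - 0.2)
})

test_that("GARD computation reproduces printed and rescaled values", {
  a_max <- alpha_g_from_gard(71.7, fx_schedule(35, 2))
  expect_equal(gard_from_schedule(a_max, fx_schedule(35, 2)), 71.7)
  # linear rescaling with fraction number at fixed 2 Gy/fx
  expect_equal(gard_from_schedule(a_max, fx_schedule(30, 2)), 71.7 * 60 / 70)
  expect_equal(gard_from_schedule(0, fx_schedule(1, 2)), 0.2)
  expect_error(fx_schedule(0, 2), "n_fractions")
  expect_error(fx_schedule(10, -1), "dose_per_fraction")
  expect_warning(gard_from_schedule(-0.2, fx_schedule(10, 1)), "negative GARD")
})

test_that("EQD2 follows the standard fractionation correction", {
  expect_equal(eqd2(fx_schedule(35, 2)), 70)
  expect_equal(eqd2(fx_schedule(33, 2.12)), 69.96 * 12.12 / 12)
  expect_equal(eqd2(fx_schedule(17, 3)), 51 * 13 / 12)
  # 2 Gy/fx identity holds for any alpha/beta
  for (ab in c(2, 3, 10)) {
    expect_equal(eqd2(fx_schedule(27, 2), alpha_beta = ab), 54)
  }
})

test_that("inverse dose solver reproduces the personalized dose bounds", {
  a <- alpha_g_from_gard(c(71.7, 19.7), fx_schedule(35, 2))
  p <- dose_for_target_gard(a, target_gard = 32, dose_per_fraction = 2)
  expect_equal(p$required_dose_continuous, 32 / (a + 0.1))
  expect_equal(p$required_dose_gy, c(31, 113))
  expect_equal(p$required_fractions, c(16L, 57L))
  expect_equal(fraction_delta(p), c(19L, -22L))
  expect_equal(p$fraction_delta, c(19L, -22L))
})

test_that("prescribing the delivered GARD returns the delivered dose exactly", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(10:40, 1); d <- runif(1, 1.5, 3)
    alpha <- runif(1, 0.05, 1)
    g <- gard_from_schedule(alpha, fx_schedule(n, d))
    p <- dose_for_target_gard(alpha, target_gard = g, dose_per_fraction = d)
    expect_equal(p$required_dose_continuous, n * d, tolerance = 1e-10)
    expect_equal(p$required_fractions, n)
  }
})

test_that("unreachable targets error with the patient named, or flag as NA", {
  expect_error(
    dose_for_target_gard(-0.15, target_gard = 32, patient_id = "PX"),
    "PX")
  p <- dose_for_target_gard(c(-0.15, 0.4), target_gard = 32, unreachable = "na")
  expect_true(p$unreachable[1])
  expect_true(is.na(p$required_dose_continuous[1]))
  expect_false(p$unreachable[2])
})

test_that("GARD group boundary belongs to the high group", {
  expect_equal(as.character(classify_gard_group(c(42, 41.999, 42 * 60 / 70))),
               c("high", "low", "low"))
})

test_that("exact identity: GARD at 2 Gy/fx equals -n log(RSI)", {
  set.seed(1)
  r <- c(runif(40, 0.01, 0.999), exp(-0.2), 0.5)
  for (n in c(1L, 7L, 30L, 35L, 60L)) {
    g <- gard_from_schedule(suppressWarnings(alpha_g_from_rsi(r)),
                            fx_schedule(n, 2))
    expect_equal(g, -n * log(r), tolerance = 1e-12)
  }
})

test_that("alpha_g and its inverse compose to the identity", {
  set.seed(2)
  r <- runif(200, 0.001, 1)
  expect_equal(rsi_from_alpha_g(suppressWarnings(alpha_g_from_rsi(r))), r,
               tolerance = 1e-12)
  a <- runif(200, -0.1, 1.5)
  expect_equal(suppressWarnings(alpha_g_from_rsi(rsi_from_alpha_g(a))), a,
               tolerance = 1e-12)
})

test_that("GARD is monotone: decreasing in RSI, increasing in fractions", {
  r <- seq(0.05, 0.95, by = 0.05)
  g <- gard_from_schedule(suppressWarnings(alpha_g_from_rsi(r)),
                          fx_schedule(35, 2))
  expect_true(all(diff(g) < 0))
  a <- 0.3
  gn <- vapply(1:60, function(n) gard_from_schedule(a, fx_schedule(n, 2)),
               numeric(1))
  expect_true(all(diff(gn) > 0))
})

test_that("prescription round trip brackets the target", {
  set.seed(3)
  for (i in 1:50) {
    alpha <- runif(1, 0.02, 1.2)
    target <- runif(1, 5, 90)
    d <- sample(c(1.8, 2, 2.12, 2.5), 1)
    p <- dose_for_target_gard(alpha, target_gard = target, dose_per_fraction = d)
    fx <- p$required_fractions
    expect_gte(gard_from_schedule(alpha, fx_schedule(fx, d)), target - 1e-9)
    if (fx > 1) {
      expect_lt(gard_from_schedule(alpha, fx_schedule(fx - 1, d)), target)
    }
  }
})
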