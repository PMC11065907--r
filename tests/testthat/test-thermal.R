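test_that("rate points are reciprocal development times from the trials", {
  pp <- postdiapause_params(rate_noise_sd = 0, seed = 2)
  trials <- simulate_postdiapause_trials(c(4, 19), pp)
  expect_message(pts <- rate_points(trials), "excluded")
  # the 4 C trial never hatches and contributes no point
  expect_equal(nrow(pts), 1)
  expect_equal(pts$temperature, 19)
  expect_equal(pts$development_time, 263.2 / (19 - 5.47), tolerance = 1e-12)
  expect_equal(pts$rate, (19 - 5.47) / 263.2, tolerance = 1e-12)

  # a 50-day development time is a rate of 0.02 per day
  one <- make_arena(c(49, 51), c(0, 40), incubation_temp = 14)
  expect_equal(rate_points(one)$rate, 1 / 50)

  # all trials hatchless: empty result plus a warning
  cold <- simulate_postdiapause_trials(c(2, 4), pp)
  expect_warning(expect_message(empty <- rate_points(cold)), "No trial")
  expect_equal(nrow(empty), 0)
})

test_that("the postdiapause clock starts at the termination date", {
  # incubation began 6 days before diapause ended: those days don't count
  tr <- make_arena(c(19, 21), c(0, 40),
    incubation_temp = 14,
    collection_date = as.Date("2005-02-12")
  )
  pts <- rate_points(tr, termination_date = as.Date("2005-02-18"))
  expect_equal(pts$development_time, 20 - 6)

  # collected after termination: unchanged
  pts2 <- rate_points(
    dplyr::mutate(tr, collection_date = as.Date("2005-02-20")),
    termination_date = as.Date("2005-02-18")
  )
  expect_equal(pts2$development_time, 20)

  expect_error(
    rate_points(make_arena(c(10, 20), c(0, 40), incubation_temp = 14),
      termination_date = as.Date("2005-02-18")
    ),
    "collection_date"
  )
})

test_that("the fitted rate line yields threshold and degree-days by x-intercept and slope", {
  # collinear points on rate = x (slope 1, intercept 0)
  unit <- tibble::tibble(temperature = c(1, 2, 3), rate = c(1, 2, 3))
  f <- fit_thermal_model(unit)
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(threshold_temperature(f), 0, tolerance = 1e-12)
  expect_equal(degree_day_requirement(f), 1)

  # derived quantities satisfy their defining identities for noisy data too
  set.seed(6)
  noisy <- tibble::tibble(
    temperature = rep(c(9, 14, 19), each = 5),
    rate = 0.004 * rep(c(9, 14, 19), each = 5) - 0.02 + rnorm(15, 0, 1e-3)
  )
  g <- fit_thermal_model(noisy)
  expect_equal(g$degree_days_K * g$slope, 1)
  expect_equal(g$slope * g$threshold_T0 + g$intercept, 0)
  expect_false(is.na(g$r_squared))
  expect_false(is.na(g$slope_se))

  # duplicating the whole point set leaves the OLS fit unchanged
  g2 <- fit_thermal_model(dplyr::bind_rows(noisy, noisy))
  expect_equal(g2$slope, g$slope)
  expect_equal(g2$intercept, g$intercept)

  # weighting by a count column equals replicating the points
  wtd <- fit_thermal_model(dplyr::mutate(noisy, w = 2), weights = "w")
  expect_equal(wtd$slope, g$slope)

  expect_error(
    fit_thermal_model(tibble::tibble(temperature = c(9, 9), rate = c(0.1, 0.2))),
    "distinct temperatures"
  )
  expect_error(
    fit_thermal_model(tibble::tibble(temperature = c(9, 14, 19), rate = c(0.3, 0.2, 0.1))),
    "Non-physical"
  )
})

test_that("tidy and glance expose the fit in broom shape", {
  f <- fit_thermal_model(tibble::tibble(temperature = c(9, 14, 19),
                                        rate = 0.0038 * c(9, 14, 19) - 0.0208))
  td <- tidy(f)
  expect_equal(td$term, c("(Intercept)", "temperature"))
  expect_equal(td$estimate, c(-0.0208, 0.0038), tolerance = 1e-12)
  gl <- glance(f)
  expect_equal(gl$nobs, 3)
  expect_equal(gl$threshold_T0, 0.0208 / 0.0038, tolerance = 1e-12)
})

test_that("noise-free simulation round-trips the thermal parameters exactly", {
  pp <- postdiapause_params(
    true_threshold = 5.47, true_degree_days = 263.2, rate_noise_sd = 0, seed = 1
  )
  trials <- simulate_postdiapause_trials(c(9, 14, 19), pp, replicates = 3)
  f <- fit_thermal_model(rate_points(trials))
  expect_equal(threshold_temperature(f), 5.47, tolerance = 1e-9)
  expect_equal(degree_day_requirement(f), 263.2, tolerance = 1e-9)
})

test_that("a noisy simulated experiment recovers the thermal parameters", {
  pp <- postdiapause_params(rate_noise_sd = 0.05, seed = 13)
  trials <- simulate_postdiapause_trials(c(4, 9, 14, 19), pp, replicates = 10)
  f <- fit_thermal_model(suppressMessages(rate_points(trials)))
  # sampling sd of T0-hat at this design is ~0.14 C, of K-hat ~6 degree-days
  expect_lt(abs(threshold_temperature(f) - 5.47), 1)
  expect_lt(abs(degree_day_requirement(f) - 263.2), 25)
})
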