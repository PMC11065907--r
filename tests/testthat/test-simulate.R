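test_that("chill-experiment simulator honours counts, layout and determinism", {
  grid <- treatment_grid(chill_temps = c(0, 4), chill_days = c(10, 100))
  p <- sim_params(seed = 11)

  eggs <- simulate_chill_experiment(grid, replicates = 3, eggs_per_arena = 40, params = p)
  expect_equal(dplyr::n_distinct(eggs$arena_id), 3 * nrow(grid))
  # cumulative counts valid within every arena
  by_arena <- split(eggs, eggs$arena_id)
  for (a in by_arena) {
    expect_false(is.unsorted(a$cumulative_hatched))
    expect_true(all(a$cumulative_hatched <= a$n_eggs))
    expect_true(all(diff(a$day) > 0))
  }
  # bit-reproducible under a fixed seed
  expect_identical(
    eggs,
    simulate_chill_experiment(grid, replicates = 3, eggs_per_arena = 40, params = p)
  )

  # no eggs, no hatch
  none <- simulate_chill_experiment(grid, replicates = 2, eggs_per_arena = 0, params = p)
  expect_true(all(none$cumulative_hatched == 0))

  # empty treatment list is an empty result, not an error
  expect_equal(nrow(simulate_chill_experiment(grid[0, ], params = p)), 0)
  expect_error(
    simulate_chill_experiment(dplyr::mutate(grid, chill_days = -1), params = p),
    "non-negative"
  )
})

test_that("a degenerate simulator configuration hatches every egg between two checks", {
  # probability clamped to ~1, zero spread, median hatch day 15, 10-day cadence:
  # the count must be 0 at day 10 and complete at day 20
  p <- sim_params(
    hatch_logit_intercept = 50, chill_day_coef = 0, photoperiod_long_bonus = 0,
    chill_temp_curvature = 0, t50_base = 15, t50_decay = 0, t50_floor = 1,
    hatch_time_cv = 0, seed = 5
  )
  eggs <- simulate_chill_experiment(
    treatment_grid(chill_temps = 4, chill_days = 10, photoperiods = "long"),
    replicates = 1, eggs_per_arena = 30, params = p
  )
  expect_equal(eggs$cumulative_hatched[eggs$day == 10], 0)
  expect_equal(eggs$cumulative_hatched[eggs$day == 20], 30)
})

test_that("simulated hatch fraction tracks the logistic response", {
  # Monte Carlo at n = 10^4 against direct evaluation of the hatch probability
  p <- sim_params(seed = 7)
  grid <- treatment_grid(chill_temps = 4, chill_days = c(10, 100), photoperiods = "short")
  eggs <- simulate_chill_experiment(grid, replicates = 1, eggs_per_arena = 10000, params = p)
  obs <- summarize_hatch(eggs)
  obs <- obs[order(obs$chill_days), ]

  p_true <- plogis(p$hatch_logit_intercept + p$chill_day_coef * pmin(c(10, 100), p$chill_day_cap))
  expect_gt(obs$hatch_fraction[2], obs$hatch_fraction[1])
  # censoring can shave the late tail, so the match to the logistic is loose
  expect_equal(obs$hatch_fraction, p_true, tolerance = 0.1)

  # long photoperiod raises hatch at equal chilling
  grid2 <- treatment_grid(chill_temps = 4, chill_days = 40)
  eggs2 <- simulate_chill_experiment(grid2, replicates = 1, eggs_per_arena = 10000,
                                     params = sim_params(seed = 8))
  obs2 <- summarize_hatch(eggs2)
  expect_gt(
    obs2$hatch_fraction[obs2$photoperiod == "long"],
    obs2$hatch_fraction[obs2$photoperiod == "short"]
  )
})

test_that("postdiapause trials follow t = K/(T - T0) and respect the threshold", {
  pp <- postdiapause_params(
    true_threshold = 5.47, true_degree_days = 263.2,
    rate_noise_sd = 0, n_eggs = 50, seed = 3
  )
  trials <- simulate_postdiapause_trials(c(4, 5.47, 19), pp)
  s <- summarize_hatch(trials)

  # below and exactly at the threshold: nothing hatches
  expect_equal(s$n_hatched[s$incubation_temp == 4], 0)
  expect_equal(s$n_hatched[s$incubation_temp == 5.47], 0)
  # above: the interpolated median hatch time equals K/(T - T0) exactly
  expect_equal(s$t50[s$incubation_temp == 19], 263.2 / (19 - 5.47), tolerance = 1e-12)

  expect_error(simulate_postdiapause_trials(numeric(0), pp), "non-empty")
  expect_identical(trials, simulate_postdiapause_trials(c(4, 5.47, 19), pp))
})

test_that("synthetic weather is a seasonal cosine with reproducible noise", {
  flat <- simulate_weather(
    "2005-01-01", "2005-03-01",
    weather_params(annual_mean = 10, annual_amplitude = 0, daily_noise_sd = 0)
  )
  expect_equal(nrow(flat), 60)
  expect_true(all(flat$t_mean == 10))

  wp <- weather_params(coldest_day_of_year = 15, daily_noise_sd = 0)
  w <- simulate_weather("2005-01-01", "2005-12-31", wp)
  doy_min <- which.min(w$t_mean)
  expect_equal(doy_min, 15)

  wp2 <- weather_params(daily_noise_sd = 2, seed = 9)
  expect_identical(
    simulate_weather("2005-01-01", "2005-06-30", wp2),
    simulate_weather("2005-01-01", "2005-06-30", wp2)
  )
  expect_error(simulate_weather("2005-02-01", "2005-01-01", wp2), "must not be after")
})
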