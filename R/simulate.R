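#' Simulate a factorial chill-duration x photoperiod hatch experiment
#'
#' Generates cumulative hatch time courses for replicate arenas of winter
#' eggs, one arena per treatment x replicate. Each egg hatches independently
#' with probability
#' \deqn{p = \mathrm{logit}^{-1}\big(a + b\,\min(d, d_{cap}) + c\,[\mathrm{long}] -
#'   q\,(T_{chill} - T_{opt})^2\big)}
#' where \eqn{d} is the chill duration; hatch days of hatching eggs are
#' lognormal with median \eqn{\max(t_{floor},\, t_{base} - r d)} and
#' coefficient of variation `hatch_time_cv`. Counts are recorded every
#' `observation_interval` days and the arena is closed by the standard
#' censoring protocol: evaluation stops after two consecutive observations
#' with no new emergence, and eggs that would have hatched later are recorded
#' as never hatched.
#'
#' @param treatments data frame with columns `chill_temp`, `chill_days`,
#'   `photoperiod` (`"long"`/`"short"`, hour strings `"16:8"`/`"8:16"`
#'   accepted) and optionally `incubation_temp`; see [treatment_grid()].
#' @param replicates arenas per treatment (>= 1).
#' @param eggs_per_arena initial egg count per arena (>= 0).
#' @param params a [sim_params()] list.
#'
#' @return A long tibble with one row per (arena, observation day):
#'   `arena_id`, `chill_temp`, `chill_days`, `photoperiod`,
#'   `incubation_temp`, `n_eggs`, `day`, `cumulative_hatched`.
#' @export
#' @examples
#' eggs <- simulate_chill_experiment(
#'   treatment_grid(chill_temps = 4, chill_days = c(10, 100)),
#'   replicates = 2, eggs_per_arena = 50, params = sim_params(seed = 1)
#' )
#' head(eggs)
simulate_chill_experiment <- function(treatments, replicates = 3,
                                      eggs_per_arena = 50,
                                      params = sim_params()) {
  stopifnot(replicates >= 1, eggs_per_arena >= 0)
  empty <- tibble::tibble(
    arena_id = character(), chill_temp = double(), chill_days = double(),
    photoperiod = character(), incubation_temp = double(), n_eggs = integer(),
    day = double(), cumulative_hatched = double()
  )
  if (is.null(treatments) || nrow(treatments) == 0) {
    return(empty)
  }
  needed <- c("chill_temp", "chill_days", "photoperiod")
  missing <- setdiff(needed, names(treatments))
  if (length(missing) > 0) {
    abort(paste0("`treatments` lacks column(s): ", paste(missing, collapse = ", "), "."))
  }
  if (any(treatments$chill_days < 0)) abort("`chill_days` must be non-negative.")
  treatments <- treatments |>
    dplyr::mutate(
      photoperiod = normalize_photoperiod(.data$photoperiod),
      incubation_temp = if ("incubation_temp" %in% names(treatments)) {
        .data$incubation_temp
      } else {
        20
      }
    )

  draw <- function() {
    grid <- tidyr::expand_grid(trt = seq_len(nrow(treatments)), rep = seq_len(replicates))
    purrr::pmap(grid, function(trt, rep) {
      tr <- treatments[trt, ]
      eta <- params$hatch_logit_intercept +
        params$chill_day_coef * min(tr$chill_days, params$chill_day_cap) +
        params$photoperiod_long_bonus * (tr$photoperiod == "long") -
        params$chill_temp_curvature * (tr$chill_temp - params$chill_temp_optimum)^2
      p <- min(max(plogis(eta), 1e-9), 1 - 1e-9)
      n_hatch <- rbinom(1L, eggs_per_arena, p)
      med <- max(params$t50_floor, params$t50_base - params$t50_decay * tr$chill_days)
      sdlog <- sqrt(log1p(params$hatch_time_cv^2))
      times <- stats::rlnorm(n_hatch, meanlog = log(med), sdlog = sdlog)
      obs <- observe_with_censoring(times, params$observation_interval)
      tibble::tibble(
        arena_id = sprintf("t%03d_r%d", trt, rep),
        chill_temp = tr$chill_temp, chill_days = tr$chill_days,
        photoperiod = tr$photoperiod, incubation_temp = tr$incubation_temp,
        n_eggs = as.integer(eggs_per_arena),
        day = obs$day, cumulative_hatched = obs$cumulative_hatched
      )
    }) |>
      purrr::list_rbind()
  }
  with_optional_seed(params$seed, draw())
}

# record hatch times at multiples of `interval`, stopping after two
# consecutive observations with zero new emergences (the censoring protocol);
# later hatch times are dropped, i.e. recorded as never hatched
observe_with_censoring <- function(times, interval, max_obs = 1000L) {
  day <- double()
  cum <- double()
  prev <- 0
  zero_run <- 0L
  for (k in seq_len(max_obs)) {
    d <- k * interval
    ck <- sum(times <= d)
    day <- c(day, d)
    cum <- c(cum, ck)
    zero_run <- if (ck == prev) zero_run + 1L else 0L
    prev <- ck
    if (zero_run >= 2L) break
  }
  list(day = day, cumulative_hatched = cum)
}

#' Simulate constant-temperature postdiapause hatch trials
#'
#' For each requested temperature `T` above the true threshold `T0`, an
#' arena's development time is centred on `K / (T - T0)` (the linear
#' rate model), with per-arena lognormal multiplicative noise of standard
#' deviation `rate_noise_sd` applied on the rate scale. Within an arena, eggs
#' hatch over a short symmetric window around the arena development time
#' (half a day each side, or half the development time if shorter), so the
#' interpolated median hatch time [t50()] recovers the arena development time
#' exactly. At or below the threshold no egg hatches and the series is closed
#' by the censoring rule.
#'
#' @param temperatures constant incubation temperatures (degrees C), non-empty.
#' @param params a [postdiapause_params()] list carrying `T0`, `K`, the noise
#'   level and eggs per arena.
#' @param replicates arenas per temperature (>= 1).
#'
#' @return A long tibble with columns `arena_id`, `incubation_temp`,
#'   `n_eggs`, `day`, `cumulative_hatched`.
#' @export
#' @examples
#' trials <- simulate_postdiapause_trials(
#'   c(4, 9, 14, 19),
#'   postdiapause_params(rate_noise_sd = 0, seed = 1)
#' )
#' summarize_hatch(trials)
simulate_postdiapause_trials <- function(temperatures,
                                         params = postdiapause_params(),
                                         replicates = 1) {
  if (length(temperatures) == 0) abort("`temperatures` must be non-empty.")
  stopifnot(replicates >= 1)
  draw <- function() {
    grid <- tidyr::expand_grid(i = seq_along(temperatures), rep = seq_len(replicates))
    purrr::pmap(grid, function(i, rep) {
      temp <- temperatures[i]
      id <- sprintf("pd%02d_r%d_%gC", i, rep, temp)
      if (temp > params$true_threshold && params$n_eggs > 0) {
        rate <- (temp - params$true_threshold) / params$true_degree_days
        rate <- rate * exp(rnorm(1L, 0, params$rate_noise_sd))
        t_dev <- 1 / rate
        h <- min(1, t_dev / 2)
        day <- c(t_dev - h, t_dev + h)
        cum <- c(0, params$n_eggs)
      } else {
        # below (or at) threshold: two empty observations close the arena
        day <- c(10, 20)
        cum <- c(0, 0)
      }
      tibble::tibble(
        arena_id = id, incubation_temp = temp,
        n_eggs = as.integer(params$n_eggs),
        day = day, cumulative_hatched = cum
      )
    }) |>
      purrr::list_rbind()
  }
  with_optional_seed(params$seed, draw())
}

#' Simulate a daily mean-temperature series
#'
#' Seasonal cosine plus Gaussian noise:
#' \deqn{T(d) = \mu - A \cos\big(2\pi (doy - doy_{cold})/365\big) + \epsilon}
#' A 365-day cycle is used; 29 February receives the day-365 seasonal value.
#'
#' @param start_date,end_date `Date`s (or ISO-8601 strings) delimiting the
#'   series, inclusive; `start_date` must not be after `end_date`.
#' @param params a [weather_params()] list.
#' @return A tibble with columns `date`, `t_mean`, one row per calendar day.
#' @export
#' @examples
#' w <- simulate_weather("2005-01-01", "2005-06-30", weather_params(seed = 1))
#' range(w$t_mean)
simulate_weather <- function(start_date, end_date, params = weather_params()) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (start_date > end_date) abort("`start_date` must not be after `end_date`.")
  dates <- seq(start_date, end_date, by = "day")
  doy <- pmin(as.POSIXlt(dates)$yday + 1L, 365L)
  seasonal <- params$annual_mean -
    params$annual_amplitude * cos(2 * pi * (doy - params$coldest_day_of_year) / 365)
  draw <- function() seasonal + rnorm(length(dates), 0, params$daily_noise_sd)
  tibble::tibble(date = dates, t_mean = with_optional_seed(params$seed, draw()))
}

with_optional_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

# accept the hour-string aliases for the two photoperiod levels
normalize_photoperiod <- function(x) {
  x <- as.character(x)
  x[x %in% c("16:8", "16:08")] <- "long"
  x[x %in% c("8:16", "08:16")] <- "short"
  bad <- setdiff(unique(x), c("long", "short"))
  if (length(bad) > 0) {
    abort(paste0(
      "`photoperiod` must be \"long\" or \"short\" (or \"16:8\"/\"8:16\"); got: ",
      paste(bad, collapse = ", "), "."
    ))
  }
  x
}
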