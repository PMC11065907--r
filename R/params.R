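#' Parameters for the chill-experiment hatch simulator
#'
#' Builds the parameter list used by [simulate_chill_experiment()]. Defaults
#' are read from the calibration file shipped with the package
#' (`inst/extdata/sim-defaults.yaml`); any argument supplied here overrides
#' the file value.
#'
#' The generative model is deliberately simple: each egg hatches with a
#' logistic probability that increases with chill duration (up to
#' `chill_day_cap`), is higher under long photoperiod, and falls off
#' quadratically as the chill temperature moves away from `chill_temp_optimum`.
#' Hatch times of hatching eggs are lognormal with a median that declines
#' linearly with chill duration down to `t50_floor`.
#'
#' @param ... named overrides of the defaults (see the fields below).
#' @param seed optional integer seed; when supplied the simulator is
#'   bit-reproducible across calls.
#'
#' @return A list of class `sim_params` with fields
#'   `hatch_logit_intercept`, `chill_day_coef`, `chill_day_cap`,
#'   `photoperiod_long_bonus`, `chill_temp_optimum`, `chill_temp_curvature`,
#'   `t50_base`, `t50_decay`, `t50_floor`, `hatch_time_cv`,
#'   `observation_interval`, `seed`.
#' @seealso [simulate_chill_experiment()], [treatment_grid()]
#' @export
#' @examples
#' sim_params(chill_day_coef = 0.05, seed = 1)
sim_params <- function(..., seed = NULL) {
  defaults <- yaml::read_yaml(
    system.file("extdata", "sim-defaults.yaml", package = "hatchphen")
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("Unknown sim_params field(s): ", paste(unknown, collapse = ", "), "."))
  }
  p <- utils::modifyList(defaults, overrides)
  p$seed <- seed
  stopifnot(
    p$observation_interval > 0, p$t50_floor > 0,
    p$hatch_time_cv >= 0, p$chill_day_cap > 0
  )
  structure(p, class = "sim_params")
}

#' Parameters for constant-temperature postdiapause trials
#'
#' Truth values for the linear developmental-rate model: at constant
#' temperature `T` above `true_threshold`, postdiapause development completes
#' after `true_degree_days / (T - true_threshold)` days. Per-arena rates are
#' perturbed by lognormal multiplicative noise with standard deviation
#' `rate_noise_sd` on the log-rate scale; at or below the threshold nothing
#' develops.
#'
#' @param true_threshold lower developmental temperature threshold T0 (degrees C).
#' @param true_degree_days thermal constant K (degree-days above T0).
#' @param rate_noise_sd sd of the multiplicative rate noise (dimensionless).
#' @param n_eggs eggs per arena.
#' @param seed optional integer seed.
#' @return A list of class `postdiapause_params`.
#' @seealso [simulate_postdiapause_trials()]
#' @export
postdiapause_params <- function(true_threshold = 5.47, true_degree_days = 263.2,
                                rate_noise_sd = 0.05, n_eggs = 50, seed = NULL) {
  stopifnot(true_degree_days > 0, n_eggs >= 0, rate_noise_sd >= 0)
  structure(
    list(
      true_threshold = true_threshold, true_degree_days = true_degree_days,
      rate_noise_sd = rate_noise_sd, n_eggs = n_eggs, seed = seed
    ),
    class = "postdiapause_params"
  )
}

#' Parameters for the synthetic daily weather generator
#'
#' Daily mean temperature follows an annual cosine (coldest at
#' `coldest_day_of_year`) plus independent Gaussian noise. A 365-day cycle is
#' used; 29 February receives the same seasonal value as day 365 of the cycle.
#'
#' @param annual_mean annual mean temperature (degrees C).
#' @param annual_amplitude half-range of the seasonal cycle (degrees C).
#' @param coldest_day_of_year day of year (1-365) at which the cosine bottoms out.
#' @param daily_noise_sd sd of day-to-day noise (degrees C).
#' @param seed optional integer seed.
#' @return A list of class `weather_params`.
#' @seealso [simulate_weather()]
#' @export
weather_params <- function(annual_mean = 13, annual_amplitude = 9,
                           coldest_day_of_year = 15, daily_noise_sd = 2,
                           seed = NULL) {
  stopifnot(annual_amplitude >= 0, daily_noise_sd >= 0)
  structure(
    list(
      annual_mean = annual_mean, annual_amplitude = annual_amplitude,
      coldest_day_of_year = coldest_day_of_year,
      daily_noise_sd = daily_noise_sd, seed = seed
    ),
    class = "weather_params"
  )
}

#' Factorial treatment grid for chill experiments
#'
#' Convenience constructor for the full cross of chill temperatures, chill
#' durations and photoperiods at a fixed incubation temperature — the design
#' used in diapause-termination bioassays (e.g. 4 temperatures x 6 durations
#' x 2 photoperiods = 48 treatments).
#'
#' @param chill_temps chill temperatures (degrees C).
#' @param chill_days chill durations (days).
#' @param photoperiods subset of `c("long", "short")` (16:8 and 8:16 h L:D).
#' @param incubation_temp incubation temperature after chilling (degrees C).
#' @return A tibble with one row per treatment and columns `chill_temp`,
#'   `chill_days`, `photoperiod`, `incubation_temp`.
#' @export
#' @examples
#' nrow(treatment_grid()) # 48
treatment_grid <- function(chill_temps = c(0, 2, 4, 8),
                           chill_days = c(10, 20, 40, 60, 80, 100),
                           photoperiods = c("long", "short"),
                           incubation_temp = 20) {
  stopifnot(all(chill_days >= 0), all(photoperiods %in% c("long", "short")))
  tidyr::expand_grid(
    chill_temp = chill_temps,
    chill_days = chill_days,
    photoperiod = photoperiods
  ) |>
    dplyr::mutate(incubation_temp = incubation_temp)
}
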