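#' Developmental-rate points from constant-temperature trials
#'
#' Converts each constant-temperature hatch trial into a developmental-rate
#' point for the linear thermal model. The development time of a trial is the
#' time from the start of postdiapause development to 50% hatch of the eggs
#' that eventually hatched ([t50()]); the rate is its reciprocal. When a
#' `termination_date` is supplied and trials carry a `collection_date`, the
#' postdiapause clock starts at the later of incubation start and the
#' termination date, so time incubated before diapause ended is not counted.
#' Trials in which no egg hatches (temperatures at or below the threshold)
#' contribute no point and are reported with a message.
#'
#' @param data a long hatch table of constant-temperature trials with an
#'   `incubation_temp` column (see [simulate_postdiapause_trials()]).
#' @param termination_date optional `Date`; requires a `collection_date`
#'   column when supplied.
#' @param time_summary `"t50"` (default; time to 50% hatch of eventually
#'   hatched eggs) or `"first_hatch"` (time of the first observation with a
#'   non-zero count, an alternative development-time summary).
#' @return A tibble of rate points: `arena_id`, `temperature`,
#'   `development_time` (days), `rate` (per day), plus `collection_date` and
#'   `year` when present.
#' @export
rate_points <- function(data, termination_date = NULL,
                        time_summary = c("t50", "first_hatch")) {
  time_summary <- match.arg(time_summary)
  check_hatch_table(data, require = "incubation_temp")
  if (nrow(data) == 0) {
    abort("`data` has no observations.")
  }
  if (!is.null(termination_date) && !"collection_date" %in% names(data)) {
    abort("`termination_date` requires a `collection_date` column in `data`.")
  }
  dev_time <- function(day, cum) {
    switch(time_summary,
      t50 = t50(day, cum),
      first_hatch = if (any(cum > 0)) day[which(cum > 0)[1]] else NA_real_
    )
  }
  meta <- intersect(c("collection_date", "year"), names(data))
  pts <- data |>
    dplyr::group_by(.data$arena_id) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(meta), dplyr::first),
      temperature = dplyr::first(.data$incubation_temp),
      development_time = dev_time(.data$day, .data$cumulative_hatched),
      .groups = "drop"
    )
  if (!is.null(termination_date)) {
    termination_date <- as.Date(termination_date)
    lag_days <- pmax(0, as.numeric(termination_date - as.Date(pts$collection_date)))
    pts$development_time <- pts$development_time - lag_days
    pts$development_time[pts$development_time <= 0] <- NA_real_
  }
  dropped <- pts$arena_id[is.na(pts$development_time)]
  if (length(dropped) > 0) {
    inform(paste0(
      length(dropped), " trial(s) without a finite development time excluded: ",
      paste(dropped, collapse = ", ")
    ))
    if (length(dropped) == nrow(pts)) {
      warn("No trial yielded a developmental-rate point.")
    }
  }
  pts |>
    dplyr::filter(!is.na(.data$development_time)) |>
    dplyr::mutate(rate = 1 / .data$development_time)
}

#' Fit the linear developmental-rate model
#'
#' Ordinary least squares of developmental rate (1/days) on temperature,
#' \deqn{1/t = a + b\,T,} the standard linear degree-day model for
#' postdiapause development. Two biologically meaningful quantities derive
#' from the fit: the lower developmental threshold \eqn{T_0 = -a/b}, the
#' temperature at which the regression line crosses the x-axis, and the
#' thermal constant \eqn{K = 1/b}, the degree-days above \eqn{T_0} required
#' to complete development.
#'
#' @param data a data frame of rate points with columns `temperature` and
#'   `rate` (or `development_time`, from which `rate` is computed); see
#'   [rate_points()].
#' @param weights optional column name (string) to weight the regression by,
#'   e.g. the number of hatched eggs behind each point; default unweighted.
#' @return An object of class `thermal_fit`: a list with `slope`,
#'   `intercept`, `threshold_T0`, `degree_days_K`, `r_squared`, `n_points`,
#'   `slope_se`, `intercept_se` (the last three `NA` when `n_points` < 3),
#'   the underlying `lm` object and the data. [tidy()], [glance()] and
#'   [autoplot()] methods are provided, plus the accessors
#'   [threshold_temperature()] and [degree_day_requirement()].
#' @export
#' @examples
#' pts <- tibble::tibble(
#'   temperature = c(9, 14, 19),
#'   rate = 0.0038 * c(9, 14, 19) - 0.0208
#' )
#' fit <- fit_thermal_model(pts)
#' threshold_temperature(fit) # 5.47 C
#' degree_day_requirement(fit) # 263.2 degree-days
fit_thermal_model <- function(data, weights = NULL) {
  if (!is.data.frame(data)) abort("`data` must be a data frame of rate points.")
  if (!"rate" %in% names(data)) {
    if (!"development_time" %in% names(data)) {
      abort("`data` needs a `rate` or `development_time` column.")
    }
    if (any(data$development_time <= 0)) abort("`development_time` must be positive.")
    data <- dplyr::mutate(data, rate = 1 / .data$development_time)
  }
  if (!"temperature" %in% names(data)) abort("`data` needs a `temperature` column.")
  if (length(unique(data$temperature)) < 2) {
    abort("At least 2 distinct temperatures are required to fit the rate line.")
  }
  w <- if (!is.null(weights)) data[[weights]] else NULL
  fit <- lm(rate ~ temperature, data = data, weights = w)
  slope <- unname(coef(fit)["temperature"])
  intercept <- unname(coef(fit)["(Intercept)"])
  if (!is.finite(slope) || slope <= 0) {
    abort(paste0(
      "Non-physical fit: slope ", format(slope),
      " <= 0; development must speed up with temperature."
    ))
  }
  n <- nrow(data)
  if (n >= 3) {
    # summary.lm warns on exactly collinear input; the fit itself is fine
    sm <- suppressWarnings(summary(fit))
    ses <- sm$coefficients[, "Std. Error"]
    r2 <- sm$r.squared
  } else {
    ses <- c(NA_real_, NA_real_)
    r2 <- NA_real_
  }
  structure(
    list(
      slope = slope, intercept = intercept,
      threshold_T0 = -intercept / slope,
      degree_days_K = 1 / slope,
      r_squared = r2, n_points = n,
      slope_se = unname(ses[2]), intercept_se = unname(ses[1]),
      lm = fit, data = tibble::as_tibble(data)
    ),
    class = "thermal_fit"
  )
}

#' Lower developmental temperature threshold of a thermal fit
#'
#' The temperature at which the fitted rate line crosses zero,
#' \eqn{T_0 = -\mathrm{intercept}/\mathrm{slope}}: below it the model
#' predicts no postdiapause development.
#'
#' @param fit a `thermal_fit` from [fit_thermal_model()].
#' @return The threshold in degrees C.
#' @export
threshold_temperature <- function(fit) {
  stopifnot(inherits(fit, "thermal_fit"))
  fit$threshold_T0
}

#' Degree-day requirement of a thermal fit
#'
#' The thermal constant \eqn{K = 1/\mathrm{slope}}: degree-days above the
#' threshold needed to complete postdiapause development.
#'
#' @inheritParams threshold_temperature
#' @return K in degree-days (degrees C x days).
#' @export
degree_day_requirement <- function(fit) {
  stopifnot(inherits(fit, "thermal_fit"))
  fit$degree_days_K
}

#' @export
print.thermal_fit <- function(x, ...) {
  cat("Linear developmental-rate model: rate = a + b * temperature\n")
  cat(sprintf(
    "  rate = %.4f %+.4f * T   (n = %d%s)\n",
    x$intercept, x$slope, x$n_points,
    if (is.na(x$r_squared)) "" else sprintf(", r^2 = %.3f", x$r_squared)
  ))
  cat(sprintf("  Lower threshold T0:  %.2f C\n", x$threshold_T0))
  cat(sprintf("  Degree-days K:       %.1f C d\n", x$degree_days_K))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.thermal_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "temperature"),
    estimate = c(x$intercept, x$slope),
    std.error = c(x$intercept_se, x$slope_se)
  )
}

#' @exportS3Method generics::glance
glance.thermal_fit <- function(x, ...) {
  tibble::tibble(
    threshold_T0 = x$threshold_T0,
    degree_days_K = x$degree_days_K,
    slope = x$slope,
    intercept = x$intercept,
    r.squared = x$r_squared,
    nobs = x$n_points
  )
}

#' @rdname fit_thermal_model
#' @param object a `thermal_fit`.
#' @param ... ignored.
#' @exportS3Method ggplot2::autoplot
autoplot.thermal_fit <- function(object, ...) {
  xmax <- max(object$data$temperature)
  line <- tibble::tibble(
    temperature = c(object$threshold_T0, xmax),
    rate = c(0, object$intercept + object$slope * xmax)
  )
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$temperature, y = .data$rate)) +
    ggplot2::geom_line(data = line, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::annotate(
      "point",
      x = object$threshold_T0, y = 0, shape = 4, size = 3, colour = "red3"
    ) +
    ggplot2::labs(
      x = "Temperature (°C)", y = "Developmental rate (1/days)",
      subtitle = sprintf(
        "T0 = %.2f °C, K = %.1f degree-days",
        object$threshold_T0, object$degree_days_K
      )
    ) +
    ggplot2::theme_minimal()
}
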