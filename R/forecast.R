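#' Daily degree-day contribution
#'
#' Simple average method: the thermal energy a day contributes to
#' postdiapause development is its mean temperature above the lower
#' threshold, `max(0, t_mean - threshold_T0)`. Vectorised over `t_mean`.
#'
#' @param t_mean daily mean temperature(s), degrees C.
#' @param threshold_T0 lower developmental threshold, degrees C.
#' @return Degree-days (degrees C x days), zero when the day is at or below
#'   the threshold.
#' @export
#' @examples
#' daily_degree_days(10, 5.47) # 4.53
#' daily_degree_days(5, 5.47) # 0
daily_degree_days <- function(t_mean, threshold_T0) {
  pmax(0, t_mean - threshold_T0)
}

#' Forecast the date of 50% egg hatch by degree-day accumulation
#'
#' Starting on `start_date` (inclusive; normally the diapause-termination
#' date), accumulates [daily_degree_days()] over a daily weather series and
#' predicts 50% hatch on the first date whose cumulative sum reaches the
#' degree-day requirement `degree_days_K`. No sub-day interpolation is done:
#' the prediction has the daily resolution of the weather record.
#'
#' @param weather a data frame with columns `date` (`Date` or ISO-8601
#'   strings, strictly increasing) and `t_mean` (degrees C).
#' @param start_date first day of accumulation; must be covered by `weather`.
#' @param threshold_T0 lower developmental threshold, degrees C.
#' @param degree_days_K degree-day requirement (>= 0).
#' @param fill_gaps if `TRUE`, single missing days are filled by linear
#'   interpolation of `t_mean`; by default any gap in the accumulation
#'   window is an error.
#' @return An object of class `hatch_forecast`: a list with `start_date`,
#'   `threshold_T0`, `degree_days_K`, `predicted_date` (`NA` if the
#'   requirement is not met within coverage) and `trajectory`, a tibble with
#'   one row per day (`date`, `t_mean`, `daily_dd`, `cumulative_dd`).
#'   [tidy()] returns the trajectory, [glance()] a one-row summary and
#'   [autoplot()] the accumulation curve.
#' @export
#' @examples
#' w <- tibble::tibble(
#'   date = seq(as.Date("2005-01-01"), as.Date("2005-03-01"), by = "day"),
#'   t_mean = 15.47
#' )
#' predict_hatch_date(w, "2005-01-01", threshold_T0 = 5.47, degree_days_K = 263.2)
predict_hatch_date <- function(weather, start_date, threshold_T0, degree_days_K,
                               fill_gaps = FALSE) {
  stopifnot(degree_days_K >= 0)
  if (!is.data.frame(weather) || !all(c("date", "t_mean") %in% names(weather))) {
    abort("`weather` must be a data frame with columns `date` and `t_mean`.")
  }
  weather <- weather |>
    dplyr::mutate(date = as.Date(.data$date)) |>
    dplyr::arrange(.data$date)
  if (anyDuplicated(weather$date) > 0) abort("`weather` has duplicated dates.")
  start_date <- as.Date(start_date)
  if (nrow(weather) == 0 || start_date < min(weather$date) || start_date > max(weather$date)) {
    abort("`start_date` is outside the weather record.")
  }
  w <- dplyr::filter(weather, .data$date >= start_date)
  if (fill_gaps) {
    full <- tibble::tibble(date = seq(min(w$date), max(w$date), by = "day"))
    w <- dplyr::left_join(full, w, by = "date")
    w$t_mean <- approx(w$date, w$t_mean, xout = w$date, method = "linear")$y
  }
  gaps <- diff(as.numeric(w$date))
  traj <- w |>
    dplyr::mutate(
      daily_dd = daily_degree_days(.data$t_mean, threshold_T0),
      cumulative_dd = cumsum(.data$daily_dd)
    )
  hit <- which(traj$cumulative_dd >= degree_days_K)
  first_gap <- which(gaps > 1)[1]
  if (!is.na(first_gap) && (length(hit) == 0 || hit[1] > first_gap)) {
    abort(paste0(
      "Gap in the weather record after ", format(w$date[first_gap]),
      " before the degree-day requirement was met",
      " (set `fill_gaps = TRUE` to interpolate single days)."
    ))
  }
  structure(
    list(
      start_date = start_date,
      threshold_T0 = threshold_T0,
      degree_days_K = degree_days_K,
      predicted_date = if (length(hit) > 0) traj$date[hit[1]] else as.Date(NA),
      trajectory = traj
    ),
    class = "hatch_forecast"
  )
}

#' @export
print.hatch_forecast <- function(x, ...) {
  cat(sprintf(
    "Degree-day hatch forecast (T0 = %.2f C, K = %.1f C d) from %s\n",
    x$threshold_T0, x$degree_days_K, format(x$start_date)
  ))
  if (is.na(x$predicted_date)) {
    cat(sprintf(
      "50%% hatch not reached within coverage (%.1f of %.1f C d accumulated)\n",
      max(x$trajectory$cumulative_dd), x$degree_days_K
    ))
  } else {
    cat("Predicted date of 50% hatch:", format(x$predicted_date), "\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.hatch_forecast <- function(x, ...) x$trajectory

#' @exportS3Method generics::glance
glance.hatch_forecast <- function(x, ...) {
  tibble::tibble(
    start_date = x$start_date,
    threshold_T0 = x$threshold_T0,
    degree_days_K = x$degree_days_K,
    predicted_date = x$predicted_date,
    days_to_prediction = as.numeric(x$predicted_date - x$start_date) + 1,
    total_dd = max(x$trajectory$cumulative_dd)
  )
}

#' @rdname predict_hatch_date
#' @param object a `hatch_forecast`.
#' @param ... ignored.
#' @exportS3Method ggplot2::autoplot
autoplot.hatch_forecast <- function(object, ...) {
  p <- ggplot2::ggplot(
    object$trajectory,
    ggplot2::aes(x = .data$date, y = .data$cumulative_dd)
  ) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$degree_days_K, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Cumulative degree-days (°C·d)") +
    ggplot2::theme_minimal()
  if (!is.na(object$predicted_date)) {
    p <- p + ggplot2::geom_vline(
      xintercept = object$predicted_date,
      linetype = "dotted", colour = "red3"
    )
  }
  p
}
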