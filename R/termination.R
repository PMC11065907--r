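#' Pooled hatch fraction within a fixed incubation window
#'
#' For each field-collection batch (all arenas sharing a `collection_date`),
#' computes the fraction of eggs hatched within `cutoff` days of incubation,
#' pooling eggs across the batch's arenas. The cumulative count of each arena
#' is linearly interpolated at exactly `cutoff` days between the two
#' observations that bracket it (zero before the first observation, carried
#' forward past the last), then summed and divided by the batch's total egg
#' count.
#'
#' @param data a long hatch table with a `collection_date` column.
#' @param cutoff incubation window in days (> 0); default 20.
#' @return A tibble with one row per collection date: `collection_date`,
#'   `n_arenas`, `n_eggs`, `hatched_at_cutoff`, `fraction`.
#' @export
fraction_within <- function(data, cutoff = 20) {
  stopifnot(cutoff > 0)
  check_hatch_table(data, require = "collection_date")
  if (nrow(data) == 0) {
    abort("`data` has no observations.")
  }
  arenas <- data |>
    dplyr::group_by(.data$arena_id, .data$collection_date) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::summarise(
      n_eggs = dplyr::first(.data$n_eggs),
      hatched = interp_count(.data$day, .data$cumulative_hatched, cutoff),
      .groups = "drop"
    )
  out <- arenas |>
    dplyr::group_by(.data$collection_date) |>
    dplyr::summarise(
      n_arenas = dplyr::n(),
      n_eggs = sum(.data$n_eggs),
      hatched_at_cutoff = sum(.data$hatched),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$collection_date)
  if (any(out$n_eggs == 0)) {
    abort("A batch with zero total eggs has an undefined hatch fraction.")
  }
  dplyr::mutate(out, fraction = .data$hatched_at_cutoff / .data$n_eggs)
}

# cumulative count at time `at`: 0 before the first observation (nothing has
# been seen to hatch yet), linearly interpolated between observations,
# constant after the last one
interp_count <- function(day, cumulative, at) {
  if (at < day[1]) {
    return(0)
  }
  if (at >= day[length(day)]) {
    return(cumulative[length(cumulative)])
  }
  approx(day, cumulative, xout = at, method = "linear", ties = "ordered")$y
}

#' Diapause-termination date from sequential collection batches
#'
#' Eggs kept under outdoor conditions are brought to standard incubation
#' (20 degrees C, long photoperiod) every few days; diapause is considered
#' terminated on the earliest collection date whose batch reaches at least
#' `threshold` hatch within `cutoff` days of incubation.
#'
#' @inheritParams fraction_within
#' @param threshold hatch fraction a batch must reach (default 0.5).
#' @return An object of class `termination_result`: a list with
#'   `termination_date` (a `Date`, or `NA` if no batch qualifies),
#'   `threshold`, `cutoff`, and `batches`, the per-batch table of
#'   [fraction_within()]. [tidy()] returns the batch table, [glance()] a
#'   one-row summary, and [autoplot()] plots fraction against collection
#'   date.
#' @export
#' @examples
#' eggs <- tibble::tibble(
#'   arena_id = rep(c("a", "b", "c"), each = 2),
#'   collection_date = as.Date(rep(c("2005-02-01", "2005-02-10", "2005-02-20"), each = 2)),
#'   n_eggs = 50L,
#'   day = rep(c(10, 20), 3),
#'   cumulative_hatched = c(2, 10, 15, 30, 20, 40)
#' )
#' termination_date(eggs)
termination_date <- function(data, threshold = 0.5, cutoff = 20) {
  stopifnot(threshold > 0, threshold <= 1)
  if (is.null(data) || nrow(data) == 0) abort("`data` has no observations.")
  batches <- fraction_within(data, cutoff = cutoff)
  hit <- batches$collection_date[batches$fraction >= threshold]
  structure(
    list(
      termination_date = if (length(hit) > 0) min(hit) else as.Date(NA),
      threshold = threshold,
      cutoff = cutoff,
      batches = batches
    ),
    class = "termination_result"
  )
}

#' @export
print.termination_result <- function(x, ...) {
  cat("Diapause termination rule: first batch with >=",
    sprintf("%.0f%%", 100 * x$threshold), "hatch within", x$cutoff, "days\n")
  if (is.na(x$termination_date)) {
    cat("Termination date: not reached (", nrow(x$batches), "batches )\n")
  } else {
    cat("Termination date:", format(x$termination_date), "\n")
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.termination_result <- function(x, ...) x$batches

#' @exportS3Method generics::glance
glance.termination_result <- function(x, ...) {
  tibble::tibble(
    termination_date = x$termination_date,
    threshold = x$threshold,
    cutoff = x$cutoff,
    n_batches = nrow(x$batches),
    max_fraction = max(x$batches$fraction)
  )
}

#' @rdname termination_date
#' @param object a `termination_result`.
#' @param ... ignored.
#' @exportS3Method ggplot2::autoplot
autoplot.termination_result <- function(object, ...) {
  p <- ggplot2::ggplot(
    object$batches,
    ggplot2::aes(x = .data$collection_date, y = .data$fraction)
  ) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(
      x = "Collection date",
      y = sprintf("Hatch fraction within %g days", object$cutoff)
    ) +
    ggplot2::theme_minimal()
  if (!is.na(object$termination_date)) {
    p <- p + ggplot2::geom_vline(
      xintercept = object$termination_date,
      linetype = "dotted", colour = "red3"
    )
  }
  p
}
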