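#' Apply the two-flat-observations censoring rule
#'
#' Evaluation of an arena ends once two consecutive observations record no
#' new emergence (with a 10-day cadence, 20 days without hatching). This
#' function truncates each arena's time course immediately after the first
#' such pair — counting the interval before the first observation, so an
#' arena whose first two checks find nothing is closed at the second check —
#' and records the closing day in a `censored_at` column (`NA` where the rule
#' never triggers). The operation is idempotent.
#'
#' @param data a long hatch table (see [simulate_chill_experiment()] for the
#'   schema): columns `arena_id`, `n_eggs`, `day`, `cumulative_hatched` plus
#'   any treatment metadata.
#' @return The truncated table, same schema plus `censored_at`.
#' @export
#' @examples
#' x <- tibble::tibble(
#'   arena_id = "a", n_eggs = 50L,
#'   day = c(10, 20, 30, 40, 50),
#'   cumulative_hatched = c(10, 30, 30, 30, 45)
#' )
#' apply_censoring(x) # closed at day 40; the day-50 count is discarded
apply_censoring <- function(data) {
  check_hatch_table(data)
  if (nrow(data) == 0) {
    return(dplyr::mutate(data, censored_at = double()))
  }
  data |>
    dplyr::group_by(.data$arena_id) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::group_modify(function(g, key) {
      inc <- diff(c(0, g$cumulative_hatched))
      flat <- which(inc == 0 & dplyr::lag(inc, default = 1) == 0)
      if (length(flat) == 0) {
        g$censored_at <- NA_real_
        return(g)
      }
      cut <- flat[1]
      g <- g[seq_len(cut), , drop = FALSE]
      g$censored_at <- g$day[cut]
      g
    }) |>
    dplyr::ungroup()
}

#' Median hatch time of a cumulative hatch curve
#'
#' `t50()` is the number of days of incubation until half of the eggs that
#' eventually hatch have hatched. The cumulative curve is anchored at
#' (day 0, 0 hatched) and linearly interpolated between observations; the
#' earliest time at which it reaches 50% of the denominator is returned, and
#' an observation that sits exactly at 50% returns that observation's day.
#'
#' @param day strictly increasing observation days (> 0).
#' @param cumulative_hatched non-decreasing cumulative counts, one per day.
#' @param denominator `"hatched"` (default; eggs that ever hatched, the
#'   standard T50 definition) or `"total"` (all eggs, for sensitivity
#'   analysis; requires `n_eggs`).
#' @param n_eggs initial egg count, needed only for `denominator = "total"`.
#' @return The median hatch time in days, or `NA` if no egg hatched (or, with
#'   `denominator = "total"`, if the curve never reaches 50% of `n_eggs`).
#' @export
#' @examples
#' t50(c(10, 20), c(0, 40)) # 15: the crossing is interpolated
#' t50(c(10, 20), c(20, 40)) # 10: exactly 50% at an observation
t50 <- function(day, cumulative_hatched, denominator = c("hatched", "total"),
                n_eggs = NULL) {
  denominator <- match.arg(denominator)
  stopifnot(length(day) == length(cumulative_hatched), length(day) > 0)
  if (is.unsorted(day, strictly = TRUE) || any(day <= 0)) {
    abort("`day` must be strictly increasing and positive.")
  }
  if (is.unsorted(cumulative_hatched)) {
    abort("`cumulative_hatched` must be non-decreasing.")
  }
  final <- cumulative_hatched[length(cumulative_hatched)]
  denom <- switch(denominator,
    hatched = final,
    total = {
      if (is.null(n_eggs)) abort("`n_eggs` is required when denominator = \"total\".")
      n_eggs
    }
  )
  if (denom <= 0 || final < denom / 2) {
    return(NA_real_)
  }
  target <- denom / 2
  d <- c(0, day)
  cc <- c(0, cumulative_hatched)
  i <- which(cc >= target)[1]
  if (cc[i] == target) {
    return(d[i])
  }
  d[i - 1] + (target - cc[i - 1]) * (d[i] - d[i - 1]) / (cc[i] - cc[i - 1])
}

#' Per-arena hatch statistics
#'
#' Summarises each arena of a hatch table into its final hatch outcome:
#' number hatched, hatch fraction and median hatch time [t50()], after
#' optionally applying the censoring rule.
#'
#' @inheritParams apply_censoring
#' @param censor apply [apply_censoring()] first (default `TRUE`).
#' @param denominator passed to [t50()].
#' @return A tibble with one row per arena: `arena_id`, any treatment
#'   metadata present, `n_eggs`, `n_hatched`, `hatch_fraction`, `t50`,
#'   `censored_at`.
#' @export
summarize_hatch <- function(data, censor = TRUE,
                            denominator = c("hatched", "total")) {
  denominator <- match.arg(denominator)
  check_hatch_table(data)
  if (nrow(data) > 0 && any(data$n_eggs == 0)) {
    abort("Hatch fraction is undefined for arenas with `n_eggs` = 0.")
  }
  if (censor) data <- apply_censoring(data) else data$censored_at <- NA_real_
  meta <- present_meta(data)
  data |>
    dplyr::group_by(.data$arena_id) |>
    dplyr::arrange(.data$day, .by_group = TRUE) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(setdiff(meta, "n_eggs")), dplyr::first),
      n_eggs = dplyr::first(.data$n_eggs),
      n_hatched = dplyr::last(.data$cumulative_hatched),
      hatch_fraction = .data$n_hatched / .data$n_eggs,
      t50 = t50(.data$day, .data$cumulative_hatched,
        denominator = denominator, n_eggs = dplyr::first(.data$n_eggs)
      ),
      censored_at = dplyr::first(.data$censored_at),
      .groups = "drop"
    )
}

#' Treatment-level summary of a hatch experiment
#'
#' Groups the per-arena summaries of [summarize_hatch()] by the treatment
#' factors present in the table (`year`, `chill_temp`, `chill_days`,
#' `photoperiod`, `incubation_temp`) and reports the mean and standard error
#' of the hatch fraction and of T50 — the tidy table on which ANOVA or
#' post-hoc tests can then be run with standard tools.
#'
#' @inheritParams summarize_hatch
#' @return A tibble with one row per treatment: the grouping columns,
#'   `n_arenas`, `mean_hatch_fraction`, `se_hatch_fraction`, `n_t50`
#'   (arenas with a defined T50), `mean_t50`, `se_t50`. Standard errors are
#'   `NA` for a single arena.
#' @export
#' @examples
#' eggs <- simulate_chill_experiment(
#'   treatment_grid(chill_temps = 4, chill_days = c(10, 100)),
#'   replicates = 3, params = sim_params(seed = 1)
#' )
#' summarize_experiment(eggs)
summarize_experiment <- function(data, censor = TRUE,
                                 denominator = c("hatched", "total")) {
  arenas <- summarize_hatch(data, censor = censor, denominator = denominator)
  groups <- intersect(.treatment_cols, names(arenas))
  se <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) NA_real_ else sd(x) / sqrt(length(x))
  }
  arenas |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::summarise(
      n_arenas = dplyr::n(),
      mean_hatch_fraction = mean(.data$hatch_fraction),
      se_hatch_fraction = se(.data$hatch_fraction),
      n_t50 = sum(!is.na(.data$t50)),
      mean_t50 = ifelse(.data$n_t50 > 0, mean(.data$t50, na.rm = TRUE), NA_real_),
      se_t50 = se(.data$t50),
      .groups = "drop"
    )
}
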