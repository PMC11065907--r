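#' Read a hatch observation table from CSV
#'
#' Reads the long hatch schema — one row per (arena, observation day) with
#' columns `arena_id`, `n_eggs`, `day`, `cumulative_hatched` and optional
#' treatment metadata (`collection_date` as ISO-8601, `year`, `chill_temp`,
#' `chill_days`, `photoperiod`, `incubation_temp`) — and validates the series
#' invariants: unique (arena, day), non-decreasing cumulative counts bounded
#' by `n_eggs`, positive days. Photoperiod hour strings (`"16:8"`, `"8:16"`)
#' are accepted as aliases for `"long"`/`"short"`.
#'
#' @param path CSV file path.
#' @return A validated tibble in the hatch-table schema.
#' @export
read_hatch_table <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(data) == 0) {
    warn(paste0("Empty hatch table: ", path))
    return(tibble::as_tibble(data))
  }
  if ("photoperiod" %in% names(data)) {
    data$photoperiod <- normalize_photoperiod(data$photoperiod)
  }
  if ("collection_date" %in% names(data)) {
    data$collection_date <- as.Date(data$collection_date)
  }
  check_hatch_table(data)
  data
}

#' Write a hatch observation table to CSV
#'
#' Inverse of [read_hatch_table()]; the round trip preserves every series
#' exactly (dates as ISO-8601, numerics at full precision).
#'
#' @param data a hatch table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_hatch_table <- function(data, path) {
  check_hatch_table(data)
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Read a daily weather table from CSV
#'
#' Expects columns `date` (ISO-8601) and `t_mean`, with optional `t_min` and
#' `t_max`; checks that dates are strictly increasing and that
#' `t_min <= t_mean <= t_max` wherever all three are present.
#'
#' @param path CSV file path.
#' @return A tibble with `date` parsed as `Date`.
#' @export
read_weather_table <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  w <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("date", "t_mean"), names(w))
  if (length(missing) > 0) {
    abort(paste0("Weather table lacks column(s): ", paste(missing, collapse = ", "), "."))
  }
  w$date <- as.Date(w$date)
  if (is.unsorted(w$date, strictly = TRUE)) {
    abort("Weather dates must be strictly increasing.")
  }
  if (all(c("t_min", "t_max") %in% names(w))) {
    ok <- is.na(w$t_min) | is.na(w$t_max) |
      (w$t_min <= w$t_mean & w$t_mean <= w$t_max)
    if (!all(ok)) abort("Rows violate t_min <= t_mean <= t_max.")
  }
  w
}

#' @rdname read_weather_table
#' @param data a weather table.
#' @param path output CSV path.
#' @export
write_weather_table <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

# keys accepted in a run configuration, by section
.config_schema <- list(
  seed = NULL,
  output_dir = NULL,
  sim = c(
    "hatch_logit_intercept", "chill_day_coef", "chill_day_cap",
    "photoperiod_long_bonus", "chill_temp_optimum", "chill_temp_curvature",
    "t50_base", "t50_decay", "t50_floor", "hatch_time_cv", "observation_interval"
  ),
  postdiapause = c("true_threshold", "true_degree_days", "rate_noise_sd", "n_eggs"),
  weather = c("annual_mean", "annual_amplitude", "coldest_day_of_year", "daily_noise_sd"),
  stats = c("censor", "denominator"),
  fit = c("weights", "time_summary"),
  forecast = c("threshold", "cutoff", "fill_gaps")
)

#' Read and validate a run configuration
#'
#' A YAML file with optional sections `sim`, `postdiapause`, `weather`,
#' `stats`, `fit`, `forecast` plus top-level `seed` and `output_dir`.
#' Unknown keys are rejected so that typos cannot silently fall back to
#' defaults. [write_run_config()] writes a configuration back; the round
#' trip is lossless.
#'
#' @param path YAML file path.
#' @return The configuration as a named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  bad_top <- setdiff(names(cfg), names(.config_schema))
  if (length(bad_top) > 0) {
    abort(paste0("Unknown config key(s): ", paste(bad_top, collapse = ", "), "."))
  }
  for (sec in names(cfg)) {
    allowed <- .config_schema[[sec]]
    if (is.null(allowed)) next
    bad <- setdiff(names(cfg[[sec]]), allowed)
    if (length(bad) > 0) {
      abort(paste0(
        "Unknown key(s) in config section `", sec, "`: ",
        paste(bad, collapse = ", "), "."
      ))
    }
  }
  cfg
}

#' @rdname read_run_config
#' @param config a configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write analysis reports and a reproducibility manifest
#'
#' Writes each element of a named result list to `out_dir` in a plain-text
#' format chosen by its class — `thermal_fit` as a JSON fit report
#' (equation, T0, K, r^2, n), `hatch_forecast` as a JSON summary plus a
#' per-day trajectory CSV, `termination_result` as a JSON summary plus the
#' per-batch CSV, data frames as CSV (hatch-fraction summary columns are
#' rendered as percentages with 2 decimals) — plus a `manifest.json`
#' recording the files written, a hash of the configuration, the seed and
#' package/R versions. Payload files are byte-identical across repeated runs
#' with the same inputs; only the manifest timestamp differs.
#'
#' @param results a named list of results.
#' @param out_dir output directory, created if needed.
#' @param config optional configuration list to hash into the manifest.
#' @param seed optional seed to record.
#' @return The manifest, invisibly.
#' @export
write_reports <- function(results, out_dir, config = NULL, seed = NULL) {
  stopifnot(is.list(results), length(results) == 0 || !is.null(names(results)))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0) {
    abort(paste0("Cannot write to directory: ", out_dir))
  }
  files <- character()
  emit_json <- function(x, name) {
    f <- file.path(out_dir, paste0(name, ".json"))
    jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, null = "null", Date = "ISO8601")
    files <<- c(files, f)
  }
  emit_csv <- function(x, name) {
    f <- file.path(out_dir, paste0(name, ".csv"))
    readr::write_csv(x, f, progress = FALSE)
    files <<- c(files, f)
  }
  for (name in names(results)) {
    x <- results[[name]]
    if (inherits(x, "thermal_fit")) {
      emit_json(list(
        slope = x$slope, intercept = x$intercept,
        t0 = x$threshold_T0, degree_days = x$degree_days_K,
        r2 = x$r_squared, n = x$n_points
      ), name)
    } else if (inherits(x, "hatch_forecast")) {
      emit_json(list(
        start_date = format(x$start_date), t0 = x$threshold_T0,
        degree_days = x$degree_days_K,
        predicted_date = if (is.na(x$predicted_date)) NULL else format(x$predicted_date)
      ), name)
      emit_csv(x$trajectory, paste0(name, "_trajectory"))
    } else if (inherits(x, "termination_result")) {
      emit_json(list(
        termination_date = if (is.na(x$termination_date)) NULL else format(x$termination_date),
        threshold = x$threshold, cutoff = x$cutoff
      ), name)
      emit_csv(x$batches, paste0(name, "_batches"))
    } else if (is.data.frame(x)) {
      emit_csv(render_percentages(x), name)
    } else {
      abort(paste0("Don't know how to report an object of class ", class(x)[1], "."))
    }
  }
  manifest <- list(
    files = basename(files),
    config_hash = rlang::hash(config),
    seed = seed,
    package_version = as.character(utils::packageVersion("hatchphen")),
    r_version = as.character(getRversion()),
    written_at = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(manifest)
}

# proportions are stored internally; reports show percentages with 2 decimals
render_percentages <- function(x) {
  for (col in c("hatch_fraction", "mean_hatch_fraction", "se_hatch_fraction")) {
    if (col %in% names(x)) {
      pct <- sub("fraction", "pct", col)
      x[[pct]] <- round(100 * x[[col]], 2)
      x[[col]] <- NULL
    }
  }
  x
}
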