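# small constructors used across the suite; all fixtures are built in code

make_arena <- function(days, counts, n_eggs = 50L, arena_id = "a1", ...) {
  tibble::tibble(
    arena_id = arena_id, ..., n_eggs = as.integer(n_eggs),
    day = days, cumulative_hatched = counts
  )
}

# a random valid step curve: counts observed on a 10-day cadence
random_step_curve <- function(n_obs = NULL, n_eggs = NULL) {
  n_obs <- n_obs %||% sample(2:8, 1)
  n_eggs <- n_eggs %||% sample(10:50, 1)
  days <- seq(10, by = 10, length.out = n_obs)
  counts <- sort(sample(0:n_eggs, n_obs, replace = TRUE))
  make_arena(days, counts, n_eggs = n_eggs)
}

# independent oracle for t50: scan a fine time grid of the interpolated
# cumulative curve (anchored at the origin) for the first time it reaches
# half of the final hatched count
t50_grid_oracle <- function(day, cumulative, resolution = 0.001) {
  final <- cumulative[length(cumulative)]
  if (final <= 0) {
    return(NA_real_)
  }
  grid <- seq(0, max(day), by = resolution)
  vals <- stats::approx(c(0, day), c(0, cumulative), xout = grid)$y
  grid[which(vals >= final / 2)[1]]
}

`%||%` <- rlang::`%||%`
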