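#' Broadcast schedules for institutional agents
#'
#' A schedule maps every timestep `t` in `1..horizon` to the belief level the
#' institution encodes in the message it broadcasts at `t`. Three named
#' patterns are provided:
#'
#' * `schedule_single()`: one constant level for the whole run;
#' * `schedule_split()`: one level for the first half, another for the second;
#' * `schedule_gradual()`: a stepwise walk that moves one level toward `end`
#'   every `interval` timesteps and then holds `end`;
#' * `schedule_custom()`: an arbitrary level sequence.
#'
#' @param horizon Number of timesteps `T` (>= 1). Timesteps are 1-based.
#' @param level,first,second,start,end Belief levels, validated against
#'   `space`.
#' @param interval Number of timesteps between consecutive one-level moves in
#'   the gradual pattern.
#' @param levels For `schedule_custom()`, an integer vector of length
#'   `horizon` giving the level broadcast at each timestep.
#' @param space A [belief_space()].
#'
#' @return A tibble with columns `t` (integer, `1:horizon`) and `level`
#'   (integer), of class `pod_schedule`. The pattern name is kept in the
#'   `schedule_name` attribute.
#' @examples
#' schedule_single(100, 6)
#' schedule_split(100, 6, 0)
#' schedule_gradual(100, 6, 0, interval = 10)
#' @name schedules
NULL

new_schedule <- function(t, level, name, space) {
  out <- tibble::tibble(t = as.integer(t), level = as.integer(level))
  attr(out, "schedule_name") <- name
  attr(out, "resolution") <- space$resolution
  class(out) <- c("pod_schedule", class(out))
  out
}

check_horizon <- function(horizon) {
  if (length(horizon) != 1 || is.na(horizon) || horizon < 1 ||
      horizon != as.integer(horizon)) {
    abort("`horizon` must be a single integer >= 1.")
  }
  as.integer(horizon)
}

#' @rdname schedules
#' @export
schedule_single <- function(horizon, level, space = belief_space()) {
  horizon <- check_horizon(horizon)
  level <- check_levels(level, space)
  new_schedule(1:horizon, rep(level, horizon), "single", space)
}

#' @rdname schedules
#' @export
schedule_split <- function(horizon, first, second, space = belief_space()) {
  horizon <- check_horizon(horizon)
  first <- check_levels(first, space, "first")
  second <- check_levels(second, space, "second")
  half <- horizon %/% 2L
  new_schedule(1:horizon, c(rep(first, half), rep(second, horizon - half)),
               "split", space)
}

#' @rdname schedules
#' @export
schedule_gradual <- function(horizon, start, end, interval = 10L,
                             space = belief_space()) {
  horizon <- check_horizon(horizon)
  start <- check_levels(start, space, "start")
  end <- check_levels(end, space, "end")
  if (length(interval) != 1 || is.na(interval) || interval < 1) {
    abort("`interval` must be a single integer >= 1.")
  }
  interval <- as.integer(interval)
  step <- if (start >= end) -1L else 1L
  t <- 1:horizon
  lev <- start + step * ((t - 1L) %/% interval)
  lev <- if (step < 0) pmax(lev, end) else pmin(lev, end)
  if (!any(lev == end)) {
    warn(sprintf(
      "horizon %d too short to reach level %d from %d at interval %d; schedule ends at level %d.",
      horizon, end, start, interval, lev[horizon]))
  }
  new_schedule(t, lev, "gradual", space)
}

#' @rdname schedules
#' @export
schedule_custom <- function(levels, space = belief_space(),
                            horizon = length(levels)) {
  horizon <- check_horizon(horizon)
  if (length(levels) != horizon) {
    abort("`levels` must have length `horizon`.")
  }
  levels <- check_levels(levels, space, "levels")
  new_schedule(1:horizon, levels, "custom", space)
}

#' Look up the level(s) broadcast at a timestep
#'
#' @param schedule A `pod_schedule`.
#' @param t A timestep in `1..horizon`.
#' @return Integer vector of belief levels broadcast at `t` (length one for
#'   the built-in patterns).
#' @export
schedule_at <- function(schedule, t) {
  lev <- schedule$level[schedule$t == t]
  if (!length(lev)) abort(sprintf("schedule is not defined at t = %s.", t))
  lev
}

#' Read or write a schedule as CSV (columns `t,level`)
#'
#' @param schedule A `pod_schedule`.
#' @param path File path.
#' @param space A [belief_space()] used to validate levels on read.
#' @return `write_schedule_csv()` returns `schedule` invisibly;
#'   `read_schedule_csv()` returns a `pod_schedule`.
#' @export
write_schedule_csv <- function(schedule, path) {
  readr::write_csv(tibble::as_tibble(schedule)[c("t", "level")], path)
  invisible(schedule)
}

#' @rdname write_schedule_csv
#' @export
read_schedule_csv <- function(path, space = belief_space()) {
  df <- readr::read_csv(path, col_types = readr::cols(
    t = readr::col_integer(), level = readr::col_integer()))
  df <- dplyr::arrange(df, .data$t)
  if (!identical(df$t, seq_len(nrow(df)))) {
    abort("schedule CSV must cover every timestep 1..T exactly once.")
  }
  schedule_custom(df$level, space)
}
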