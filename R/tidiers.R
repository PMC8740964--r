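#' Tidy and summarize simulation results
#'
#' `tidy()` returns the long belief timeseries; `glance()` a one-row
#' summary with the population size, horizon, subscriber count and the
#' final shares at the extreme belief levels.
#'
#' @param x A `pod_run` or `pod_batch`.
#' @param ... Unused.
#' @return A tibble.
#' @examples
#' run <- run_simulation(simulation_config(n_agents = 80, horizon = 10,
#'                                         seed = 1))
#' glance(run)
#' @exportS3Method generics::tidy
tidy.pod_run <- function(x, ...) {
  x$timeseries
}

#' @rdname tidy.pod_run
#' @exportS3Method generics::tidy
tidy.pod_batch <- function(x, ...) {
  x$summary
}

#' @rdname tidy.pod_run
#' @exportS3Method generics::glance
glance.pod_run <- function(x, ...) {
  fin <- dplyr::filter(x$timeseries, .data$t == max(.data$t))
  top <- max(fin$level)
  tibble::tibble(
    n_agents = length(x$final_beliefs),
    horizon = max(x$timeseries$t),
    n_subscribers = x$n_subscribers,
    final_frac_top = fin$fraction[fin$level == top],
    final_frac_bottom = fin$fraction[fin$level == 0])
}

#' @rdname tidy.pod_run
#' @exportS3Method generics::glance
glance.pod_batch <- function(x, ...) {
  fin <- dplyr::filter(x$summary, .data$t == max(.data$t))
  top <- max(fin$level)
  tibble::tibble(
    replicates = length(x$seeds),
    n_agents = x$config$n_agents,
    horizon = x$config$horizon,
    final_frac_top = fin$mean_fraction[fin$level == top],
    final_frac_bottom = fin$mean_fraction[fin$level == 0])
}

#' Plot belief-share trajectories
#'
#' The model's standard result figure: the share of agents at each belief
#' level against time, one line per level.
#'
#' @param object A `pod_run` or `pod_batch`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pod_run <- function(object, ...) {
  plot_timeseries(object$timeseries, "fraction")
}

#' @rdname autoplot.pod_run
#' @exportS3Method ggplot2::autoplot
autoplot.pod_batch <- function(object, ...) {
  plot_timeseries(object$summary, "mean_fraction")
}

plot_timeseries <- function(ts, col) {
  ggplot2::ggplot(ts, ggplot2::aes(.data$t, .data[[col]],
                                   color = factor(.data$level))) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = "timestep", y = "share of agents",
                  color = "belief level") +
    ggplot2::theme_minimal()
}
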