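#' Simulation configuration
#'
#' Bundles every knob of a public-opinion-diffusion experiment. The defaults
#' are the study conditions used throughout: 500 agents, one institution
#' with perceived belief at the top of a 7-level scale, subscriber distance
#' bound `epsilon = 0`, 100 timesteps, the DCC contagion rule on an ER
#' random graph, and 10 replicates.
#'
#' @param n_agents Number of networked agents `N`.
#' @param horizon Number of timesteps `T`.
#' @param belief_resolution Number of discrete belief levels `R`.
#' @param epsilon Subscriber belief-distance bound (>= 0).
#' @param institution_belief The institution's perceived belief; defaults to
#'   the top level `R - 1`.
#' @param schedule Either a schedule name (`"single"`, `"split"`,
#'   `"gradual"`) or a `pod_schedule` object. The named patterns expand to
#'   the canonical experiment sets: constant top level; top level then
#'   bottom level at half time; stepwise descent from top to bottom one
#'   level per 10 steps.
#' @param graph A [graph_spec()].
#' @param contagion A [contagion_spec()] or preset name (see
#'   [contagion_preset()]). Distance parameters are rescaled automatically
#'   when `belief_resolution != 7` (see [scale_spec_for_resolution()]).
#' @param replicates Number of replicate runs for [run_batch()].
#' @param seed Base random seed (integer).
#' @param retry_policy Whether an agent that rejects a message may be
#'   retried on later deliveries of the same message: `"once"` (default; one
#'   adoption trial per agent and message) or `"per-delivery"` (every
#'   delivery of a not-yet-believed message triggers an independent trial).
#' @param proportional_frozen If `TRUE`, the proportional rule evaluates
#'   neighbor beliefs frozen at message-injection time instead of at trial
#'   time.
#' @param record_events If `TRUE`, runs keep a per-delivery cascade event
#'   log (large; intended for small graphs and tests).
#'
#' @return An object of class `pod_config`.
#' @examples
#' cfg <- simulation_config(seed = 1)
#' @export
simulation_config <- function(n_agents = 500L,
                              horizon = 100L,
                              belief_resolution = 7L,
                              epsilon = 0,
                              institution_belief = belief_resolution - 1L,
                              schedule = "single",
                              graph = graph_spec("ER"),
                              contagion = "dcc",
                              replicates = 10L,
                              seed = 1L,
                              retry_policy = c("once", "per-delivery"),
                              proportional_frozen = FALSE,
                              record_events = FALSE) {
  retry_policy <- match.arg(retry_policy)
  space <- belief_space(belief_resolution)
  if (is.character(contagion)) contagion <- contagion_preset(contagion)
  stopifnot(inherits(contagion, "contagion_spec"))
  if (belief_resolution != 7L) {
    contagion <- scale_spec_for_resolution(contagion, space)
  }
  if (is.character(schedule)) {
    top <- space$resolution - 1L
    schedule <- switch(schedule,
      single = schedule_single(horizon, top, space),
      split = schedule_split(horizon, top, 0L, space),
      gradual = schedule_gradual(horizon, top, 0L, 10L, space),
      abort(sprintf("unknown schedule name '%s'.", schedule)))
  }
  stopifnot(inherits(schedule, "pod_schedule"))
  if (max(schedule$t) < horizon) {
    abort("schedule does not cover every timestep 1..horizon.")
  }
  if (n_agents < 2 || horizon < 1 || replicates < 1 || epsilon < 0) {
    abort("counts must be positive and `epsilon` >= 0.")
  }
  institution_belief <- check_levels(institution_belief, space,
                                     "institution_belief")
  structure(
    list(n_agents = as.integer(n_agents), horizon = as.integer(horizon),
         space = space, epsilon = epsilon,
         institution_belief = institution_belief,
         schedule = schedule, graph = graph, contagion = contagion,
         replicates = as.integer(replicates), seed = as.integer(seed),
         retry_policy = retry_policy,
         proportional_frozen = isTRUE(proportional_frozen),
         record_events = isTRUE(record_events)),
    class = "pod_config"
  )
}

#' @export
print.pod_config <- function(x, ...) {
  cat("<pod_config> N =", x$n_agents, "| T =", x$horizon,
      "| R =", x$space$resolution,
      "| graph:", x$graph$family,
      "| contagion:", x$contagion$variant,
      "| schedule:", attr(x$schedule, "schedule_name"),
      "| replicates:", x$replicates, "| seed:", x$seed, "\n")
  invisible(x)
}

#' Read/write a simulation configuration as YAML
#'
#' Field names mirror [simulation_config()] arguments; `graph` and
#' `contagion` are nested maps, `schedule` is either a pattern name or an
#' explicit list of levels.
#'
#' @param config A `pod_config`.
#' @param path File path.
#' @return `read_config()` returns a `pod_config`.
#' @export
write_config <- function(config, path) {
  sch <- attr(config$schedule, "schedule_name")
  lst <- list(
    n_agents = config$n_agents, horizon = config$horizon,
    belief_resolution = config$space$resolution, epsilon = config$epsilon,
    institution_belief = config$institution_belief,
    schedule = if (sch %in% c("single", "split", "gradual")) sch
               else list(levels = config$schedule$level),
    graph = unclass(config$graph)[!vapply(unclass(config$graph), is.null, TRUE)],
    contagion = unclass(config$contagion),
    replicates = config$replicates, seed = config$seed,
    retry_policy = config$retry_policy,
    proportional_frozen = config$proportional_frozen,
    record_events = config$record_events)
  yaml::write_yaml(lst, path)
  invisible(config)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  space <- belief_space(lst$belief_resolution %||% 7L)
  schedule <- lst$schedule
  if (is.list(schedule)) {
    schedule <- schedule_custom(unlist(schedule$levels), space)
  }
  graph <- do.call(graph_spec, lst$graph %||% list())
  contagion <- do.call(contagion_spec, lst$contagion %||% list("simple"))
  args <- lst[setdiff(names(lst), c("graph", "contagion", "schedule",
                                    "belief_resolution"))]
  do.call(simulation_config,
          c(args, list(graph = graph, contagion = contagion,
                       schedule = schedule,
                       belief_resolution = space$resolution)))
}
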