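#' @title Cascade engine internals
#' @description
#' One message cascade: breadth-first delivery waves starting from the
#' institution's subscribers. Deliveries in a wave are evaluated
#' synchronously against wave-start beliefs; adoptions are applied between
#' waves, and the random stream is consumed in delivery order (senders in
#' ascending id, neighbors in adjacency order), so runs are bit-reproducible
#' under a seed. An agent believes (and hence shares) a given message at
#' most once; under the default `"once"` retry policy it also gets at most
#' one adoption trial per message.
#' @noRd
cascade_message <- function(adj, beliefs, content, seeds, spec,
                            retry = "once", prop_frozen = FALSE,
                            record_events = FALSE, uid = 1L, t = 1L) {
  n <- length(beliefs)
  done <- logical(n)
  tried <- logical(n)
  b_ref <- beliefs  # proportional: frozen snapshot at injection
  ev_send <- ev_recv <- ev_out <- list()
  k <- 0L
  log_ev <- function(send, recv, out) {
    if (record_events && length(recv)) {
      k <<- k + 1L
      ev_send[[k]] <<- send; ev_recv[[k]] <<- recv
      ev_out[[k]] <<- rep(out, length(recv))
    }
  }
  send <- rep(0L, length(seeds))  # 0 = the institution
  recv <- as.integer(seeds)
  n_believed <- 0L
  while (length(recv)) {
    keep <- !done[recv]
    if (retry == "once") keep <- keep & !tried[recv]
    log_ev(send[!keep], recv[!keep], "ignored-duplicate")
    recv <- recv[keep]; send <- send[keep]
    if (retry == "once" && length(recv)) {
      first <- !duplicated(recv)
      log_ev(send[!first], recv[!first], "ignored-duplicate")
      recv <- recv[first]; send <- send[first]
    }
    if (!length(recv)) break
    pr <- switch(spec$variant,
      simple = rep(spec$p, length(recv)),
      proportional = {
        bb <- if (prop_frozen) b_ref else beliefs
        ur <- unique(recv)
        fr <- vapply(ur, function(i) {
          nb <- adj[[i]]
          if (!length(nb)) 0 else mean(bb[nb] == content)
        }, numeric(1))
        as.numeric(fr[match(recv, ur)] >= spec$ratio_alpha)
      },
      beta_at_distance(spec, abs(beliefs[recv] - content)))
    succ <- runif(length(recv)) < pr
    tried[recv] <- TRUE
    if (record_events) {
      first_succ <- succ & !duplicated(ifelse(succ, recv, NA_integer_))
      log_ev(send[first_succ], recv[first_succ], "believed")
      log_ev(send[succ & !first_succ], recv[succ & !first_succ],
             "ignored-duplicate")
      log_ev(send[!succ], recv[!succ], "rejected")
    }
    adopters <- sort(unique(recv[succ]))
    if (!length(adopters)) break
    beliefs[adopters] <- content
    done[adopters] <- TRUE
    n_believed <- n_believed + length(adopters)
    send <- rep(adopters, lengths(adj[adopters]))
    recv <- unlist(adj[adopters], use.names = FALSE)
  }
  events <- NULL
  if (record_events) {
    events <- tibble::tibble(
      t = t, uid = uid,
      sender = unlist(ev_send, use.names = FALSE) %||% integer(0),
      receiver = unlist(ev_recv, use.names = FALSE) %||% integer(0),
      outcome = unlist(ev_out, use.names = FALSE) %||% character(0))
  }
  list(beliefs = beliefs, n_believed = n_believed, events = events)
}

# igraph -> plain adjacency list of integer neighbor ids
adjacency_list <- function(graph) {
  lapply(igraph::adjacent_vertices(graph, igraph::V(graph)), as.integer)
}

#' Propagate a single message through a graph
#'
#' Runs one within-timestep cascade: the message (a belief level) is
#' delivered to the seed agents, each delivery triggers an adoption trial
#' under `spec`, believers jump to the message's level and share it with all
#' their neighbors, and the cascade runs to exhaustion. Believe-once
#' semantics: an agent believes and shares a given message at most once.
#'
#' @param graph An igraph object with a `belief` vertex attribute.
#' @param content The belief level the message encodes.
#' @param seeds Integer vector of initial receiver ids (e.g. an
#'   institution's subscribers).
#' @param spec A [contagion_spec()].
#' @param retry_policy,proportional_frozen,record_events See
#'   [simulation_config()].
#' @return A list with `graph` (beliefs updated), `n_believed`, and
#'   `events` (a tibble `t, uid, sender, receiver, outcome` when
#'   `record_events = TRUE`; sender 0 denotes the institution).
#' @examples
#' g <- assign_beliefs_uniform(graph_er(50, 0.2))
#' out <- propagate_message(g, 6, seeds = 1:5, contagion_preset("dcc"))
#' @export
propagate_message <- function(graph, content, seeds, spec,
                              retry_policy = "once",
                              proportional_frozen = FALSE,
                              record_events = TRUE) {
  b <- graph_beliefs(graph)
  res <- cascade_message(adjacency_list(graph), b, as.integer(content),
                         seeds, spec, retry_policy, proportional_frozen,
                         record_events)
  list(graph = igraph::set_vertex_attr(graph, "belief", value = res$beliefs),
       n_believed = res$n_believed, events = res$events)
}

#' Run one public-opinion-diffusion simulation
#'
#' Builds the graph, assigns uniform initial beliefs, wires the institution's
#' subscribers, then iterates timesteps `1..T`: at each step the institution
#' broadcasts its scheduled message(s) to all subscribers (minting a fresh
#' message uid per broadcast), each message cascades to exhaustion within
#' the timestep, and the belief histogram is recorded. The `t = 0` row holds
#' the pre-broadcast initial state. Fully deterministic given
#' `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param graph Optionally, a pre-built belief-annotated igraph to run on
#'   (e.g. from [make_fixture()] or [read_belief_graphml()]); the
#'   configured graph family is then ignored.
#' @return An object of class `pod_run`: a list with `timeseries` (tibble
#'   `t, level, count, fraction`, with `t` from 0 to `T`), `config`, `seed`,
#'   `n_subscribers`, `initial_beliefs`, `final_beliefs`, and `events`
#'   (`NULL` unless `config$record_events`).
#' @examples
#' run <- run_simulation(simulation_config(n_agents = 100, horizon = 20,
#'                                         seed = 1))
#' head(tidy(run))
#' @export
run_simulation <- function(config, graph = NULL) {
  stopifnot(inherits(config, "pod_config"))
  set.seed(config$seed)
  if (is.null(graph)) {
    graph <- build_graph(config$graph, config$n_agents, config$space)
  }
  n <- igraph::vcount(graph)
  beliefs <- graph_beliefs(graph)
  R <- config$space$resolution
  inst <- institution(config$institution_belief, config$schedule)
  inst <- wire_subscribers(inst, graph, config$epsilon)
  adj <- adjacency_list(graph)
  Tn <- config$horizon
  hist <- matrix(0L, Tn + 1L, R)
  hist[1L, ] <- tabulate(beliefs + 1L, R)
  initial_beliefs <- beliefs
  uid <- 0L
  events <- if (config$record_events) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    lv <- schedule_at(config$schedule, t)
    ev_t <- list()
    for (content in lv) {
      uid <- uid + 1L
      res <- cascade_message(adj, beliefs, content, inst$subscribers,
                             config$contagion, config$retry_policy,
                             config$proportional_frozen,
                             config$record_events, uid = uid, t = t)
      beliefs <- res$beliefs
      if (config$record_events) ev_t[[length(ev_t) + 1L]] <- res$events
    }
    if (config$record_events) events[[t]] <- dplyr::bind_rows(ev_t)
    hist[t + 1L, ] <- tabulate(beliefs + 1L, R)
  }
  ts <- tibble::tibble(
    t = rep(0:Tn, each = R),
    level = rep.int(config$space$levels, Tn + 1L),
    count = as.integer(t(hist)))
  ts$fraction <- ts$count / n
  structure(
    list(timeseries = ts, config = config, seed = config$seed,
         n_subscribers = length(inst$subscribers),
         initial_beliefs = initial_beliefs, final_beliefs = beliefs,
         events = if (config$record_events) dplyr::bind_rows(events)),
    class = "pod_run")
}

#' Run a batch of replicate simulations
#'
#' Replicate `r` runs with seed `config$seed + r`, so adding replicates
#' never perturbs earlier ones. Results are averaged across replicates.
#'
#' @param config A [simulation_config()].
#' @param replicates Number of replicates; defaults to `config$replicates`.
#' @return An object of class `pod_batch`: a list with `summary` (tibble
#'   `t, level, mean_count, mean_fraction, var_fraction`), `timeseries`
#'   (per-replicate long tibble with a `replicate` column), `config`, and
#'   `seeds`.
#' @examples
#' b <- run_batch(simulation_config(n_agents = 100, horizon = 20, seed = 1,
#'                                  replicates = 2))
#' @export
run_batch <- function(config, replicates = config$replicates) {
  stopifnot(replicates >= 1)
  seeds <- config$seed + seq_len(replicates)
  runs <- purrr::map(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    run_simulation(cfg)
  })
  ts <- purrr::imap(runs, function(r, i) {
    dplyr::mutate(r$timeseries, replicate = as.integer(i), .before = 1)
  })
  ts <- dplyr::bind_rows(ts)
  summary <- ts |>
    dplyr::group_by(.data$t, .data$level) |>
    dplyr::summarise(
      mean_count = mean(.data$count),
      mean_fraction = mean(.data$fraction),
      var_fraction = if (dplyr::n() > 1) var(.data$fraction) else 0,
      .groups = "drop")
  structure(list(summary = summary, timeseries = ts, config = config,
                 seeds = seeds),
            class = "pod_batch")
}

#' @export
print.pod_run <- function(x, ...) {
  cat("<pod_run> N =", length(x$final_beliefs),
      "| T =", max(x$timeseries$t), "| seed =", x$seed,
      "| subscribers =", x$n_subscribers, "\n")
  fin <- dplyr::filter(x$timeseries, .data$t == max(.data$t))
  cat("final histogram:", paste0(fin$level, ":", fin$count, collapse = " "),
      "\n")
  invisible(x)
}

#' @export
print.pod_batch <- function(x, ...) {
  cat("<pod_batch>", length(x$seeds), "replicates | graph:",
      x$config$graph$family, "| contagion:", x$config$contagion$variant,
      "| schedule:", attr(x$config$schedule, "schedule_name"), "\n")
  invisible(x)
}
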