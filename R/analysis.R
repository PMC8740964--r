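#' Probability that a message survives a path of agents
#'
#' A message cascading from an institution reaches an agent only if every
#' agent along the way believes it; under a pairwise cognitive rule the
#' path's transmission probability is the product, over the agents on the
#' path, of the single-exposure adoption probability at the distance between
#' that agent's belief and the message's level. Any agent at distance >= 3
#' from the message (under DCC) collapses the whole product toward zero.
#'
#' @param spec A cognitive [contagion_spec()] (linear, threshold or sigmoid).
#' @param path_beliefs Ordered belief levels of the agents on the path
#'   (excluding the institution). An empty path has probability 1.
#' @param message_level The belief level encoded by the message.
#' @return A probability.
#' @examples
#' path_probability(contagion_preset("dcc"), c(5, 5), 6)
#' @export
path_probability <- function(spec, path_beliefs, message_level) {
  if (!length(path_beliefs)) return(1)
  prod(beta_at_distance(spec, abs(path_beliefs - message_level)))
}

# Directed arc view for max-product path search: arc (x -> y) costs
# -log beta(|b_y - message|); the institution is an extra vertex with arcs
# to its subscribers. Returns list(graph, weights, inst_vertex).
neglog_arc_graph <- function(graph, inst, message_level, spec) {
  b <- graph_beliefs(graph)
  n <- igraph::vcount(graph)
  dg <- igraph::as_directed(graph, mode = "mutual")
  nodecost <- -log(beta_at_distance(spec, abs(b - message_level)))
  w <- nodecost[igraph::head_of(dg, igraph::E(dg))]
  dg <- igraph::add_vertices(dg, 1)
  iv <- n + 1L
  if (length(inst$subscribers)) {
    dg <- igraph::add_edges(dg, rbind(iv, inst$subscribers))
    w <- c(w, nodecost[inst$subscribers])
  }
  list(graph = dg, weights = w, inst = iv)
}

#' Neighbors of an agent likely to relay a message
#'
#' For each graph neighbor `v` of the target agent, finds the
#' maximum-probability path from the institution to `v` (a shortest-path
#' search under negative-log adoption probabilities) and keeps `v` if that
#' probability is at least `1 - delta`. These are the neighbors through whom
#' the message can plausibly reach the target.
#'
#' @param graph An igraph object with beliefs assigned.
#' @param inst A wired [institution()].
#' @param target Target agent id.
#' @param message_level Belief level of the message.
#' @param delta Credibility bound in `[0, 1]`; larger admits less likely
#'   relays.
#' @param spec A cognitive [contagion_spec()].
#' @return Integer vector of neighbor ids (possibly empty); unreachable
#'   neighbors are excluded.
#' @export
believing_neighbor_set <- function(graph, inst, target, message_level,
                                   delta, spec) {
  nb <- as.integer(igraph::neighbors(graph, target))
  nb <- setdiff(nb, target)
  if (!length(nb)) return(integer(0))
  al <- neglog_arc_graph(graph, inst, message_level, spec)
  d <- suppressWarnings(igraph::distances(al$graph, v = al$inst, to = nb,
                                          weights = al$weights,
                                          mode = "out"))
  p <- exp(-as.numeric(d))
  sort(nb[p >= 1 - delta])
}

#' Existence of a tau-bounded institution-to-neighbor path
#'
#' Tests whether some path leads from the institution to a *neighbor* of the
#' target agent with every agent on the path (the target itself excluded)
#' within belief distance `tau` of the message. Realized exactly as
#' reachability on the subgraph induced by the agents satisfying the bound:
#' a qualifying path exists iff a neighbor of the target within the bound
#' lies in the same induced component as a subscriber within the bound.
#'
#' @inheritParams believing_neighbor_set
#' @param tau Belief-distance bound for agents on the path.
#' @return Logical scalar.
#' @export
qualifying_path_exists <- function(graph, inst, target, message_level, tau) {
  b <- graph_beliefs(graph)
  ok <- which(abs(b - message_level) <= tau)
  ok <- setdiff(ok, target)
  subs <- intersect(inst$subscribers, ok)
  nb <- intersect(as.integer(igraph::neighbors(graph, target)), ok)
  if (!length(subs) || !length(nb)) return(FALSE)
  if (length(intersect(subs, nb))) return(TRUE)
  sg <- igraph::induced_subgraph(graph, ok)
  comp <- igraph::components(sg)$membership
  map <- match(c(subs, nb), ok)
  any(comp[map[seq_along(subs)]] %in%
        comp[map[length(subs) + seq_along(nb)]])
}

# The min-sum heuristic used historically for this census: Dijkstra from the
# institution to the target with arc weights |b(entered agent) - message|,
# then check the tau bound on the single returned path (target excluded).
dijkstra_path_qualifies <- function(graph, inst, target, message_level, tau) {
  b <- graph_beliefs(graph)
  n <- igraph::vcount(graph)
  dg <- igraph::as_directed(graph, mode = "mutual")
  nodecost <- abs(b - message_level)
  w <- nodecost[igraph::head_of(dg, igraph::E(dg))]
  dg <- igraph::add_vertices(dg, 1)
  iv <- n + 1L
  if (!length(inst$subscribers)) return(FALSE)
  dg <- igraph::add_edges(dg, rbind(iv, inst$subscribers))
  w <- c(w, nodecost[inst$subscribers])
  sp <- suppressWarnings(igraph::shortest_paths(dg, from = iv, to = target,
                                                weights = w,
                                                output = "vpath"))
  vp <- as.integer(sp$vpath[[1]])
  if (length(vp) < 2) return(FALSE)
  mid <- setdiff(vp, c(iv, target))
  all(abs(b[mid] - message_level) <= tau)
}

#' Qualifying-path census over a graph ensemble
#'
#' Generates `n_graphs` fresh graphs (new topology and beliefs each), in
#' each picks one uniformly random agent at `target_level`, and reports the
#' fraction of graphs in which a tau-bounded path from the institution to a
#' neighbor of that agent exists. Graphs with no agent at the target level
#' are regenerated (with a message). `method = "reachability"` (default)
#' answers the existence question exactly; `method = "dijkstra"` reproduces
#' the min-sum shortest-path heuristic, which can miss qualifying paths.
#'
#' @param graph A [graph_spec()].
#' @param tau Belief-distance bound.
#' @param target_level Belief level of the sampled target agent.
#' @param message_level Message belief level; the institution's perceived
#'   belief (subscribers are wired at `epsilon`).
#' @param n_graphs Ensemble size.
#' @param n_agents Agents per graph.
#' @param epsilon Subscriber wiring bound.
#' @param space A [belief_space()].
#' @param method `"reachability"` or `"dijkstra"`.
#' @return A one-row tibble: `family, tau, target_level, message_level,
#'   proportion, n_graphs`.
#' @examples
#' path_census(graph_spec("ER"), tau = 1, target_level = 0, n_graphs = 10,
#'             n_agents = 100)
#' @export
path_census <- function(graph, tau, target_level,
                        message_level = space$resolution - 1L,
                        n_graphs = 100L, n_agents = 500L, epsilon = 0,
                        space = belief_space(),
                        method = c("reachability", "dijkstra")) {
  method <- match.arg(method)
  stopifnot(inherits(graph, "graph_spec"), n_graphs >= 1,
            tau >= 0, tau <= space$resolution - 1L)
  target_level <- check_levels(target_level, space, "target_level")
  message_level <- check_levels(message_level, space, "message_level")
  hits <- logical(n_graphs)
  sched <- schedule_single(1L, message_level, space)
  for (i in seq_len(n_graphs)) {
    repeat {
      g <- build_graph(graph, n_agents, space)
      cand <- which(graph_beliefs(g) == target_level)
      if (length(cand)) break
      message("regenerating graph with no agent at level ", target_level)
    }
    u <- if (length(cand) == 1L) cand else sample(cand, 1L)
    inst <- suppressWarnings(
      wire_subscribers(institution(message_level, sched), g, epsilon))
    hits[i] <- if (method == "reachability") {
      qualifying_path_exists(g, inst, u, message_level, tau)
    } else {
      dijkstra_path_qualifies(g, inst, u, message_level, tau)
    }
  }
  tibble::tibble(family = graph$family, tau = tau,
                 target_level = target_level,
                 message_level = message_level,
                 proportion = mean(hits), n_graphs = as.integer(n_graphs))
}

#' Full census grid over families, bounds and target levels
#'
#' @param families Character vector of graph families.
#' @param taus Integer vector of distance bounds.
#' @param target_levels Integer vector of target belief levels.
#' @inheritParams path_census
#' @return A tibble with one row per (family, tau, target level) cell.
#' @export
census_grid <- function(families = c("ER", "WS", "BA", "MAG"),
                        taus = c(1L, 2L),
                        target_levels = belief_space()$levels,
                        message_level = space$resolution - 1L,
                        n_graphs = 100L, n_agents = 500L,
                        space = belief_space(),
                        method = c("reachability", "dijkstra")) {
  method <- match.arg(method)
  grid <- tidyr::expand_grid(family = families, tau = taus,
                             target_level = target_levels)
  purrr::pmap(grid, function(family, tau, target_level) {
    path_census(graph_spec(family), tau, target_level, message_level,
                n_graphs, n_agents, space = space, method = method)
  }) |> dplyr::bind_rows()
}

# Pull a per-level fraction (or count) matrix, timesteps x levels, from a
# timeseries tibble with columns t, level and `value_col`.
ts_matrix <- function(ts, value_col) {
  wide <- ts |>
    dplyr::select(dplyr::all_of(c("t", "level", value_col))) |>
    dplyr::arrange(.data$t, .data$level) |>
    tidyr::pivot_wider(names_from = "level",
                       values_from = dplyr::all_of(value_col))
  as.matrix(wide[, -1, drop = FALSE])
}

#' Average Pearson correlation across belief levels
#'
#' For each belief level, correlates the two fraction-believing timeseries;
#' levels whose series is constant in either input carry no signal and are
#' excluded. Returns the mean of the remaining coefficients, or `NA` if all
#' levels are excluded (no changes occurred from initial conditions in at
#' least one input).
#'
#' @param ts_a,ts_b Timeseries tibbles with columns `t`, `level` and a
#'   fraction column — a `pod_run$timeseries` (`fraction`) or a
#'   `pod_batch$summary` (`mean_fraction`). Both inputs must share horizon
#'   and belief space.
#' @return A scalar in `[-1, 1]`, or `NA`.
#' @examples
#' b <- run_batch(simulation_config(n_agents = 80, horizon = 15, seed = 1,
#'                                  replicates = 2))
#' avg_pearson(b$summary, b$summary)
#' @export
avg_pearson <- function(ts_a, ts_b) {
  col_a <- intersect(c("mean_fraction", "fraction"), names(ts_a))[1]
  col_b <- intersect(c("mean_fraction", "fraction"), names(ts_b))[1]
  if (is.na(col_a) || is.na(col_b)) {
    abort("inputs need a `fraction` or `mean_fraction` column.")
  }
  A <- ts_matrix(ts_a, col_a)
  B <- ts_matrix(ts_b, col_b)
  if (!identical(dim(A), dim(B))) {
    abort("timeseries have mismatched horizons or belief spaces.")
  }
  rs <- vapply(seq_len(ncol(A)), function(j) {
    if (stats::sd(A[, j]) == 0 || stats::sd(B[, j]) == 0) NA_real_
    else cor(A[, j], B[, j])
  }, numeric(1))
  if (all(is.na(rs))) NA_real_ else mean(rs, na.rm = TRUE)
}

#' Timestep-wise chi-squared similarity of two belief timeseries
#'
#' At each timestep, a two-sample chi-squared homogeneity test compares the
#' per-level agent counts of the two runs; the statistic returned is the
#' fraction of timesteps at which the test does *not* reject at the given
#' significance level. 1 means the belief distributions are
#' indistinguishable at every step; 0 means they differ at every step.
#' Levels with zero counts in both runs at a timestep are dropped from that
#' step's table (standard small-expected-count handling).
#'
#' @param ts_a,ts_b Timeseries tibbles with columns `t`, `level` and a count
#'   column (`count` or `mean_count`).
#' @param significance Rejection level (default 0.05).
#' @return A scalar in `[0, 1]`.
#' @export
chi2_timeseries <- function(ts_a, ts_b, significance = 0.05) {
  col_a <- intersect(c("mean_count", "count"), names(ts_a))[1]
  col_b <- intersect(c("mean_count", "count"), names(ts_b))[1]
  if (is.na(col_a) || is.na(col_b)) {
    abort("inputs need a `count` or `mean_count` column.")
  }
  A <- ts_matrix(ts_a, col_a)
  B <- ts_matrix(ts_b, col_b)
  if (!identical(dim(A), dim(B))) {
    abort("timeseries have mismatched horizons or belief spaces.")
  }
  keep_ok <- vapply(seq_len(nrow(A)), function(i) {
    tab <- rbind(A[i, ], B[i, ])
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2) return(TRUE)  # identical degenerate distributions
    p <- suppressWarnings(chisq.test(tab)$p.value)
    is.na(p) || p >= significance
  }, logical(1))
  mean(keep_ok)
}

#' Homophily over a graph ensemble
#'
#' Generates `n_graphs` graphs from the specification (fresh uniform
#' beliefs each) and summarizes their [homophily_score()]s.
#'
#' @param graph A [graph_spec()].
#' @param n_graphs Ensemble size (>= 2).
#' @param n_agents Agents per graph.
#' @param space A [belief_space()].
#' @return A one-row tibble: `family, n_graphs, mean, var`.
#' @examples
#' summarize_homophily(graph_spec("ER"), n_graphs = 3, n_agents = 100)
#' @export
summarize_homophily <- function(graph, n_graphs = 10L, n_agents = 500L,
                                space = belief_space()) {
  stopifnot(n_graphs >= 2)
  scores <- vapply(seq_len(n_graphs), function(i) {
    homophily_score(build_graph(graph, n_agents, space))
  }, numeric(1))
  tibble::tibble(family = graph$family, n_graphs = as.integer(n_graphs),
                 mean = mean(scores), var = var(scores))
}
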