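#' Random social-graph generators
#'
#' Agents live on an undirected simple graph; institutions are kept outside
#' the graph and connect to their subscribers by directed broadcast links
#' (see [institution()]). Four families are supported, all returning an
#' igraph object whose vertices are agents `1..n`:
#'
#' * `graph_er(n, rho)`: Erdos-Renyi `G(n, rho)` — every unordered pair is an
#'   edge independently with probability `rho`.
#' * `graph_ws(n, k, rho)`: Watts-Strogatz small world — ring lattice with
#'   `k` initial neighbors per node (realized as `floor(k/2)` on each side),
#'   each edge rewired with probability `rho`; rewiring preserves the edge
#'   count.
#' * `graph_ba(n, m)`: Barabasi-Albert preferential attachment, `m` edges per
#'   newly added node.
#' * `graph_mag(n, affinity, beliefs)`: multiplicative attribute graph over a
#'   single belief attribute — pair `(u, v)` is an edge independently with
#'   probability `affinity[b_u, b_v]`.
#'
#' Generators consume R's current random stream, so fixing the seed makes
#' edge sets bit-identical.
#'
#' @param n Number of agents (>= 2).
#' @param rho Edge probability (ER) or rewiring chance (WS), in `[0, 1]`.
#' @param k WS initial neighbor count (`k < n`).
#' @param m BA edges per new node (`1 <= m < n`).
#' @param affinity An `R x R` affinity matrix, e.g. [default_affinity()].
#' @param beliefs Integer vector of per-agent belief levels (length `n`),
#'   assigned before edges since MAG edge probabilities depend on them.
#' @return An igraph object; `graph_mag()` also stores `beliefs` in the
#'   `belief` vertex attribute.
#' @examples
#' g <- graph_er(100, 0.05)
#' @name graph_generators
NULL

#' @rdname graph_generators
#' @export
graph_er <- function(n, rho) {
  stopifnot(n >= 2, rho >= 0, rho <= 1)
  igraph::sample_gnp(n, rho)
}

#' @rdname graph_generators
#' @export
graph_ws <- function(n, k, rho) {
  if (k >= n) abort("`k` must be smaller than `n`.")
  stopifnot(rho >= 0, rho <= 1)
  igraph::sample_smallworld(dim = 1, size = n, nei = max(1L, k %/% 2L), p = rho)
}

#' @rdname graph_generators
#' @export
graph_ba <- function(n, m) {
  if (m >= n || m < 1) abort("`m` must satisfy 1 <= m < n.")
  igraph::sample_pa(n, m = m, directed = FALSE)
}

#' @rdname graph_generators
#' @export
graph_mag <- function(n, affinity, beliefs) {
  stopifnot(n >= 2, length(beliefs) == n)
  R <- nrow(affinity)
  if (any(beliefs < 0) || any(beliefs > R - 1)) {
    abort("`beliefs` exceed the affinity matrix's belief range.")
  }
  idx <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
  p <- affinity[cbind(beliefs[idx[, 1]] + 1L, beliefs[idx[, 2]] + 1L)]
  sel <- runif(nrow(idx)) < p
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(idx[sel, , drop = FALSE]))
  igraph::set_vertex_attr(g, "belief", value = as.integer(beliefs))
}

#' Homophilic belief-affinity matrix
#'
#' The edge-probability kernel used for the multiplicative attribute graph:
#' `theta_ij = 1 / (6 + 50 * (j - i)^2)`, a sharply decaying function of
#' belief distance (0.167 on the diagonal down to 0.0006 at distance 6) that
#' yields graphs with very high homophily — agents at the same belief level
#' connect at roughly ER density while distant levels are nearly siloed.
#'
#' @param space A [belief_space()].
#' @return A symmetric `R x R` matrix with entries in `(0, 1]`.
#' @examples
#' round(default_affinity(), 4)
#' @export
default_affinity <- function(space = belief_space()) {
  lv <- space$levels
  1 / (6 + 50 * outer(lv, lv, function(i, j) (j - i)^2))
}

#' Assign uniform beliefs to a graph's agents
#'
#' Each agent's initial belief is drawn i.i.d. uniform over the belief
#' levels, stored in the `belief` vertex attribute.
#'
#' @param graph An igraph object.
#' @param space A [belief_space()].
#' @return The graph with a `belief` vertex attribute.
#' @export
assign_beliefs_uniform <- function(graph, space = belief_space()) {
  n <- igraph::vcount(graph)
  igraph::set_vertex_attr(graph, "belief",
                          value = sample(space$levels, n, replace = TRUE))
}

# Beliefs of all agents, as an integer vector; errors if unassigned.
graph_beliefs <- function(graph) {
  b <- igraph::vertex_attr(graph, "belief")
  if (is.null(b)) abort("graph has no `belief` vertex attribute; assign beliefs first.")
  as.integer(b)
}

#' Institutional broadcaster agents
#'
#' An institution is a media-like agent with a perceived belief level that
#' broadcasts scheduled messages to its subscribers. [wire_subscribers()]
#' freezes the subscriber set: every agent whose belief lies within
#' `epsilon` of the institution's perceived belief subscribes (with the
#' default `epsilon = 0`, exactly the agents sharing the institution's
#' belief).
#'
#' @param belief The institution's perceived belief level.
#' @param schedule A `pod_schedule` (see [schedules]).
#' @param id Institution identifier.
#' @return An object of class `institution`.
#' @examples
#' inst <- institution(6, schedule_single(100, 6))
#' @export
institution <- function(belief, schedule, id = "i1") {
  stopifnot(inherits(schedule, "pod_schedule"))
  structure(list(id = id, belief = as.integer(belief), schedule = schedule,
                 subscribers = integer(0)),
            class = "institution")
}

#' @rdname institution
#' @param graph An igraph object with beliefs assigned.
#' @param inst An `institution`.
#' @param epsilon Maximum belief distance for subscription (>= 0).
#' @export
wire_subscribers <- function(inst, graph, epsilon = 0) {
  stopifnot(inherits(inst, "institution"), epsilon >= 0)
  b <- graph_beliefs(graph)
  inst$subscribers <- which(abs(b - inst$belief) <= epsilon)
  if (!length(inst$subscribers)) {
    warn(sprintf("institution %s has no subscribers; its cascades are inert.",
                 inst$id))
  }
  inst
}

#' Global homophily score of a belief-annotated graph
#'
#' The mean absolute belief difference `|b_u - b_v|` over all adjacent pairs
#' (equivalently over directed adjacent pairs, since the distance is
#' symmetric). Lower values mean like-believing agents cluster; 0 means all
#' neighbors agree. For an ER graph with beliefs uniform on a 7-level scale
#' the expected score is `E|X - Y| = 112/49` (about 2.29), while the default
#' MAG affinity drives it down to about 0.3.
#'
#' @param graph An igraph object with beliefs assigned and at least one edge.
#' @return A nonnegative scalar.
#' @export
homophily_score <- function(graph) {
  if (igraph::ecount(graph) == 0) {
    abort("homophily score is undefined on an edgeless graph.")
  }
  b <- graph_beliefs(graph)
  e <- igraph::as_edgelist(graph, names = FALSE)
  mean(abs(b[e[, 1]] - b[e[, 2]]))
}

#' Build a graph (plus beliefs) from a graph specification
#'
#' A `graph_spec` bundles a family name and its parameters so that
#' configurations are fully serializable. `build_graph()` realizes it:
#' generates the topology, assigns uniform beliefs (except MAG, whose
#' edges already depend on the beliefs drawn first), or loads a
#' belief-annotated graph from file for `family = "file"`.
#'
#' @param family One of `"ER"`, `"WS"`, `"BA"`, `"MAG"`, `"file"`.
#' @param er_rho,ws_k,ws_rho,ba_m Family parameters (defaults: the study
#'   conditions `rho = 0.05`, `k = 5`, `rho = 0.5`, `m = 3`).
#' @param path Input file for `family = "file"` (GraphML, see
#'   [read_belief_graphml()]).
#' @return `graph_spec()` returns a `graph_spec` object; `build_graph()`
#'   returns an igraph object with a `belief` vertex attribute.
#' @examples
#' g <- build_graph(graph_spec("ER"), n = 100, space = belief_space())
#' @export
graph_spec <- function(family = c("ER", "WS", "BA", "MAG", "file"),
                       er_rho = 0.05, ws_k = 5L, ws_rho = 0.5, ba_m = 3L,
                       path = NULL) {
  family <- match.arg(family)
  if (family == "file" && is.null(path)) abort("family 'file' needs `path`.")
  structure(list(family = family, er_rho = er_rho, ws_k = as.integer(ws_k),
                 ws_rho = ws_rho, ba_m = as.integer(ba_m), path = path),
            class = "graph_spec")
}

#' @rdname graph_spec
#' @param spec A `graph_spec`.
#' @param n Number of agents.
#' @param space A [belief_space()].
#' @export
build_graph <- function(spec, n, space = belief_space()) {
  stopifnot(inherits(spec, "graph_spec"))
  switch(spec$family,
    ER = assign_beliefs_uniform(graph_er(n, spec$er_rho), space),
    WS = assign_beliefs_uniform(graph_ws(n, spec$ws_k, spec$ws_rho), space),
    BA = assign_beliefs_uniform(graph_ba(n, spec$ba_m), space),
    MAG = {
      b <- sample(space$levels, n, replace = TRUE)
      graph_mag(n, default_affinity(space), b)
    },
    file = read_belief_graphml(spec$path)
  )
}

#' Read/write belief-annotated graphs
#'
#' GraphML IO keeps the integer `belief` node attribute; the edge-list
#' format uses two CSV files, `<stem>_edges.csv` (`src,dst`) and
#' `<stem>_nodes.csv` (`id,belief`), with 0-based agent ids.
#'
#' @param graph An igraph object with beliefs assigned.
#' @param path GraphML file path.
#' @param stem Path stem for the edge-list pair.
#' @return Readers return an igraph object; writers return the graph
#'   invisibly.
#' @export
write_belief_graphml <- function(graph, path) {
  graph_beliefs(graph)  # validate presence
  igraph::write_graph(graph, path, format = "graphml")
  invisible(graph)
}

#' @rdname write_belief_graphml
#' @export
read_belief_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  g <- igraph::set_vertex_attr(g, "belief",
                               value = as.integer(igraph::vertex_attr(g, "belief")))
  g
}

#' @rdname write_belief_graphml
#' @export
write_belief_edgelist <- function(graph, stem) {
  b <- graph_beliefs(graph)
  e <- igraph::as_edgelist(graph, names = FALSE)
  readr::write_csv(tibble::tibble(src = e[, 1] - 1L, dst = e[, 2] - 1L),
                   paste0(stem, "_edges.csv"))
  readr::write_csv(tibble::tibble(id = seq_along(b) - 1L, belief = b),
                   paste0(stem, "_nodes.csv"))
  invisible(graph)
}

#' @rdname write_belief_graphml
#' @export
read_belief_edgelist <- function(stem) {
  nodes <- readr::read_csv(paste0(stem, "_nodes.csv"),
                           col_types = readr::cols(id = readr::col_integer(),
                                                   belief = readr::col_integer()))
  edges <- readr::read_csv(paste0(stem, "_edges.csv"),
                           col_types = readr::cols(src = readr::col_integer(),
                                                   dst = readr::col_integer()))
  nodes <- dplyr::arrange(nodes, .data$id)
  g <- igraph::make_empty_graph(nrow(nodes), directed = FALSE)
  g <- igraph::add_edges(g, rbind(edges$src + 1L, edges$dst + 1L))
  igraph::set_vertex_attr(g, "belief", value = nodes$belief)
}
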