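#' Deterministic toy graphs for tests and demonstrations
#'
#' Small hand-built belief-annotated graphs:
#'
#' * `"fig2-toy"`: an 10-agent network in which an institution at the top
#'   belief level has three subscribers, each with further neighbors at
#'   varied beliefs — the minimal setting in which multi-hop cascades,
#'   believe-once semantics and duplicate deliveries all occur.
#' * `"line-chain"`: a 7-agent path with beliefs 6,5,4,3,2,1,0 in order;
#'   the canonical fixture for path-probability and tau-bounded path tests.
#' * `"two-cluster"`: two complete 5-agent clusters (all at the top and all
#'   at the bottom level) bridged by a single edge — a maximally homophilic
#'   silo graph.
#'
#' @param name One of `"fig2-toy"`, `"line-chain"`, `"two-cluster"`.
#' @return An igraph object with a `belief` vertex attribute. The intended
#'   institution belief is stored in the `institution_belief` graph
#'   attribute.
#' @examples
#' g <- make_fixture("line-chain")
#' igraph::vertex_attr(g, "belief")
#' @export
make_fixture <- function(name = c("fig2-toy", "line-chain", "two-cluster")) {
  name <- match.arg(name)
  g <- switch(name,
    "line-chain" = {
      g <- igraph::make_ring(7, circular = FALSE)
      igraph::set_vertex_attr(g, "belief", value = 6:0)
    },
    "two-cluster" = {
      g <- igraph::disjoint_union(igraph::make_full_graph(5),
                                  igraph::make_full_graph(5))
      g <- igraph::add_edges(g, c(5, 6))
      igraph::set_vertex_attr(g, "belief", value = c(rep(6L, 5), rep(0L, 5)))
    },
    "fig2-toy" = {
      # agents 1..3 are subscribers (belief 6); 4..10 second-hop neighbors
      edges <- c(1,4, 1,5, 2,5, 2,6, 3,6, 3,7, 4,8, 5,9, 6,9, 7,10, 9,10)
      g <- igraph::make_empty_graph(10, directed = FALSE)
      g <- igraph::add_edges(g, edges)
      igraph::set_vertex_attr(
        g, "belief", value = c(6L, 6L, 6L, 5L, 5L, 4L, 3L, 5L, 4L, 2L))
    })
  igraph::set_graph_attr(g, "institution_belief", 6L)
}

#' Write a fixture to a GraphML file
#'
#' @param name Fixture name (see [make_fixture()]).
#' @param path Output file path.
#' @return The graph, invisibly.
#' @export
write_fixture <- function(name, path) {
  write_belief_graphml(make_fixture(name), path)
}
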