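# Shared helpers: independent oracles kept deliberately naive.

# Sigmoid adoption probability, written directly from the definition.
oracle_sigmoid <- function(d, alpha = 4, gamma = 2) {
  1 / (1 + exp(alpha * (d - gamma)))
}

# Max product of per-node adoption probabilities over all simple paths from
# any subscriber to `to`, by exhaustive enumeration (institution excluded
# from the product; subscribers included). Small graphs only.
oracle_max_path_prob <- function(graph, subscribers, to, message_level, spec) {
  b <- igraph::vertex_attr(graph, "belief")
  beta <- function(v) adoption_probability(spec, b[v], message_level)
  best <- 0
  for (s in subscribers) {
    if (s == to) {
      best <- max(best, beta(s))
      next
    }
    paths <- igraph::all_simple_paths(graph, from = s, to = to)
    for (p in paths) {
      best <- max(best, prod(vapply(as.integer(p), beta, numeric(1))))
    }
  }
  best
}

# Exhaustive qualifying-path check: does any simple path from a subscriber
# reach a neighbor of `target` using only agents within `tau` of the
# message (target excluded)? Small graphs only.
oracle_qualifying_path <- function(graph, subscribers, target, message_level,
                                   tau) {
  b <- igraph::vertex_attr(graph, "belief")
  ok <- function(v) abs(b[v] - message_level) <= tau && v != target
  nbrs <- as.integer(igraph::neighbors(graph, target))
  for (s in subscribers) {
    if (!ok(s)) next
    if (s %in% nbrs) return(TRUE)
    for (v in nbrs) {
      if (!ok(v)) next
      paths <- igraph::all_simple_paths(graph, from = s, to = v)
      for (p in paths) {
        if (all(vapply(as.integer(p), ok, logical(1)))) return(TRUE)
      }
    }
  }
  FALSE
}

# A wired institution at `level` on `graph` with a one-step constant schedule.
wired_institution <- function(graph, level = 6L, epsilon = 0,
                              space = belief_space()) {
  suppressWarnings(wire_subscribers(
    institution(level, schedule_single(1L, level, space)), graph, epsilon))
}
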