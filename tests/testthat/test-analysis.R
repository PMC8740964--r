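dcc <- contagion_preset("dcc")

test_that("path probability is the product of per-agent adoption terms", {
  expect_equal(path_probability(dcc, c(5, 5), 6),
               oracle_sigmoid(1)^2)
  expect_equal(path_probability(dcc, integer(0), 6), 1)
  expect_equal(path_probability(dcc, 6, 6), oracle_sigmoid(0))
  # one distant agent on the path collapses the product
  expect_lt(path_probability(dcc, c(5, 0, 5), 6), 1e-6)
  expect_equal(path_probability(dcc, c(5, 0, 5), 6),
               oracle_sigmoid(1)^2 * oracle_sigmoid(6))
  expect_equal(path_probability(contagion_preset("threshold-stubborn"),
                                c(5, 3), 6), 0)
})

test_that("believing-neighbor search matches the exhaustive max-product oracle", {
  g <- make_fixture("fig2-toy")
  inst <- wired_institution(g, 6L)
  for (target in c(9L, 10L, 8L)) {
    nb <- setdiff(as.integer(igraph::neighbors(g, target)), target)
    probs <- vapply(nb, function(v) {
      oracle_max_path_prob(g, inst$subscribers, v, 6L, dcc)
    }, numeric(1))
    for (delta in c(0.05, 0.3, 0.6, 0.999)) {
      expect_identical(
        believing_neighbor_set(g, inst, target, 6L, delta, dcc),
        sort(nb[probs >= 1 - delta]),
        info = paste("target", target, "delta", delta))
    }
  }
})

test_that("believing-neighbor search handles isolated targets and tight bounds", {
  g <- make_fixture("line-chain")
  inst <- wired_institution(g, 6L)
  # nothing passes a delta = 0 bound through a lossy chain
  expect_identical(believing_neighbor_set(g, inst, 4L, 6L, 0, dcc),
                   integer(0))
  # delta = 1 admits every reachable neighbor
  expect_identical(believing_neighbor_set(g, inst, 4L, 6L, 1, dcc),
                   c(3L, 5L))
  iso <- igraph::add_vertices(g, 1, belief = 3L)
  expect_identical(believing_neighbor_set(iso, inst, 8L, 6L, 1, dcc),
                   integer(0))
})

test_that("qualifying-path reachability matches exhaustive path enumeration", {
  set.seed(31)
  checked <- 0L
  for (i in 1:40) {
    g <- assign_beliefs_uniform(graph_er(9, 0.3))
    inst <- wired_institution(g, 6L)
    if (!length(inst$subscribers)) next
    target <- sample(setdiff(1:9, inst$subscribers), 1)
    for (tau in c(1L, 2L, 4L)) {
      expect_identical(
        qualifying_path_exists(g, inst, target, 6L, tau),
        oracle_qualifying_path(g, inst$subscribers, target, 6L, tau),
        info = paste("iter", i, "tau", tau))
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 50)
})

test_that("qualifying paths exclude the target and respect the bound", {
  g <- make_fixture("line-chain")  # beliefs 6..0 along a path
  inst <- wired_institution(g, 6L)
  # reaching a neighbor of agent 4 (belief 3) needs agent 3 (belief 4),
  # at distance 2 from the message
  expect_false(qualifying_path_exists(g, inst, 4L, 6L, 1L))
  expect_true(qualifying_path_exists(g, inst, 4L, 6L, 2L))
  # agent 2's neighborhood includes subscriber 1 directly
  expect_true(qualifying_path_exists(g, inst, 2L, 6L, 0L))
  # a disconnected target has no qualifying path at any bound
  g2 <- igraph::delete_edges(g, igraph::E(g)[3])  # cut between 3 and 4
  expect_false(qualifying_path_exists(g2, inst, 4L, 6L, 6L))
})

test_that("the census proportion is exactly monotone in tau on a fixed ensemble", {
  spec <- graph_spec("ER", er_rho = 0.05)
  props <- vapply(c(0L, 1L, 2L, 6L), function(tau) {
    set.seed(77)
    path_census(spec, tau, target_level = 0L, n_graphs = 15,
                n_agents = 80)$proportion
  }, numeric(1))
  expect_true(all(diff(props) >= 0))
  expect_true(all(props >= 0 & props <= 1))
})

test_that("census bookkeeping records the cell it measured", {
  set.seed(5)
  out <- path_census(graph_spec("WS"), tau = 2L, target_level = 3L,
                     n_graphs = 5, n_agents = 60)
  expect_identical(out$family, "WS")
  expect_identical(out$tau, 2L)
  expect_identical(out$target_level, 3L)
  expect_identical(out$message_level, 6L)
  expect_identical(out$n_graphs, 5L)
  set.seed(5)
  dij <- path_census(graph_spec("WS"), tau = 2L, target_level = 3L,
                     n_graphs = 5, n_agents = 60, method = "dijkstra")
  # the min-sum heuristic can only miss qualifying paths, never invent them
  expect_lte(dij$proportion, out$proportion)
})

test_that("census grid covers the requested cells", {
  set.seed(6)
  grid <- census_grid(families = c("ER", "BA"), taus = 1L,
                      target_levels = c(0L, 6L), n_graphs = 3,
                      n_agents = 50)
  expect_equal(nrow(grid), 4)
  expect_setequal(grid$family, c("ER", "BA"))
})

synthetic_ts <- function(mat) {
  tibble::tibble(
    t = rep(seq_len(nrow(mat)) - 1L, each = ncol(mat)),
    level = rep.int(seq_len(ncol(mat)) - 1L, nrow(mat)),
    fraction = as.numeric(t(mat)),
    count = as.integer(round(100 * t(mat))))
}

test_that("average Pearson rewards shared dynamics and drops flat levels", {
  A <- cbind(seq(0, 1, length.out = 6), seq(1, 0, length.out = 6))
  tsA <- synthetic_ts(A)
  expect_equal(avg_pearson(tsA, tsA), 1)
  # reversing time anti-correlates every level
  tsR <- synthetic_ts(A[6:1, ])
  expect_equal(avg_pearson(tsA, tsR), -1)
  # a level flat in either input is excluded, not zero-counted
  B <- cbind(A[, 1], rep(0.5, 6))
  expect_equal(avg_pearson(tsA, synthetic_ts(B)), 1)
  # all-flat inputs carry no signal
  flat <- synthetic_ts(matrix(0.5, 6, 2))
  expect_true(is.na(avg_pearson(flat, flat)))
  expect_error(avg_pearson(tsA, synthetic_ts(matrix(0.5, 4, 2))),
               "mismatched")
})

test_that("average Pearson accepts run and batch timeseries alike", {
  cfg <- simulation_config(n_agents = 80, horizon = 15, seed = 4,
                           replicates = 2)
  run <- run_simulation(cfg)
  expect_equal(avg_pearson(run$timeseries, run$timeseries), 1)
  batch <- run_batch(cfg)
  r <- avg_pearson(batch$summary, run$timeseries)
  expect_true(is.na(r) || (r >= -1 && r <= 1))
})

test_that("chi-squared similarity is one for identical runs, low for opposites", {
  counts <- function(mat) {
    out <- synthetic_ts(mat / rowSums(mat))
    out$count <- as.integer(t(mat))
    out
  }
  same <- counts(matrix(c(300, 100), 10, 2, byrow = TRUE))
  expect_equal(chi2_timeseries(same, same), 1)
  flipped <- counts(matrix(c(100, 300), 10, 2, byrow = TRUE))
  expect_equal(chi2_timeseries(same, flipped), 0)
  # zero-only levels are dropped rather than breaking the test
  degenerate <- counts(matrix(c(400, 0), 10, 2, byrow = TRUE))
  expect_equal(chi2_timeseries(degenerate, degenerate), 1)
})

test_that("homophily summaries report the ensemble mean and variance", {
  set.seed(8)
  out <- summarize_homophily(graph_spec("ER"), n_graphs = 5, n_agents = 300)
  expect_identical(out$family, "ER")
  expect_lt(abs(out$mean - 112 / 49), 0.1)
  expect_gte(out$var, 0)
  expect_error(summarize_homophily(graph_spec("ER"), n_graphs = 1), "n_graphs")
})
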