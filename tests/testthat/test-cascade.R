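dcc <- contagion_preset("dcc")

test_that("certain adoption percolates exactly to the reachable set", {
  certain <- contagion_spec("simple", p = 1)
  set.seed(21)
  for (i in 1:5) {
    g <- assign_beliefs_uniform(graph_er(60, 0.03))
    seeds <- sample(60, 3)
    out <- propagate_message(g, 6, seeds, certain, record_events = FALSE)
    reach <- sort(unique(unlist(lapply(
      seeds, function(s) as.integer(igraph::subcomponent(g, s, "all"))))))
    at_six <- sort(unique(c(
      which(igraph::vertex_attr(g, "belief") == 6L), reach)))
    expect_identical(which(igraph::vertex_attr(out$graph, "belief") == 6L),
                     at_six)
    expect_equal(out$n_believed, length(reach))
  }
})

test_that("impossible adoption leaves every belief untouched", {
  g <- make_fixture("fig2-toy")
  out <- propagate_message(g, 6, 1:3, contagion_spec("simple", p = 0))
  expect_identical(igraph::vertex_attr(out$graph, "belief"),
                   igraph::vertex_attr(g, "belief"))
  expect_equal(out$n_believed, 0)
  expect_true(all(out$events$outcome == "rejected"))
})

test_that("a full run is bit-reproducible and conserves agents", {
  cfg <- simulation_config(n_agents = 120, horizon = 25, seed = 9)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$timeseries, r2$timeseries)
  expect_identical(r1$final_beliefs, r2$final_beliefs)
  sums <- r1$timeseries |>
    dplyr::group_by(t) |>
    dplyr::summarise(n = sum(count), f = sum(fraction))
  expect_true(all(sums$n == 120))
  expect_equal(sums$f, rep(1, 26))
  # t = 0 row is the pre-broadcast initial histogram
  h0 <- dplyr::filter(r1$timeseries, t == 0)$count
  expect_identical(h0, tabulate(r1$initial_beliefs + 1L, 7L))
})

test_that("an agent believes a given message at most once", {
  cfg <- simulation_config(n_agents = 100, horizon = 20, seed = 3,
                           record_events = TRUE)
  run <- run_simulation(cfg)
  ev <- run$events
  believed <- dplyr::filter(ev, outcome == "believed")
  expect_equal(anyDuplicated(believed[c("uid", "receiver")]), 0)
  # the "once" retry policy also caps trials at one per agent and message
  trials <- dplyr::filter(ev, outcome %in% c("believed", "rejected"))
  expect_equal(anyDuplicated(trials[c("uid", "receiver")]), 0)
  # every non-institution sender of a delivery believed that same message
  senders <- dplyr::filter(ev, sender > 0)
  key <- paste(senders$uid, senders$sender)
  expect_true(all(key %in% paste(believed$uid, believed$receiver)))
})

test_that("the per-delivery policy allows repeat trials but not repeat beliefs", {
  cfg <- simulation_config(n_agents = 100, horizon = 20, seed = 3,
                           retry_policy = "per-delivery",
                           record_events = TRUE)
  run <- run_simulation(cfg)
  believed <- dplyr::filter(run$events, outcome == "believed")
  expect_equal(anyDuplicated(believed[c("uid", "receiver")]), 0)
  trials <- dplyr::filter(run$events, outcome %in% c("believed", "rejected"))
  expect_gt(nrow(trials), nrow(dplyr::distinct(trials, uid, receiver)))
})

test_that("cascades spread along the chain with distance-damped probability", {
  g <- make_fixture("line-chain")  # beliefs 6,5,4,3,2,1,0 along a path
  set.seed(1)
  reached <- replicate(2000, {
    out <- propagate_message(g, 6, seeds = 1L, dcc, record_events = FALSE)
    sum(igraph::vertex_attr(out$graph, "belief") == 6L)
  })
  # agent 2 holds belief 5: adopts with probability beta(1) = 0.982
  expect_lt(abs(mean(reached >= 2) - oracle_sigmoid(1)), 0.03)
  # conditional on 2 believing, 3 (distance 2 before, then exposed) follows
  # with beta(2) = 0.5
  expect_lt(abs(mean(reached >= 3) - oracle_sigmoid(1) * oracle_sigmoid(2)),
            0.04)
})

test_that("proportional contagion needs the neighbor quorum", {
  g <- make_fixture("two-cluster")  # K5 at belief 6 bridged to K5 at 0
  prop <- contagion_spec("proportional", ratio_alpha = 0.35)
  # bridge agent 6 has 5 neighbors, only 1 (agent 5) believing: 0.2 < 0.35
  out <- propagate_message(g, 6, seeds = 1:5, prop)
  expect_identical(igraph::vertex_attr(out$graph, "belief"),
                   igraph::vertex_attr(g, "belief"))
  # with a lower quorum the far cluster flips wholesale
  out2 <- propagate_message(g, 6, seeds = 1:5,
                            contagion_spec("proportional", ratio_alpha = 0.15))
  expect_true(all(igraph::vertex_attr(out2$graph, "belief") == 6L))
})

test_that("frozen proportional references pre-injection beliefs", {
  g <- make_fixture("two-cluster")
  spec <- contagion_spec("proportional", ratio_alpha = 0.15)
  # frozen: the far cluster's quorum is measured against the original
  # all-zero neighborhood, so the flip stops at the bridge agent
  out <- propagate_message(g, 6, seeds = 1:5, spec,
                           proportional_frozen = TRUE)
  b <- igraph::vertex_attr(out$graph, "belief")
  expect_true(all(b[1:6] == 6L))
  expect_true(all(b[7:10] == 0L))
})

test_that("batches replicate independently from offset seeds", {
  cfg <- simulation_config(n_agents = 80, horizon = 10, seed = 5,
                           replicates = 3)
  b <- run_batch(cfg)
  expect_equal(b$seeds, 5 + 1:3)
  solo <- run_simulation({cfg2 <- cfg; cfg2$seed <- 6L; cfg2})
  rep1 <- dplyr::filter(b$timeseries, replicate == 1) |>
    dplyr::select(-replicate)
  expect_equal(as.data.frame(rep1), as.data.frame(solo$timeseries))
  # mean fractions still sum to one
  sums <- b$summary |>
    dplyr::group_by(t) |>
    dplyr::summarise(f = sum(mean_fraction))
  expect_equal(sums$f, rep(1, 11))
  b2 <- run_batch(cfg, replicates = 5)
  rep3 <- dplyr::filter(b2$timeseries, replicate == 3)
  expect_equal(as.data.frame(rep3),
               as.data.frame(dplyr::filter(b$timeseries, replicate == 3)))
})

test_that("simulations accept pre-built graphs and custom schedules", {
  g <- make_fixture("fig2-toy")
  cfg <- simulation_config(n_agents = 10, horizon = 4, seed = 2,
                           schedule = schedule_single(4, 6),
                           contagion = contagion_spec("simple", p = 1))
  run <- run_simulation(cfg, graph = g)
  expect_equal(run$n_subscribers, 3)
  # p = 1 floods the (connected) toy graph in the first step
  expect_true(all(run$final_beliefs == 6L))
  fin <- dplyr::filter(run$timeseries, t == 1, level == 6)
  expect_equal(fin$count, 10L)
})

test_that("a split schedule moves the population twice", {
  cfg <- simulation_config(n_agents = 10, horizon = 6, seed = 2,
                           schedule = schedule_split(6, 6, 0),
                           contagion = contagion_spec("simple", p = 1),
                           epsilon = 6)
  run <- run_simulation(cfg, graph = make_fixture("fig2-toy"))
  at3 <- dplyr::filter(run$timeseries, t == 3, level == 6)$count
  expect_equal(at3, 10L)
  expect_true(all(run$final_beliefs == 0L))
})
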