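test_that("a noise-free, lateral-free plant is a straight vertical primary", {
  g <- generate_root_system(sim_params(primary_length = 10,
                                       tortuosity_sigma = 0,
                                       lateral_density = 0, seed = 1))
  tr <- extract_traits(g)
  expect_equal(tr$depth, 10)
  expect_equal(tr$primary_tortuosity, 1)
  expect_equal(tr$n_lateral_roots, 0L)
  expect_true(all(abs(g$nodes$x) < 1e-12))
})

test_that("generation is deterministic per seed and passes validation", {
  p <- sim_params(seed = 33)
  g1 <- generate_root_system(p)
  g2 <- generate_root_system(p)
  expect_identical(g1$nodes, g2$nodes)
  expect_silent(validate_root_graph(g1))
  g3 <- generate_root_system(sim_params(seed = 34))
  expect_false(identical(g1$nodes, g3$nodes))
})

test_that("lateral counts follow the Poisson placement process", {
  n <- vapply(1:200, function(s) {
    g <- generate_root_system(sim_params(primary_length = 20,
                                         lateral_density = 0.5, seed = s))
    extract_traits(g)$n_lateral_roots
  }, integer(1L))
  # E = 0.5 * 20 = 10; mean of 200 draws within 3 sigma
  expect_lt(abs(mean(n) - 10), 3 * sqrt(10 / 200))
})

test_that("time series are nested and monotone", {
  series <- generate_time_series(sim_params(seed = 11), days = 7:12)
  expect_length(series, 6L)
  traits <- do.call(rbind, lapply(series, function(s)
    extract_traits(s$graph)))
  for (tr in c("total_root_length", "primary_root_length", "n_tips",
               "n_lateral_roots", "depth")) {
    expect_true(all(diff(traits[[tr]]) >= -1e-12))
  }
  # geometric nesting: every node position of day d appears at day d+1
  for (i in seq_len(length(series) - 1L)) {
    a <- series[[i]]$graph$nodes
    b <- series[[i + 1L]]$graph$nodes
    expect_true(all(paste(round(a$x, 9), round(a$y, 9)) %in%
                      paste(round(b$x, 9), round(b$y, 9))))
  }
  single <- generate_time_series(sim_params(seed = 11), days = 9)
  expect_length(single, 1L)
})

test_that("front fixtures lie on the exact front at their alpha", {
  set.seed(3)
  ts <- rand_cone_instance(3L)
  fx0 <- generate_front_fixture(ts, 0)
  # alpha 0: the satellite star graph
  expect_equal(nrow(fx0$nodes), 4L)
  expect_cost_pair(cost_pair(fx0),
                   cost_pair(satellite_tree(ts))[["total_length"]],
                   cost_pair(satellite_tree(ts))[["travel_distance"]])

  fx1 <- generate_front_fixture(fermat_terminals(), 1)
  expect_equal(cost_pair(fx1)[["total_length"]], 1 + sqrt(3),
               tolerance = 1e-9)
  j <- fx1$nodes[fx1$nodes$y > 0.4 & fx1$nodes$y < 0.45, ]
  expect_equal(nrow(j), 1L)
  expect_equal(j$y, 1 - 1 / sqrt(3), tolerance = 1e-6)

  fr <- brute_force_front(ts, seq(0, 1, by = 0.1))
  for (astar in c(0, 0.5, 1)) {
    fx <- generate_front_fixture(ts, astar)
    sd <- scaling_distance(cost_pair(fx), fr)
    expect_lte(sd$distance, 1 + 1e-6)
  }
})

test_that("parameter validation rejects impossible settings", {
  expect_error(sim_params(primary_length = -1), "positive")
  expect_error(sim_params(step = 0), "positive")
  expect_error(sim_params(lateral_density = -0.5), "non-negative")
  expect_error(generate_time_series(sim_params(), days = c(9, 8)),
               "increasing")
  expect_error(generate_time_series(sim_params(elongation_per_day = 6),
                                    days = 0.05), "too early")
})
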