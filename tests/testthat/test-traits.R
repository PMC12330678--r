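test_that("trait extraction matches the hand-computed fixture", {
  tr <- extract_traits(make_lateral_graph())
  expect_equal(tr$total_root_length, 5.5)
  expect_equal(tr$travel_distance, 7.5)
  expect_equal(tr$primary_root_length, 4)
  expect_equal(tr$depth, 4)
  expect_equal(tr$width, 1.5)
  expect_equal(tr$convex_hull_area, 3)
  expect_equal(tr$n_tips, 2L)
  expect_equal(tr$n_lateral_roots, 1L)
  expect_equal(tr$mean_lateral_length, 1.5)
  expect_equal(tr$lateral_density, 0.25)
  expect_equal(tr$primary_tortuosity, 1)
  expect_equal(tr$n_tips, tr$n_lateral_roots + 1L)
})

test_that("a bare straight primary has degenerate lateral traits", {
  tr <- extract_traits(make_path_graph())
  expect_equal(tr$total_root_length, 4)
  expect_equal(tr$primary_root_length, 4)
  expect_equal(tr$depth, 4)
  expect_equal(tr$n_lateral_roots, 0L)
  expect_equal(tr$convex_hull_area, 0)
  expect_true(is.na(tr$mean_lateral_length))
})

test_that("traits scale with the right homogeneity degrees", {
  t1 <- extract_traits(make_lateral_graph(scale = 1))
  t2 <- extract_traits(make_lateral_graph(scale = 2))
  for (len in c("total_root_length", "travel_distance",
                "primary_root_length", "depth", "width",
                "mean_lateral_length")) {
    expect_equal(t2[[len]], 2 * t1[[len]])
  }
  expect_equal(t2$convex_hull_area, 4 * t1$convex_hull_area)
  expect_equal(t2$n_tips, t1$n_tips)
  expect_equal(t2$primary_tortuosity, t1$primary_tortuosity)
  expect_equal(t2$lateral_density, t1$lateral_density / 2)
})

test_that("trait extraction recovers generator parameters in expectation", {
  lens <- vapply(1:100, function(s) {
    g <- generate_root_system(sim_params(primary_length = 40,
                                         lateral_density = 0.3, seed = s))
    extract_traits(g)$mean_lateral_length
  }, numeric(1L))
  # truncation at zero lifts the mean of N(12, 6) slightly; stay within 10%
  expect_lt(abs(mean(lens, na.rm = TRUE) - 12) / 12, 0.1)
})

test_that("growth rates are finite differences over days", {
  series <- generate_time_series(
    sim_params(primary_length = 15, elongation_per_day = 1,
               lateral_density = 0, tortuosity_sigma = 0, seed = 2),
    days = 7:10
  )
  dyn <- growth_dynamics(series)
  expect_equal(nrow(dyn), 3L)
  expect_equal(dyn$primary_root_length_rate, rep(1, 3L))
  expect_equal(dyn$depth_rate, rep(1, 3L))

  g <- make_lateral_graph()
  flat <- growth_dynamics(list(list(day = 1, graph = g),
                               list(day = 2, graph = g)))
  expect_true(all(abs(as.matrix(flat[, -(1:2)])) < 1e-12))

  expect_error(growth_dynamics(list(list(day = 3, graph = g),
                                    list(day = 1, graph = g))),
               "increasing")
  expect_error(growth_dynamics(list(list(day = 3, graph = g))), "2 time")
})

test_that("shrinking traces are flagged as inconsistencies", {
  big <- make_lateral_graph()
  small <- make_path_graph()
  expect_warning(growth_dynamics(list(list(day = 1, graph = big),
                                      list(day = 2, graph = small))),
                 "inconsistency")
})

test_that("aggregation produces sorted group means with counts", {
  rec <- extract_traits(make_lateral_graph())
  recs <- rec[rep(1L, 15L), ]
  recs$genotype <- "WT"; recs$condition <- "ctrl"; recs$day <- 7
  agg <- aggregate_table(recs, c("genotype", "condition", "day"))
  expect_equal(nrow(agg), 1L)
  expect_equal(agg$n, 15L)
  expect_equal(agg$total_root_length, rec$total_root_length)

  recs2 <- rec[rep(1L, 5L), ]
  recs2$genotype <- c("a", "a", "a", "b", "b")
  recs2$total_root_length <- c(1, 2, 3, 10, 20)
  agg2 <- aggregate_table(recs2, "genotype")
  expect_equal(agg2$n, c(3L, 2L))
  expect_equal(agg2$total_root_length, c(2, 15))

  expect_error(aggregate_table(recs2, "nonesuch"), "unknown")

  # keying on a unique id is the identity on numeric columns
  recs2$plant_id <- letters[1:5]
  ident <- aggregate_table(recs2, "plant_id")
  expect_equal(ident$total_root_length,
               recs2$total_root_length[order(recs2$plant_id)])
})

test_that("one-hot encoding makes binary indicator columns", {
  df <- data.frame(g = c("WT", "mut", "WT"), x = 1:3,
                   stringsAsFactors = FALSE)
  oh <- one_hot_encode(df)
  expect_equal(oh$g.WT, c(1L, 0L, 1L))
  expect_equal(oh$g.mut, c(0L, 1L, 0L))
  expect_equal(oh$x, 1:3)
})
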