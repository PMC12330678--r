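test_that("JSON reader accepts a minimal arborescence and preserves it", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"metadata": {}, "scale": null, "nodes": [
    {"id": 1, "x": 0, "y": 0, "parent": null, "order": 0},
    {"id": 2, "x": 0, "y": 2, "parent": 1, "order": 0},
    {"id": 3, "x": 0, "y": 4, "parent": 2, "order": 0}]}', path)
  g <- read_root_json(path)
  expect_s3_class(g, "root_graph")
  expect_equal(nrow(g$nodes), 3L)
  expect_equal(sum(!is.na(g$nodes$parent)), 2L)  # 2 edges
  expect_length(rootpareto:::graph_leaves(g), 1L)
})

test_that("schema violations are rejected with informative errors", {
  two_roots <- withr::local_tempfile(fileext = ".json")
  writeLines('{"nodes": [
    {"id": 1, "x": 0, "y": 0, "parent": null, "order": 0},
    {"id": 2, "x": 1, "y": 1, "parent": null, "order": 0}]}', two_roots)
  expect_error(read_root_json(two_roots), "multiple roots")

  self_parent <- withr::local_tempfile(fileext = ".json")
  writeLines('{"nodes": [
    {"id": 1, "x": 0, "y": 0, "parent": null, "order": 0},
    {"id": 2, "x": 1, "y": 1, "parent": 2, "order": 0}]}', self_parent)
  expect_error(read_root_json(self_parent), "cycle")

  dup <- data.frame(id = c(1L, 1L), x = 0, y = c(0, 1),
                    parent = c(NA, 1L), order = 0L)
  expect_error(root_graph(dup), "duplicate")

  bad_coord <- data.frame(id = 1:2, x = c(0, NA), y = 0,
                          parent = c(NA, 1L), order = 0L)
  expect_error(root_graph(bad_coord), "node 2")

  cyc <- data.frame(id = 1:3, x = 0, y = 0:2,
                    parent = c(NA, 3L, 2L), order = 0L)
  expect_error(root_graph(cyc), "cycle")
})

test_that("JSON write/read round trip is the identity", {
  g <- make_lateral_graph()
  g$metadata <- list(genotype = "WT", plant_id = "p1")
  path <- withr::local_tempfile(fileext = ".json")
  write_root_json(g, path)
  g2 <- read_root_json(path)
  expect_equal(g2$nodes, g$nodes)
  expect_equal(g2$metadata$genotype, "WT")
  expect_equal(g2$scale, g$scale)

  big <- generate_root_system(sim_params(primary_length = 120,
                                         lateral_density = 0.4, seed = 9))
  p2 <- withr::local_tempfile(fileext = ".json")
  write_root_json(big, p2)
  big2 <- read_root_json(p2)
  expect_equal(nrow(big2$nodes), nrow(big$nodes))
  expect_equal(big2$nodes$x, big$nodes$x, tolerance = 1e-12)
  expect_equal(cost_pair(big2), cost_pair(big), tolerance = 1e-12)
})

test_that("terminal extraction finds the base and all leaves", {
  expect_equal(nrow(extract_terminals(make_path_graph())$tips), 1L)
  expect_equal(extract_terminals(make_path_graph())$tips[1, ],
               c(x = 0, y = 4))
  expect_equal(nrow(extract_terminals(make_lateral_graph())$tips), 2L)
  # star with k children
  k <- 5L
  star <- root_graph(data.frame(
    id = 1:(k + 1L), x = c(0, seq_len(k)), y = c(0, rep(1, k)),
    parent = c(NA, rep(1L, k)), order = c(0L, rep(1L, k))
  ))
  expect_equal(nrow(extract_terminals(star)$tips), k)
})

test_that("cost pair matches hand-computed examples", {
  star <- root_graph(data.frame(
    id = 1:3, x = c(0, 3, -3), y = c(0, 4, 4),
    parent = c(NA, 1L, 1L), order = c(0L, 0L, 1L)
  ))
  expect_cost_pair(cost_pair(star), 10, 10)
  expect_cost_pair(cost_pair(make_path_graph()), 4, 4)
  expect_cost_pair(cost_pair(make_lateral_graph()), 5.5, 7.5)
})

test_that("cost pair is scale-equivariant and bounded by straight lines", {
  g <- make_lateral_graph(scale = 1)
  g3 <- make_lateral_graph(scale = 3.5)
  expect_equal(as.numeric(cost_pair(g3)), 3.5 * as.numeric(cost_pair(g)))

  # travel distance of any random tree is at least the satellite's
  set.seed(42)
  for (rep in 1:20) {
    ts <- rand_unit_instance(sample(3:6, 1))
    sat_travel <- cost_pair(satellite_tree(ts))[["travel_distance"]]
    tr <- sample_random_trees(ts, 5, seed = rep)
    for (t in tr) {
      expect_gte(cost_pair(t)[["travel_distance"]], sat_travel - 1e-9)
    }
  }
})
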