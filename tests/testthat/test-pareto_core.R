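test_that("satellite tree is the star of straight base-tip links", {
  expect_cost_pair(cost_pair(satellite_tree(
    terminal_set(c(0, 0), rbind(c(3, 4), c(-3, 4))))), 10, 10)
  expect_cost_pair(cost_pair(satellite_tree(fermat_terminals())),
                   2 * sqrt(2), 2 * sqrt(2))
  expect_cost_pair(cost_pair(satellite_tree(collinear_terminals())), 3, 3)
})

test_that("joint objective is the linear scalarization with domain checks", {
  sat <- satellite_tree(terminal_set(c(0, 0), rbind(c(3, 4), c(-3, 4))))
  for (a in c(0, 0.3, 1)) expect_equal(joint_objective(sat, a), 10)
  cp <- structure(c(total_length = 2, travel_distance = 3),
                  class = "cost_pair")
  expect_equal(joint_objective(cp, 1), 2)
  expect_equal(joint_objective(cp, 0.5), 2.5)
  expect_error(joint_objective(cp, 1.2), "alpha")
  expect_error(joint_objective(cp, -0.1), "alpha")
})

test_that("greedy construction reduces to the satellite at alpha 0", {
  set.seed(5)
  for (rep in 1:10) {
    ts <- rand_unit_instance(sample(2:6, 1))
    g <- greedy_joint_tree(ts, 0)
    s <- satellite_tree(ts)
    expect_identical(g$edges, s$edges)
    expect_identical(g$vertices, s$vertices)
  }
})

test_that("greedy at alpha 1 chains collinear tips (Prim behaviour)", {
  g <- greedy_joint_tree(collinear_terminals(), 1)
  expect_cost_pair(cost_pair(g), 2, 3)
})

test_that("junction refinement reaches the Fermat closed form", {
  ts <- fermat_terminals()
  r <- refine_junctions(greedy_joint_tree(ts, 1), 1)
  expect_equal(cost_pair(r)[["total_length"]], 1 + sqrt(3),
               tolerance = 1e-9)
  expect_equal(nrow(r$vertices), 4L)
  expect_equal(unname(r$vertices[4L, ]), c(0, 1 - 1 / sqrt(3)),
               tolerance = 1e-6)
  # below the 2 - sqrt(2) threshold the junction is driven to the base
  r2 <- refine_junctions(greedy_joint_tree(ts, 0.5), 0.5)
  expect_equal(nrow(r2$vertices), 3L)
})

test_that("refinement never increases the joint objective", {
  set.seed(8)
  for (rep in 1:15) {
    ts <- rand_unit_instance(sample(2:6, 1))
    a <- runif(1)
    g <- greedy_joint_tree(ts, a)
    r <- refine_junctions(g, a)
    expect_lte(joint_objective(r, a),
               joint_objective(g, a) + 1e-9)
  }
})

test_that("front of the collinear instance collapses to the chain", {
  fr <- build_front(collinear_terminals())
  expect_equal(nrow(fr$points), 1L)
  expect_equal(fr$points$total_length, 2)
  expect_equal(fr$points$travel_distance, 3)
})

test_that("front endpoints match the satellite and Steiner closed forms", {
  fr <- build_front(fermat_terminals())
  p <- fr$points
  expect_equal(p$alpha[1L], 0)
  expect_equal(unlist(p[1L, 2:3], use.names = FALSE),
               c(2 * sqrt(2), 2 * sqrt(2)), tolerance = 1e-9)
  expect_equal(p$alpha[nrow(p)], 1)
  expect_equal(p$total_length[nrow(p)], 1 + sqrt(3), tolerance = 1e-9)
  expect_equal(p$travel_distance[nrow(p)], 2 * (1 + 1 / sqrt(3)),
               tolerance = 1e-6)
})

test_that("single-tip front is the straight segment", {
  fr <- build_front(terminal_set(c(0, 0), rbind(c(1, 2))))
  expect_equal(nrow(fr$points), 1L)
  expect_equal(fr$points$total_length, sqrt(5))
  expect_equal(fr$points$travel_distance, sqrt(5))
})

test_that("fronts are monotone and dominance-free on random instances", {
  set.seed(13)
  for (rep in 1:10) {
    ts <- rand_unit_instance(sample(3:7, 1))
    fr <- build_front(ts, seq(0, 1, by = 0.05))
    p <- fr$points
    expect_true(all(diff(p$total_length) <= 1e-9 * (1 + p$total_length[-1L])))
    expect_true(all(diff(p$travel_distance) >=
                      -1e-9 * (1 + p$travel_distance[-1L])))
    # heuristic never loses to both anchors
    sat <- satellite_tree(ts)
    mst <- greedy_joint_tree(ts, 1)
    for (i in seq_len(nrow(p))) {
      a <- p$alpha[i]
      jv <- a * p$total_length[i] + (1 - a) * p$travel_distance[i]
      expect_lte(jv, joint_objective(sat, a) + 1e-9)
      expect_lte(jv, joint_objective(mst, a) + 1e-9)
    }
  }
})

test_that("front construction is scale-invariant up to the factor", {
  set.seed(17)
  ts <- rand_unit_instance(4)
  s <- 37.5
  ts2 <- terminal_set(ts$rho0 * s, ts$tips * s)
  f1 <- build_front(ts, seq(0, 1, by = 0.1))
  f2 <- build_front(ts2, seq(0, 1, by = 0.1))
  expect_equal(f2$points$alpha, f1$points$alpha)
  expect_equal(f2$points$total_length, s * f1$points$total_length,
               tolerance = 1e-9)
  expect_equal(f2$points$travel_distance, s * f1$points$travel_distance,
               tolerance = 1e-9)
})

test_that("alpha grid is validated", {
  ts <- fermat_terminals()
  expect_error(build_front(ts, numeric(0)), "empty")
  expect_error(build_front(ts, c(0.2, 0.8)), "contain 0 and 1")
  expect_error(build_front(ts, c(0, 0.5, 1.2)), "within")
})
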