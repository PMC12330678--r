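test_that("scaling distance obeys on-front identity and ratio arithmetic", {
  fr <- brute_force_front(collinear_terminals(), seq(0, 1, by = 0.25))
  # the front is the single point (2, 3)
  sd1 <- scaling_distance(c(2, 3), fr)
  expect_equal(sd1$distance, 1)
  sd2 <- scaling_distance(c(3, 3), fr)       # satellite star
  expect_equal(sd2$distance, 1.5)
  sd3 <- scaling_distance(c(4, 6), fr)       # ratio homogeneity
  expect_equal(sd3$distance, 2)

  # on-front identity with alpha lookup on a richer front
  set.seed(31)
  ts <- rand_cone_instance(3L)
  fr2 <- brute_force_front(ts, seq(0, 1, by = 0.1))
  for (i in c(1L, nrow(fr2$points))) {
    sd <- scaling_distance(unlist(fr2$points[i, 2:3]), fr2)
    expect_equal(sd$distance, 1, tolerance = 1e-9)
    expect_equal(sd$alpha_value, fr2$points$alpha[i])
  }
  expect_error(scaling_distance(c(-1, 2), fr), "positive")
})

test_that("random spanning trees are uniform over the labeled trees", {
  # 2 terminals: only one tree exists
  ts2 <- terminal_set(c(0, 0), rbind(c(0, 1)))
  tr <- sample_random_trees(ts2, 5L, seed = 1)
  for (t in tr) expect_equal(t$edges, cbind(1L, 2L))

  # 3 terminals: 3 labeled trees (Cayley), frequencies within 3 sigma
  n <- 3000L
  tr <- sample_random_trees(collinear_terminals(), n, seed = 7)
  key <- vapply(tr, function(t) {
    paste(sort(paste(pmin(t$edges[, 1], t$edges[, 2]),
                     pmax(t$edges[, 1], t$edges[, 2]))), collapse = ";")
  }, "")
  freq <- table(key)
  expect_length(freq, 3L)
  sigma <- sqrt(1 / 3 * 2 / 3 / n)
  expect_true(all(abs(freq / n - 1 / 3) <= 3 * sigma))
})

test_that("collinear random trees have the three hand-enumerated cost pairs", {
  tr <- sample_random_trees(collinear_terminals(), 300L, seed = 3)
  costs <- unique(round(t(vapply(tr, cost_pair, numeric(2L))), 9))
  costs <- costs[order(costs[, 1L], costs[, 2L]), ]
  expect_equal(unname(costs), rbind(c(2, 3), c(3, 3), c(3, 5)))
})

test_that("null summary computes the barycenter and its distance", {
  ts <- collinear_terminals()
  fr <- brute_force_front(ts, seq(0, 1, by = 0.25))
  # all three labeled trees exactly once: barycenter (8/3, 11/3)
  pts <- rbind(ts$rho0, ts$tips)
  trees <- list(
    rsa_tree(pts, rbind(c(1L, 2L), c(1L, 3L)), tips = 2:3),  # star (3,3)
    rsa_tree(pts, rbind(c(1L, 2L), c(2L, 3L)), tips = 2:3),  # chain (2,3)
    rsa_tree(pts, rbind(c(1L, 3L), c(3L, 2L)), tips = 2:3)   # via tip2 (3,5)
  )
  ns <- null_summary(trees, fr)
  expect_equal(as.numeric(ns$barycenter), c(8 / 3, 11 / 3))
  expect_equal(ns$barycenter_scaling_distance, 4 / 3)

  # samples all equal to a front tree have barycenter distance 1
  chain <- trees[[2L]]
  ns2 <- null_summary(list(chain, chain), fr)
  expect_equal(ns2$barycenter_scaling_distance, 1)
})

test_that("barycenter distance is at least the minimum sample distance", {
  set.seed(19)
  for (rep in 1:5) {
    ts <- rand_cone_instance(4L)
    fr <- brute_force_front(ts, seq(0, 1, by = 0.1))
    tr <- sample_random_trees(ts, 50L, seed = rep)
    ds <- vapply(tr, function(t)
      scaling_distance(cost_pair(t), fr)$distance, numeric(1L))
    ns <- null_summary(tr, fr)
    expect_gte(ns$barycenter_scaling_distance, min(ds) - 1e-9)
    expect_true(all(ds >= 1 - 1e-6))    # exact front lower bound
  }
})

test_that("a satellite-shaped plant sits on the front at alpha 0", {
  set.seed(29)
  ts <- rand_cone_instance(3L)
  g <- tree <- satellite_tree(ts)
  graph <- rootpareto:::tree_to_root_graph(tree)
  fit <- pareto_rsa(graph, alpha_step = 0.05, null_n = 20L, seed = 1,
                    method = "exact")
  expect_equal(fit$scaling_distance, 1, tolerance = 1e-9)
  expect_equal(fit$alpha_value, 0)
})

test_that("the analysis is deterministic given the seed", {
  g <- generate_root_system(sim_params(primary_length = 25, seed = 14))
  f1 <- pareto_rsa(g, alpha_step = 0.1, null_n = 50L, seed = 9)
  f2 <- pareto_rsa(g, alpha_step = 0.1, null_n = 50L, seed = 9)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$null$sample_costs, f2$null$sample_costs)
  expect_identical(simulate(f1, 10L), simulate(f2, 10L))
  # and the sampler does not disturb the caller's RNG stream
  set.seed(1); a <- runif(1)
  set.seed(1); invisible(sample_random_trees(extract_terminals(g), 5, 3))
  b <- runif(1)
  expect_identical(a, b)
})
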