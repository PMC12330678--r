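# Shared fixtures: tiny instances with hand-computable geometry, plus random
# instance generators used by the property tests.

# root(0,0) -> (0,2) -> tip(0,4), lateral (0,2) -> (1.5,2)
make_lateral_graph <- function(scale = 1) {
  root_graph(data.frame(
    id = 1:4, x = c(0, 0, 0, 1.5), y = c(0, 2, 4, 2),
    parent = c(NA, 1, 2, 2), order = c(0L, 0L, 0L, 1L)
  ), scale = scale)
}

# vertical path root(0,0) -> (0,2) -> (0,4)
make_path_graph <- function() {
  root_graph(data.frame(
    id = 1:3, x = 0, y = c(0, 2, 4), parent = c(NA, 1, 2), order = 0L
  ))
}

# symmetric two-tip instance with Fermat-point closed forms
fermat_terminals <- function() {
  terminal_set(c(0, 0), rbind(c(1, 1), c(-1, 1)))
}

# collinear instance: rho0 (0,0), tips (0,1), (0,2)
collinear_terminals <- function() {
  terminal_set(c(0, 0), rbind(c(0, 1), c(0, 2)))
}

# random instance with all points in the unit square
rand_unit_instance <- function(k) {
  terminal_set(runif(2), matrix(runif(2L * k), k, 2L))
}

# random instance with tips spread in a downward cone below rho0, the
# arrangement of a plate-grown root system
rand_cone_instance <- function(k, half_angle = 35) {
  ang <- pi / 2 + runif(k, -half_angle, half_angle) * pi / 180
  rad <- runif(k, 0.5, 1.5)
  terminal_set(c(0, 0), cbind(rad * cos(ang), rad * sin(ang)))
}

expect_cost_pair <- function(cp, total, travel, tol = 1e-9) {
  expect_equal(unname(cp[["total_length"]]), total, tolerance = tol)
  expect_equal(unname(cp[["travel_distance"]]), travel, tolerance = tol)
}
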