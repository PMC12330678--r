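#' Parameters of the synthetic root system generator
#'
#' Defaults emulate a well-watered Arabidopsis seedling grown on a vertical
#' agar plate to about 17 days, traced in millimetres: a nearly straight
#' primary root of 80 mm discretized in 1 mm steps with mild per-step heading
#' noise, first-order laterals placed by a Poisson process along the primary
#' (0.25 per mm, about 2-3 per cm), truncated-normal lateral lengths
#' (mean 12 mm, sd 6 mm), emergence angles of about 69 degrees from the local
#' primary direction, and a primary elongation rate of 6 mm/day for time
#' series (laterals elongate at half that rate and emerge one day after the
#' primary passes their position).
#'
#' @param primary_length primary root length (mm).
#' @param step segment length of the polyline discretization (mm).
#' @param tortuosity_sigma per-step heading noise, sd in radians; 0 gives a
#'   perfectly straight vertical primary.
#' @param lateral_density laterals per unit primary length (1/mm).
#' @param lateral_length_mean,lateral_length_sigma truncated-normal (>= 0)
#'   lateral length distribution (mm).
#' @param lateral_angle_mean,lateral_angle_sigma emergence angle from the
#'   primary (radians).
#' @param elongation_per_day primary elongation rate (mm/day).
#' @param lateral_elongation_ratio lateral elongation rate relative to the
#'   primary's.
#' @param seed integer seed; generation is fully deterministic per seed.
#' @return A `sim_params` list.
#' @export
sim_params <- function(primary_length = 80, step = 1,
                       tortuosity_sigma = 0.05, lateral_density = 0.25,
                       lateral_length_mean = 12, lateral_length_sigma = 6,
                       lateral_angle_mean = 1.2, lateral_angle_sigma = 0.25,
                       elongation_per_day = 6, lateral_elongation_ratio = 0.5,
                       seed = 1L) {
  p <- list(primary_length = primary_length, step = step,
            tortuosity_sigma = tortuosity_sigma,
            lateral_density = lateral_density,
            lateral_length_mean = lateral_length_mean,
            lateral_length_sigma = lateral_length_sigma,
            lateral_angle_mean = lateral_angle_mean,
            lateral_angle_sigma = lateral_angle_sigma,
            elongation_per_day = elongation_per_day,
            lateral_elongation_ratio = lateral_elongation_ratio,
            seed = as.integer(seed))
  if (p$primary_length <= 0 || p$step <= 0) {
    stop("primary_length and step must be positive", call. = FALSE)
  }
  if (p$tortuosity_sigma < 0 || p$lateral_density < 0 ||
      p$lateral_length_mean < 0 || p$lateral_length_sigma < 0 ||
      p$elongation_per_day <= 0) {
    stop("rates, lengths and noise levels must be non-negative",
         call. = FALSE)
  }
  structure(p, class = "sim_params")
}

# All randomness of one plant, drawn once: the blueprint is the fully grown
# plant, and any developmental stage is a prefix of it. This is what makes
# daily graphs of a time series exactly nested.
plant_blueprint <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, {
    n_steps <- ceiling(params$primary_length / params$step)
    headings <- pi / 2 +
      cumsum(rnorm(n_steps, 0, params$tortuosity_sigma))  # y-down: pi/2 = down
    n_lat <- rpois(1L, params$lateral_density * params$primary_length)
    lats <- list()
    if (n_lat > 0L) {
      u <- sort(runif(n_lat, 0, params$primary_length))
      side <- sample(c(-1, 1), n_lat, replace = TRUE)
      ang <- rnorm(n_lat, params$lateral_angle_mean,
                   params$lateral_angle_sigma)
      len <- numeric(n_lat)
      for (j in seq_len(n_lat)) {     # truncated normal, >= 0 by rejection
        repeat {
          l <- rnorm(1L, params$lateral_length_mean,
                     params$lateral_length_sigma)
          if (l >= 0) break
        }
        len[j] <- max(l, params$step * 1e-3)
      }
      for (j in seq_len(n_lat)) {
        nst <- max(1L, ceiling(len[j] / params$step))
        lats[[j]] <- list(
          u = u[j], side = side[j], angle = ang[j], length = len[j],
          noise = rnorm(nst, 0, params$tortuosity_sigma)
        )
      }
    }
    list(params = params, headings = headings, laterals = lats)
  })
}

# Build a polyline from a start point, headings and a target arc length.
walk_polyline <- function(start, headings, step, length_out) {
  n_full <- floor(length_out / step + 1e-12)
  rem <- length_out - n_full * step
  segs <- rep(step, n_full)
  use <- headings[seq_len(n_full)]
  if (rem > step * 1e-9) {
    segs <- c(segs, rem)
    use <- headings[seq_len(n_full + 1L)]
  }
  if (length(segs) == 0L) return(matrix(start, ncol = 2L))
  xs <- start[1L] + cumsum(segs * cos(use))
  ys <- start[2L] + cumsum(segs * sin(use))
  rbind(start, cbind(xs, ys))
}

# Materialize a blueprint at given primary length and per-lateral lengths.
materialize_plant <- function(bp, primary_len, lateral_lens, metadata) {
  params <- bp$params
  prim <- walk_polyline(c(0, 0), bp$headings, params$step, primary_len)
  np <- nrow(prim)
  nodes <- data.frame(
    id = seq_len(np), x = prim[, 1L], y = prim[, 2L],
    parent = c(NA_integer_, seq_len(np - 1L)), order = 0L
  )
  next_id <- np + 1L
  for (j in seq_along(bp$laterals)) {
    L <- lateral_lens[j]
    if (L <= 0) next
    lat <- bp$laterals[[j]]
    attach <- min(round(lat$u / params$step), np - 1L) + 1L  # vertex index
    base_heading <- bp$headings[max(1L, min(attach, length(bp$headings)))]
    lat_headings <- base_heading + lat$side * lat$angle +
      cumsum(lat$noise)
    poly <- walk_polyline(as.numeric(nodes[attach, c("x", "y")]),
                          lat_headings, params$step, L)
    nl <- nrow(poly) - 1L
    if (nl < 1L) next
    ids <- seq.int(next_id, next_id + nl - 1L)
    nodes <- rbind(nodes, data.frame(
      id = ids, x = poly[-1L, 1L], y = poly[-1L, 2L],
      parent = c(nodes$id[attach], ids[-length(ids)]), order = 1L
    ))
    next_id <- next_id + nl
  }
  root_graph(nodes, scale = 1, metadata = metadata)
}

#' Generate a synthetic Arabidopsis-like root system
#'
#' The primary root is a downward random-heading walk of the requested
#' length; first-order laterals are placed by a Poisson process along it,
#' each emerging at a drawn angle and growing as a straight-ish walk of
#' truncated-normal length. The output satisfies every [root_graph()]
#' invariant and is identical for identical seeds.
#'
#' @param params a [sim_params()] object.
#' @return A [root_graph()] with metadata `plant_id`, `genotype`,
#'   `condition`.
#' @export
#' @examples
#' g <- generate_root_system(sim_params(primary_length = 20, seed = 42))
#' extract_traits(g)[, c("primary_root_length", "n_lateral_roots")]
generate_root_system <- function(params) {
  bp <- plant_blueprint(params)
  lens <- vapply(bp$laterals, function(l) l$length, numeric(1L))
  materialize_plant(
    bp, params$primary_length, lens,
    metadata = list(plant_id = paste0("synthetic-", params$seed),
                    genotype = "synthetic", condition = "control")
  )
}

#' Generate a nested developmental time series
#'
#' Emulates daily imaging of a growing plant: the primary elongates at
#' `elongation_per_day`, a lateral emerges one day after the primary tip
#' passes its position and then elongates at `lateral_elongation_ratio`
#' times the primary rate, and every structure is capped at its blueprint
#' (fully grown) size. Lengths are quantized to whole discretization steps so
#' each day's graph is exactly a prefix of the next day's — the traced
#' structure only ever grows.
#'
#' @param params a [sim_params()] object.
#' @param days strictly increasing day numbers; each day must allow at least
#'   one primary segment.
#' @return List of `list(day = <day>, graph = <root_graph>)`.
#' @export
generate_time_series <- function(params, days) {
  if (length(days) < 1L || any(diff(days) <= 0)) {
    stop("days must be strictly increasing", call. = FALSE)
  }
  bp <- plant_blueprint(params)
  e <- params$elongation_per_day
  quant <- function(l) floor(l / params$step + 1e-12) * params$step
  lapply(days, function(d) {
    plen <- quant(min(params$primary_length, e * d))
    if (plen < params$step) {
      stop("day ", d, " too early: primary has no complete segment",
           call. = FALSE)
    }
    lens <- vapply(bp$laterals, function(lat) {
      emerge <- lat$u / e + 1
      quant(min(lat$length,
                max(0, params$lateral_elongation_ratio * e * (d - emerge))))
    }, numeric(1L))
    g <- materialize_plant(
      bp, plen, lens,
      metadata = list(plant_id = paste0("synthetic-", params$seed),
                      genotype = "synthetic", condition = "control", day = d)
    )
    list(day = d, graph = g)
  })
}

#' Generate a fixture lying exactly on the Pareto front
#'
#' Builds the exhaustively optimal tree at a given alpha (via the
#' [brute_force_front()] machinery, at most 4 tips) and converts it to a
#' [root_graph()]: junction points become branch nodes, the root keeps order
#' 0 along its first descending chain and order increments at every other
#' branch. Such fixtures are ground truth for alpha recovery: analyzed
#' against the exact front of their own terminals they sit on the front
#' (scaling distance 1) at the alpha they were built for. Note that an
#' optimal tree that routes through a tip leaves that tip as an internal
#' node, so the fixture graph then exposes fewer leaves than the instance
#' had tips.
#'
#' @param terminals a `terminal_set` with at most 4 tips.
#' @param alpha weight in `[0, 1]`.
#' @return A [root_graph()] with metadata `alpha_star`.
#' @export
generate_front_fixture <- function(terminals, alpha) {
  if (nrow(terminals$tips) > 4L) {
    stop("front fixtures limited to at most 4 tips", call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop("alpha must be a single value in [0, 1]", call. = FALSE)
  }
  tree <- brute_force_tree(terminals, alpha)$tree
  tree_to_root_graph(tree, metadata = list(alpha_star = alpha))
}

# Convert an rsa_tree to a root_graph: BFS from the root; the first child (by
# vertex index) continues its parent's order, further children increment it.
tree_to_root_graph <- function(tree, metadata = list()) {
  parent <- tree_parents(tree)
  ord_bfs <- attr(parent, "bfs_order")
  nv <- nrow(tree$vertices)
  order_of <- rep(NA_integer_, nv)
  order_of[tree$root] <- 0L
  seen_child <- rep(FALSE, nv)
  for (v in ord_bfs[-1L]) {
    p <- parent[v]
    order_of[v] <- if (seen_child[p]) order_of[p] + 1L else order_of[p]
    seen_child[p] <- TRUE
  }
  nodes <- data.frame(
    id = seq_len(nv),
    x = tree$vertices[, 1L], y = tree$vertices[, 2L],
    parent = ifelse(parent == 0L, NA_integer_, parent),
    order = order_of
  )
  root_graph(nodes, scale = 1, metadata = metadata)
}
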