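#' Build the Pareto front between the satellite and Steiner trees
#'
#' For every weight in `alpha_grid`, a candidate tree is constructed by
#' [greedy_joint_tree()] and tightened by [refine_junctions()]. A polish pass
#' then re-evaluates every refined topology at every alpha (the joint
#' objective of a fixed geometry is linear in its cost pair, so this is
#' cheap), re-relocates the best topology at each alpha, and keeps the
#' winner. Duplicated cost pairs are collapsed onto their smallest alpha,
#' dominated points are removed, and the surviving points are ordered by
#' alpha with total length non-increasing and travel distance non-decreasing.
#'
#' @param terminals a `terminal_set` (see [extract_terminals()]).
#' @param alpha_grid increasing weights spanning `[0, 1]`; must contain 0 and
#'   1 (default: step 0.01, i.e. 101 values).
#' @param polish logical; run the cross-alpha topology polish pass.
#' @param ... tolerances passed to [refine_junctions()].
#' @return A `pareto_front`: list with `points` (data frame `alpha`,
#'   `total_length`, `travel_distance`) and the corresponding `trees`.
#' @export
#' @examples
#' ts <- terminal_set(c(0, 0), rbind(c(1, 1), c(-1, 1)))
#' front <- build_front(ts, seq(0, 1, by = 0.25))
#' front$points
build_front <- function(terminals, alpha_grid = seq(0, 1, by = 0.01),
                        polish = TRUE, ...) {
  alpha_grid <- check_alpha_grid(alpha_grid)
  sat <- satellite_tree(terminals)
  # Refinement effort scales with instance size: small instances afford the
  # satellite-seeded second chain and the reattachment local search (which
  # together recover essentially optimal topologies); large instances rely
  # on the greedy chain plus the cross-alpha polish below.
  small <- nrow(terminals$tips) <= 6L
  medium <- nrow(terminals$tips) <= 12L
  trees <- lapply(alpha_grid, function(a) {
    cand <- refine_junctions(greedy_joint_tree(terminals, a), a, ...)
    if (a > 0 && medium) {
      # the star seeds a different topology family than the greedy tree:
      # junctions emerge from the root outward instead of along MST edges
      cand2 <- refine_junctions(sat, a, ...)
      if (joint_objective(cand2, a) < joint_objective(cand, a)) {
        cand <- cand2
      }
    }
    cand
  })
  costs <- t(vapply(trees, cost_pair, numeric(2L)))

  # reattachment local search on a coarse alpha subset (every point of a
  # short grid); the polish pass below propagates any improved topology to
  # the rest of the grid
  if (small) {
    ra <- if (length(alpha_grid) <= 21L) {
      which(alpha_grid > 0)
    } else {
      vapply(c(0.1, 0.25, 0.5, 0.75, 0.9, 1),
             function(a) which.min(abs(alpha_grid - a)), 0L)
    }
    for (i in unique(ra)) {
      cand <- reattach_search(trees[[i]], alpha_grid[i], ...)
      if (joint_objective(cand, alpha_grid[i]) <
          joint_objective(trees[[i]], alpha_grid[i])) {
        trees[[i]] <- cand
        costs[i, ] <- cost_pair(cand)
      }
    }
  }

  if (polish && length(alpha_grid) > 1L) {
    for (i in seq_along(alpha_grid)) {
      a <- alpha_grid[i]
      lin <- a * costs[, 1L] + (1 - a) * costs[, 2L]
      b <- which.min(lin)
      if (b != i) {
        cand <- refine_junctions(trees[[b]], a, ...)
        if (joint_objective(cand, a) < lin[i] - 1e-15 * (1 + lin[i])) {
          trees[[i]] <- cand
          costs[i, ] <- cost_pair(cand)
        }
      }
    }
  }
  new_pareto_front(alpha_grid, costs, trees, method = "greedy")
}

check_alpha_grid <- function(alpha_grid) {
  if (length(alpha_grid) == 0L) stop("empty alpha grid", call. = FALSE)
  if (any(!is.finite(alpha_grid)) || any(alpha_grid < 0) ||
      any(alpha_grid > 1)) {
    stop("alpha grid must lie within [0, 1]", call. = FALSE)
  }
  alpha_grid <- sort(unique(alpha_grid))
  if (alpha_grid[1L] != 0 || alpha_grid[length(alpha_grid)] != 1) {
    stop("alpha grid must contain 0 and 1", call. = FALSE)
  }
  alpha_grid
}

# Subtree reattachment local search (small instances): detach each subtree
# from its parent, reattach it at another vertex, re-run junction insertion
# and relocation, and keep the move when the joint objective improves. A
# cheap first-order score (edge swap at frozen junction positions) screens
# the moves so only promising reattachments pay for a full refinement; this
# escapes greedy topologies that pairwise junction insertion cannot fix.
reattach_search <- function(tree, alpha, max_pass = 3L, ...) {
  obj <- joint_objective(tree, alpha)
  for (pass in seq_len(max_pass)) {
    parent <- tree_parents(tree)
    nv <- nrow(tree$vertices)
    depth <- tree_depths(tree, parent)
    cnt <- edge_tip_counts(tree, parent)
    echild <- ifelse(parent[tree$edges[, 1L]] == tree$edges[, 2L],
                     tree$edges[, 1L], tree$edges[, 2L])
    improved <- FALSE
    for (cc in seq_len(nv)[-tree$root]) {
      p <- parent[cc]
      eidx <- which(echild == cc)
      k_c <- cnt[eidx]
      w_c <- alpha + (1 - alpha) * k_c
      # members of the subtree rooted at cc
      insub <- rep(FALSE, nv)
      insub[cc] <- TRUE
      for (v in attr(parent, "bfs_order")) {
        if (!insub[v] && parent[v] > 0L && insub[parent[v]]) insub[v] <- TRUE
      }
      targets <- which(!insub & seq_len(nv) != p)
      if (length(targets) == 0L) next
      d_new <- sqrt((tree$vertices[targets, 1L] - tree$vertices[cc, 1L])^2 +
                    (tree$vertices[targets, 2L] - tree$vertices[cc, 2L])^2)
      d_old <- edist(tree$vertices[cc, ], tree$vertices[p, ])
      lazy <- w_c * (d_new - d_old) +
        (1 - alpha) * k_c * (depth[targets] - depth[p])
      for (u in targets[lazy <= 0.15 * obj]) {
        t2 <- tree
        t2$edges[eidx, ] <- c(u, cc)
        t2 <- refine_junctions(t2, alpha, ...)
        o2 <- joint_objective(t2, alpha)
        if (o2 < obj - 1e-10 * (1 + obj)) {
          tree <- t2
          obj <- o2
          improved <- TRUE
          break
        }
      }
      if (improved) break
    }
    if (!improved) return(tree)
  }
  tree
}

# Assemble a pareto_front from per-alpha trees: deduplicate equal cost pairs
# (keeping the smallest alpha), drop dominated points, enforce monotonicity.
new_pareto_front <- function(alphas, costs, trees, method) {
  stopifnot(nrow(costs) == length(alphas))
  o <- order(alphas)
  alphas <- alphas[o]
  costs <- costs[o, , drop = FALSE]
  trees <- trees[o]

  keep <- rep(TRUE, length(alphas))
  rtol <- function(a, b) abs(a - b) <= 1e-12 * (1 + abs(b))
  for (i in seq_along(alphas)) {
    if (!keep[i]) next
    for (j in seq_along(alphas)) {
      if (i == j || !keep[i]) next
      if (rtol(costs[i, 1L], costs[j, 1L]) &&
          rtol(costs[i, 2L], costs[j, 2L])) {
        # duplicate: keep the smaller alpha
        if (j < i) keep[i] <- FALSE else keep[j] <- FALSE
      } else if (keep[j] &&
                 costs[j, 1L] <= costs[i, 1L] + 1e-15 &&
                 costs[j, 2L] <= costs[i, 2L] + 1e-15) {
        keep[i] <- FALSE                         # j dominates i
      }
    }
  }
  alphas <- alphas[keep]; costs <- costs[keep, , drop = FALSE]
  trees <- trees[keep]

  # monotone sweep: total length non-increasing, travel non-decreasing
  keep <- rep(TRUE, length(alphas))
  last <- 1L
  for (i in seq_along(alphas)[-1L]) {
    if (costs[i, 1L] > costs[last, 1L] + 1e-12 * (1 + costs[last, 1L]) ||
        costs[i, 2L] < costs[last, 2L] - 1e-12 * (1 + costs[last, 2L])) {
      keep[i] <- FALSE
    } else {
      last <- i
    }
  }
  points <- data.frame(alpha = alphas[keep],
                       total_length = unname(costs[keep, 1L]),
                       travel_distance = unname(costs[keep, 2L]))
  rownames(points) <- NULL
  structure(
    list(points = points, trees = trees[keep], method = method),
    class = "pareto_front"
  )
}

#' @export
print.pareto_front <- function(x, ...) {
  p <- x$points
  cat("Pareto front (", x$method, "): ", nrow(p), " point(s), alpha in [",
      format(min(p$alpha)), ", ", format(max(p$alpha)), "]\n", sep = "")
  cat("  total length in [", format(min(p$total_length)), ", ",
      format(max(p$total_length)), "]; travel distance in [",
      format(min(p$travel_distance)), ", ", format(max(p$travel_distance)),
      "]\n", sep = "")
  invisible(x)
}

#' @export
plot.pareto_front <- function(x, ...) {
  p <- x$points
  plot(p$total_length, p$travel_distance, type = "b", pch = 16, cex = 0.5,
       xlab = "total length (cost)", ylab = "travel distance", ...)
  invisible(x)
}

# --- exhaustive oracle -------------------------------------------------------

#' Exact Pareto front by exhaustive enumeration (small instances)
#'
#' Test oracle for the NP-hard joint optimization, limited to at most 4 tips.
#' All labeled spanning trees over the terminals are enumerated via Prüfer
#' sequences, and all full Steiner topologies (n - 2 junctions of degree 3)
#' via recursive edge insertion. Per fixed topology the joint objective is
#' convex in the junction coordinates; it is minimized by Weiszfeld
#' coordinate descent from several deterministic starts plus a Nelder-Mead
#' polish. Since every Steiner topology is a degeneration of a full topology,
#' the minimum over all candidates is the exact optimum up to numerical
#' tolerance.
#'
#' @param terminals a `terminal_set` with at most 4 tips.
#' @param alpha_grid increasing weights containing 0 and 1.
#' @return A `pareto_front` with `method = "exact"`.
#' @export
brute_force_front <- function(terminals, alpha_grid = seq(0, 1, by = 0.01)) {
  alpha_grid <- check_alpha_grid(alpha_grid)
  k <- nrow(terminals$tips)
  if (k > 4L) stop("brute force limited to at most 4 tips", call. = FALSE)
  cand <- brute_force_candidates(terminals)
  trees <- vector("list", length(alpha_grid))
  costs <- matrix(NA_real_, length(alpha_grid), 2L)
  warm <- vector("list", length(cand$topologies))  # per-topology warm starts
  for (i in seq_along(alpha_grid)) {
    best <- brute_force_tree(terminals, alpha_grid[i], cand, warm)
    trees[[i]] <- best$tree
    costs[i, ] <- cost_pair(best$tree)
    warm <- best$warm
  }
  new_pareto_front(alpha_grid, costs, trees, method = "exact")
}

# Alpha-independent candidate structures: spanning trees with their cost
# pairs, and full Steiner topologies.
brute_force_candidates <- function(terminals) {
  pts <- rbind(terminals$rho0, terminals$tips)
  m <- nrow(pts)
  span <- all_spanning_trees(m)
  span_trees <- lapply(span, function(e) {
    rsa_tree(pts, e, root = 1L, tips = seq.int(2L, m))
  })
  span_costs <- t(vapply(span_trees, cost_pair, numeric(2L)))
  list(pts = pts, m = m, span_trees = span_trees, span_costs = span_costs,
       topologies = if (m >= 3L) full_steiner_topologies(m) else list())
}

# Optimal tree at a single alpha, given precomputed candidates. `warm`
# carries per-topology junction coordinates from a previous (nearby) alpha;
# the optimum varies continuously along the grid, so warm starts converge in
# a few sweeps. Returns the best tree plus updated warm starts.
brute_force_tree <- function(terminals, alpha, cand = NULL, warm = NULL) {
  if (is.null(cand)) cand <- brute_force_candidates(terminals)
  if (is.null(warm)) warm <- vector("list", length(cand$topologies))
  lin <- alpha * cand$span_costs[, 1L] + (1 - alpha) * cand$span_costs[, 2L]
  best_tree <- cand$span_trees[[which.min(lin)]]
  best_obj <- min(lin)
  for (ti in seq_along(cand$topologies)) {
    res <- optimize_topology(cand$pts, cand$topologies[[ti]], alpha,
                             warm = warm[[ti]])
    warm[[ti]] <- res$junctions
    if (res$objective < best_obj - 1e-12 * (1 + abs(best_obj))) {
      best_obj <- res$objective
      best_tree <- res$tree
    }
  }
  # canonicalize: collapse objective-neutral (degenerate) junctions so that
  # two optimizations of the same instance yield identical cost pairs
  best_tree <- merge_degenerate_junctions(best_tree, alpha)
  list(tree = best_tree, warm = warm)
}

# Minimize the joint objective over junction coordinates of one full
# topology: per fixed topology the objective is convex, so Weiszfeld
# coordinate descent from deterministic starts (plus an optional warm start)
# followed by a Nelder-Mead polish of the best iterate reaches the global
# optimum; the polish resolves the rare stalls at junction-junction
# coincidences that plain coordinate descent cannot escape.
optimize_topology <- function(pts, edges, alpha, warm = NULL) {
  m <- nrow(pts)
  nj <- max(edges) - m
  tree0 <- rsa_tree(rbind(pts, matrix(colMeans(pts), nj, 2L, byrow = TRUE)),
                    edges, root = 1L, tips = seq.int(2L, m))
  parent <- tree_parents(tree0)
  w <- edge_weights(tree0, alpha, parent)
  movable <- c(rep(FALSE, m), rep(TRUE, nj))

  span <- max(apply(pts, 2L, function(v) diff(range(v))), 1e-6)
  starts <- list(
    matrix(colMeans(pts), nj, 2L, byrow = TRUE),
    matrix(colMeans(pts), nj, 2L, byrow = TRUE) +
      0.25 * span * cbind(cos(2 * pi * seq_len(nj) / max(nj, 1L)),
                          sin(2 * pi * seq_len(nj) / max(nj, 1L)))
  )
  if (!is.null(warm)) starts <- c(list(warm), starts)
  edges0 <- edges - 1L
  xy_tmpl <- rbind(pts, matrix(0, nj, 2L))
  jrows <- seq.int(m + 1L, m + nj)
  obj_fn <- function(par) {
    xy_tmpl[jrows, ] <- par
    edge_weighted_length(xy_tmpl, edges0, w)
  }
  best <- NULL
  for (s in starts) {
    res <- weiszfeld_descent(rbind(pts, s), edges - 1L, w, movable,
                             1e-11, 1500L)
    if (is.null(best) || res$objective < best$objective) {
      best <- list(objective = res$objective,
                   junctions = res$coords[seq.int(m + 1L, m + nj), ,
                                          drop = FALSE])
    }
  }
  # Nelder-Mead polish of the best iterate: coordinate descent can stall
  # where adjacent junctions coincide, which the simplex search escapes.
  pol <- stats::optim(as.vector(best$junctions), obj_fn,
                      method = "Nelder-Mead",
                      control = list(maxit = 500L, reltol = 1e-13))
  if (pol$value < best$objective) {
    # simplex convergence is on the objective only; re-descend so junction
    # positions (hence the cost-pair components) are converged too
    res <- weiszfeld_descent(rbind(pts, matrix(pol$par, nj, 2L)),
                             edges0, w, movable, 1e-12, 2000L)
    if (res$objective <= pol$value + 1e-14 * (1 + pol$value)) {
      best <- list(objective = res$objective,
                   junctions = res$coords[jrows, , drop = FALSE])
    } else {
      best <- list(objective = pol$value,
                   junctions = matrix(pol$par, nj, 2L))
    }
  }
  tree <- rsa_tree(rbind(pts, best$junctions), edges, root = 1L,
                   tips = seq.int(2L, m))
  list(objective = best$objective, tree = tree, junctions = best$junctions)
}

# All labeled spanning trees on m vertices (Prüfer enumeration; m <= 5).
all_spanning_trees <- function(m) {
  if (m == 2L) return(list(cbind(1L, 2L)))
  seqs <- as.matrix(expand.grid(rep(list(seq_len(m)), m - 2L)))
  lapply(seq_len(nrow(seqs)), function(i) prufer_decode(seqs[i, ], m))
}

# Decode a Prüfer sequence into an edge list (classic O(m^2) construction).
prufer_decode <- function(pseq, m) {
  pseq <- as.integer(pseq)
  deg <- rep(1L, m)
  for (v in pseq) deg[v] <- deg[v] + 1L
  edges <- matrix(0L, m - 1L, 2L)
  for (i in seq_along(pseq)) {
    leaf <- which(deg == 1L)[1L]
    edges[i, ] <- c(leaf, pseq[i])
    deg[leaf] <- deg[leaf] - 1L
    deg[pseq[i]] <- deg[pseq[i]] - 1L
  }
  last <- which(deg == 1L)
  edges[m - 1L, ] <- last
  edges
}

# Full Steiner topologies on m terminals: terminals have degree 1, the m - 2
# junctions degree 3. Built recursively by inserting terminal t into every
# edge of every topology on t - 1 terminals. Junctions are encoded as
# negative labels during construction and renumbered to m+1 .. 2m-2.
full_steiner_topologies <- function(m) {
  if (m < 3L) return(list())
  topos <- list(rbind(c(1L, -1L), c(2L, -1L), c(3L, -1L)))
  t <- 4L
  while (t <= m) {
    nxt <- list()
    for (topo in topos) {
      for (e in seq_len(nrow(topo))) {
        jnew <- min(c(topo[topo < 0L], 0L)) - 1L
        a <- topo[e, 1L]; b <- topo[e, 2L]
        nxt[[length(nxt) + 1L]] <-
          rbind(topo[-e, , drop = FALSE], c(a, jnew), c(jnew, b), c(t, jnew))
      }
    }
    topos <- nxt
    t <- t + 1L
  }
  lapply(topos, function(topo) {
    jl <- sort(unique(topo[topo < 0L]), decreasing = TRUE)  # -1, -2, ...
    out <- topo
    for (i in seq_along(jl)) out[topo == jl[i]] <- m + i
    out
  })
}
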