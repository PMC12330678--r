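#' Satellite tree: the transport-optimal extreme architecture
#'
#' The satellite tree connects the hypocotyl base directly to every root tip
#' by a straight segment. It attains the global minimum of travel distance
#' (the sum of straight-line base-to-tip distances) at the price of maximal
#' construction cost, and anchors the `alpha = 0` end of the Pareto front.
#'
#' @param terminals a `terminal_set` (see [extract_terminals()]).
#' @return An `rsa_tree` star.
#' @export
#' @examples
#' cost_pair(satellite_tree(terminal_set(c(0, 0), rbind(c(3, 4), c(-3, 4)))))
satellite_tree <- function(terminals) {
  k <- nrow(terminals$tips)
  if (k < 1L) stop("satellite tree needs at least one tip", call. = FALSE)
  rsa_tree(
    vertices = rbind(terminals$rho0, terminals$tips),
    edges = cbind(1L, seq_len(k) + 1L),
    root = 1L,
    tips = seq_len(k) + 1L
  )
}

#' Greedy construction of a joint-objective tree
#'
#' Builds a spanning arborescence over the terminals by greedy insertion:
#' starting from the hypocotyl base, the (unattached tip, tree vertex) pair
#' minimizing the incremental joint objective
#' `alpha * d(u, v) + (1 - alpha) * (pathlen(rho0 -> v) + d(u, v))`
#' is attached repeatedly. Ties are broken by the smallest tip index, then
#' the smallest tree-vertex index. At `alpha = 0` the construction reduces
#' exactly to the satellite star; at `alpha = 1` it is Prim's minimum
#' spanning tree over the terminals. The exact joint optimization is NP-hard,
#' so this heuristic (tightened by [refine_junctions()]) is benchmarked
#' against the exhaustive [brute_force_front()] oracle on small instances.
#'
#' @param terminals a `terminal_set`.
#' @param alpha weight in `[0, 1]`.
#' @return An `rsa_tree` over the terminals (no junction points).
#' @export
greedy_joint_tree <- function(terminals, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    stop("alpha must be a single value in [0, 1]", call. = FALSE)
  }
  k <- nrow(terminals$tips)
  if (k < 1L) stop("needs at least one tip", call. = FALSE)
  if (alpha == 0) return(satellite_tree(terminals))   # exact limit

  pts <- rbind(terminals$rho0, terminals$tips)        # 1 = rho0, 1+i = tip i
  in_tree <- c(TRUE, rep(FALSE, k))
  plen <- c(0, rep(NA_real_, k))                      # path length to rho0
  parent <- rep(NA_integer_, k + 1L)
  for (step in seq_len(k)) {
    out <- which(!in_tree)
    inn <- which(in_tree)
    d <- cross_dist(pts[inn, , drop = FALSE], pts[out, , drop = FALSE])
    score <- alpha * d + (1 - alpha) * (plen[inn] + d)
    # column-major scan of (vertex in tree) x (tip outside): minimum with
    # ties to the smallest tip index, then smallest tree-vertex index
    best <- which(score == min(score), arr.ind = TRUE)
    best <- best[order(out[best[, 2L]], inn[best[, 1L]]), , drop = FALSE]
    v <- inn[best[1L, 1L]]
    u <- out[best[1L, 2L]]
    parent[u] <- v
    plen[u] <- plen[v] + edist(pts[u, ], pts[v, ])
    in_tree[u] <- TRUE
  }
  rsa_tree(pts, cbind(which(!is.na(parent)), parent[!is.na(parent)]),
           root = 1L, tips = seq_len(k) + 1L)
}

# --- junction refinement ------------------------------------------------------

# Steiner insertion move: for each vertex, find the pair of incident edges
# whose weighted pull exceeds the weight of a fresh junction-to-vertex edge
# (the condition under which a junction placed at the vertex escapes to an
# interior position — the weighted 120-degree rule), and insert a junction
# taking over exactly that pair. One insertion per vertex per round; edges
# already moved in this round are left for the next one.
insert_junctions <- function(tree, alpha) {
  nv0 <- nrow(tree$vertices)
  parent <- tree_parents(tree)
  cnt <- edge_tip_counts(tree, parent)        # tips routed through each edge
  w <- alpha + (1 - alpha) * cnt
  n_tips_total <- length(tree$tips)
  is_tip <- rep(FALSE, nv0)
  is_tip[tree$tips] <- TRUE

  edges <- tree$edges
  vertices <- tree$vertices
  dirty <- rep(FALSE, nv0)
  inserted <- FALSE

  # incidence: for vertex v, edge e reaches nbr with k tips beyond it
  ch1 <- parent[edges[, 1L]] == edges[, 2L]
  child <- edges[, 2L]
  child[ch1] <- edges[ch1, 1L]
  ne <- nrow(edges)
  inc <- split(rep.int(seq_len(ne), 2L),
               factor(c(edges[, 1L], edges[, 2L]), levels = seq_len(nv0)))
  for (v in seq_len(nv0)) {
    if (dirty[v]) next
    eidx <- inc[[v]]
    if (length(eidx) < 2L) next
    nbr <- edges[eidx, 1L]
    swap <- nbr == v
    nbr[swap] <- edges[eidx[swap], 2L]
    if (any(dirty[nbr])) next
    dvec <- vertices[nbr, , drop = FALSE] -
      matrix(vertices[v, ], length(nbr), 2L, byrow = TRUE)
    dn <- sqrt(rowSums(dvec^2))
    if (any(dn < 1e-12)) next
    uvec <- dvec / dn
    k_beyond <- ifelse(child[eidx] == nbr, cnt[eidx],
                       n_tips_total - cnt[eidx])
    we <- w[eidx]
    # subtree tip count below v (v on the root side of its parent edge)
    own <- which(child[eidx] == v)
    cnt_below_v <- sum(cnt[eidx][child[eidx] != v]) + is_tip[v]

    best_gain <- 1e-9
    best_pair <- NULL
    for (i in seq_along(eidx)[-length(eidx)]) {
      for (j in seq.int(i + 1L, length(eidx))) {
        pull <- sqrt(sum((we[i] * uvec[i, ] + we[j] * uvec[j, ])^2))
        pair_par <- length(own) > 0L && own %in% c(i, j)
        t_jv <- if (pair_par) {
          moved_child <- setdiff(c(i, j), own)
          cnt_below_v - cnt[eidx][moved_child]
        } else {
          k_beyond[i] + k_beyond[j]
        }
        w_jv <- alpha + (1 - alpha) * t_jv
        gain <- pull - w_jv
        if (gain > best_gain) {
          best_gain <- gain
          best_pair <- c(i, j)
        }
      }
    }
    if (is.null(best_pair)) next
    jnew <- nrow(vertices) + 1L
    vertices <- rbind(vertices, vertices[v, , drop = FALSE])
    for (i in best_pair) {
      e <- eidx[i]
      edges[e, ] <- c(jnew, nbr[i])
    }
    edges <- rbind(edges, c(v, jnew))
    dirty[c(v, nbr[best_pair])] <- TRUE
    inserted <- TRUE
  }
  if (!inserted) return(tree)
  # valid by construction: skip re-validation on this hot path
  structure(list(vertices = vertices, edges = edges, root = tree$root,
                 tips = tree$tips), class = "rsa_tree")
}

# Contract junctions whose removal does not increase the joint objective by
# more than `tol` (relative): merge into the best neighbour, then splice out
# any junction left with degree <= 2. Degeneracy is judged on the objective,
# not on raw distance, so a junction parked at its boundary optimum (e.g. on
# the root below the satellite/Steiner transition) is recognized as such.
#
# Contractions are batched per pass: merging a junction into a neighbour
# redirects its edges but leaves every edge's routed-tip count (hence its
# weight) unchanged, so one parent/weight computation serves a whole pass.
merge_degenerate_junctions <- function(tree, alpha, tol = 1e-9) {
  repeat {
    nv <- nrow(tree$vertices)
    n_terminal <- length(tree$tips) + 1L
    if (nv <= n_terminal) return(tree)
    parent <- tree_parents(tree)
    w <- edge_weights(tree, alpha, parent)
    edges <- tree$edges
    verts <- tree$vertices
    obj <- sum(w * sqrt(rowSums((verts[edges[, 1L], , drop = FALSE] -
                                 verts[edges[, 2L], , drop = FALSE])^2)))
    alive <- rep(TRUE, nv)
    changed <- FALSE
    ne <- nrow(edges)
    edead <- rep(FALSE, ne)
    inc <- split(rep.int(seq_len(ne), 2L),
                 factor(c(edges[, 1L], edges[, 2L]), levels = seq_len(nv)))
    for (j in seq.int(n_terminal + 1L, nv)) {
      eidx <- inc[[j]]
      eidx <- eidx[!edead[eidx]]
      # neighbour aligned with its edge (and weight w[eidx])
      nbrs <- edges[eidx, 1L]
      swap <- nbrs == j
      nbrs[swap] <- edges[eidx[swap], 2L]
      if (length(nbrs) == 0L) next
      target <- NA_integer_
      if (length(nbrs) <= 2L) {           # splice a pass-through junction
        target <- nbrs[1L]
      } else {
        cur <- sum(w[eidx] * sqrt((verts[nbrs, 1L] - verts[j, 1L])^2 +
                                  (verts[nbrs, 2L] - verts[j, 2L])^2))
        for (u in nbrs[order(nbrs)]) {
          alt <- sum(w[eidx] * sqrt((verts[nbrs, 1L] - verts[u, 1L])^2 +
                                    (verts[nbrs, 2L] - verts[u, 2L])^2))
          if (alt - cur <= tol * (1 + abs(obj))) {
            target <- u
            break
          }
        }
      }
      if (!is.na(target)) {
        sel1 <- edges[eidx, 1L] == j
        edges[eidx[sel1], 1L] <- target
        edges[eidx[!sel1], 2L] <- target
        self <- eidx[edges[eidx, 1L] == edges[eidx, 2L]]
        edead[self] <- TRUE
        # the surviving redirected edges now belong to the target vertex
        inc[[target]] <- c(inc[[target]], setdiff(eidx, self))
        alive[j] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) return(tree)
    newid <- cumsum(alive)
    edges <- edges[!edead, , drop = FALSE]
    edges[] <- newid[edges]
    tree <- structure(
      list(vertices = verts[alive, , drop = FALSE], edges = edges,
           root = newid[tree$root], tips = newid[tree$tips]),
      class = "rsa_tree"
    )
  }
}

#' Relocate junction points under the joint objective
#'
#' Inserts movable junction points beside branching vertices and iteratively
#' relocates each junction to the weighted geometric median of its
#' neighbours, the exact coordinate-descent step for the joint objective
#' (edge weights `alpha + (1 - alpha) * tips routed through the edge`).
#' Junctions whose removal is objective-neutral are merged away, and the
#' insert/descend/merge cycle repeats until the objective stops improving.
#' Terminals never move, and the objective is non-increasing across sweeps.
#'
#' On the two-tip instance with tips (1, 1) and (-1, 1), at `alpha = 1` the
#' junction converges to the Fermat point (0, 1 - 1/sqrt(3)) and the total
#' length to 1 + sqrt(3); an interior junction exists only for
#' `alpha >= 2 - sqrt(2)`.
#'
#' @param tree an `rsa_tree` over terminals.
#' @param alpha weight in `[0, 1]`.
#' @param tol convergence tolerance on the per-sweep junction displacement.
#' @param max_sweeps cap on relocation sweeps per descent.
#' @param merge_tol relative objective tolerance below which a junction is
#'   considered degenerate and merged into a neighbour.
#' @return An `rsa_tree` with relocated (possibly removed) junctions;
#'   `joint_objective(result, alpha) <= joint_objective(tree, alpha)`.
#' @export
refine_junctions <- function(tree, alpha, tol = 1e-10, max_sweeps = 1000L,
                             merge_tol = 1e-9) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    stop("alpha must be a single value in [0, 1]", call. = FALSE)
  }
  best <- tree
  obj_best <- joint_objective(best, alpha)
  for (round in seq_len(20L)) {
    t2 <- insert_junctions(best, alpha)
    nv <- nrow(t2$vertices)
    n_terminal <- length(t2$tips) + 1L
    if (nv == n_terminal) break                    # nothing to relocate
    t2 <- descend_tree(t2, alpha, tol, max_sweeps)
    t2 <- merge_degenerate_junctions(t2, alpha, merge_tol)
    obj2 <- joint_objective(t2, alpha)
    if (obj2 < obj_best - 1e-12 * (1 + abs(obj_best))) {
      best <- t2
      obj_best <- obj2
    } else {
      break
    }
  }
  best
}

# One Weiszfeld coordinate-descent pass over all junctions of a tree.
descend_tree <- function(tree, alpha, tol = 1e-10, max_sweeps = 1000L) {
  parent <- tree_parents(tree)
  w <- edge_weights(tree, alpha, parent)
  movable <- rep(FALSE, nrow(tree$vertices))
  if (nrow(tree$vertices) > length(tree$tips) + 1L) {
    movable[seq.int(length(tree$tips) + 2L, nrow(tree$vertices))] <- TRUE
  }
  res <- weiszfeld_descent(tree$vertices, tree$edges - 1L, w, movable,
                           tol, as.integer(max_sweeps))
  tree$vertices <- res$coords
  colnames(tree$vertices) <- c("x", "y")
  tree
}
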