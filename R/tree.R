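#' Candidate transport trees over a terminal set
#'
#' An `rsa_tree` is a candidate network connecting the terminals of a root
#' system: vertices are 2D points (terminals first — the hypocotyl base at
#' index 1, then the tips in terminal order — followed by any added junction
#' points), and edges are undirected vertex-index pairs forming a spanning
#' tree. Travel distance is always accumulated over the *terminal tips*
#' (vertices `tips`), whether or not the tree routes through them.
#'
#' @param vertices numeric matrix with one row per vertex (columns x, y).
#' @param edges integer matrix with two columns (vertex indices).
#' @param root index of the hypocotyl base vertex (default 1).
#' @param tips indices of the terminal tip vertices.
#' @return An object of class `rsa_tree`.
#' @export
rsa_tree <- function(vertices, edges, root = 1L, tips) {
  vertices <- matrix(as.numeric(vertices), ncol = 2L,
                     dimnames = list(NULL, c("x", "y")))
  edges <- matrix(as.integer(edges), ncol = 2L)
  nv <- nrow(vertices)
  if (nrow(edges) != nv - 1L) {
    stop("tree: needs |edges| = |vertices| - 1", call. = FALSE)
  }
  t <- structure(list(vertices = vertices, edges = edges,
                      root = as.integer(root), tips = as.integer(tips)),
                 class = "rsa_tree")
  if (anyNA(tree_parents(t))) {
    stop("tree: disconnected structure", call. = FALSE)
  }
  t
}

#' @export
print.rsa_tree <- function(x, ...) {
  nj <- nrow(x$vertices) - length(x$tips) - 1L
  cp <- cost_pair(x)
  cat("Transport tree: ", length(x$tips), " tip(s), ", nj, " junction(s); ",
      "total length ", format(cp[["total_length"]]), ", travel distance ",
      format(cp[["travel_distance"]]), "\n", sep = "")
  invisible(x)
}

# Parent index of each vertex when rooted at tree$root (NA for unreachable
# vertices and 0 for the root itself); vertices returned in BFS order attr.
tree_parents <- function(tree) {
  nv <- nrow(tree$vertices)
  e1 <- tree$edges[, 1L]; e2 <- tree$edges[, 2L]
  adj <- split(c(e2, e1), factor(c(e1, e2), levels = seq_len(nv)))
  parent <- rep(NA_integer_, nv)
  parent[tree$root] <- 0L
  ord <- integer(nv)
  ord[1L] <- tree$root
  head_ <- 1L; tail_ <- 1L
  while (head_ <= tail_) {
    v <- ord[head_]; head_ <- head_ + 1L
    for (u in adj[[v]]) {
      if (is.na(parent[u])) {
        parent[u] <- v
        tail_ <- tail_ + 1L
        ord[tail_] <- u
      }
    }
  }
  attr(parent, "bfs_order") <- ord[seq_len(tail_)]
  parent
}

# Along-tree distance of every vertex from the root.
tree_depths <- function(tree, parent = tree_parents(tree)) {
  ord <- attr(parent, "bfs_order")
  depth <- rep(NA_real_, nrow(tree$vertices))
  depth[tree$root] <- 0
  for (v in ord[-1L]) {
    depth[v] <- depth[parent[v]] + edist(tree$vertices[v, ],
                                         tree$vertices[parent[v], ])
  }
  depth
}

#' @rdname cost_pair
#' @export
cost_pair.rsa_tree <- function(x, ...) {
  lens <- sqrt(rowSums((x$vertices[x$edges[, 1L], , drop = FALSE] -
                        x$vertices[x$edges[, 2L], , drop = FALSE])^2))
  depth <- tree_depths(x)
  new_cost_pair(sum(lens), sum(depth[x$tips]))
}

# Number of terminal tips routed through each edge (edge order preserved):
# tips in the subtree hanging below the edge when rooted at tree$root.
edge_tip_counts <- function(tree, parent = tree_parents(tree)) {
  nv <- nrow(tree$vertices)
  cnt <- integer(nv)
  cnt[tree$tips] <- 1L
  ord <- attr(parent, "bfs_order")
  for (v in rev(ord)) {
    if (parent[v] > 0L) cnt[parent[v]] <- cnt[parent[v]] + cnt[v]
  }
  # edge (a,b): the child endpoint determines the subtree
  child <- ifelse(parent[tree$edges[, 1L]] == tree$edges[, 2L],
                  tree$edges[, 1L], tree$edges[, 2L])
  cnt[child]
}

# Joint-objective weight of each edge.
edge_weights <- function(tree, alpha, parent = tree_parents(tree)) {
  alpha + (1 - alpha) * edge_tip_counts(tree, parent)
}

#' Weighted cost-efficiency objective of a tree
#'
#' Evaluates `alpha * total_length + (1 - alpha) * travel_distance`, the
#' linear scalarization whose minimizers over all candidate trees sweep the
#' Pareto front from the satellite star (`alpha = 0`) to the Steiner tree
#' (`alpha = 1`).
#'
#' @param tree an `rsa_tree`, a [root_graph()], or a `cost_pair`.
#' @param alpha weight in `[0, 1]`.
#' @return The scalar objective value.
#' @export
#' @examples
#' star <- satellite_tree(terminal_set(c(0, 0), rbind(c(3, 4), c(-3, 4))))
#' joint_objective(star, 0.5) # 10 at any alpha: cost = travel = 10
joint_objective <- function(tree, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha < 0 || alpha > 1) {
    stop("alpha must be a single value in [0, 1]", call. = FALSE)
  }
  cp <- if (inherits(tree, "cost_pair")) tree else cost_pair(tree)
  alpha * cp[["total_length"]] + (1 - alpha) * cp[["travel_distance"]]
}
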