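#' Construct a traced root-system graph
#'
#' A `root_graph` is the data model for a traced 2D root system: a set of
#' nodes with image-convention coordinates (y increases downward), parent
#' links forming a single arborescence rooted at the hypocotyl base, and an
#' integer root order per node (0 = primary root, 1 = first-order lateral,
#' and so on).
#'
#' @param nodes data frame with columns `id` (unique integers), `x`, `y`
#'   (finite coordinates), `parent` (id of the parent node, `NA` for the
#'   hypocotyl base) and `order` (non-negative integer root order).
#' @param scale optional length-per-pixel factor applied to all reported
#'   lengths (default 1, i.e. pixel units).
#' @param metadata free-form named list (plant id, genotype, condition, day,
#'   ...), passed through unchanged by readers and writers.
#'
#' @return An object of class `root_graph`.
#' @seealso [read_root_json()], [read_rsml()], [extract_terminals()],
#'   [cost_pair()]
#' @export
#' @examples
#' g <- root_graph(data.frame(
#'   id = 1:3, x = c(0, 0, 0), y = c(0, 2, 4),
#'   parent = c(NA, 1, 2), order = 0L
#' ))
#' cost_pair(g)
root_graph <- function(nodes, scale = 1, metadata = list()) {
  stopifnot(is.data.frame(nodes))
  need <- c("id", "x", "y", "parent", "order")
  miss <- setdiff(need, names(nodes))
  if (length(miss) > 0) {
    stop("root graph: nodes lack column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  nodes <- nodes[, need]
  nodes$id <- as.integer(nodes$id)
  nodes$parent <- suppressWarnings(as.integer(nodes$parent))
  nodes$order <- as.integer(nodes$order)
  g <- structure(
    list(nodes = nodes, scale = scale %||% 1, metadata = metadata),
    class = "root_graph"
  )
  validate_root_graph(g)
}

#' Validate a root graph
#'
#' Checks all structural invariants: unique ids, numeric finite coordinates,
#' exactly one parentless node (the hypocotyl base), parent links that form a
#' single arborescence (connected and acyclic), non-negative root orders and
#' at least two nodes. Errors name the offending node.
#'
#' @param g a [root_graph()].
#' @return `g`, invisibly unchanged, if valid; otherwise an error is thrown.
#' @export
validate_root_graph <- function(g) {
  if (!inherits(g, "root_graph")) stop("not a root_graph", call. = FALSE)
  n <- g$nodes
  if (nrow(n) < 2L) stop("root graph: fewer than 2 nodes", call. = FALSE)
  if (anyNA(n$id)) stop("root graph: missing node id", call. = FALSE)
  if (anyDuplicated(n$id)) {
    stop("root graph: duplicate node id ", n$id[duplicated(n$id)][1L],
         call. = FALSE)
  }
  bad <- !is.finite(n$x) | !is.finite(n$y)
  if (any(bad)) {
    stop("root graph: non-numeric coordinates at node ", n$id[bad][1L],
         call. = FALSE)
  }
  if (anyNA(n$order) || any(n$order < 0L)) {
    stop("root graph: negative or missing root order at node ",
         n$id[which(is.na(n$order) | n$order < 0L)[1L]], call. = FALSE)
  }
  if (!is.numeric(g$scale) || length(g$scale) != 1L || !is.finite(g$scale) ||
      g$scale <= 0) {
    stop("root graph: scale must be a positive number", call. = FALSE)
  }
  rootless <- which(is.na(n$parent))
  if (length(rootless) == 0L) {
    stop("root graph: no parentless node (multiple roots or cycle)",
         call. = FALSE)
  }
  if (length(rootless) > 1L) {
    stop("root graph: multiple roots (nodes ",
         paste(n$id[rootless], collapse = ", "), ")", call. = FALSE)
  }
  idx <- match(n$parent, n$id)
  orphan <- which(!is.na(n$parent) & is.na(idx))
  if (length(orphan) > 0L) {
    stop("root graph: node ", n$id[orphan[1L]], " has unknown parent ",
         n$parent[orphan[1L]], call. = FALSE)
  }
  # Walk each node towards the root; more than nrow steps means a cycle.
  nn <- nrow(n)
  for (i in seq_len(nn)) {
    j <- i
    steps <- 0L
    while (!is.na(n$parent[j])) {
      if (n$parent[j] == n$id[j]) {
        stop("root graph: cycle at node ", n$id[j], " (self parent)",
             call. = FALSE)
      }
      j <- idx[j]
      steps <- steps + 1L
      if (steps > nn) {
        stop("root graph: cycle involving node ", n$id[i], call. = FALSE)
      }
    }
  }
  invisible(g)
}

#' @export
print.root_graph <- function(x, ...) {
  n <- x$nodes
  tips <- graph_leaves(x)
  cat("Traced root system: ", nrow(n), " nodes, ", nrow(n) - 1L, " edges, ",
      length(tips), " tip(s)\n", sep = "")
  cat("  scale: ", format(x$scale), " length/px; max order: ",
      max(n$order), "\n", sep = "")
  if (length(x$metadata) > 0) {
    kv <- vapply(x$metadata, function(v) paste(format(v), collapse = ","), "")
    cat("  metadata: ",
        paste(names(kv), kv, sep = "=", collapse = "; "), "\n", sep = "")
  }
  invisible(x)
}

# --- internal graph helpers -------------------------------------------------

graph_root_index <- function(g) which(is.na(g$nodes$parent))

# Leaves (out-degree 0) in deterministic traversal order: depth-first from the
# root, children visited in ascending id.
graph_leaves <- function(g) {
  n <- g$nodes
  kids <- split(seq_len(nrow(n)), factor(n$parent, levels = n$id))
  root <- graph_root_index(g)
  ord <- integer(0)
  stack <- root
  while (length(stack) > 0L) {
    v <- stack[[1L]]
    stack <- stack[-1L]
    ord <- c(ord, v)
    ch <- kids[[as.character(n$id[v])]]
    if (length(ch) > 0L) {
      ch <- ch[order(n$id[ch])]
      stack <- c(ch, stack)
    }
  }
  has_child <- n$id %in% n$parent
  ord[!has_child[ord]]
}

#' Extract the terminal set of a root graph
#'
#' The terminals are the inputs of the Pareto analysis: the hypocotyl base
#' (the parentless node) and every root tip (leaf of the arborescence), in
#' deterministic depth-first traversal order with ties broken by ascending
#' node id. Coordinates are returned in scaled units (`scale` applied), so
#' that fronts built from the terminals are commensurate with [cost_pair()]
#' of the graph itself.
#'
#' @param graph a [root_graph()].
#' @return An object of class `terminal_set`: a list with `rho0` (length-2
#'   numeric), `tips` (matrix with one row per tip) and `tip_ids`.
#' @export
#' @examples
#' g <- root_graph(data.frame(
#'   id = 1:3, x = c(0, 0, 0), y = c(0, 2, 4),
#'   parent = c(NA, 1, 2), order = 0L
#' ))
#' extract_terminals(g)
extract_terminals <- function(graph) {
  validate_root_graph(graph)
  n <- graph$nodes
  root <- graph_root_index(graph)
  leaves <- graph_leaves(graph)
  s <- graph$scale
  structure(
    list(
      rho0 = c(x = n$x[root] * s, y = n$y[root] * s),
      tips = cbind(x = n$x[leaves] * s, y = n$y[leaves] * s),
      tip_ids = n$id[leaves]
    ),
    class = "terminal_set"
  )
}

#' @export
print.terminal_set <- function(x, ...) {
  cat("Terminal set: rho0 = (", format(x$rho0[1]), ", ", format(x$rho0[2]),
      "), ", nrow(x$tips), " tip(s)\n", sep = "")
  invisible(x)
}

#' Construct a terminal set directly from coordinates
#'
#' Convenience constructor for synthetic instances: the hypocotyl base and
#' tip coordinates are given explicitly instead of being extracted from a
#' traced graph.
#'
#' @param rho0 length-2 numeric, position of the hypocotyl base.
#' @param tips matrix with one row per tip (columns x, y).
#' @return A `terminal_set`.
#' @export
#' @examples
#' terminal_set(c(0, 0), rbind(c(1, 1), c(-1, 1)))
terminal_set <- function(rho0, tips) {
  tips <- matrix(as.numeric(tips), ncol = 2L,
                 dimnames = list(NULL, c("x", "y")))
  if (nrow(tips) < 1L) stop("terminal set needs at least one tip",
                            call. = FALSE)
  structure(list(rho0 = c(x = rho0[[1]], y = rho0[[2]]), tips = tips,
                 tip_ids = seq_len(nrow(tips))),
            class = "terminal_set")
}

# --- cost pair --------------------------------------------------------------

#' Total length and travel distance of a root network
#'
#' The two competing objectives of the cost-efficiency tradeoff. Total length
#' (the construction cost) is the sum of all edge lengths; travel distance
#' (the transport-efficiency proxy) is the sum, over root tips, of the
#' along-network path length from the hypocotyl base to the tip. For a
#' [root_graph()] the tips are its leaves and lengths are reported in scaled
#' units; for a candidate tree over a terminal set (see [satellite_tree()],
#' [greedy_joint_tree()]) the tips are the terminal tips, whether or not the
#' tree routes other edges through them.
#'
#' @param x a [root_graph()] or an `rsa_tree`.
#' @param ... unused.
#' @return A `cost_pair`: named numeric vector with components `total_length`
#'   and `travel_distance`.
#' @export
#' @examples
#' star <- satellite_tree(terminal_set(c(0, 0), rbind(c(3, 4), c(-3, 4))))
#' cost_pair(star) # both components 10
cost_pair <- function(x, ...) UseMethod("cost_pair")

new_cost_pair <- function(total_length, travel_distance) {
  structure(c(total_length = total_length, travel_distance = travel_distance),
            class = "cost_pair")
}

#' @export
print.cost_pair <- function(x, ...) {
  cat("cost pair: total length = ", format(x[["total_length"]]),
      ", travel distance = ", format(x[["travel_distance"]]), "\n", sep = "")
  invisible(x)
}

#' @rdname cost_pair
#' @export
cost_pair.root_graph <- function(x, ...) {
  validate_root_graph(x)
  n <- x$nodes
  idx <- match(n$parent, n$id)
  root <- graph_root_index(x)
  has_parent <- !is.na(idx)
  elen <- rep(0, nrow(n))
  elen[has_parent] <- sqrt((n$x[has_parent] - n$x[idx[has_parent]])^2 +
                           (n$y[has_parent] - n$y[idx[has_parent]])^2)
  # depth = along-tree distance from the root, accumulated in BFS order
  depth <- rep(NA_real_, nrow(n))
  depth[root] <- 0
  frontier <- root
  while (length(frontier) > 0L) {
    ch <- which(has_parent & idx %in% frontier & is.na(depth))
    if (length(ch) == 0L) break
    depth[ch] <- depth[idx[ch]] + elen[ch]
    frontier <- ch
  }
  leaves <- graph_leaves(x)
  new_cost_pair(sum(elen) * x$scale, sum(depth[leaves]) * x$scale)
}
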