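#' Read a traced root system from an RSML file
#'
#' Consumes the Root System Markup Language (XML) geometry: the first
#' `<plant>` of the scene, its single top-level `<root>` (the primary root)
#' and arbitrarily nested child `<root>` elements. Each root contributes its
#' `geometry/polyline/point` vertices (attributes `x`, `y`) as graph nodes;
#' a child root is attached at the geometrically nearest vertex of its parent
#' polyline (a deterministic approximation: no interpolated attachment point
#' is created). When the child polyline starts exactly on its parent (shared
#' branch point, as written by [write_rsml()]), the duplicated first point is
#' dropped. Root orders follow nesting depth. Functions and annotations are
#' ignored; only 2D geometry is consumed.
#'
#' @param path path to an RSML file.
#' @param scale optional length-per-pixel factor stored on the result.
#' @return A validated [root_graph()].
#' @export
read_rsml <- function(path, scale = 1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  plants <- xml2::xml_find_all(doc, ".//scene/plant")
  if (length(plants) == 0L || length(xml2::xml_find_all(doc, ".//root")) == 0L) {
    stop("RSML: empty scene (no <root> element) in ", path, call. = FALSE)
  }
  if (length(plants) > 1L) {
    warning("RSML: multiple plants; reading the first one")
  }
  top <- xml2::xml_find_all(plants[[1L]], "./root")
  if (length(top) == 0L) {
    stop("RSML: empty scene (no <root> element) in ", path, call. = FALSE)
  }
  if (length(top) > 1L) {
    stop("RSML: orphan root (", length(top), " top-level roots; expected a ",
         "single primary)", call. = FALSE)
  }

  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env$next_id <- 1L

  add_node <- function(x, y, parent, ord) {
    id <- env$next_id
    env$next_id <- id + 1L
    env$nodes[[id]] <- data.frame(id = id, x = x, y = y,
                                  parent = parent, order = ord)
    id
  }

  parse_root <- function(node, parent_pts, parent_ids, ord) {
    pts <- xml2::xml_find_all(node, "./geometry/polyline/point")
    if (length(pts) == 0L) {
      stop("RSML: orphan root with no polyline geometry", call. = FALSE)
    }
    xs <- as.numeric(xml2::xml_attr(pts, "x"))
    ys <- as.numeric(xml2::xml_attr(pts, "y"))
    if (anyNA(xs) || anyNA(ys)) {
      stop("RSML: non-numeric point coordinates", call. = FALSE)
    }
    ids <- integer(length(xs))
    if (is.null(parent_pts)) {                       # primary root
      prev <- NA_integer_
      start <- 1L
    } else {                                         # lateral: attach
      d <- cross_dist(cbind(xs[1L], ys[1L]), parent_pts)
      j <- which.min(d)
      tolr <- 1e-9 * max(1, max(abs(parent_pts)))
      prev <- parent_ids[j]
      start <- if (d[j] <= tolr) 2L else 1L          # drop duplicated point
      if (start > length(xs)) {
        stop("RSML: lateral polyline has no points beyond its branch point",
             call. = FALSE)
      }
    }
    for (k in seq(start, length(xs))) {
      prev <- add_node(xs[k], ys[k], prev, ord)
      ids[k] <- prev
    }
    if (start == 2L) ids[1L] <- parent_ids[which.min(
      cross_dist(cbind(xs[1L], ys[1L]), parent_pts))]
    for (child in xml2::xml_find_all(node, "./root")) {
      parse_root(child, cbind(xs, ys), ids, ord + 1L)
    }
    invisible(NULL)
  }

  parse_root(top[[1L]], NULL, NULL, 0L)
  nodes <- do.call(rbind, env$nodes)
  root_graph(nodes, scale = scale, metadata = list(source = basename(path)))
}

#' Write a traced root system to RSML
#'
#' Decomposes the graph into per-order root chains (the maximal same-order
#' paths) and writes them as nested `<root>` polylines. Each lateral polyline
#' begins at its branch point on the parent, so [read_rsml()] reattaches it
#' exactly and a write/read round trip preserves node count and total length.
#'
#' @param graph a [root_graph()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_rsml <- function(graph, path) {
  validate_root_graph(graph)
  n <- graph$nodes
  idx <- match(n$parent, n$id)

  # Chain decomposition: a node continues its parent's polyline iff it has
  # the same root order and is the first (lowest-id) such child; every other
  # node starts a new chain. This keeps each chain a simple path even when a
  # root bifurcates into two same-order children.
  nn <- nrow(n)
  cont <- rep(FALSE, nn)
  for (v in seq_len(nn)) {
    p <- idx[v]
    if (is.na(p) || n$order[v] != n$order[p]) next
    sibs <- which(!is.na(idx) & idx == p & n$order == n$order[p])
    cont[v] <- v == sibs[order(n$id[sibs])][1L]
  }
  starts <- which(!cont)
  chain_of <- integer(nn)
  for (s in starts) {
    v <- s
    repeat {
      chain_of[v] <- s
      nxt <- which(cont & !is.na(idx) & idx == v)
      if (length(nxt) == 0L) break
      v <- nxt[1L]
    }
  }

  fmt <- function(v) sprintf("%.17g", v)
  chain_xml <- function(s) {
    members <- which(chain_of == s)
    # order members along the chain by walking parents
    depth <- vapply(members, function(v) {
      d <- 0L
      while (!is.na(idx[v]) && chain_of[idx[v]] == s) { v <- idx[v]; d <- d + 1L }
      d
    }, 0L)
    members <- members[order(depth)]
    pts <- character(0)
    if (!is.na(idx[members[1L]])) {   # branch point on the parent root
      p <- idx[members[1L]]
      pts <- sprintf('<point x="%s" y="%s"/>', fmt(n$x[p]), fmt(n$y[p]))
    }
    pts <- c(pts, sprintf('<point x="%s" y="%s"/>',
                          fmt(n$x[members]), fmt(n$y[members])))
    kids <- starts[!is.na(idx[starts]) & chain_of[idx[starts]] == s]
    child_xml <- vapply(kids, chain_xml, "")
    paste0('<root ID="', s, '"><geometry><polyline>',
           paste(pts, collapse = ""),
           "</polyline></geometry>", paste(child_xml, collapse = ""),
           "</root>")
  }

  primary <- starts[is.na(idx[starts])]
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    "<rsml><metadata><version>1</version><unit>pixel</unit></metadata>",
    "<scene><plant>", chain_xml(primary), "</plant></scene></rsml>"
  )
  ok <- tryCatch({ writeLines(xml, path); TRUE }, error = function(e) FALSE)
  if (!ok) stop("cannot write ", path, call. = FALSE)
  invisible(path)
}
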