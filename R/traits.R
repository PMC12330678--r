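#' Extract canonical root system architecture traits
#'
#' Computes the morphological and geometrical trait set from a traced graph:
#' total root length, travel distance, primary root length (the maximal
#' order-0 chain), rooting depth (`max(y) - y(base)`, image convention),
#' width, convex hull area over all node positions, tip and lateral counts,
#' mean lateral length, lateral density (laterals per unit primary length)
#' and primary tortuosity (arc length / chord). Lengths are reported in
#' scaled units (length scales as the coordinate scale, areas as its square,
#' counts and tortuosity are dimensionless). When a fitted [pareto_rsa()] is
#' supplied its scaling distance and alpha value are appended.
#'
#' A lateral root is a maximal chain of nodes of equal order starting where
#' the order increases over the parent; its length includes the emergence
#' edge from the parent root.
#'
#' @param graph a [root_graph()].
#' @param optimality optional `pareto_rsa` fit of the same graph.
#' @return A one-row data frame (a trait record).
#' @export
#' @examples
#' g <- root_graph(data.frame(
#'   id = 1:4, x = c(0, 0, 0, 1.5), y = c(0, 2, 4, 2),
#'   parent = c(NA, 1, 2, 2), order = c(0L, 0L, 0L, 1L)
#' ))
#' extract_traits(g)
extract_traits <- function(graph, optimality = NULL) {
  validate_root_graph(graph)
  n <- graph$nodes
  s <- graph$scale
  idx <- match(n$parent, n$id)
  root <- graph_root_index(graph)
  cp <- cost_pair(graph)

  elen <- rep(0, nrow(n))
  hp <- !is.na(idx)
  elen[hp] <- sqrt((n$x[hp] - n$x[idx[hp]])^2 + (n$y[hp] - n$y[idx[hp]])^2)

  # primary root: edges between two order-0 nodes
  on_primary <- hp & n$order == 0L & n$order[idx] == 0L
  primary_len <- sum(elen[on_primary]) * s
  primary_nodes <- which(n$order == 0L)
  # primary tip: the order-0 node with no order-0 child
  has_o0_child <- n$id %in% n$parent[which(n$order == 0L)]
  ptip <- primary_nodes[!has_o0_child[primary_nodes]][1L]
  chord <- edist(c(n$x[root], n$y[root]), c(n$x[ptip], n$y[ptip])) * s
  tortuosity <- if (primary_len > 0 && chord > 0) primary_len / chord else 1

  # laterals: nodes whose order exceeds the parent's start a lateral chain
  lat_start <- which(hp & n$order > n$order[idx])
  lat_lengths <- vapply(lat_start, function(v) {
    total <- elen[v]
    repeat {
      nxt <- which(hp & idx == v & n$order == n$order[v])
      if (length(nxt) == 0L) break
      v <- nxt[1L]
      total <- total + elen[v]
    }
    total * s
  }, numeric(1L))

  hull_area <- convex_hull_area(n$x, n$y) * s^2
  leaves <- graph_leaves(graph)

  data.frame(
    plant_id = as.character(graph$metadata$plant_id %||% NA_character_),
    day = as.numeric(graph$metadata$day %||% NA_real_),
    genotype = as.character(graph$metadata$genotype %||% NA_character_),
    condition = as.character(graph$metadata$condition %||% NA_character_),
    total_root_length = cp[["total_length"]],
    travel_distance = cp[["travel_distance"]],
    primary_root_length = primary_len,
    depth = (max(n$y) - n$y[root]) * s,
    width = (max(n$x) - min(n$x)) * s,
    convex_hull_area = hull_area,
    n_tips = length(leaves),
    n_lateral_roots = length(lat_start),
    mean_lateral_length = if (length(lat_lengths) > 0) mean(lat_lengths)
                          else NA_real_,
    lateral_density = if (primary_len > 0) length(lat_start) / primary_len
                      else NA_real_,
    primary_tortuosity = tortuosity,
    scaling_distance = if (is.null(optimality)) NA_real_ else
      optimality$scaling_distance,
    alpha_value = if (is.null(optimality)) NA_real_ else
      optimality$alpha_value,
    stringsAsFactors = FALSE
  )
}

# Shoelace area of the convex hull of a point set (0 for collinear sets).
convex_hull_area <- function(x, y) {
  pts <- unique(cbind(x, y))
  if (nrow(pts) < 3L) return(0)
  h <- chull(pts[, 1L], pts[, 2L])
  hx <- pts[h, 1L]; hy <- pts[h, 2L]
  k <- length(h)
  if (k < 3L) return(0)
  abs(sum(hx * hy[c(2:k, 1L)] - hx[c(2:k, 1L)] * hy)) / 2
}

#' Per-day growth rates from a traced time series
#'
#' For each consecutive pair of days, computes the finite-difference rate
#' `(trait(t2) - trait(t1)) / (t2 - t1)` of every length and count trait.
#' Negative length rates are physically impossible for a growing root and are
#' flagged as tracing-inconsistency warnings.
#'
#' @param series list of `list(day = <number>, graph = <root_graph>)`,
#'   strictly increasing in day, same plant.
#' @return Data frame with one row per consecutive interval: `day_start`,
#'   `day_end` and one `<trait>_rate` column per dynamic trait.
#' @export
growth_dynamics <- function(series) {
  if (length(series) < 2L) stop("need at least 2 time points", call. = FALSE)
  days <- vapply(series, function(s) as.numeric(s$day), numeric(1L))
  if (any(diff(days) <= 0)) {
    stop("days must be strictly increasing", call. = FALSE)
  }
  traits <- do.call(rbind, lapply(series, function(s) {
    extract_traits(s$graph)
  }))
  dynamic <- c("total_root_length", "travel_distance", "primary_root_length",
               "depth", "width", "convex_hull_area", "n_tips",
               "n_lateral_roots")
  out <- lapply(seq_len(length(series) - 1L), function(i) {
    dt <- days[i + 1L] - days[i]
    rates <- (traits[i + 1L, dynamic] - traits[i, dynamic]) / dt
    names(rates) <- paste0(dynamic, "_rate")
    cbind(data.frame(day_start = days[i], day_end = days[i + 1L]), rates)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  lengthy <- paste0(c("total_root_length", "primary_root_length", "depth"),
                    "_rate")
  if (any(as.matrix(out[, lengthy]) < 0)) {
    warning("negative length growth rate: tracing inconsistency between days")
  }
  out
}

#' Aggregate trait records into group means
#'
#' Condenses per-plant trait records to group means (e.g. per condition,
#' genotype and day, averaging the plants of each group before downstream
#' modeling). All numeric traits are averaged per key combination; a group
#' count column `n` is appended and rows are ordered by the sorted keys.
#'
#' @param records data frame of trait records (see [extract_traits()]).
#' @param keys character vector of categorical column names to group by.
#' @return Aggregated data frame, one row per key combination.
#' @export
aggregate_table <- function(records, keys) {
  if (nrow(records) == 0L) stop("no records", call. = FALSE)
  unknown <- setdiff(keys, names(records))
  if (length(unknown) > 0L) {
    stop("unknown aggregation key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  num <- names(records)[vapply(records, is.numeric, TRUE)]
  num <- setdiff(num, keys)
  groups <- records[, keys, drop = FALSE]
  key_str <- do.call(paste, c(groups, sep = "\r"))
  split_idx <- split(seq_len(nrow(records)), key_str)
  rows <- lapply(split_idx, function(ii) {
    g <- records[ii[1L], keys, drop = FALSE]
    means <- as.data.frame(as.list(colMeans(records[ii, num, drop = FALSE],
                                            na.rm = TRUE)))
    cbind(g, means, n = length(ii))
  })
  out <- do.call(rbind, rows)
  out <- out[do.call(order, out[, keys, drop = FALSE]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-hot encode categorical columns
#'
#' Export option for downstream machine learning: each categorical column is
#' replaced by one binary indicator column per observed level
#' (`<column>.<level>`). Numeric columns pass through unchanged.
#'
#' @param df a data frame.
#' @param columns columns to encode; default every character/factor column.
#' @return A data frame with indicator columns.
#' @export
one_hot_encode <- function(df, columns = NULL) {
  if (is.null(columns)) {
    columns <- names(df)[vapply(df, function(v)
      is.character(v) || is.factor(v), TRUE)]
  }
  out <- df[, setdiff(names(df), columns), drop = FALSE]
  for (col in columns) {
    v <- as.character(df[[col]])
    for (lev in sort(unique(v))) {
      out[[paste(col, lev, sep = ".")]] <- as.integer(v == lev)
    }
  }
  out
}
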