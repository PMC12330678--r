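#' Pareto-optimality analysis of a traced root system
#'
#' The central fitting function. The terminals (hypocotyl base and root tips)
#' are extracted from the traced graph, the Pareto front of the joint
#' objective `alpha * total length + (1 - alpha) * travel distance` is built
#' over those terminals, and the measured architecture is projected onto the
#' front using its bona fide cost (total root length) and transport
#' efficiency (travel distance): its scaling distance to the front and alpha
#' value quantify, respectively, how close to optimal and where on the
#' cost-efficiency spectrum the plant sits. A uniform random spanning tree
#' null model over the same terminals calibrates how non-random the plant
#' architecture is: the barycenter of the random trees is compared to the
#' same front.
#'
#' Only the terminal positions shape the front; the branch geometry of the
#' real plant enters through its own cost pair. All results are deterministic
#' given `seed`.
#'
#' @param graph a [root_graph()] (from [read_root_json()], [read_rsml()] or
#'   [generate_root_system()]).
#' @param alpha_step grid step for the front (default 0.01, giving 101
#'   two-decimal alpha values).
#' @param null_n number of random spanning trees (default 1000); 0 skips the
#'   null model.
#' @param seed integer seed for the null sampler.
#' @param method `"greedy"` for the heuristic front (any instance size) or
#'   `"exact"` for the exhaustive oracle front (at most 4 tips).
#' @return An object of class `pareto_rsa` with components `actual`
#'   (cost pair), `front`, `scaling_distance`, `alpha_value`,
#'   `euclidean_distance`, `null` (or `NULL`), `terminals`, `metadata`,
#'   `seed`, `alpha_step`.
#' @seealso [scaling_distance()], [build_front()], [sample_random_trees()]
#' @export
#' @examples
#' g <- generate_root_system(sim_params(primary_length = 30, seed = 7))
#' fit <- pareto_rsa(g, null_n = 50)
#' fit
#' coef(fit)
pareto_rsa <- function(graph, alpha_step = 0.01, null_n = 1000L, seed = 1L,
                       method = c("greedy", "exact")) {
  method <- match.arg(method)
  validate_root_graph(graph)
  if (nrow(graph$nodes) < 2L) stop("graph too small", call. = FALSE)
  if (alpha_step <= 0 || alpha_step > 0.5) {
    stop("alpha_step must lie in (0, 0.5]", call. = FALSE)
  }
  terminals <- extract_terminals(graph)
  grid <- unique(c(seq(0, 1, by = alpha_step), 1))
  front <- if (method == "exact") {
    brute_force_front(terminals, grid)
  } else {
    build_front(terminals, grid)
  }
  actual <- cost_pair(graph)
  sd <- scaling_distance(actual, front)
  null <- NULL
  if (null_n > 0L) {
    samples <- sample_random_trees(terminals, null_n, seed = seed)
    null <- null_summary(samples, front, seed = seed)
  }
  structure(
    list(
      actual = actual,
      front = front,
      scaling_distance = sd$distance,
      alpha_value = sd$alpha_value,
      euclidean_distance = sd$euclidean,
      null = null,
      terminals = terminals,
      metadata = graph$metadata,
      seed = as.integer(seed),
      alpha_step = alpha_step,
      method = method,
      call = match.call()
    ),
    class = "pareto_rsa"
  )
}

#' @export
print.pareto_rsa <- function(x, ...) {
  cat("Pareto optimality of a root system (", nrow(x$terminals$tips),
      " tip(s), ", x$method, " front)\n", sep = "")
  cat("  total length    ", format(x$actual[["total_length"]]), "\n",
      "  travel distance ", format(x$actual[["travel_distance"]]), "\n",
      sep = "")
  cat("  scaling distance to front: ", format(x$scaling_distance),
      "   alpha value: ", format(x$alpha_value), "\n", sep = "")
  if (!is.null(x$null)) {
    cat("  null barycenter scaling distance: ",
        format(x$null$barycenter_scaling_distance), " (", x$null$n_samples,
        " random trees)\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.pareto_rsa <- function(object, ...) {
  structure(list(fit = object), class = "summary.pareto_rsa")
}

#' @export
print.summary.pareto_rsa <- function(x, ...) {
  f <- x$fit
  print(f)
  p <- f$front$points
  cat("\nFront: ", nrow(p), " point(s); endpoints ",
      "(", format(p$total_length[1L]), ", ", format(p$travel_distance[1L]),
      ") at alpha ", format(p$alpha[1L]), " -> (",
      format(p$total_length[nrow(p)]), ", ",
      format(p$travel_distance[nrow(p)]), ") at alpha ",
      format(p$alpha[nrow(p)]), "\n", sep = "")
  cat("Euclidean distance to front (diagnostic): ",
      format(f$euclidean_distance), "\n", sep = "")
  if (length(f$metadata) > 0) {
    kv <- vapply(f$metadata, function(v) paste(format(v), collapse = ","), "")
    cat("Metadata: ", paste(names(kv), kv, sep = "=", collapse = "; "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.pareto_rsa <- function(object, ...) {
  c(alpha_value = object$alpha_value,
    scaling_distance = object$scaling_distance,
    total_length = object$actual[["total_length"]],
    travel_distance = object$actual[["travel_distance"]],
    euclidean_distance = object$euclidean_distance)
}

#' Plot a fitted Pareto-optimality analysis
#'
#' Draws the Pareto front in (total length, travel distance) space, the
#' measured plant, the random-tree cloud and its barycenter.
#'
#' @param x a `pareto_rsa` fit.
#' @param show_null logical; overlay the random-tree samples.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pareto_rsa <- function(x, show_null = TRUE, ...) {
  p <- x$front$points
  xs <- c(p$total_length, x$actual[["total_length"]])
  ys <- c(p$travel_distance, x$actual[["travel_distance"]])
  if (show_null && !is.null(x$null)) {
    xs <- c(xs, x$null$sample_costs$total_length)
    ys <- c(ys, x$null$sample_costs$travel_distance)
  }
  plot(range(xs), range(ys), type = "n",
       xlab = "total length (cost)", ylab = "travel distance", ...)
  if (show_null && !is.null(x$null)) {
    points(x$null$sample_costs$total_length,
           x$null$sample_costs$travel_distance,
           pch = 4, col = "darkgreen", cex = 0.5)
    points(x$null$barycenter[["total_length"]],
           x$null$barycenter[["travel_distance"]],
           pch = 17, col = "blue", cex = 1.2)
  }
  lines(p$total_length, p$travel_distance, col = "grey30")
  points(p$total_length, p$travel_distance, pch = 16, cex = 0.6)
  points(x$actual[["total_length"]], x$actual[["travel_distance"]],
         pch = 19, col = "red", cex = 1.2)
  legend("topleft", bty = "n",
         legend = c("Pareto front", "plant", "random trees", "barycenter"),
         col = c("grey30", "red", "darkgreen", "blue"),
         pch = c(16, 19, 4, 17), cex = 0.8)
  invisible(x)
}

#' Simulate from the null model of a fitted analysis
#'
#' Draws fresh uniform random spanning trees over the fitted terminals and
#' returns their cost pairs — the stochastic reference distribution the
#' plant's position is compared against.
#'
#' @param object a `pareto_rsa` fit.
#' @param nsim number of trees.
#' @param seed integer seed (defaults to the fit's seed).
#' @param ... unused.
#' @return Data frame with columns `total_length` and `travel_distance`.
#' @export
simulate.pareto_rsa <- function(object, nsim = 1L, seed = NULL, ...) {
  seed <- seed %||% object$seed
  samples <- sample_random_trees(object$terminals, nsim, seed = seed)
  costs <- t(vapply(samples, cost_pair, numeric(2L)))
  data.frame(total_length = costs[, 1L], travel_distance = costs[, 2L])
}

#' One-row data frame summary of a fitted analysis
#'
#' The CSV-export form: plant metadata, cost pair, scaling distance, alpha
#' value, null-model barycenter values, seed and grid step.
#'
#' @param x a `pareto_rsa` fit.
#' @param ... unused.
#' @export
as.data.frame.pareto_rsa <- function(x, ...) {
  meta <- x$metadata
  data.frame(
    plant_id = as.character(meta$plant_id %||% NA_character_),
    genotype = as.character(meta$genotype %||% NA_character_),
    condition = as.character(meta$condition %||% NA_character_),
    day = as.numeric(meta$day %||% NA_real_),
    n_tips = nrow(x$terminals$tips),
    total_length = x$actual[["total_length"]],
    travel_distance = x$actual[["travel_distance"]],
    scaling_distance = x$scaling_distance,
    alpha_value = x$alpha_value,
    euclidean_distance = x$euclidean_distance,
    null_n = if (is.null(x$null)) 0L else x$null$n_samples,
    null_total_length = if (is.null(x$null)) NA_real_ else
      x$null$barycenter[["total_length"]],
    null_travel_distance = if (is.null(x$null)) NA_real_ else
      x$null$barycenter[["travel_distance"]],
    null_scaling_distance = if (is.null(x$null)) NA_real_ else
      x$null$barycenter_scaling_distance,
    null_alpha = if (is.null(x$null)) NA_real_ else x$null$barycenter_alpha,
    seed = x$seed,
    alpha_step = x$alpha_step,
    stringsAsFactors = FALSE
  )
}
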