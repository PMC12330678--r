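#' Scaling distance of an architecture to the Pareto front
#'
#' The Pareto optimality value of a measured architecture: the factor by
#' which its (total length, travel distance) pair exceeds the nearest front
#' point, measured as the minimum over front points of
#' `max(length / front length, travel / front travel)`. A tree that lies on
#' the front scores exactly 1; architectures off the front score above 1 (up
#' to heuristic-front slack). The alpha of the minimizing front point is the
#' architecture's alpha value (cost-efficiency tradeoff); ties go to the
#' smallest alpha. The raw Euclidean distance in (cost, travel) space is
#' returned as an auxiliary diagnostic.
#'
#' @param actual a `cost_pair` (or length-2 numeric: total length, travel
#'   distance) of the measured architecture.
#' @param front a `pareto_front` over the same terminals and units.
#' @return A list with `distance`, `alpha_value`, `euclidean` and `index`
#'   (row of the minimizing front point).
#' @export
#' @examples
#' ts <- terminal_set(c(0, 0), rbind(c(0, 1), c(0, 2)))
#' fr <- brute_force_front(ts, seq(0, 1, by = 0.25))
#' scaling_distance(c(3, 3), fr) # satellite star vs front {(2, 3)}: 1.5
scaling_distance <- function(actual, front) {
  stopifnot(inherits(front, "pareto_front"))
  p <- front$points
  if (nrow(p) == 0L) stop("empty front", call. = FALSE)
  if (any(p$total_length <= 0) || any(p$travel_distance <= 0)) {
    stop("degenerate front: zero-valued component", call. = FALSE)
  }
  a <- as.numeric(actual)
  if (length(a) != 2L || any(!is.finite(a)) || any(a <= 0)) {
    stop("actual cost pair must be two positive numbers", call. = FALSE)
  }
  ratio <- pmax(a[1L] / p$total_length, a[2L] / p$travel_distance)
  dmin <- min(ratio)
  idx <- which(ratio <= dmin * (1 + 1e-12))[1L]   # smallest alpha on ties
  eucl <- sqrt((a[1L] - p$total_length)^2 + (a[2L] - p$travel_distance)^2)
  list(distance = dmin, alpha_value = p$alpha[idx], euclidean = min(eucl),
       index = idx)
}

#' Sample uniform random spanning trees over the terminals
#'
#' The null model: spanning trees over the terminal set (hypocotyl base plus
#' tips, no junction points) drawn uniformly from all labeled spanning trees
#' of the complete graph on the terminals, via uniform random Prüfer
#' sequences. Travel distances of the samples are computed with the
#' hypocotyl base as root; by Cayley's formula there are `m^(m-2)` such trees
#' on `m` terminals.
#'
#' @param terminals a `terminal_set`.
#' @param n number of samples (>= 1).
#' @param seed integer seed; the sampler is reproducible and leaves the
#'   caller's RNG state untouched.
#' @return A list of `n` `rsa_tree` objects.
#' @export
sample_random_trees <- function(terminals, n, seed = 1L) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  pts <- rbind(terminals$rho0, terminals$tips)
  m <- nrow(pts)
  if (m < 2L) stop("need at least 2 terminals", call. = FALSE)
  tips <- seq.int(2L, m)
  if (m == 2L) {
    tree <- rsa_tree(pts, cbind(1L, 2L), root = 1L, tips = tips)
    return(rep(list(tree), n))
  }
  seqs <- with_seed(seed, matrix(sample.int(m, (m - 2L) * n, replace = TRUE),
                                 nrow = n))
  lapply(seq_len(n), function(i) {
    rsa_tree(pts, prufer_decode(seqs[i, ], m), root = 1L, tips = tips)
  })
}

#' Summarize the random-tree null model against a front
#'
#' Computes the cost pair of every sampled tree, their barycenter
#' (component-wise mean, the one representative random architecture), and
#' the barycenter's scaling distance and alpha value against the same front
#' the measured plant is compared to.
#'
#' @param samples list of `rsa_tree` (see [sample_random_trees()]).
#' @param front a `pareto_front`.
#' @param seed optional seed recorded on the result for provenance.
#' @return An object of class `rsa_null`: `n_samples`, `sample_costs` (data
#'   frame), `barycenter`, `barycenter_scaling_distance`, `barycenter_alpha`,
#'   `seed`.
#' @export
null_summary <- function(samples, front, seed = NA_integer_) {
  if (length(samples) < 1L) stop("need at least one sample", call. = FALSE)
  costs <- t(vapply(samples, cost_pair, numeric(2L)))
  colnames(costs) <- c("total_length", "travel_distance")
  bary <- colMeans(costs)
  sd <- scaling_distance(bary, front)
  structure(
    list(
      n_samples = length(samples),
      sample_costs = as.data.frame(costs),
      barycenter = new_cost_pair(bary[[1L]], bary[[2L]]),
      barycenter_scaling_distance = sd$distance,
      barycenter_alpha = sd$alpha_value,
      seed = seed
    ),
    class = "rsa_null"
  )
}

#' @export
print.rsa_null <- function(x, ...) {
  cat("Random spanning tree null model: ", x$n_samples, " sample(s)\n",
      "  barycenter: total length ", format(x$barycenter[["total_length"]]),
      ", travel distance ", format(x$barycenter[["travel_distance"]]), "\n",
      "  barycenter scaling distance ",
      format(x$barycenter_scaling_distance),
      " (alpha ", format(x$barycenter_alpha), ")\n", sep = "")
  invisible(x)
}
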