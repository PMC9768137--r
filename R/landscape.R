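#' Derive a per-run seed from a base seed, grid node and replicate index
#'
#' Mixes the indices through a Lehmer-style modular recurrence so that every
#' (node, replicate) pair of a sweep gets its own reproducible seed,
#' independent of execution order. All arithmetic stays below 2^31.
#'
#' @param base_seed Integer base seed of the sweep.
#' @param node Grid node index (1-based).
#' @param rep Replicate index (1-based).
#' @return A single integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(base_seed, node, rep) {
  m <- 2147483647 # 2^31 - 1 (Mersenne prime)
  x <- as.double(base_seed) %% m
  x <- (x * 69621 + as.double(node) * 10007 + as.double(rep)) %% m
  x <- (x * 69621 + 12345) %% m
  as.integer(x + 1)
}

#' Define a sweep of the two behavioural probabilities
#'
#' The default schedule is the full factorial grid of P_P and P_D from 0 to
#' 1 in steps of 0.05 (21 x 21 = 441 combinations) with 10 replicate
#' simulations per combination.
#'
#' @param tree_height Tree height in cells for every simulation of the sweep.
#' @param values Probability values used for both axes.
#' @param pp_values,pd_values Per-axis overrides of `values`.
#' @param replicates Replicate simulations per (P_P, P_D) combination.
#' @param n_ants,t_max,cost_coefficient,forage_prob,detection_radius Fixed
#'   simulation settings, as in [simulation_params()] and
#'   [behaviour_params()].
#' @param base_seed Base seed from which each run's seed is derived via
#'   [derive_seed()].
#' @return A list of class `"sweep_schedule"`.
#' @examples
#' nrow(expand.grid(sweep_schedule(20)$pp_values, sweep_schedule(20)$pd_values))
#' @export
sweep_schedule <- function(tree_height, values = seq(0, 1, by = 0.05),
                           pp_values = values, pd_values = values,
                           replicates = 10, n_ants = 25, t_max = 10000,
                           cost_coefficient = 0.3, forage_prob = 0.95,
                           detection_radius = 5, base_seed = 1) {
  pp_values <- sort(unique(as.numeric(pp_values)))
  pd_values <- sort(unique(as.numeric(pd_values)))
  if (any(pp_values < 0 | pp_values > 1) || any(pd_values < 0 | pd_values > 1)) {
    stop("probability values must lie in [0, 1]", call. = FALSE)
  }
  if (replicates < 1) stop("`replicates` must be >= 1", call. = FALSE)
  structure(
    list(
      tree_height = as.integer(tree_height),
      pp_values = pp_values, pd_values = pd_values,
      replicates = as.integer(replicates),
      n_ants = as.integer(n_ants), t_max = as.integer(t_max),
      cost_coefficient = as.numeric(cost_coefficient),
      forage_prob = as.numeric(forage_prob),
      detection_radius = as.integer(detection_radius),
      base_seed = as.integer(base_seed)
    ),
    class = "sweep_schedule"
  )
}

#' Number of (P_P, P_D) combinations in a sweep schedule
#'
#' @param schedule A [sweep_schedule()] object.
#' @return The number of grid nodes (441 for the default schedule).
#' @export
n_combinations <- function(schedule) {
  stopifnot(inherits(schedule, "sweep_schedule"))
  length(schedule$pp_values) * length(schedule$pd_values)
}

#' Run a fitness-landscape sweep
#'
#' Runs `replicates` independent colony simulations at every (P_P, P_D)
#' node of the schedule and averages the resulting fitness omega per node.
#' Each run's seed is derived from the base seed and the node and replicate
#' indices, so the landscape is reproducible and independent of execution
#' order.
#'
#' @param schedule A [sweep_schedule()] object.
#' @param verbose Print one progress line per node to stderr.
#' @return An object of class `"fitness_landscape"`: `pp_values`,
#'   `pd_values`, and matrices `mean_omega`, `sd_omega` and `n_reps` indexed
#'   \[P_P node, P_D node\], plus `tree_height` and the `schedule`. With one
#'   replicate per node the standard deviation is reported as 0.
#' @export
run_sweep <- function(schedule, verbose = FALSE) {
  stopifnot(inherits(schedule, "sweep_schedule"))
  npp <- length(schedule$pp_values)
  npd <- length(schedule$pd_values)
  mean_omega <- matrix(NA_real_, npp, npd)
  sd_omega <- matrix(NA_real_, npp, npd)
  behaviour_base <- behaviour_params(
    forage_prob = schedule$forage_prob,
    detection_radius = schedule$detection_radius
  )
  for (i in seq_len(npp)) {
    for (j in seq_len(npd)) {
      node <- (i - 1L) * npd + j
      b <- behaviour_base
      b$pickup_prob <- schedule$pp_values[i]
      b$drop_prob <- schedule$pd_values[j]
      omegas <- vapply(seq_len(schedule$replicates), function(r) {
        run_colony(simulation_params(
          tree_height = schedule$tree_height, behaviour = b,
          n_ants = schedule$n_ants, t_max = schedule$t_max,
          cost_coefficient = schedule$cost_coefficient,
          seed = derive_seed(schedule$base_seed, node, r)
        ))$omega
      }, numeric(1))
      mean_omega[i, j] <- mean(omegas)
      sd_omega[i, j] <- if (length(omegas) > 1) stats::sd(omegas) else 0
      if (verbose) {
        message(sprintf(
          "node %d/%d (P_P=%.2f, P_D=%.2f): mean omega %.1f",
          node, npp * npd, b$pickup_prob, b$drop_prob, mean_omega[i, j]
        ))
      }
    }
  }
  structure(
    list(
      pp_values = schedule$pp_values, pd_values = schedule$pd_values,
      mean_omega = mean_omega, sd_omega = sd_omega,
      n_reps = matrix(schedule$replicates, npp, npd),
      tree_height = schedule$tree_height,
      schedule = schedule
    ),
    class = "fitness_landscape"
  )
}

#' @export
print.fitness_landscape <- function(x, ...) {
  cat(sprintf(
    "<fitness_landscape> tree height %d: %d x %d grid, mean omega in [%.1f, %.1f]\n",
    x$tree_height, length(x$pp_values), length(x$pd_values),
    min(x$mean_omega), max(x$mean_omega)
  ))
  invisible(x)
}

#' Interpolate colony fitness between landscape nodes
#'
#' Bilinear interpolation of the replicate-averaged fitness on the regular
#' (P_P, P_D) grid. Exact at the grid nodes; this is the fitness lookup the
#' evolutionary simulations use.
#'
#' @param landscape A [run_sweep()] result.
#' @param pp,pd Query pick-up and drop probabilities (vectorised; recycled
#'   to a common length).
#' @return Interpolated mean fitness values.
#' @export
interpolate_fitness <- function(landscape, pp, pd) {
  stopifnot(inherits(landscape, "fitness_landscape"))
  n <- max(length(pp), length(pd))
  pp <- rep_len(as.numeric(pp), n)
  pd <- rep_len(as.numeric(pd), n)
  xs <- landscape$pp_values
  ys <- landscape$pd_values
  if (any(is.na(pp)) || any(is.na(pd)) ||
      any(pp < xs[1]) || any(pp > xs[length(xs)]) ||
      any(pd < ys[1]) || any(pd > ys[length(ys)])) {
    stop("query points must lie within the landscape grid", call. = FALSE)
  }
  i <- pmin(pmax(findInterval(pp, xs), 1L), length(xs) - 1L)
  j <- pmin(pmax(findInterval(pd, ys), 1L), length(ys) - 1L)
  tx <- (pp - xs[i]) / (xs[i + 1L] - xs[i])
  ty <- (pd - ys[j]) / (ys[j + 1L] - ys[j])
  M <- landscape$mean_omega
  (1 - tx) * (1 - ty) * M[cbind(i, j)] +
    tx * (1 - ty) * M[cbind(i + 1L, j)] +
    (1 - tx) * ty * M[cbind(i, j + 1L)] +
    tx * ty * M[cbind(i + 1L, j + 1L)]
}

#' Fitness gradient field of a landscape
#'
#' Finite-difference gradient of the mean fitness at every grid node:
#' central differences at interior nodes, one-sided at the edges. This is
#' the arrow field conventionally drawn over the landscape.
#'
#' @param landscape A [run_sweep()] result.
#' @return A list with matrices `d_pp` and `d_pd` of the partial derivatives
#'   of mean fitness with respect to P_P and P_D at each node.
#' @export
landscape_gradient <- function(landscape) {
  stopifnot(inherits(landscape, "fitness_landscape"))
  M <- landscape$mean_omega
  list(
    d_pp = apply(M, 2, finite_diff, at = landscape$pp_values),
    d_pd = t(apply(M, 1, finite_diff, at = landscape$pd_values))
  )
}

finite_diff <- function(v, at) {
  n <- length(v)
  if (n < 2) return(rep(0, n))
  d <- numeric(n)
  d[1] <- (v[2] - v[1]) / (at[2] - at[1])
  d[n] <- (v[n] - v[n - 1]) / (at[n] - at[n - 1])
  if (n > 2) {
    k <- 2:(n - 1)
    d[k] <- (v[k + 1] - v[k - 1]) / (at[k + 1] - at[k - 1])
  }
  d
}

#' Tabulate a fitness landscape
#'
#' @param landscape A [run_sweep()] result.
#' @return A tibble with one row per grid node: `tree_height`, `pp`, `pd`,
#'   `mean_omega`, `sd_omega`, `n_reps`.
#' @export
landscape_to_tibble <- function(landscape) {
  stopifnot(inherits(landscape, "fitness_landscape"))
  grid <- expand.grid(
    pd = landscape$pd_values, pp = landscape$pp_values,
    KEEP.OUT.ATTRS = FALSE
  )
  # expand.grid varies pd fastest, matching row-major traversal of the matrix
  tibble::tibble(
    tree_height = landscape$tree_height,
    pp = grid$pp,
    pd = grid$pd,
    mean_omega = as.vector(t(landscape$mean_omega)),
    sd_omega = as.vector(t(landscape$sd_omega)),
    n_reps = as.vector(t(landscape$n_reps))
  )
}

#' Rebuild a fitness landscape from its tabular form
#'
#' Inverse of [landscape_to_tibble()]; used to reload a `landscape.csv`
#' written by the sweep command before running evolutionary simulations.
#'
#' @param tab A data frame with columns `tree_height`, `pp`, `pd`,
#'   `mean_omega`, and optionally `sd_omega` and `n_reps`.
#' @return A `"fitness_landscape"` object.
#' @export
landscape_from_tibble <- function(tab) {
  required <- c("tree_height", "pp", "pd", "mean_omega")
  if (!all(required %in% names(tab))) {
    stop(
      "landscape table must have columns ",
      paste(required, collapse = ", "),
      call. = FALSE
    )
  }
  pp_values <- sort(unique(tab$pp))
  pd_values <- sort(unique(tab$pd))
  if (nrow(tab) != length(pp_values) * length(pd_values)) {
    stop("landscape table is not a complete grid", call. = FALSE)
  }
  idx <- cbind(match(tab$pp, pp_values), match(tab$pd, pd_values))
  fill <- function(col, default) {
    m <- matrix(default, length(pp_values), length(pd_values))
    if (!is.null(col)) m[idx] <- col
    m
  }
  structure(
    list(
      pp_values = pp_values, pd_values = pd_values,
      mean_omega = fill(tab$mean_omega, NA_real_),
      sd_omega = fill(tab$sd_omega, 0),
      n_reps = fill(tab$n_reps, 1L),
      tree_height = as.integer(tab$tree_height[1]),
      schedule = NULL
    ),
    class = "fitness_landscape"
  )
}
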