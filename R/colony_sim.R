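MERGED_AREAS <- c("NEST+CACHE", "TREE", "FORAGE+DROP")

#' Parameters of one colony simulation
#'
#' Defaults follow the study conditions: 25 foraging ants over 10,000
#' timesteps, with a fitness cost coefficient of c = 0.3 on the pick-up
#' probability.
#'
#' @param tree_height Tree height in cells (1 terrestrial, 10 intermediate,
#'   20 arboreal).
#' @param behaviour A [behaviour_params()] object (P_P, P_D, forage
#'   probability, detection radius).
#' @param n_ants Number of foraging ants.
#' @param t_max Number of timesteps.
#' @param cost_coefficient Cost c per unit of pick-up probability, subtracted
#'   from the leaf count in the fitness omega = W - c * P_P.
#' @param seed Optional integer seed; if supplied, [run_colony()] seeds the
#'   R RNG with it so the run is exactly reproducible.
#' @return A list of class `"simulation_params"`.
#' @export
simulation_params <- function(tree_height, behaviour = behaviour_params(),
                              n_ants = 25, t_max = 10000,
                              cost_coefficient = 0.3, seed = NULL) {
  stopifnot(inherits(behaviour, "behaviour_params"))
  if (n_ants < 1) stop("`n_ants` must be >= 1", call. = FALSE)
  if (t_max < 0) stop("`t_max` must be >= 0", call. = FALSE)
  if (cost_coefficient < 0) stop("`cost_coefficient` must be >= 0", call. = FALSE)
  structure(
    list(
      tree_height = as.integer(tree_height),
      behaviour = behaviour,
      n_ants = as.integer(n_ants),
      t_max = as.integer(t_max),
      cost_coefficient = as.numeric(cost_coefficient),
      seed = if (!is.null(seed)) as.integer(seed)
    ),
    class = "simulation_params"
  )
}

#' Colony fitness
#'
#' omega = W - c * P_P: the number of leaves delivered to the nest over the
#' whole run, minus a linear cost on the pick-up probability reflecting the
#' time and energy spent searching the cache for food items.
#'
#' @param W Number of leaves delivered (non-negative).
#' @param pickup_prob Pick-up probability P_P in \[0, 1\].
#' @param cost_coefficient Cost coefficient c (default 0.3).
#' @return The fitness omega. Vectorised over `W` and `pickup_prob`.
#' @examples
#' compute_fitness(200, 1) # 199.7
#' @export
compute_fitness <- function(W, pickup_prob, cost_coefficient = 0.3) {
  if (any(is.na(W)) || any(W < 0)) {
    stop("`W` must be non-negative", call. = FALSE)
  }
  if (any(is.na(pickup_prob)) || any(pickup_prob < 0) || any(pickup_prob > 1)) {
    stop("`pickup_prob` must be in [0, 1]", call. = FALSE)
  }
  if (any(is.na(cost_coefficient)) || any(cost_coefficient < 0)) {
    stop("`cost_coefficient` must be >= 0", call. = FALSE)
  }
  W - cost_coefficient * pickup_prob
}

#' Run one colony simulation
#'
#' Simulates `n_ants` ants for `t_max` timesteps on the arena determined by
#' the tree height. Each timestep, every ant is activated exactly once in a
#' freshly randomised order; cache changes are visible immediately within
#' the step, so the first ant to reach a leaf takes it. Occupancy is
#' recorded after all ants have moved; ants in the Cache and Drop rows are
#' pooled with the Nest and Forage areas respectively.
#'
#' @param params A [simulation_params()] object.
#' @return An object of class `"colony_sim_result"` with elements:
#'   `W` (leaves delivered), `omega` (fitness `W - c * P_P`), `cut`,
#'   `dropped`, `picked_up` (event totals), `occupancy` (a `t_max` x 3
#'   integer matrix of ant counts in the merged areas NEST+CACHE, TREE and
#'   FORAGE+DROP), `cache_series`, `w_series`, `cut_series`,
#'   `carried_series` (per-timestep totals), and the `params` and `seed`
#'   used.
#' @examples
#' res <- run_colony(simulation_params(
#'   tree_height = 20,
#'   behaviour = behaviour_params(pickup_prob = 1, drop_prob = 1),
#'   t_max = 500, seed = 1
#' ))
#' res$W
#' @export
run_colony <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  arena <- build_arena(params$tree_height)
  b <- params$behaviour
  raw <- run_colony_cpp(
    params$n_ants, params$t_max,
    arena$width, arena$total_rows, arena$cache_row, arena$drop_row,
    arena$nest_cell[1], arena$nest_cell[2],
    b$pickup_prob, b$drop_prob, b$forage_prob, b$detection_radius
  )
  occupancy <- raw$occupancy
  colnames(occupancy) <- MERGED_AREAS
  structure(
    list(
      W = raw$W,
      omega = compute_fitness(raw$W, b$pickup_prob, params$cost_coefficient),
      cut = raw$cut,
      dropped = raw$dropped,
      picked_up = raw$picked_up,
      occupancy = occupancy,
      cache_series = raw$cache_series,
      w_series = raw$w_series,
      cut_series = raw$cut_series,
      carried_series = raw$carried_series,
      params = params,
      seed = params$seed
    ),
    class = "colony_sim_result"
  )
}

#' @export
print.colony_sim_result <- function(x, ...) {
  b <- x$params$behaviour
  cat(sprintf(
    "<colony_sim_result> h=%d P_P=%.2f P_D=%.2f: W=%d leaves, omega=%.2f (%d steps, %d ants)\n",
    x$params$tree_height, b$pickup_prob, b$drop_prob, x$W, x$omega,
    x$params$t_max, x$params$n_ants
  ))
  invisible(x)
}

params_signature <- function(p) {
  p$seed <- NULL
  p
}

#' Summarise occupancy over replicate simulations
#'
#' Per-timestep mean and standard deviation of the number of ants in each
#' merged area (NEST+CACHE, TREE, FORAGE+DROP) across replicate runs that
#' share all parameters except the seed.
#'
#' @param results A list of [run_colony()] results with identical parameters
#'   apart from `seed`.
#' @param t_window Number of initial timesteps to summarise (defaults to the
#'   full run; the collective movement dynamics are conventionally shown
#'   over the first 1,000 steps).
#' @return A tibble with columns `t`, `area`, `mean`, `sd` and `n_reps`.
#'   With a single replicate the spread is reported as 0.
#' @export
occupancy_summary <- function(results, t_window = NULL) {
  if (!length(results) || !all(vapply(results, inherits, logical(1), "colony_sim_result"))) {
    stop("`results` must be a non-empty list of colony_sim_result objects",
      call. = FALSE
    )
  }
  sigs <- lapply(results, function(r) params_signature(r$params))
  if (!all(vapply(sigs, identical, logical(1), sigs[[1]]))) {
    stop("all results must share parameters (except the seed)", call. = FALSE)
  }
  t_max <- results[[1]]$params$t_max
  if (is.null(t_window)) t_window <- t_max
  if (t_window > t_max) {
    stop("`t_window` exceeds the simulated number of timesteps", call. = FALSE)
  }
  n <- length(results)
  out <- lapply(MERGED_AREAS, function(area) {
    counts <- vapply(
      results, function(r) r$occupancy[seq_len(t_window), area],
      numeric(t_window)
    )
    counts <- matrix(counts, nrow = t_window)
    tibble::tibble(
      t = seq_len(t_window),
      area = area,
      mean = rowMeans(counts),
      sd = if (n > 1) apply(counts, 1, stats::sd) else rep(0, t_window),
      n_reps = n
    )
  })
  do.call(rbind, out)
}
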