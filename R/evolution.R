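#' Parameters of an evolutionary simulation
#'
#' Defaults follow the study conditions: populations of 50 colonies whose
#' two loci (P_P and P_D) are initialised uniformly on \[0, 0.2\], evolving
#' for 10,000 non-overlapping generations with a per-locus mutation
#' probability of 0.01 and Gaussian mutation steps of standard deviation
#' 0.1, truncated to \[0, 1\].
#'
#' @param n_colonies Number of colonies in the population.
#' @param generations Number of generations to simulate.
#' @param mutation_rate Per-locus mutation probability.
#' @param mutation_sd Standard deviation of the Gaussian mutation step.
#' @param init_range Two-element range from which initial locus values are
#'   drawn uniformly.
#' @param thin_genotypes Store the full genotype list every this many
#'   generations (summary statistics are stored every generation).
#' @param seed Optional integer seed for the whole evolutionary run.
#' @return A list of class `"evolution_params"`.
#' @export
evolution_params <- function(n_colonies = 50, generations = 10000,
                             mutation_rate = 0.01, mutation_sd = 0.1,
                             init_range = c(0, 0.2), thin_genotypes = 100,
                             seed = NULL) {
  if (n_colonies < 2) stop("`n_colonies` must be >= 2", call. = FALSE)
  if (generations < 0) stop("`generations` must be >= 0", call. = FALSE)
  if (mutation_rate < 0 || mutation_rate > 1) {
    stop("`mutation_rate` must be in [0, 1]", call. = FALSE)
  }
  if (mutation_sd < 0) stop("`mutation_sd` must be >= 0", call. = FALSE)
  if (length(init_range) != 2 || init_range[1] > init_range[2] ||
      init_range[1] < 0 || init_range[2] > 1) {
    stop("`init_range` must be an increasing range within [0, 1]", call. = FALSE)
  }
  structure(
    list(
      n_colonies = as.integer(n_colonies),
      generations = as.integer(generations),
      mutation_rate = as.numeric(mutation_rate),
      mutation_sd = as.numeric(mutation_sd),
      init_range = as.numeric(init_range),
      thin_genotypes = as.integer(thin_genotypes),
      seed = if (!is.null(seed)) as.integer(seed)
    ),
    class = "evolution_params"
  )
}

#' Initialise a population of colony genotypes
#'
#' Each colony's two loci (P_P, P_D) are drawn independently and uniformly
#' from the initial range.
#'
#' @param params An [evolution_params()] object.
#' @return A data frame with `n_colonies` rows and columns `pp` and `pd`.
#' @export
init_population <- function(params) {
  stopifnot(inherits(params, "evolution_params"))
  n <- params$n_colonies
  r <- params$init_range
  data.frame(
    pp = stats::runif(n, r[1], r[2]),
    pd = stats::runif(n, r[1], r[2])
  )
}

#' Mutate locus values
#'
#' With probability `rate` per locus, a Gaussian step with mean 0 and
#' standard deviation `sd` is added and the result is truncated (clipped)
#' to \[0, 1\]; otherwise the value is unchanged.
#'
#' @param values Numeric vector of locus values in \[0, 1\].
#' @param rate Per-locus mutation probability.
#' @param sd Standard deviation of the mutation step.
#' @return The mutated values, all within \[0, 1\].
#' @export
mutate_locus <- function(values, rate, sd) {
  hit <- stats::runif(length(values)) < rate
  if (any(hit)) {
    values[hit] <- pmin(pmax(values[hit] + stats::rnorm(sum(hit), 0, sd), 0), 1)
  }
  values
}

#' Produce the next generation of colonies
#'
#' Colonies reproduce sexually in proportion to their fitness: for each
#' offspring, two parents are sampled independently (with replacement) with
#' probability proportional to `max(fitness, 0)` — uniformly if every weight
#' is zero. The two loci are haploid and unlinked: each locus is inherited
#' from one of the two parents by an independent fair coin, then mutated via
#' [mutate_locus()].
#'
#' @param population Data frame of genotypes (`pp`, `pd`).
#' @param fitnesses Numeric vector of colony fitnesses, one per row of
#'   `population`.
#' @param params An [evolution_params()] object.
#' @return The offspring population, same shape as `population`.
#' @export
next_generation <- function(population, fitnesses, params) {
  stopifnot(inherits(params, "evolution_params"))
  n <- nrow(population)
  if (length(fitnesses) != n) {
    stop("`fitnesses` must have one entry per colony", call. = FALSE)
  }
  w <- pmax(fitnesses, 0)
  if (all(w == 0)) w <- rep(1, n)
  mother <- sample.int(n, n, replace = TRUE, prob = w)
  father <- sample.int(n, n, replace = TRUE, prob = w)
  from_mother_pp <- stats::runif(n) < 0.5
  from_mother_pd <- stats::runif(n) < 0.5
  offspring <- data.frame(
    pp = ifelse(from_mother_pp, population$pp[mother], population$pp[father]),
    pd = ifelse(from_mother_pd, population$pd[mother], population$pd[father])
  )
  offspring$pp <- mutate_locus(offspring$pp, params$mutation_rate, params$mutation_sd)
  offspring$pd <- mutate_locus(offspring$pd, params$mutation_rate, params$mutation_sd)
  offspring
}

#' Degree of task partitioning of a genotype
#'
#' Defined as the average of the pick-up and drop probabilities:
#' 0 for the fully generalist strategy (P_P = P_D = 0), 1 for the fully
#' task-partitioned one (P_P = P_D = 1).
#'
#' @param pp,pd Pick-up and drop probabilities (vectorised).
#' @return `(pp + pd) / 2`.
#' @export
degree_of_task_partitioning <- function(pp, pd) {
  (pp + pd) / 2
}

#' Run an evolutionary simulation on a fitness landscape
#'
#' Evolves a population of colony genotypes on a precomputed, interpolated
#' fitness landscape. Every generation each colony's fitness is looked up
#' via [interpolate_fitness()] — no fresh agent simulations are run — and
#' the next generation is produced by [next_generation()]. Generations are
#' non-overlapping and the population size is constant.
#'
#' @param landscape A [run_sweep()] result whose grid covers \[0, 1\]^2.
#' @param params An [evolution_params()] object.
#' @return An object of class `"evo_trajectory"`: `summary`, a tibble with
#'   one row per generation (0 ... `generations`) holding `generation`,
#'   `mean_pp`, `mean_pd` and `mean_degree`; `genotypes`, a tibble of full
#'   genotype lists stored every `thin_genotypes` generations (and at the
#'   final generation); and the `params` used.
#' @export
run_evolution <- function(landscape, params) {
  stopifnot(
    inherits(landscape, "fitness_landscape"),
    inherits(params, "evolution_params")
  )
  xs <- landscape$pp_values
  ys <- landscape$pd_values
  if (xs[1] > 0 || xs[length(xs)] < 1 || ys[1] > 0 || ys[length(ys)] < 1) {
    stop("landscape grid must cover [0, 1] on both axes", call. = FALSE)
  }
  if (!is.null(params$seed)) set.seed(params$seed)
  pop <- init_population(params)
  gens <- params$generations
  mean_pp <- mean_pd <- numeric(gens + 1)
  keep <- unique(c(
    seq(0, gens, by = max(params$thin_genotypes, 1L)), gens
  ))
  genotypes <- vector("list", length(keep))
  record <- function(g, pop) {
    if (g %in% keep) {
      genotypes[[match(g, keep)]] <<- tibble::tibble(
        generation = g, colony = seq_len(nrow(pop)),
        pp = pop$pp, pd = pop$pd
      )
    }
  }
  mean_pp[1] <- mean(pop$pp)
  mean_pd[1] <- mean(pop$pd)
  record(0L, pop)
  if (gens > 0) {
    for (g in seq_len(gens)) {
      fit <- interpolate_fitness(landscape, pop$pp, pop$pd)
      pop <- next_generation(pop, fit, params)
      mean_pp[g + 1] <- mean(pop$pp)
      mean_pd[g + 1] <- mean(pop$pd)
      record(g, pop)
    }
  }
  structure(
    list(
      summary = tibble::tibble(
        generation = 0:gens,
        mean_pp = mean_pp,
        mean_pd = mean_pd,
        mean_degree = degree_of_task_partitioning(mean_pp, mean_pd)
      ),
      genotypes = do.call(rbind, genotypes),
      params = params
    ),
    class = "evo_trajectory"
  )
}

#' @export
print.evo_trajectory <- function(x, ...) {
  last <- x$summary[nrow(x$summary), ]
  cat(sprintf(
    "<evo_trajectory> %d colonies, %d generations: final mean P_P=%.3f, P_D=%.3f, degree=%.3f\n",
    x$params$n_colonies, x$params$generations,
    last$mean_pp, last$mean_pd, last$mean_degree
  ))
  invisible(x)
}
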