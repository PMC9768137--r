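# shared fixtures built in code

quick_sim <- function(tree_height, pp, pd, seed, t_max = 2000, ...) {
  run_colony(simulation_params(
    tree_height = tree_height,
    behaviour = behaviour_params(pickup_prob = pp, drop_prob = pd),
    t_max = t_max, seed = seed, ...
  ))
}

# hand-built landscape with a prescribed mean-fitness function f(pp, pd)
synthetic_landscape <- function(f, pp_values = seq(0, 1, by = 0.25),
                                pd_values = pp_values, tree_height = 20L) {
  structure(
    list(
      pp_values = pp_values, pd_values = pd_values,
      mean_omega = outer(pp_values, pd_values, function(x, y) mapply(f, x, y)),
      sd_omega = matrix(0, length(pp_values), length(pd_values)),
      n_reps = matrix(1L, length(pp_values), length(pd_values)),
      tree_height = tree_height, schedule = NULL
    ),
    class = "fitness_landscape"
  )
}

# binomial 95% CI check for an observed proportion
expect_prop_close <- function(successes, n, p) {
  ci <- stats::binom.test(successes, n)$conf.int
  expect_lte(ci[1], p)
  expect_gte(ci[2], p)
}
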