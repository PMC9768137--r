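# leafcutter

An agent-based model of collective foraging in leaf-cutter ants, built to
study how **task partitioning** — one set of workers cutting and dropping
leaves from the treetop, another collecting the fallen fragments from a
ground cache and carrying them to the nest — can evolve gradually through
**stigmergy**, the indirect coordination created by the dropped leaves
themselves.

The package is for behavioural ecologists and modellers of social-insect
division of labour. It provides three layers:

1. **Colony simulation** (`run_colony()`): 25 ants on an 11-column grid
   partitioned bottom-to-top into Nest, Cache, Tree, Drop and Forage areas
   (tree height 1 = terrestrial, 10 = intermediate, 20 = arboreal). Ants
   move one cell per timestep — stochastically when searching, in straight
   lines when homing with a leaf — and are driven by two evolvable
   Bernoulli decisions: drop a carried leaf at the treetop with probability
   *P<sub>D</sub>*, pick up a detected cache leaf with probability
   *P<sub>P</sub>*. Colony fitness over a 10,000-step run is

   *ω* = *W* − *c* · *P<sub>P</sub>*,  *c* = 0.3,

   where *W* counts leaves delivered to the nest.
2. **Fitness landscapes** (`run_sweep()`, `interpolate_fitness()`,
   `landscape_gradient()`): replicate-averaged *ω* over the full 21 × 21
   grid of (*P<sub>P</sub>*, *P<sub>D</sub>*) values (441 combinations, 10
   replicates each), with bilinear interpolation between nodes.
3. **Evolutionary simulations** (`run_evolution()`): populations of 50
   colony genotypes with haploid, unlinked *P<sub>P</sub>* and
   *P<sub>D</sub>* loci evolve for 10,000 non-overlapping generations by
   fitness-proportional sexual reproduction and rare (0.01) Gaussian
   mutation (SD 0.1, truncated to [0, 1]), with fitness looked up from a
   precomputed landscape. The headline statistic is the degree of task
   partitioning, (*P<sub>P</sub>* + *P<sub>D</sub>*)/2.

See the vignette (`vignettes/task-partitioning-model.Rmd`) for the full
model description and design rationale.

## Worked example

```r
library(leafcutter)

build_arena(20)
#> <arena> 11 x 35 grid, tree height 20 (arboreal)
#>   rows bottom-up: NEST 0-6 | CACHE 7 | TREE 8-26 | DROP 27 | FORAGE 28-34
#>   nest cell: (6, 3)

# a fully task-partitioned colony in the arboreal environment ...
run_colony(simulation_params(
  tree_height = 20,
  behaviour = behaviour_params(pickup_prob = 1, drop_prob = 1),
  seed = 42
))
#> <colony_sim_result> h=20 P_P=1.00 P_D=1.00: W=8763 leaves, omega=8762.70 (10000 steps, 25 ants)

# ... delivers almost three times what a generalist colony manages there
run_colony(simulation_params(
  tree_height = 20,
  behaviour = behaviour_params(pickup_prob = 0, drop_prob = 0),
  seed = 42
))
#> <colony_sim_result> h=20 P_P=0.00 P_D=0.00: W=3167 leaves, omega=3167.00 (10000 steps, 25 ants)

# a reduced-resolution arboreal fitness landscape, then evolution on it
ls <- run_sweep(sweep_schedule(20, values = seq(0, 1, by = 0.25),
                               replicates = 3, t_max = 2000, base_seed = 1))
ls
#> <fitness_landscape> tree height 20: 5 x 5 grid, mean omega in [0.0, 1675.4]
interpolate_fitness(ls, 0.6, 0.9)
#> [1] 565.7533

run_evolution(ls, evolution_params(generations = 2000, seed = 1))
#> <evo_trajectory> 50 colonies, 2000 generations: final mean P_P=1.000, P_D=1.000, degree=1.000
```

The last line is the phenomenon the package exists to show: starting from
near-generalist genotypes (loci uniform on [0, 0.2]), an arboreal
population climbs the landscape to full task partitioning. On a terrestrial
(height 1) landscape the same populations stay near the generalist corner.

The `W = 8763` vs `W = 3167` contrast above reflects the cost of the
generalist's round trips up a 20-cell trunk; at tree height 1 the ordering
reverses, because the partitioned handoff (cut, drop, pick up, deliver,
plus searching the cache) costs more than it saves when there is no tree to
climb.

## Command-line interface

`inst/cli/leafcutter` is a thin Rscript over the same functions:

```sh
Rscript inst/cli/leafcutter simulate --tree-height 20 --pp 1 --pd 1 \
    --replicates 10 --seed 1 --out runs/tp
Rscript inst/cli/leafcutter sweep --tree-height 20 --step 0.05 \
    --sweep-replicates 10 --seed 1 --out runs/arboreal
Rscript inst/cli/leafcutter evolve --landscape runs/arboreal/landscape.csv \
    --replicates 100 --seed 1 --out runs/arboreal_evo
Rscript inst/cli/leafcutter report --out runs/arboreal_evo
```

Each command writes plain CSV outputs (`occupancy.csv`, `cache.csv`,
`result.csv`, `landscape.csv`, `trajectory.csv`, `genotypes.csv`) and a
`manifest.json` recording the full configuration and derived seeds, enough
to re-run bit-identically. A flat `key: value` config file can be supplied
with `--config`; explicit flags win.

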