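---
title: "An agent-based model of task partitioning in leaf-cutter ant foraging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of task partitioning in leaf-cutter ant foraging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological question

Arboreal leaf-cutter ant colonies often split leaf retrieval into two
sequential subtasks: some workers cut leaf fragments in the canopy and drop
them to the ground, others collect the fallen fragments from the resulting
cache and carry them to the nest. This *task partitioning* exploits gravity
to spare each worker the climb, but it is coordinated by nobody: dropped
leaves are a stigmergic signal that recruits collectors. `leafcutter`
implements a minimal agent-based model of this system to ask how such
partitioning can evolve gradually when only two behavioural tendencies —
the probability of dropping a carried leaf from the treetop ($P_D$) and the
probability of picking up a detected cache leaf ($P_P$) — are free to
evolve, each in small independent mutational steps.

## The arena and the agents

The world is an 11-column grid whose rows are partitioned, bottom to top,
into a 7-row **Nest area** (with the nest itself a single cell at column 6,
row 3), a 1-row **Cache area** at the foot of the tree, the **Tree trunk**,
a 1-row **Drop area** at the treetop, and a 7-row **Forage area** (the
canopy). The printed tree height $h$ counts the Drop row as the treetop, so
the trunk occupies $h - 1$ interior rows and the grid has $15 + h$ rows:
11×16 for the terrestrial environment ($h = 1$, where the Drop row sits
directly on the Cache row), 11×25 for the intermediate one ($h = 10$), and
11×35 for the arboreal one ($h = 20$). This is the only row accounting
consistent with all three grid sizes. Cells are addressed `(column, row)`,
0-indexed from the bottom-left.

25 ants forage for 10,000 timesteps. Each timestep every ant acts exactly
once, in a freshly randomised order, and moves at most one cell
(Chebyshev speed ≤ 1). Movement comes in two kinds:

* **Carrying a leaf**: a deterministic straight-line walk to the nest cell
  (one step of −1/0/+1 per coordinate towards the target), mimicking path
  integration. The same greedy stepping is used by ants walking to a
  specific target cell (a detected leaf, or a chosen canopy cell).
* **Otherwise**: a uniform draw over the in-bounds subset of five
  candidates — forward, the two forward diagonals, left and right — where
  "forward" is up for ants heading to the canopy and down for ants heading
  to the ground. This directional noise stands in for imperfect olfactory
  orientation.

The per-ant state machine is driven by three Bernoulli decisions:

1. **Pick-up** ($P_P$): an ant standing on the cache row scans for the
   nearest cache cell holding a leaf within 5 cells (Chebyshev distance,
   matching the 8-neighbour movement; ties broken uniformly at random). On
   detection it draws the pick-up Bernoulli *once*: on success it walks to
   the leaf and picks it up; on decline it commits to climbing and ignores
   the cache until its next state change, so per-step re-rolling cannot
   inflate the effective pick-up probability.
2. **Forage** (fixed at 0.95): an ant reaching the Drop row on the way up
   either picks a uniformly random canopy cell to cut at (95%) or climbs
   back down empty (5%). The 5% branch is the noise that lets the colony
   rebalance the ratio of droppers to collectors; descending empty ants
   scan the cache row on the way down and turn back up once they reach the
   Nest area.
3. **Drop** ($P_D$): a carrying ant whose activation starts in the Drop row
   drops its leaf into the cache (same column) with probability $P_D$ and
   turns back up; otherwise it continues its straight line to the nest.

**Handling steps.** Every leaf manipulation — cutting at the chosen canopy
cell, picking up a cache leaf, dropping into the cache, delivering at the
nest — is an action that consumes the ant's whole activation: the ant acts
instead of moving on that timestep (decisions themselves are
instantaneous). This is the package's representation of transfer-related
handling costs, and it matters for the comparison of strategies: a
partitioned leaf passes through four handling events (cut, drop, pick up,
deliver) where a generalist leaf needs only two (cut, deliver). Together
with the restriction of cache scanning to the cache row itself (finding a
dropped fragment requires being at the cache, not merely within sensory
range of it from deep inside the nest area), these two choices are what
makes the handoff costly enough that the generalist strategy wins on the
ground while partitioning wins in the canopy — without them the detection
radius covers the entire 11-column cache from the nest cell and the
partitioned handoff is free, so partitioning would dominate even with no
tree to climb, which contradicts the behaviour of real ground-foraging
colonies. A consequence of handling steps is that a carrying ant's distance
to the nest is non-increasing and strictly decreases on every step in which
it moves, rather than strictly decreasing every step.

Other behavioural conventions: leaves in the canopy are unlimited and cut
exactly where the ant chose to go; the cache stacks any number of leaves
per cell; several ants may share a cell; several ants may target the same
leaf, the first arrival takes it and later arrivals rescan; ants start at
uniformly random cells, empty-handed, heading for the canopy.

## Colony fitness and the landscape sweep

A colony's productivity is $W$, the number of leaves delivered over the
run; its fitness is

$$\omega = W - c \, P_P, \qquad c = 0.3,$$

charging a small linear cost for the time and energy spent searching the
cache. The landscape sweep (`run_sweep()`) runs 10 replicate simulations at
every combination of $P_P$ and $P_D$ from 0 to 1 in steps of 0.05 — 441
combinations per environment — and averages $\omega$ per node.
`interpolate_fitness()` interpolates the node means bilinearly ("linear
interpolation" on a regular 2-D grid is taken as bilinear; the result is
exact at the nodes), and `landscape_gradient()` provides the
finite-difference gradient field (central differences inside, one-sided at
the edges).

## Evolutionary simulations

`run_evolution()` evolves a population of 50 colony genotypes
$(P_P, P_D)$, initialised i.i.d. uniform on $[0, 0.2]$, for 10,000
non-overlapping generations. Each generation every colony's fitness is
looked up from the *precomputed interpolated landscape* — no fresh agent
simulations — so the landscape's sampling noise is frozen once per
environment. Colonies reproduce sexually in proportion to fitness: for each
offspring, two parents are drawn independently with replacement with
probability proportional to $\max(\omega, 0)$ (uniformly if all weights are
zero — $\omega$ can only be negative when $W = 0$, which does not occur at
the default scale); the two loci are haploid and unlinked, each inherited
from one of the two parents by an independent fair coin; each locus then
mutates with probability 0.01 by adding a $\mathcal{N}(0, 0.1)$ step,
truncated to $[0, 1]$ by clipping (clipping, rather than resampling, is the
simplest reading of truncation and keeps the mutation kernel monotone).
Selfing is possible; the population size is constant. The summary statistic
tracked over time is the *degree of task partitioning*, $(P_P + P_D)/2$.

Two consequences of this design are worth noting when reading
trajectories. First, selection on $P_P$ is nearly neutral wherever nobody
drops ($P_D \approx 0$ makes $W$ independent of $P_P$, leaving only the
$-c P_P$ nudge), so populations drift along the $P_P$ axis before the
$(P_P, P_D)$ gradient engages — this is exactly what makes the *gradual*
evolution of partitioning possible. Second, because the landscape noise is
frozen, a flat region of the true surface acquires small spurious local
gradients from simulation noise; with few replicates per node this lets
occasional terrestrial populations wander along the neutral ridge.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `tree_height` | 1 / 10 / 20 | trunk height in cells; terrestrial, intermediate, arboreal |
| `n_ants` | 25 | foragers per colony |
| `t_max` | 10,000 | timesteps per simulation |
| `pickup_prob` ($P_P$) | evolvable | probability of picking up a detected cache leaf |
| `drop_prob` ($P_D$) | evolvable | probability of dropping a carried leaf at the treetop |
| `forage_prob` | 0.95 | probability of cutting rather than descending empty |
| `detection_radius` | 5 cells | Chebyshev scan radius along the cache row |
| `cost_coefficient` $c$ | 0.3 | fitness cost per unit of $P_P$ |
| sweep `values` | 0–1 by 0.05 | 21 × 21 = 441 nodes, 10 replicates each |
| `n_colonies` | 50 | colonies per evolving population |
| `generations` | 10,000 | non-overlapping generations |
| `mutation_rate` | 0.01 | per locus, per generation |
| `mutation_sd` | 0.1 | SD of the Gaussian mutation step |
| `init_range` | [0, 0.2] | initial genotype distribution |

## Reproducibility and numerical choices

All randomness — initial placement, activation order, movement draws, the
three Bernoullis, forage targets, genetic sampling — flows from R's RNG, so
a `seed` makes any run bit-reproducible; the C++ core draws from the same
stream. Sweeps and replicate batches derive one seed per (node, replicate)
pair from the base seed with a Lehmer-style modular mix (`derive_seed()`,
all arithmetic below $2^{31}$), so results are independent of execution
order and partial reruns reproduce exactly. Degenerate inputs are defined,
not special-cased: `t_max = 0` returns $W = 0$ and $\omega = -c P_P$;
`tree_height = 1` has an empty trunk; a single-replicate node reports a
standard deviation of 0 by convention; equal-fitness (or all-zero-fitness)
populations select parents uniformly. CSV exports serialise doubles with 17
significant digits so read-back is exact.

## What the simulations emulate, and what passing tests show

The model is the data generator: there is no external data. It emulates the
geometry of a single foraging trail (one tree, one nest, one cache), the
stigmergic handoff through fallen leaves, and noisy individual movement. It
deliberately omits pheromone trails and direct communication, worker
polymorphism, load–size matching, energy budgets, leaf loss from the cache,
and colony-size dynamics. Tests that pass on this generator therefore
certify the model's internal logic (conservation laws, movement contracts,
operator statistics) and the qualitative comparative statics the model was
built to exhibit — generalist productivity falling with tree height while
partitioned productivity is robust, the fittest corner strategy reversing
between terrestrial and arboreal environments, and partitioning evolving in
arboreal but not terrestrial populations — not quantitative predictions
about real colonies.

The test suite and the acceptance script keep full-scale settings where
they matter for the claim (corner strategies: 10 replicates × 10,000
steps) and scale down where only qualitative contrast is needed: the
evolution endpoint contrast uses landscapes on a 0.25 grid with 3
replicates per node and 2,000-step simulations, and 20 evolutionary
replicates of 2,000 generations per environment. These sizes are the
package's chosen study design for its own checks; the full 441-node,
10-replicate, 10,000-step sweep for all three environments is available
unattended through `sweep_to_dir()` or the CLI.

## Known limitations

* The row-scan restriction and handling steps are modelling commitments;
  other frictions (e.g. probabilistic detection failure, leaf decay) would
  serve the same role and would shift the quantitative position of the
  terrestrial/arboreal crossover.
* The drop Bernoulli is drawn on the activation *starting* in the Drop row,
  one step after entry; with one decision per traversal the two conventions
  are behaviourally equivalent up to a single cell.
* Fitness landscapes freeze simulation noise into the surface; evolution on
  nearly-neutral regions is sensitive to that frozen noise at low replicate
  counts.
* The genotype is two-dimensional by construction; nothing can be said
  about the evolution of the behavioural architecture itself.
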