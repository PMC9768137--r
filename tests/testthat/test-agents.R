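test_that("bernoulli_decision is a single draw with the right degenerate cases", {
  set.seed(1)
  expect_false(any(vapply(1:100, function(i) bernoulli_decision(0), logical(1))))
  expect_true(all(vapply(1:100, function(i) bernoulli_decision(1), logical(1))))
  expect_error(bernoulli_decision(-0.1), "probability")
  expect_error(bernoulli_decision(1.1), "probability")
  # consumes exactly one draw from the stream
  set.seed(42)
  u <- stats::runif(2)
  set.seed(42)
  bernoulli_decision(0.5)
  expect_equal(stats::runif(1), u[2])
  # empirical frequency at p = 0.95 within its 95% binomial CI
  set.seed(7)
  hits <- sum(vapply(1:10000, function(i) bernoulli_decision(0.95), logical(1)))
  expect_prop_close(hits, 10000, 0.95)
})

test_that("detect_leaf finds the nearest cache leaf within Chebyshev radius 5", {
  arena <- build_arena(20)
  cache <- integer(11)
  ant <- ant_state(pos = c(5L, 7L))
  # leaf exactly 5 cells away is found, 6 away is not
  cache[1] <- 1 # column 0
  expect_equal(detect_leaf(ant, cache, arena), c(0L, 7L))
  expect_null(detect_leaf(ant_state(pos = c(6L, 7L)), cache, arena))
  # vertical reach: an ant in the nest area senses the cache row above it
  expect_equal(detect_leaf(ant_state(pos = c(0L, 2L)), cache, arena), c(0L, 7L))
  expect_null(detect_leaf(ant_state(pos = c(0L, 1L)), cache, arena))
  # nearest leaf wins over a farther one
  cache[6] <- 1 # column 5, right at the ant
  expect_equal(detect_leaf(ant, cache, arena), c(5L, 7L))
})

test_that("equidistant leaves are chosen uniformly at random", {
  arena <- build_arena(20)
  cache <- integer(11)
  cache[c(3, 11)] <- 1 # columns 2 and 10, both 4 cells from column 6
  ant <- ant_state(pos = c(6L, 7L))
  set.seed(11)
  picks <- vapply(1:10000, function(i) detect_leaf(ant, cache, arena)[1], integer(1))
  expect_setequal(unique(picks), c(2L, 10L))
  expect_prop_close(sum(picks == 2L), 10000, 0.5)
})

test_that("carrying ants home along the discrete straight line to the nest", {
  arena <- build_arena(20)
  carrying <- function(pos) ant_state(pos, carrying = TRUE, goal = "TO_NEST")
  expect_equal(step_with_leaf(carrying(c(6L, 9L)), arena), c(6L, 8L))
  expect_equal(step_with_leaf(carrying(c(9L, 7L)), arena), c(8L, 6L))
  expect_equal(step_with_leaf(carrying(c(0L, 3L)), arena), c(1L, 3L))
  expect_equal(step_with_leaf(carrying(arena$nest_cell), arena), arena$nest_cell)
  expect_error(step_with_leaf(ant_state(c(0L, 0L)), arena), "carrying")
})

test_that("leafless directional movement is uniform over the in-bounds candidates", {
  arena <- build_arena(20)
  # interior ant heading up: 5 candidates, each at frequency ~1/5
  ant <- ant_state(pos = c(5L, 10L), goal = "TO_FORAGE")
  set.seed(3)
  moves <- t(vapply(1:10000, function(i) step_without_leaf(ant, arena), integer(2)))
  keys <- paste(moves[, 1], moves[, 2])
  expected <- c("5 11", "4 11", "6 11", "4 10", "6 10")
  expect_setequal(unique(keys), expected)
  counts <- table(factor(keys, expected))
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
  # left-wall ant: the two left candidates are filtered out
  wall <- ant_state(pos = c(0L, 10L), goal = "TO_FORAGE")
  set.seed(4)
  wmoves <- t(vapply(1:3000, function(i) step_without_leaf(wall, arena), integer(2)))
  expect_setequal(paste(wmoves[, 1], wmoves[, 2]), c("0 11", "1 11", "1 10"))
  # bottom corner heading down: a single legal move
  corner <- ant_state(pos = c(0L, 0L), goal = "TO_NEST")
  expect_equal(step_without_leaf(corner, arena), c(1L, 0L))
})

test_that("target-cell goals step greedily and stop at the target", {
  arena <- build_arena(20)
  ant <- ant_state(pos = c(2L, 3L), goal = "TO_LEAF", target = c(5L, 7L))
  expect_equal(step_without_leaf(ant, arena), c(3L, 4L))
  there <- ant_state(pos = c(5L, 7L), goal = "TO_LEAF", target = c(5L, 7L))
  expect_equal(step_without_leaf(there, arena), c(5L, 7L))
})

test_that("the drop decision fires once, on the activation starting in the Drop row", {
  arena <- build_arena(20)
  cache <- integer(11)
  carrying <- ant_state(c(4L, arena$drop_row), carrying = TRUE, goal = "TO_NEST")
  # P_D = 1: the leaf lands in the cache (same column) and the ant turns back
  set.seed(5)
  res <- transition(carrying, arena, cache, behaviour_params(drop_prob = 1))
  expect_equal(res$events$dropped, 1L)
  expect_equal(res$cache[5], 1L) # column 4
  expect_false(res$ant$carrying)
  expect_equal(res$ant$goal, "TO_FORAGE")
  expect_equal(res$ant$pos, c(4L, arena$drop_row)) # handling consumed the step
  # P_D = 0: still carrying, moved one cell down towards the nest
  res0 <- transition(carrying, arena, cache, behaviour_params(drop_prob = 0))
  expect_equal(res0$events$dropped, 0L)
  expect_true(res0$ant$carrying)
  expect_equal(res0$ant$pos, c(5L, arena$drop_row - 1L))
})

test_that("the forage decision at the treetop follows the 95% probability", {
  arena <- build_arena(20)
  cache <- integer(11)
  ant <- ant_state(c(5L, arena$drop_row), goal = "TO_FORAGE")
  params <- behaviour_params() # forage_prob 0.95
  set.seed(6)
  goals <- vapply(1:10000, function(i) {
    transition(ant, arena, cache, params)$ant$goal
  }, character(1))
  expect_setequal(unique(goals), c("TO_FORAGE_CELL", "TO_NEST"))
  expect_prop_close(sum(goals == "TO_FORAGE_CELL"), 10000, 0.95)
})

test_that("pick-up, cutting and delivery are handling steps with the right events", {
  arena <- build_arena(20)
  params <- behaviour_params(pickup_prob = 1, drop_prob = 1)
  # pick-up at the walked-to leaf
  cache <- integer(11)
  cache[4] <- 2L # column 3
  coll <- ant_state(c(3L, 7L), goal = "TO_LEAF", target = c(3L, 7L))
  res <- transition(coll, arena, cache, params)
  expect_equal(res$events$picked_up, 1L)
  expect_true(res$ant$carrying)
  expect_equal(res$ant$goal, "TO_NEST")
  expect_equal(res$cache[4], 1L)
  expect_equal(res$ant$pos, c(3L, 7L))
  # leaf already taken: rescan finds the other leaf and walks towards it
  cache2 <- integer(11)
  cache2[6] <- 1L # column 5
  res2 <- transition(coll, arena, cache2, params)
  expect_equal(res2$events$picked_up, 0L)
  expect_false(res2$ant$carrying)
  expect_equal(res2$ant$goal, "TO_LEAF")
  expect_equal(res2$ant$target, c(5L, 7L))
  expect_equal(res2$ant$pos, c(4L, 7L))
  # cutting at the chosen canopy cell
  cutter <- ant_state(c(8L, 30L), goal = "TO_FORAGE_CELL", target = c(8L, 30L))
  res3 <- transition(cutter, arena, integer(11), params)
  expect_equal(res3$events$cut, 1L)
  expect_true(res3$ant$carrying)
  expect_equal(res3$ant$pos, c(8L, 30L))
  # delivery at the nest cell
  porter <- ant_state(arena$nest_cell, carrying = TRUE, goal = "TO_NEST")
  res4 <- transition(porter, arena, integer(11), params)
  expect_equal(res4$events$delivered, 1L)
  expect_false(res4$ant$carrying)
  expect_equal(res4$ant$goal, "TO_FORAGE")
  expect_equal(res4$ant$pos, arena$nest_cell)
})

test_that("inconsistent ant states are rejected", {
  arena <- build_arena(5)
  expect_error(ant_state(c(0L, 0L), carrying = TRUE, goal = "TO_FORAGE"), "inconsistent")
  bad <- ant_state(c(0L, 0L), carrying = TRUE, goal = "TO_NEST")
  bad$goal <- "TO_FORAGE"
  expect_error(
    transition(bad, arena, integer(11), behaviour_params()),
    "inconsistent"
  )
})

test_that("a driven ant keeps speed <= 1, stays in bounds, and homes monotonically", {
  arena <- build_arena(5)
  params <- behaviour_params(pickup_prob = 0.5, drop_prob = 0.5)
  cache <- integer(11)
  cache[c(2, 9)] <- 3L
  ant <- ant_state(c(0L, 0L))
  nest_dist <- function(p) max(abs(p - arena$nest_cell))
  set.seed(9)
  for (i in 1:600) {
    res <- transition(ant, arena, cache, params)
    new <- res$ant
    expect_lte(max(abs(new$pos - ant$pos)), 1L)
    expect_true(all(new$pos >= 0L) && new$pos[1] < arena$width &&
      new$pos[2] < arena$total_rows)
    if (new$carrying) expect_equal(new$goal, "TO_NEST")
    if (ant$carrying && new$carrying) {
      # non-increasing distance; strict decrease whenever the ant moved
      expect_lte(nest_dist(new$pos), nest_dist(ant$pos))
      if (!identical(new$pos, ant$pos)) {
        expect_lt(nest_dist(new$pos), nest_dist(ant$pos))
      }
    }
    ant <- new
    cache <- res$cache
  }
})
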