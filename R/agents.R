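GOAL_LEVELS <- c("TO_FORAGE", "TO_NEST", "TO_LEAF", "TO_FORAGE_CELL")

goal_code <- function(goal) {
  code <- match(goal, GOAL_LEVELS) - 1L
  if (is.na(code)) stop("unknown goal: ", goal, call. = FALSE)
  code
}

check_prob <- function(p, name) {
  if (length(p) != 1 || is.na(p) || p < 0 || p > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
      call. = FALSE
    )
  }
  invisible(p)
}

#' Behavioural parameters of the ants
#'
#' The two evolvable probabilities, plus the two fixed behavioural constants.
#' `pickup_prob` (P_P) is the probability that an ant that has detected a
#' leaf in the cache decides to pick it up; `drop_prob` (P_D) is the
#' probability that a leaf-carrying ant drops its leaf from the treetop into
#' the cache. `forage_prob` is the probability that an ant reaching the
#' treetop on the way up proceeds to cut a leaf rather than climbing back
#' down empty (fixed at 0.95; the 5% noise lets the colony rebalance
#' droppers and collectors). Ants detect cache leaves within
#' `detection_radius` cells (Chebyshev distance, default 5).
#'
#' @param pickup_prob Pick-up probability P_P, in \[0, 1\].
#' @param drop_prob Drop probability P_D, in \[0, 1\].
#' @param forage_prob Probability of cutting a leaf at the treetop.
#' @param detection_radius Leaf detection radius in cells.
#' @return A list of class `"behaviour_params"`.
#' @export
behaviour_params <- function(pickup_prob = 0, drop_prob = 0,
                             forage_prob = 0.95, detection_radius = 5) {
  check_prob(pickup_prob, "pickup_prob")
  check_prob(drop_prob, "drop_prob")
  check_prob(forage_prob, "forage_prob")
  if (length(detection_radius) != 1 || is.na(detection_radius) ||
      detection_radius < 0) {
    stop("`detection_radius` must be a single value >= 0", call. = FALSE)
  }
  structure(
    list(
      pickup_prob = as.numeric(pickup_prob),
      drop_prob = as.numeric(drop_prob),
      forage_prob = as.numeric(forage_prob),
      detection_radius = as.integer(detection_radius)
    ),
    class = "behaviour_params"
  )
}

#' Construct a single ant's state
#'
#' @param pos `(column, row)` position, 0-indexed.
#' @param carrying Is the ant carrying a leaf? Carrying ants must be homing
#'   (`goal = "TO_NEST"`).
#' @param goal One of `"TO_FORAGE"` (heading up to the canopy), `"TO_NEST"`
#'   (heading down), `"TO_LEAF"` (walking to a detected cache leaf),
#'   `"TO_FORAGE_CELL"` (walking to a chosen canopy cell).
#' @param target Target cell for `"TO_LEAF"` / `"TO_FORAGE_CELL"` goals,
#'   else `NULL`.
#' @param scan Whether the ant is scanning for cache leaves; set to `FALSE`
#'   after an ant declines a pick-up, until its next state change.
#' @return A list of class `"ant_state"`.
#' @export
ant_state <- function(pos, carrying = FALSE, goal = "TO_FORAGE",
                      target = NULL, scan = TRUE) {
  goal <- match.arg(goal, GOAL_LEVELS)
  if (carrying && goal != "TO_NEST") {
    stop("inconsistent ant state: carrying but goal is not TO_NEST",
      call. = FALSE
    )
  }
  structure(
    list(
      pos = as.integer(pos), carrying = isTRUE(carrying), goal = goal,
      target = if (!is.null(target)) as.integer(target),
      scan = isTRUE(scan)
    ),
    class = "ant_state"
  )
}

#' Draw a single Bernoulli decision
#'
#' Consumes exactly one draw from the R random number stream.
#'
#' @param p Success probability in \[0, 1\].
#' @return `TRUE` with probability `p`.
#' @export
bernoulli_decision <- function(p) {
  check_prob(p, "p")
  stats::runif(1) < p
}

#' Detect the nearest leaf in the cache
#'
#' Returns the nearest cache cell holding at least one leaf within
#' `radius` cells of the ant (Chebyshev distance, matching the ants'
#' 8-neighbour movement); ties are broken uniformly at random.
#'
#' @param ant An [ant_state()] (only its position is used).
#' @param cache Integer vector of per-column leaf counts on the cache row.
#' @param arena An [build_arena()] object.
#' @param radius Detection radius in cells.
#' @return The target cell `(column, cache_row)`, or `NULL` if no leaf is in
#'   range.
#' @export
detect_leaf <- function(ant, cache, arena, radius = 5) {
  stopifnot(inherits(arena, "arena"), length(cache) == arena$width)
  col <- detect_leaf_cpp(
    as.integer(ant$pos), as.integer(cache),
    arena$cache_row, as.integer(radius)
  )
  if (col < 0) NULL else c(col, arena$cache_row)
}

#' Move a leaf-carrying ant one cell towards the nest
#'
#' Carrying ants home in a discrete straight line to the nest cell,
#' mimicking path integration: one step of -1/0/+1 in each coordinate
#' towards the target, diagonals allowed. Deterministic.
#'
#' @param ant A carrying [ant_state()] with goal `"TO_NEST"`.
#' @param arena An [build_arena()] object.
#' @return The new `(column, row)` position.
#' @export
step_with_leaf <- function(ant, arena) {
  stopifnot(inherits(arena, "arena"))
  if (!isTRUE(ant$carrying) || ant$goal != "TO_NEST") {
    stop("step_with_leaf() requires a carrying ant homing to the nest",
      call. = FALSE
    )
  }
  greedy_step_cpp(as.integer(ant$pos), arena$nest_cell)
}

#' Move a leafless ant one cell
#'
#' For the directional goals (`"TO_FORAGE"` up, `"TO_NEST"` down) the ant
#' takes a uniform draw over the in-bounds subset of the five candidate
#' cells: forward, the two forward diagonals, left and right. For the
#' target-cell goals (`"TO_LEAF"`, `"TO_FORAGE_CELL"`) it steps
#' deterministically along the straight line to the target, as in
#' [step_with_leaf()].
#'
#' @param ant A leafless [ant_state()].
#' @param arena An [build_arena()] object.
#' @return The new `(column, row)` position.
#' @export
step_without_leaf <- function(ant, arena) {
  stopifnot(inherits(arena, "arena"))
  if (isTRUE(ant$carrying)) {
    stop("step_without_leaf() requires an ant without a leaf", call. = FALSE)
  }
  if (ant$goal %in% c("TO_LEAF", "TO_FORAGE_CELL")) {
    if (is.null(ant$target)) stop("target-cell goal without a target", call. = FALSE)
    greedy_step_cpp(as.integer(ant$pos), as.integer(ant$target))
  } else {
    random_step_cpp(
      as.integer(ant$pos), ant$goal == "TO_FORAGE",
      arena$width, arena$total_rows
    )
  }
}

#' Advance one ant by one timestep
#'
#' Runs the full per-ant state machine for a single activation. Leaf
#' manipulations are handling actions that consume the whole activation —
#' the ant acts instead of moving that timestep: delivering at the nest,
#' drawing a true drop Bernoulli on the activation that starts in the Drop
#' row with a leaf, picking up the leaf it has walked to, or cutting at its
#' chosen canopy cell. Otherwise the ant makes its decisions (the forage
#' Bernoulli at the treetop; a cache scan with the pick-up Bernoulli while
#' standing on the cache row) and moves one cell. This is the same routine
#' the full colony simulation applies to every ant.
#'
#' @param ant An [ant_state()].
#' @param arena An [build_arena()] object.
#' @param cache Integer vector of per-column cache leaf counts.
#' @param params A [behaviour_params()] object.
#' @return A list with the updated `ant` ([ant_state()]), the updated
#'   `cache`, and `events`, a named integer list counting `cut`, `dropped`,
#'   `picked_up` and `delivered` leaves during this activation.
#' @export
transition <- function(ant, arena, cache, params) {
  stopifnot(
    inherits(arena, "arena"), inherits(params, "behaviour_params"),
    length(cache) == arena$width
  )
  res <- transition_cpp(
    list(
      pos = as.integer(ant$pos), carrying = isTRUE(ant$carrying),
      goal = goal_code(ant$goal),
      target = if (!is.null(ant$target)) as.integer(ant$target),
      scan = isTRUE(ant$scan)
    ),
    unclass(arena), as.integer(cache), unclass(params)
  )
  st <- res$state
  list(
    ant = ant_state(
      pos = st$pos, carrying = st$carrying,
      goal = GOAL_LEVELS[st$goal + 1L], target = st$target, scan = st$scan
    ),
    cache = res$cache,
    events = res$events
  )
}
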