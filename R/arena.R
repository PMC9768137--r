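#' Build the foraging arena for a given tree height
#'
#' The arena is an 11-cell-wide grid partitioned, bottom to top, into the
#' Nest area (7 rows), the Cache area (1 row) at the foot of the tree, the
#' Tree trunk, the Drop area (1 row) at the treetop, and the Forage area
#' (7 rows, the canopy). The printed tree height counts the Drop row as the
#' treetop, so the trunk itself occupies `tree_height - 1` interior rows and
#' the grid has `15 + tree_height` rows in total: 11 x 16 for the terrestrial
#' environment (height 1), 11 x 25 for the intermediate (height 10) and
#' 11 x 35 for the arboreal one (height 20). At height 1 the trunk is empty
#' and the Drop row sits directly above the Cache row.
#'
#' Cells are addressed as `(column, row)`, 0-indexed, with row 0 at the
#' bottom (nest side). The nest is the single cell at (6, 3).
#'
#' @param tree_height Height of the tree in cells; a positive integer.
#'   1, 10 and 20 correspond to the terrestrial, intermediate and arboreal
#'   environments.
#' @return An object of class `"arena"`: a list with `width`, `tree_height`,
#'   `total_rows`, `nest_cell`, the `cache_row` and `drop_row` indices, and
#'   `spans`, a named list giving the inclusive row range of each area.
#' @examples
#' build_arena(20)
#' @export
build_arena <- function(tree_height) {
  if (length(tree_height) != 1 || is.na(tree_height) ||
      tree_height < 1 || tree_height != as.integer(tree_height)) {
    stop("`tree_height` must be a single integer >= 1", call. = FALSE)
  }
  h <- as.integer(tree_height)
  total_rows <- 15L + h
  cache_row <- 7L
  drop_row <- 7L + h
  spans <- list(
    NEST   = c(0L, 6L),
    CACHE  = c(cache_row, cache_row),
    TREE   = if (h > 1L) c(8L, drop_row - 1L) else NULL,
    DROP   = c(drop_row, drop_row),
    FORAGE = c(drop_row + 1L, total_rows - 1L)
  )
  structure(
    list(
      width = 11L,
      tree_height = h,
      total_rows = total_rows,
      nest_cell = c(6L, 3L),
      cache_row = cache_row,
      drop_row = drop_row,
      spans = spans
    ),
    class = "arena"
  )
}

#' @export
print.arena <- function(x, ...) {
  env <- switch(as.character(x$tree_height),
    "1" = " (terrestrial)", "10" = " (intermediate)", "20" = " (arboreal)",
    ""
  )
  cat(sprintf(
    "<arena> %d x %d grid, tree height %d%s\n",
    x$width, x$total_rows, x$tree_height, env
  ))
  cat(sprintf(
    "  rows bottom-up: NEST 0-6 | CACHE 7 | TREE %s | DROP %d | FORAGE %d-%d\n",
    if (x$tree_height > 1L) sprintf("8-%d", x$drop_row - 1L) else "(none)",
    x$drop_row, x$drop_row + 1L, x$total_rows - 1L
  ))
  cat(sprintf("  nest cell: (%d, %d)\n", x$nest_cell[1], x$nest_cell[2]))
  invisible(x)
}

check_in_bounds <- function(arena, cell) {
  if (length(cell) != 2 || any(is.na(cell))) {
    stop("`cell` must be a (column, row) pair", call. = FALSE)
  }
  if (cell[1] < 0 || cell[1] >= arena$width ||
      cell[2] < 0 || cell[2] >= arena$total_rows) {
    stop(sprintf(
      "cell (%d, %d) is outside the %d x %d grid",
      cell[1], cell[2], arena$width, arena$total_rows
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' Area label of a grid cell
#'
#' @param arena An [build_arena()] object.
#' @param cell Integer `(column, row)` pair, 0-indexed, row 0 at the bottom.
#' @return One of `"NEST"`, `"CACHE"`, `"TREE"`, `"DROP"`, `"FORAGE"`.
#' @examples
#' area_of(build_arena(20), c(6, 3)) # the nest cell
#' @export
area_of <- function(arena, cell) {
  stopifnot(inherits(arena, "arena"))
  check_in_bounds(arena, cell)
  row <- cell[2]
  if (row <= 6L) return("NEST")
  if (row == arena$cache_row) return("CACHE")
  if (row < arena$drop_row) return("TREE")
  if (row == arena$drop_row) return("DROP")
  "FORAGE"
}

#' Merged area label of a grid cell
#'
#' Occupancy series pool the single-row Cache and Drop areas with their large
#' neighbours: ants in the Cache area count towards the Nest area and ants in
#' the Drop area towards the Forage area.
#'
#' @inheritParams area_of
#' @return One of `"NEST+CACHE"`, `"TREE"`, `"FORAGE+DROP"`.
#' @export
merged_area_of <- function(arena, cell) {
  switch(area_of(arena, cell),
    NEST = ,
    CACHE = "NEST+CACHE",
    TREE = "TREE",
    DROP = ,
    FORAGE = "FORAGE+DROP"
  )
}
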