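#' Periodic food concentration field
#'
#' A square grid of relative food concentration in `[0, 1]`, uniform at 1
#' initially.  Worm feeding depletes the cell under each worm head; total
#' food is non-increasing.
#'
#' @param arena_side arena side, mm.
#' @param cell_size grid resolution, mm per cell.
#' @param initial initial relative concentration (scalar in `[0, 1]` or a
#'   full grid matrix).
#' @return an object of class `food_field` with elements `grid`,
#'   `cell_size`, `arena_side` and `periodic`.
#' @export
food_field <- function(arena_side = 8, cell_size = 0.2, initial = 1) {
  n <- max(1L, round(arena_side / cell_size))
  grid <- if (is.matrix(initial)) initial else matrix(initial, n, n)
  if (any(grid < 0 | grid > 1)) stop("food concentrations must lie in [0, 1]")
  structure(list(grid = grid, cell_size = arena_side / nrow(grid),
                 arena_side = arena_side, periodic = TRUE),
            class = "food_field")
}

food_cell_index <- function(food, position) {
  n <- nrow(food$grid)
  i <- floor((position[1] %% food$arena_side) / food$cell_size) + 1
  j <- floor((position[2] %% food$arena_side) / food$cell_size) + 1
  c(min(i, n), min(j, n))
}

#' Deplete food under feeding worms
#'
#' Each grid cell containing at least one worm head decreases by
#' `feed_rate * dt` per occupant, floored at zero; all other cells are
#' unchanged.
#'
#' @param food a [food_field()] object.
#' @param worm_positions matrix (rows = worms) of head positions, mm.
#' @param feed_rate consumption rate per worm, 1/s.
#' @param dt time step, s.
#' @return the updated `food_field`.
#' @export
deplete_step <- function(food, worm_positions, feed_rate, dt) {
  stopifnot(inherits(food, "food_field"))
  if (feed_rate < 0) stop("feed_rate must be >= 0")
  worm_positions <- matrix(as.numeric(worm_positions), ncol = 2)
  for (w in seq_len(nrow(worm_positions))) {
    ij <- food_cell_index(food, worm_positions[w, ])
    food$grid[ij[1], ij[2]] <- max(0, food$grid[ij[1], ij[2]] - feed_rate * dt)
  }
  food
}

#' Is food present at a position?
#'
#' `TRUE` iff the relative concentration of the containing cell is at or
#' above the threshold (boundary convention: `>=`).
#'
#' @param food a [food_field()] object.
#' @param position length-2 position, mm.
#' @param threshold relative concentration threshold.
#' @return logical.
#' @export
local_food <- function(food, position, threshold = 0.05) {
  stopifnot(inherits(food, "food_field"))
  ij <- food_cell_index(food, position)
  food$grid[ij[1], ij[2]] >= threshold
}
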