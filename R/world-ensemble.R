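#' Construct a world ensemble
#'
#' A world ensemble is a weighted collection of simulated complete election
#' outcomes: an `n_sims x n_units` binary matrix whose entry is 1 iff the
#' focal candidate wins that unit in that simulation, standing in for the
#' prior distribution over counterfactual worlds. The presidency outcome of
#' every simulation (the weighted threshold function of the row) is derived
#' at construction and cached; mutation goes through the constructor, so the
#' cache cannot go stale.
#'
#' @param map An [electoral_map].
#' @param outcomes Binary matrix, `n_sims` rows, one column per map unit.
#'   Column names, if present, must match `map$units` (any order; columns are
#'   reordered to map order).
#' @param weights Nonnegative per-simulation weights; normalized to sum to 1.
#'   Default uniform.
#' @return An object of class `world_ensemble`: list with `map`, `outcomes`
#'   (integer matrix with unit column names), `weights`, `totals` (per-sim
#'   electoral votes for the focal candidate) and `presidency` (cached binary
#'   vector).
#' @export
world_ensemble <- function(map, outcomes, weights = NULL) {
  stopifnot(inherits(map, "electoral_map"))
  outcomes <- as.matrix(outcomes)
  if (nrow(outcomes) < 1L) {
    stop("an ensemble needs at least one simulation", call. = FALSE)
  }
  if (ncol(outcomes) != length(map$units)) {
    stop("`outcomes` must have one column per map unit", call. = FALSE)
  }
  if (!is.null(colnames(outcomes))) {
    missing <- setdiff(map$units, colnames(outcomes))
    if (length(missing)) {
      stop(
        "outcome columns missing units: ", paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
    outcomes <- outcomes[, map$units, drop = FALSE]
  } else {
    colnames(outcomes) <- map$units
  }
  check_binary(outcomes, "outcomes")
  storage.mode(outcomes) <- "integer"

  n <- nrow(outcomes)
  if (is.null(weights)) {
    weights <- rep(1 / n, n)
  } else {
    if (length(weights) != n || any(is.na(weights)) || any(weights < 0)) {
      stop("`weights` must be nonnegative, one per simulation", call. = FALSE)
    }
    s <- sum(weights)
    if (s <= 0) stop("`weights` must not all be zero", call. = FALSE)
    weights <- weights / s
  }

  totals <- as.vector(outcomes %*% map$votes)
  presidency <- as.integer(totals >= map$threshold)

  structure(
    list(
      map = map, outcomes = outcomes, weights = weights,
      totals = totals, presidency = presidency
    ),
    class = "world_ensemble"
  )
}

#' @export
print.world_ensemble <- function(x, ...) {
  cat(
    "<world_ensemble> ", nrow(x$outcomes), " simulations x ",
    ncol(x$outcomes), " units; Pr(presidency) = ",
    formatC(sum(x$weights * x$presidency), digits = 4, format = "f"),
    "\n", sep = ""
  )
  invisible(x)
}

#' @export
dim.world_ensemble <- function(x) dim(x$outcomes)

#' Per-unit summary statistics of an ensemble
#'
#' The building blocks of the effect-size measures: the weighted win
#' probability `Pr(S)` of a unit, the population standard deviation of the
#' unit's binary outcome, and the population standard deviation of the
#' presidency outcome. For a binary variable the population SD has the closed
#' form `sqrt(p (1 - p))`, which is used exactly.
#'
#' @param ensemble A [world_ensemble].
#' @param unit Unit name.
#' @return List with `unit`, `p_win`, `sd_unit`, `sd_presidency`.
#' @export
unit_stats <- function(ensemble, unit) {
  stopifnot(inherits(ensemble, "world_ensemble"))
  j <- unit_index(ensemble$map, unit)
  p <- sum(ensemble$weights * ensemble$outcomes[, j])
  q <- sum(ensemble$weights * ensemble$presidency)
  list(
    unit = unit,
    p_win = p,
    sd_unit = sqrt(p * (1 - p)),
    sd_presidency = sqrt(q * (1 - q))
  )
}

#' Toggle one unit's outcome in a world
#'
#' Returns a copy of the world with only the named unit's entry flipped —
#' the minimal intervention used by the twin-world and pivotality
#' computations. An involution: flipping twice restores the original.
#'
#' @param world Binary outcome vector; named, or `map` supplied for name
#'   lookup.
#' @param unit Unit name (or index when the vector is unnamed and no map is
#'   given).
#' @param map Optional [electoral_map] used to resolve `unit`.
#' @return The flipped world vector; the input is not modified.
#' @export
flip_unit <- function(world, unit, map = NULL) {
  if (!is.null(map)) {
    j <- unit_index(map, unit)
  } else if (!is.null(names(world))) {
    j <- match(unit, names(world))
    if (is.na(j)) stop(sprintf("unknown unit '%s'", unit), call. = FALSE)
  } else if (is.numeric(unit)) {
    j <- as.integer(unit)
    if (j < 1L || j > length(world)) {
      stop("unit index out of range", call. = FALSE)
    }
  } else {
    stop("`world` is unnamed; supply `map` or a numeric index", call. = FALSE)
  }
  world[j] <- 1L - world[j]
  world
}

# internal: presidency outcomes after forcing unit j to `value` in every
# simulation, from the cached vote totals (O(n_sims), no matrix rebuild)
forced_presidency <- function(ensemble, j, value) {
  v <- ensemble$map$votes[j]
  col <- ensemble$outcomes[, j]
  totals <- ensemble$totals + (value - col) * v
  as.integer(totals >= ensemble$map$threshold)
}

# internal: presidency outcomes after toggling unit j in every simulation
toggled_presidency <- function(ensemble, j) {
  v <- ensemble$map$votes[j]
  col <- ensemble$outcomes[, j]
  totals <- ensemble$totals + (1L - 2L * col) * v
  as.integer(totals >= ensemble$map$threshold)
}
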