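#' Construct an electoral map
#'
#' An electoral map is the deterministic part of the election model: a set of
#' named voting units (states, or congressional districts listed as separate
#' units), an integer electoral-vote weight per unit, and the vote threshold a
#' candidate must reach to win the presidency. The default threshold is a
#' strict majority, `floor(total/2) + 1` (270 of 538 on the real map), so an
#' exact electoral-vote tie counts as a loss for the focal candidate. A lower
#' threshold (e.g. "either unit suffices" in toy disjunctive maps) can be set
#' explicitly.
#'
#' @param units Character vector of unique unit names.
#' @param votes Positive integer electoral votes per unit, recycled names are
#'   not allowed; must match `units` in length.
#' @param threshold Votes needed to win. Default: strict majority of the total.
#' @return An object of class `electoral_map`: a list with `units`, `votes`
#'   (named integer vector) and `threshold`.
#' @examples
#' m <- electoral_map(c("A", "B", "C"), c(5, 3, 2))
#' m$threshold # 6
#' @export
electoral_map <- function(units, votes, threshold = NULL) {
  units <- as.character(units)
  if (anyDuplicated(units)) {
    stop("unit names must be unique", call. = FALSE)
  }
  if (length(votes) != length(units)) {
    stop("`votes` must have one entry per unit", call. = FALSE)
  }
  votes <- as.integer(votes)
  if (any(is.na(votes)) || any(votes < 1L)) {
    stop("every vote count must be a positive integer", call. = FALSE)
  }
  total <- sum(votes)
  if (is.null(threshold)) {
    threshold <- total %/% 2L + 1L
  }
  threshold <- as.integer(threshold)
  if (is.na(threshold) || threshold < 1L || threshold > total) {
    stop("`threshold` must lie in [1, total votes]", call. = FALSE)
  }
  names(votes) <- units
  structure(
    list(units = units, votes = votes, threshold = threshold),
    class = "electoral_map"
  )
}

#' @export
print.electoral_map <- function(x, ...) {
  cat(
    "<electoral_map> ", length(x$units), " units, ",
    sum(x$votes), " electoral votes, threshold ", x$threshold, "\n",
    sep = ""
  )
  invisible(x)
}

#' Presidency outcome of a single world
#'
#' Applies the electoral-college rule to one complete outcome vector: the
#' focal candidate wins the presidency iff the electoral votes of the units
#' they win reach the map's threshold. Pure and deterministic.
#'
#' @param outcome_row Binary vector (0/1), one entry per unit in map order.
#' @param map An [electoral_map].
#' @return `1L` if the focal candidate wins, else `0L`.
#' @examples
#' m <- electoral_map(c("A", "B"), c(2, 1), threshold = 2)
#' presidency_outcome(c(1, 0), m) # 1
#' presidency_outcome(c(0, 1), m) # 0
#' @export
presidency_outcome <- function(outcome_row, map) {
  stopifnot(inherits(map, "electoral_map"))
  if (length(outcome_row) != length(map$units)) {
    stop("outcome row length must equal the number of units", call. = FALSE)
  }
  check_binary(outcome_row, "outcome_row")
  as.integer(sum(map$votes * outcome_row) >= map$threshold)
}

# internal: validate 0/1 content
check_binary <- function(x, what) {
  if (any(is.na(x)) || !all(x %in% c(0, 1))) {
    stop(sprintf("`%s` must contain only 0 and 1", what), call. = FALSE)
  }
  invisible(x)
}

# internal: resolve a unit name to its column index
unit_index <- function(map, unit) {
  j <- match(unit, map$units)
  if (is.na(j)) {
    stop(sprintf("unknown unit '%s'", unit), call. = FALSE)
  }
  j
}

#' The 2020 U.S. electoral map
#'
#' The 50 states plus the District of Columbia with their 2020 electoral-vote
#' counts (538 total, threshold 270). Maine's and Nebraska's congressional-
#' district electors are folded into the statewide unit (winner-take-all
#' simplification); districts can instead be listed as separate units by
#' building a custom map.
#'
#' @return An [electoral_map] with 51 units.
#' @export
us_electoral_map_2020 <- function() {
  ev <- c(
    AL = 9L, AK = 3L, AZ = 11L, AR = 6L, CA = 55L, CO = 9L, CT = 7L,
    DE = 3L, DC = 3L, FL = 29L, GA = 16L, HI = 4L, ID = 4L, IL = 20L,
    IN = 11L, IA = 6L, KS = 6L, KY = 8L, LA = 8L, ME = 4L, MD = 10L,
    MA = 11L, MI = 16L, MN = 10L, MS = 6L, MO = 10L, MT = 3L, NE = 5L,
    NV = 6L, NH = 4L, NJ = 14L, NM = 5L, NY = 29L, NC = 15L, ND = 3L,
    OH = 18L, OK = 7L, OR = 7L, PA = 20L, RI = 4L, SC = 9L, SD = 3L,
    TN = 11L, TX = 38L, UT = 6L, VT = 3L, VA = 13L, WA = 12L, WV = 5L,
    WI = 10L, WY = 3L
  )
  electoral_map(names(ev), ev, threshold = 270L)
}

#' Units won by the focal candidate in the 2020 election
#'
#' The 26 units Biden won (25 states plus DC), i.e. the units for which human
#' causal ratings were collected in the election study this package models.
#'
#' @return Character vector of 26 unit abbreviations.
#' @export
units_won_2020 <- function() {
  c(
    "AZ", "CA", "CO", "CT", "DE", "DC", "GA", "HI", "IL", "ME", "MD",
    "MA", "MI", "MN", "NV", "NH", "NJ", "NM", "NY", "OR", "PA", "RI",
    "VT", "VA", "WA", "WI"
  )
}

#' Actual 2020 world on a map
#'
#' Binary outcome vector over `map$units`: 1 where the focal candidate
#' (Biden) won in 2020, 0 elsewhere.
#'
#' @param map An [electoral_map]; defaults to [us_electoral_map_2020()].
#' @return Named binary integer vector in map order.
#' @export
actual_world_2020 <- function(map = us_electoral_map_2020()) {
  w <- as.integer(map$units %in% units_won_2020())
  names(w) <- map$units
  w
}
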