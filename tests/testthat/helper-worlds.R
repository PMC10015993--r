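# Shared fixtures and independent oracles, built in code.

# Enumerate all 2^k worlds of mutually independent units with win
# probabilities `p`, weighted by their exact product probabilities.
enumerate_independent_ensemble <- function(p, votes, threshold = NULL) {
  k <- length(p)
  worlds <- as.matrix(expand.grid(rep(list(0:1), k)))
  colnames(worlds) <- paste0("u", seq_len(k))
  w <- apply(worlds, 1L, function(row) prod(ifelse(row == 1, p, 1 - p)))
  map <- electoral_map(colnames(worlds), votes, threshold = threshold)
  world_ensemble(map, worlds, w)
}

# Conjunctive two-cause toy: A improbable-to-lose (p = .9, 2 votes),
# B a coin flip (p = .5, 1 vote); threshold 3 means both are needed.
conjunctive_toy <- function() {
  enumerate_independent_ensemble(c(.9, .5), c(2, 1), threshold = 3)
}

# Disjunctive variant: either unit's votes suffice.
disjunctive_toy <- function() {
  enumerate_independent_ensemble(c(.9, .5), c(2, 1), threshold = 1)
}

# Brute-force minimal-flip pivotality distance: try all subsets of the
# other units, smallest first. Oracle for the DP (maps of <= 15 units).
brute_pivotality_k <- function(actual_world, unit, map) {
  j <- match(unit, map$units)
  others <- setdiff(seq_along(map$units), j)
  rest <- sum(map$votes[others] * actual_world[others])
  lo <- map$threshold - map$votes[j]
  hi <- map$threshold - 1L
  n <- length(others)
  deltas <- ifelse(actual_world[others] == 1L, -map$votes[others],
    map$votes[others]
  )
  subsets <- as.matrix(expand.grid(rep(list(0:1), n)))
  totals <- rest + as.vector(subsets %*% deltas)
  sizes <- rowSums(subsets)
  ok <- totals >= lo & totals <= hi
  if (!any(ok)) {
    return(NA_integer_)
  }
  as.integer(min(sizes[ok]))
}

# Random small electoral map plus an actual world in which the focal
# candidate wins, with at least one won unit.
random_map_world <- function(n_units, max_votes = 9L) {
  repeat {
    votes <- sample.int(max_votes, n_units, replace = TRUE)
    threshold <- sample.int(sum(votes), 1L)
    world <- stats::rbinom(n_units, 1L, runif(1, .3, .8))
    map <- electoral_map(paste0("u", seq_len(n_units)), votes,
      threshold = threshold
    )
    names(world) <- map$units
    if (sum(world) > 0L && presidency_outcome(world, map) == 1L) {
      return(list(map = map, world = world))
    }
  }
}

# Tiny deterministic ratings fixture: ratings constructed from a known
# per-unit pattern.
toy_ratings <- function(values, n_participants = 4L, groups = NULL) {
  m <- matrix(rep(values, each = n_participants), n_participants,
    length(values),
    dimnames = list(
      sprintf("p%02d", seq_len(n_participants)),
      names(values)
    )
  )
  meta <- data.frame(
    participant = rownames(m),
    voted_for = if (is.null(groups)) rep("biden", n_participants) else groups,
    stringsAsFactors = FALSE
  )
  ratings_table(m, meta)
}
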