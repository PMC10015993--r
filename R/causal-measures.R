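#' Counterfactual effect size of a unit (sampled twins)
#'
#' The counterfactual effect size model (CESM) scores the causal strength of
#' "the focal candidate wins unit S" for "the focal candidate wins the
#' presidency" as a standardized average causal effect across counterfactual
#' worlds. For each simulated world, a twin world is created by an
#' intervention that resamples the unit's outcome from its marginal win
#' probability `Pr(S)`, holding every other unit fixed. Over the pairs in
#' which the unit's value actually changed, the ratio of the change in the
#' presidency outcome to the change in the unit outcome (`dP/dS`) is
#' averaged, then multiplied by `sd(S)/sd(P)`. The result behaves like a
#' correlation between S and P that is zeroed when interventions on S cannot
#' move P.
#'
#' Pairs where the resampled twin equals the original carry no ratio and are
#' excluded from the average. If either `sd(S)` or `sd(P)` is zero the score
#' is 0 by convention: a never-varying factor has no effect size.
#'
#' @param ensemble A [world_ensemble] with at least 2 simulations.
#' @param unit Unit name.
#' @param seed Integer seed for the twin resampling (mandatory, so scores are
#'   reproducible).
#' @return Causal-strength score in `[-1, 1]`.
#' @seealso [cesm_exhaustive()] for the variance-free expectation of this
#'   estimator.
#' @export
cesm <- function(ensemble, unit, seed) {
  stopifnot(inherits(ensemble, "world_ensemble"))
  if (nrow(ensemble$outcomes) < 2L) {
    stop("CESM needs at least 2 simulations", call. = FALSE)
  }
  j <- unit_index(ensemble$map, unit)
  st <- unit_stats(ensemble, unit)
  if (st$sd_unit == 0 || st$sd_presidency == 0) {
    return(0)
  }
  col <- ensemble$outcomes[, j]
  twin <- local_seed(seed, stats::rbinom(length(col), 1L, st$p_win))
  ds <- twin - col
  keep <- ds != 0L
  if (!any(keep)) {
    return(0)
  }
  p_twin <- forced_presidency(ensemble, j, twin)
  dp <- p_twin - ensemble$presidency
  ratio <- dp[keep] / ds[keep]
  w <- ensemble$weights[keep]
  mean_ratio <- sum(w * ratio) / sum(w)
  mean_ratio * st$sd_unit / st$sd_presidency
}

#' Counterfactual effect size, variance-free form
#'
#' Replaces the sampled twin of [cesm()] by both possible twin values,
#' weighted by `Pr(S)` and `Pr(not S)`: the exact expectation of the sampled
#' estimator over its resampling randomness. Deterministic, and the default
#' used by [score_all()].
#'
#' When unit outcomes are mutually independent in the ensemble, this equals
#' the weighted Pearson correlation between the unit outcome and the
#' presidency outcome.
#'
#' @inheritParams cesm
#' @return Causal-strength score in `[-1, 1]`.
#' @export
cesm_exhaustive <- function(ensemble, unit) {
  stopifnot(inherits(ensemble, "world_ensemble"))
  if (nrow(ensemble$outcomes) < 2L) {
    stop("CESM needs at least 2 simulations", call. = FALSE)
  }
  j <- unit_index(ensemble$map, unit)
  st <- unit_stats(ensemble, unit)
  p <- st$p_win
  if (st$sd_unit == 0 || st$sd_presidency == 0) {
    return(0)
  }
  col <- ensemble$outcomes[, j]
  p_toggle <- toggled_presidency(ensemble, j)
  dp <- p_toggle - ensemble$presidency
  # a pair differs only when the resampled value lands on the opposite side:
  # probability (1 - p) for originally-won worlds (dS = -1), p for
  # originally-lost worlds (dS = +1); dP/dS = dp/dS either way
  ratio <- dp * ifelse(col == 1L, -1, 1)
  pair_w <- ensemble$weights * ifelse(col == 1L, 1 - p, p)
  mean_ratio <- sum(pair_w * ratio) / sum(pair_w)
  mean_ratio * st$sd_unit / st$sd_presidency
}

#' Is a unit necessary for the actual outcome?
#'
#' Counterfactual necessity in the actual world: would the presidency
#' outcome have failed had the focal candidate lost this unit, everything
#' else unchanged? Defined only for worlds where the outcome occurred.
#'
#' @param actual_world Binary outcome vector over the map's units, with
#'   presidency outcome 1.
#' @param unit Unit name.
#' @param map An [electoral_map].
#' @return `TRUE` iff flipping the unit alone makes the presidency outcome 0.
#' @export
necessity <- function(actual_world, unit, map) {
  if (presidency_outcome(actual_world, map) != 1L) {
    stop(
      "necessity is defined for worlds where the outcome occurred",
      call. = FALSE
    )
  }
  flipped <- flip_unit(actual_world, unit, map)
  presidency_outcome(flipped, map) == 0L
}

#' Sufficiency strength of a unit
#'
#' Among simulations where the focal candidate lost both the unit and the
#' presidency, the (weighted) fraction in which intervening to win the unit
#' would have won the presidency. Returns `NA` when fewer than `min_sims`
#' qualifying simulations exist — with too few qualifying worlds the
#' proportion is not meaningfully estimable (the default cut-off is 10
#' simulations).
#'
#' @param ensemble A [world_ensemble].
#' @param unit Unit name.
#' @param min_sims Minimum number of qualifying simulations (unweighted
#'   count); below it the score is `NA`.
#' @return Score in `[0, 1]`, or `NA_real_`.
#' @export
sufficiency_strength <- function(ensemble, unit, min_sims = 10L) {
  stopifnot(inherits(ensemble, "world_ensemble"))
  j <- unit_index(ensemble$map, unit)
  qualifying <- ensemble$outcomes[, j] == 0L & ensemble$presidency == 0L
  if (sum(qualifying) < min_sims) {
    return(NA_real_)
  }
  p_forced <- forced_presidency(ensemble, j, 1L)
  w <- ensemble$weights[qualifying]
  sum(w * p_forced[qualifying]) / sum(w)
}

#' Necessity-sufficiency causal-strength score
#'
#' Combines counterfactual necessity in the actual world with sufficiency
#' strength across possible worlds. Sufficiency is modulated by `Pr(S)`, the
#' frequency with which counterfactuals where the candidate wins the unit
#' come to mind. The default combination is
#' `w_nec * 1(necessary) + Pr(S) * sufficiency`, with `w_nec = 1`; the rule
#' and weight used are recorded in the result's attributes so downstream
#' output can report them.
#'
#' @inheritParams sufficiency_strength
#' @param actual_world Binary outcome vector with presidency outcome 1.
#' @param w_nec Weight on the necessity indicator.
#' @return Score (`NA` when sufficiency is `NA`), with attributes
#'   `combination` and `w_nec`.
#' @export
nsm_score <- function(ensemble, unit, actual_world, min_sims = 10L,
                      w_nec = 1) {
  suff <- sufficiency_strength(ensemble, unit, min_sims = min_sims)
  if (is.na(suff)) {
    out <- NA_real_
  } else {
    nec <- necessity(actual_world, unit, ensemble$map)
    p <- unit_stats(ensemble, unit)$p_win
    out <- w_nec * as.numeric(nec) + p * suff
  }
  structure(out,
    combination = "w_nec * 1(necessary) + Pr(S) * sufficiency",
    w_nec = w_nec
  )
}

#' Distance from pivotality
#'
#' A unit the focal candidate won is pivotal if flipping it alone would flip
#' the presidency outcome. Its distance from pivotality, `k`, is the minimal
#' number of OTHER units whose outcomes must change before the focal unit
#' becomes pivotal; causal strength is `1 / (1 + k)`. Equivalently, after the
#' `k` flips the focal candidate's vote total excluding the focal unit must
#' land in `[threshold - votes_unit, threshold - 1]`.
#'
#' The minimum is found by dynamic programming over reachable vote totals
#' (flipping a won unit subtracts its votes, flipping a lost unit adds them;
#' each unit flips at most once — a 0/1 knapsack on minimal flip counts,
#' bounded by the map's total votes).
#'
#' @param actual_world Binary outcome vector with presidency outcome 1; the
#'   focal unit must have been won.
#' @param unit Unit name.
#' @param map An [electoral_map].
#' @return List with `k` (integer distance) and `strength` (`1/(1+k)`); both
#'   `NA` with a `reason` attribute when no flip set makes the unit pivotal.
#' @export
pivotality <- function(actual_world, unit, map) {
  stopifnot(inherits(map, "electoral_map"))
  if (presidency_outcome(actual_world, map) != 1L) {
    stop(
      "pivotality is defined for worlds where the outcome occurred",
      call. = FALSE
    )
  }
  j <- unit_index(map, unit)
  if (actual_world[j] != 1L) {
    stop(sprintf("unit '%s' was not won in the actual world", unit),
      call. = FALSE
    )
  }
  v_focal <- map$votes[j]
  lo <- map$threshold - v_focal
  hi <- map$threshold - 1L

  others <- setdiff(seq_along(map$units), j)
  rest <- sum(map$votes[others] * actual_world[others])
  # dp over totals 0..max_total: minimal flips among the other units to move
  # the focal-excluded total from `rest` to each value
  max_total <- sum(map$votes[others])
  dp <- rep(NA_integer_, max_total + 1L) # index t+1 <-> total t
  dp[rest + 1L] <- 0L
  for (u in others) {
    delta <- if (actual_world[u] == 1L) -map$votes[u] else map$votes[u]
    new_dp <- dp
    reachable <- which(!is.na(dp)) - 1L
    targets <- reachable + delta
    ok <- targets >= 0L & targets <= max_total
    if (any(ok)) {
      cand <- dp[reachable[ok] + 1L] + 1L
      idx <- targets[ok] + 1L
      better <- is.na(new_dp[idx]) | cand < new_dp[idx]
      new_dp[idx[better]] <- cand[better]
    }
    dp <- new_dp
  }
  window <- intersect(seq.int(max(lo, 0L), min(hi, max_total)) + 1L,
                      which(!is.na(dp)))
  if (lo > max_total || hi < 0L || length(window) == 0L) {
    return(structure(list(k = NA_integer_, strength = NA_real_),
      reason = "no reachable pivotal configuration"
    ))
  }
  k <- min(dp[window])
  list(k = k, strength = 1 / (1 + k))
}

#' Observational Delta-P
#'
#' The probabilistic contrast `P(win presidency | won unit) - P(win
#' presidency | lost unit)`, computed under the ensemble weights. `NA` when
#' either conditioning stratum has zero weight.
#'
#' @inheritParams sufficiency_strength
#' @return Score in `[-1, 1]`, or `NA_real_`.
#' @export
delta_p_observational <- function(ensemble, unit) {
  stopifnot(inherits(ensemble, "world_ensemble"))
  j <- unit_index(ensemble$map, unit)
  col <- ensemble$outcomes[, j]
  w1 <- sum(ensemble$weights[col == 1L])
  w0 <- sum(ensemble$weights[col == 0L])
  if (w1 == 0 || w0 == 0) {
    return(NA_real_)
  }
  p1 <- sum(ensemble$weights[col == 1L] * ensemble$presidency[col == 1L]) / w1
  p0 <- sum(ensemble$weights[col == 0L] * ensemble$presidency[col == 0L]) / w0
  p1 - p0
}

#' Interventional Delta-P (probability of necessity and sufficiency)
#'
#' The contrast that conditions on interventions rather than observations:
#' within each simulated world, force the unit to a win and to a loss (other
#' units fixed) and average the difference in presidency outcomes over the
#' ensemble. Always defined, and equal to the probability that the unit is
#' necessary and sufficient for the outcome, so this single function backs
#' both the `delta_p_int` and `pns` columns of a score table. Coincides with
#' [delta_p_observational()] when unit outcomes are independent; the two
#' diverge under correlated outcomes (e.g. a shared national swing).
#'
#' @inheritParams sufficiency_strength
#' @return Score in `[-1, 1]`.
#' @export
delta_p_interventional <- function(ensemble, unit) {
  stopifnot(inherits(ensemble, "world_ensemble"))
  j <- unit_index(ensemble$map, unit)
  p_win <- forced_presidency(ensemble, j, 1L)
  p_lose <- forced_presidency(ensemble, j, 0L)
  sum(ensemble$weights * (p_win - p_lose))
}

#' Cheng's causal power (Power-PC), generative form
#'
#' Observational Delta-P rescaled by the headroom left by the background:
#' `delta_p / (1 - P(win presidency | lost unit))`. `NA` when the lost-unit
#' stratum is empty or the background probability is 1 (no headroom).
#'
#' @inheritParams sufficiency_strength
#' @return Score, or `NA_real_`.
#' @export
power_pc <- function(ensemble, unit) {
  stopifnot(inherits(ensemble, "world_ensemble"))
  j <- unit_index(ensemble$map, unit)
  col <- ensemble$outcomes[, j]
  w0 <- sum(ensemble$weights[col == 0L])
  if (w0 == 0) {
    return(NA_real_)
  }
  p0 <- sum(ensemble$weights[col == 0L] * ensemble$presidency[col == 0L]) / w0
  if (p0 >= 1) {
    return(NA_real_)
  }
  dp <- delta_p_observational(ensemble, unit)
  dp / (1 - p0)
}

#' Score every won unit under a set of causal measures
#'
#' Builds the unit-by-measure causal score table: one row per unit the focal
#' candidate won in the actual world, one column per requested measure.
#' `NA` appears only where a measure's own precondition fails (too few
#' qualifying simulations for sufficiency, empty conditioning stratum, no
#' reachable pivotal configuration).
#'
#' @param ensemble A [world_ensemble].
#' @param actual_world Binary outcome vector over the map's units with
#'   presidency outcome 1.
#' @param measures Subset of
#'   `c("cesm", "nsm", "pivotality", "delta_p_obs", "pns", "power_pc")`.
#' @param config A [measure_config()] list: CESM evaluation method and seed,
#'   sufficiency cut-off, necessity weight.
#' @return Data frame with a `unit` column and one numeric column per
#'   measure, `config` stored as an attribute. `pns` is the interventional
#'   Delta-P.
#' @export
score_all <- function(ensemble, actual_world,
                      measures = c(
                        "cesm", "nsm", "pivotality",
                        "delta_p_obs", "pns", "power_pc"
                      ),
                      config = measure_config()) {
  stopifnot(inherits(ensemble, "world_ensemble"))
  measures <- match.arg(measures, several.ok = TRUE)
  map <- ensemble$map
  if (length(actual_world) != length(map$units)) {
    stop("`actual_world` must cover every map unit", call. = FALSE)
  }
  won <- map$units[actual_world == 1L]
  if (length(won) == 0L) {
    stop("the focal candidate won no units in `actual_world`", call. = FALSE)
  }

  out <- data.frame(unit = won, stringsAsFactors = FALSE)
  for (m in measures) {
    out[[m]] <- vapply(won, function(u) {
      switch(m,
        cesm = if (identical(config$cesm_method, "sampled")) {
          cesm(ensemble, u, seed = config$cesm_seed)
        } else {
          cesm_exhaustive(ensemble, u)
        },
        nsm = as.numeric(nsm_score(ensemble, u, actual_world,
          min_sims = config$min_sims, w_nec = config$nsm_w_nec
        )),
        pivotality = pivotality(actual_world, u, map)$strength,
        delta_p_obs = delta_p_observational(ensemble, u),
        pns = delta_p_interventional(ensemble, u),
        power_pc = power_pc(ensemble, u)
      )
    }, numeric(1))
  }
  attr(out, "config") <- config
  out
}

#' Configuration for the causal measures
#'
#' @param cesm_method `"exhaustive"` (variance-free twin expectation, the
#'   default) or `"sampled"` (one resampled twin per simulation).
#' @param cesm_seed Seed for the sampled CESM; required when
#'   `cesm_method = "sampled"`.
#' @param min_sims Sufficiency-strength qualifying-simulation cut-off.
#' @param nsm_w_nec Necessity weight in the necessity-sufficiency
#'   combination.
#' @return A named list of class `measure_config`.
#' @export
measure_config <- function(cesm_method = c("exhaustive", "sampled"),
                           cesm_seed = NULL, min_sims = 10L, nsm_w_nec = 1) {
  cesm_method <- match.arg(cesm_method)
  if (identical(cesm_method, "sampled") && is.null(cesm_seed)) {
    stop("`cesm_seed` is required when cesm_method = \"sampled\"",
      call. = FALSE
    )
  }
  structure(
    list(
      cesm_method = cesm_method, cesm_seed = cesm_seed,
      min_sims = as.integer(min_sims), nsm_w_nec = nsm_w_nec
    ),
    class = "measure_config"
  )
}
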