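#' Specification of a synthetic forecast ensemble
#'
#' A latent-margin probit generator for forecast-like world ensembles. Unit
#' `j` in simulation `i` is won iff `mu_j + eta_i + eps_ij > 0`, with a
#' national shock `eta_i ~ Normal(0, sigma_nat)` shared by all units of a
#' simulation and independent unit shocks `eps_ij ~ Normal(0, sigma_unit)`.
#' The marginal win probability is therefore
#' `Phi(mu_j / sqrt(sigma_nat^2 + sigma_unit^2))`, and `sigma_nat > 0`
#' induces the positive cross-state outcome correlation real forecasts
#' exhibit (a uniform national polling swing). This is the simplest generator
#' with the two features the causal measures are sensitive to —
#' heterogeneous win probabilities and correlated outcomes — and makes no
#' attempt to emulate poll aggregation or a real forecast's richer
#' correlation structure.
#'
#' @param mu Per-unit prior mean margin on the latent scale; named by unit or
#'   aligned with `map$units`.
#' @param map An [electoral_map].
#' @param seed Integer seed (mandatory).
#' @param sigma_nat National shock SD, `>= 0`.
#' @param sigma_unit Unit shock SD, `> 0`.
#' @return Object of class `forecast_spec`.
#' @export
forecast_spec <- function(mu, map, seed, sigma_nat = 1, sigma_unit = 1) {
  stopifnot(inherits(map, "electoral_map"))
  if (!is.null(names(mu))) {
    missing <- setdiff(map$units, names(mu))
    if (length(missing)) {
      stop("`mu` missing units: ", paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
    mu <- mu[map$units]
  } else if (length(mu) == length(map$units)) {
    names(mu) <- map$units
  } else {
    stop("`mu` must have one entry per map unit", call. = FALSE)
  }
  if (sigma_unit <= 0) {
    stop("`sigma_unit` must be positive (a degenerate generator has no ",
      "per-unit outcome uncertainty)",
      call. = FALSE
    )
  }
  if (sigma_nat < 0) stop("`sigma_nat` must be >= 0", call. = FALSE)
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory", call. = FALSE)
  structure(
    list(
      mu = mu, map = map, seed = as.integer(seed),
      sigma_nat = sigma_nat, sigma_unit = sigma_unit
    ),
    class = "forecast_spec"
  )
}

#' Implied marginal win probabilities of a forecast spec
#'
#' The probit closed form `Phi(mu / sqrt(sigma_nat^2 + sigma_unit^2))`,
#' against which simulated win frequencies converge at rate `1/sqrt(n)`.
#'
#' @param spec A [forecast_spec].
#' @return Named vector of win probabilities.
#' @export
implied_p_win <- function(spec) {
  stopifnot(inherits(spec, "forecast_spec"))
  stats::pnorm(spec$mu / sqrt(spec$sigma_nat^2 + spec$sigma_unit^2))
}

#' Simulate a forecast-like world ensemble
#'
#' Draws `n_sims` worlds from the latent-margin probit model of a
#' [forecast_spec]. Bit-reproducible from the spec's seed.
#'
#' @param spec A [forecast_spec].
#' @param n_sims Number of simulations, `>= 1`.
#' @return A [world_ensemble] with uniform weights.
#' @export
simulate_forecast <- function(spec, n_sims) {
  stopifnot(inherits(spec, "forecast_spec"))
  n_sims <- as.integer(n_sims)
  if (is.na(n_sims) || n_sims < 1L) {
    stop("`n_sims` must be >= 1", call. = FALSE)
  }
  k <- length(spec$mu)
  outcomes <- local_seed(spec$seed, {
    eta <- stats::rnorm(n_sims, 0, spec$sigma_nat)
    eps <- matrix(stats::rnorm(n_sims * k, 0, spec$sigma_unit), n_sims, k)
    latent <- sweep(eps + eta, 2L, spec$mu, `+`)
    (latent > 0) + 0L
  })
  colnames(outcomes) <- spec$map$units
  world_ensemble(spec$map, outcomes)
}

# Final-week Biden win probabilities in the style of a 2020 poll-aggregation
# forecast; synthetic round numbers, not a copy of any published table.
forecast_2020_p_win <- function() {
  c(
    AL = 0.03, AK = 0.12, AZ = 0.67, AR = 0.02, CA = 0.999, CO = 0.96,
    CT = 0.99, DE = 0.99, DC = 0.999, FL = 0.69, GA = 0.58, HI = 0.99,
    ID = 0.01, IL = 0.99, IN = 0.05, IA = 0.41, KS = 0.05, KY = 0.01,
    LA = 0.03, ME = 0.94, MD = 0.999, MA = 0.999, MI = 0.95, MN = 0.90,
    MS = 0.06, MO = 0.09, MT = 0.12, NE = 0.05, NV = 0.89, NH = 0.89,
    NJ = 0.99, NM = 0.97, NY = 0.999, NC = 0.64, ND = 0.01, OH = 0.45,
    OK = 0.01, OR = 0.97, PA = 0.84, RI = 0.99, SC = 0.08, SD = 0.02,
    TN = 0.03, TX = 0.38, UT = 0.03, VT = 0.999, VA = 0.98, WA = 0.99,
    WV = 0.01, WI = 0.94, WY = 0.005
  )
}

#' A 2020-style forecast spec
#'
#' Preset [forecast_spec] on the full [us_electoral_map_2020()]: per-state
#' latent margins back-solved so the marginal win probabilities match a
#' plausible final-week 2020 forecast (safe Democratic states near 0.99,
#' Georgia near 0.58, and so on), with a shared national shock producing
#' correlated state outcomes. This is the package's stand-in for a real
#' forecast simulation file; it reproduces the qualitative structure the
#' measures respond to (a close 16-vote Georgia scores high under the
#' effect-size measure while a safe 55-vote California scores high under
#' pivotality), not any real forecast's exact numbers.
#'
#' @param seed Integer seed.
#' @param sigma_nat,sigma_unit Shock SDs as in [forecast_spec()].
#' @return A [forecast_spec] over 51 units.
#' @export
forecast_spec_2020 <- function(seed, sigma_nat = 1, sigma_unit = 1) {
  p <- forecast_2020_p_win()
  scale <- sqrt(sigma_nat^2 + sigma_unit^2)
  mu <- stats::qnorm(p) * scale
  forecast_spec(mu, us_electoral_map_2020(), seed,
    sigma_nat = sigma_nat, sigma_unit = sigma_unit
  )
}

#' Specification of a synthetic ratings table
#'
#' Generates participant-by-unit ratings on the 0-10 agreement scale as a
#' noisy monotone function of a chosen generating model's causal scores:
#' `rating = clip(round(intercept + slope * z(score) + a_p + offset_g +
#' e_pj), 0, 10)` with participant effects `a_p ~ Normal(0, participant_sd)`
#' and residuals `e ~ Normal(0, residual_sd)`. Participants belong to groups
#' (e.g. which candidate they voted for) that shift the mean additively but
#' leave the ranking of units intact — mimicking the empirical pattern that
#' supporters of the losing candidate give lower ratings overall while
#' ranking states almost identically.
#'
#' Default calibration: `slope = 2` and `residual_sd = 3` put the expected
#' within-participant correlation with the generating scores near
#' `slope / sqrt(slope^2 + residual_sd^2) = 0.55`, the individual-level fit
#' observed in the election study; group fractions echo its sample (about
#' 76% voters of the winner, 14% of the loser, 10% others). The loser-voter
#' latent offset of -2.0 is calibrated so the OBSERVED group means land near
#' 4.6 and 2.9 (the study's values) after the floor at 0 compresses the
#' lower group's ratings.
#'
#' @param scores Named numeric vector of generating-model scores per rated
#'   unit (no NA).
#' @param n_participants Number of participants.
#' @param seed Integer seed (mandatory).
#' @param intercept,slope Map from standardized scores to the 0-10 scale.
#' @param participant_sd,residual_sd Participant-effect and residual SDs.
#' @param groups Data frame with columns `group`, `fraction` (summing to 1),
#'   `offset`, and optionally `p_legitimate` (probability a member believes
#'   the outcome legitimate).
#' @return Object of class `rating_spec`.
#' @export
rating_spec <- function(scores, n_participants = 207L, seed,
                        intercept = 4.6, slope = 2,
                        participant_sd = 1, residual_sd = 3,
                        groups = default_rating_groups()) {
  if (length(scores) == 0L) stop("`scores` must be nonempty", call. = FALSE)
  if (anyNA(scores)) {
    stop("generating scores must have no NA for rated units", call. = FALSE)
  }
  if (is.null(names(scores))) {
    stop("`scores` must be named by unit", call. = FALSE)
  }
  if (missing(seed) || is.null(seed)) stop("`seed` is mandatory", call. = FALSE)
  stopifnot(
    is.data.frame(groups),
    all(c("group", "fraction", "offset") %in% names(groups))
  )
  if (abs(sum(groups$fraction) - 1) > 1e-8) {
    stop("group fractions must sum to 1", call. = FALSE)
  }
  structure(
    list(
      scores = scores, n_participants = as.integer(n_participants),
      seed = as.integer(seed), intercept = intercept, slope = slope,
      participant_sd = participant_sd, residual_sd = residual_sd,
      groups = groups
    ),
    class = "rating_spec"
  )
}

#' Default participant group mixture
#'
#' Two-main-group mixture with a small remainder, echoing the composition of
#' the election-study sample: winner's voters (offset 0), loser's voters
#' (latent offset -2.0, chosen so the observed group means straddle the
#' study's 4.6-vs-2.9 split after clipping; mostly disbelieving the
#' outcome's legitimacy), others.
#'
#' @return Data frame with `group`, `fraction`, `offset`, `p_legitimate`.
#' @export
default_rating_groups <- function() {
  data.frame(
    group = c("biden", "trump", "other"),
    fraction = c(0.763, 0.140, 0.097),
    offset = c(0, -2.0, -0.8),
    p_legitimate = c(0.98, 0.28, 0.80),
    stringsAsFactors = FALSE
  )
}

#' Simulate a ratings table
#'
#' Draws a [ratings_table] from a [rating_spec]: group sizes by largest-
#' remainder rounding of the fractions, then the additive participant /
#' group / residual noise model, rounded to integers and clipped to
#' `[0, 10]`. Bit-reproducible from the spec's seed.
#'
#' @param spec A [rating_spec].
#' @return A [ratings_table].
#' @export
simulate_ratings <- function(spec) {
  stopifnot(inherits(spec, "rating_spec"))
  n <- spec$n_participants
  k <- length(spec$scores)
  z <- as.vector(scale(spec$scores))
  if (k == 1L || stats::sd(spec$scores) == 0) {
    z <- rep(0, k)
  }

  sizes <- largest_remainder(spec$groups$fraction, n)
  group <- rep(spec$groups$group, sizes)

  dat <- local_seed(spec$seed, {
    a <- stats::rnorm(n, 0, spec$participant_sd)
    e <- matrix(stats::rnorm(n * k, 0, spec$residual_sd), n, k)
    p_leg <- if ("p_legitimate" %in% names(spec$groups)) {
      rep(spec$groups$p_legitimate, sizes)
    } else {
      rep(1, n)
    }
    leg <- stats::rbinom(n, 1L, p_leg) == 1L
    list(a = a, e = e, leg = leg)
  })

  offset <- rep(spec$groups$offset, sizes)
  latent <- spec$intercept + outer(rep(1, n), spec$slope * z) +
    dat$a + offset + dat$e
  ratings <- pmin(pmax(round(latent), 0), 10)
  storage.mode(ratings) <- "integer"
  rownames(ratings) <- sprintf("p%03d", seq_len(n))
  colnames(ratings) <- names(spec$scores)

  party <- c(biden = "democrat", trump = "republican", other = "independent")
  meta <- data.frame(
    participant = rownames(ratings),
    voted_for = group,
    party_id = ifelse(group %in% names(party), party[group], "other"),
    believes_legitimate = dat$leg,
    stringsAsFactors = FALSE
  )
  ratings_table(ratings, meta)
}

# Largest-remainder apportionment of n into integer group sizes.
largest_remainder <- function(fractions, n) {
  raw <- fractions * n
  sizes <- floor(raw)
  short <- n - sum(sizes)
  if (short > 0) {
    order_rem <- order(raw - sizes, decreasing = TRUE)
    sizes[order_rem[seq_len(short)]] <- sizes[order_rem[seq_len(short)]] + 1
  }
  as.integer(sizes)
}
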