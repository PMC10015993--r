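#' Per-unit mean ratings with confidence intervals
#'
#' Unweighted mean causal rating per unit across participants, with a
#' t-based 95% CI (`mean +/- t_{0.975, n-1} * SE`). With a single
#' participant the CI is undefined and returned as `NA` with a warning.
#'
#' @param ratings A [ratings_table].
#' @param conf_level Confidence level for the interval.
#' @return Data frame with `unit`, `mean`, `ci_lo`, `ci_hi`, `n`.
#' @export
state_means <- function(ratings, conf_level = 0.95) {
  stopifnot(inherits(ratings, "ratings_table"))
  m <- ratings$ratings
  n <- nrow(m)
  means <- colMeans(m)
  if (n < 2L) {
    warning("single participant: confidence intervals undefined")
    half <- rep(NA_real_, ncol(m))
  } else {
    se <- apply(m, 2L, stats::sd) / sqrt(n)
    half <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1L) * se
  }
  data.frame(
    unit = colnames(m), mean = unname(means),
    ci_lo = unname(means - half), ci_hi = unname(means + half),
    n = n, stringsAsFactors = FALSE
  )
}

# internal: align a named score vector (or score-table column) with a means
# table / named vector; returns complete pairs
align_pairs <- function(scores, means) {
  if (is.data.frame(means)) {
    mv <- stats::setNames(means$mean, means$unit)
  } else {
    mv <- means
  }
  if (is.null(names(scores)) || is.null(names(mv))) {
    stop("scores and means must be named by unit", call. = FALSE)
  }
  common <- intersect(names(scores), names(mv))
  x <- scores[common]
  y <- mv[common]
  ok <- !is.na(x) & !is.na(y)
  list(x = unname(x[ok]), y = unname(y[ok]), units = common[ok])
}

#' Correlation between a model's scores and mean human ratings
#'
#' Pearson correlation over the units where both the model score and the
#' human mean are available (pairwise-complete), with the t-transform
#' two-sided p-value and `df = n - 2`. The df bookkeeping matters because
#' some measures are undefined for some units (e.g. sufficiency strength in
#' units the candidate essentially never loses), so different models can be
#' evaluated on different unit subsets.
#'
#' @param scores Named numeric vector of model scores per unit (NA allowed).
#' @param means A [state_means()] data frame or named vector of human means.
#' @return Data frame (one row) with `r`, `df`, `p`, `n_used`.
#' @export
model_human_correlation <- function(scores, means) {
  pr <- align_pairs(scores, means)
  n <- length(pr$x)
  if (n < 3L) {
    stop("need at least 3 complete unit pairs", call. = FALSE)
  }
  ct <- stats::cor.test(pr$x, pr$y, method = "pearson")
  data.frame(
    r = unname(ct$estimate), df = n - 2L, p = ct$p.value, n_used = n
  )
}

#' Per-participant correlations with a model's scores
#'
#' One Pearson correlation per participant between that participant's
#' ratings and the model scores, over units where the score is defined.
#' Participants with zero rating variance on those units have no defined
#' correlation and are excluded, with the exclusion count reported.
#'
#' @param ratings A [ratings_table].
#' @param scores Named numeric score vector (NA allowed).
#' @return List with `r` (named vector, one per retained participant),
#'   `median`, `n_excluded`.
#' @export
individual_correlations <- function(ratings, scores) {
  stopifnot(inherits(ratings, "ratings_table"))
  keep_units <- intersect(ratings$units, names(scores)[!is.na(scores)])
  if (length(keep_units) < 3L) {
    stop("need at least 3 scored units", call. = FALSE)
  }
  s <- scores[keep_units]
  m <- ratings$ratings[, keep_units, drop = FALSE]
  variances <- apply(m, 1L, stats::var)
  usable <- variances > 0
  r <- apply(m[usable, , drop = FALSE], 1L, function(row) {
    stats::cor(row, s)
  })
  list(
    r = r,
    median = stats::median(r),
    n_excluded = sum(!usable)
  )
}

#' Paired permutation test between two models' fits
#'
#' Tests whether model A predicts the human unit means better than model B.
#' The observed statistic is `T = |r_A| - |r_B|` on the units where both
#' models and the means are available. The null distribution is built by
#' independently swapping, per unit, which model contributed which
#' prediction (the standard paired scheme for two predictors of one target);
#' the two-sided p-value is `(1 + #{|T_perm| >= |T_obs|}) / (1 + n_perm)`.
#' The scheme and statistic are recorded in the result.
#'
#' @param scores_a,scores_b Named score vectors (NA allowed).
#' @param means A [state_means()] data frame or named vector.
#' @param n_perm Number of permutations, at least 100.
#' @param seed Integer seed.
#' @return List with `t_obs`, `r_a`, `r_b`, `p`, `n_units`, `n_perm`,
#'   `scheme`.
#' @export
paired_permutation_test <- function(scores_a, scores_b, means,
                                    n_perm = 10000L, seed) {
  if (n_perm < 100L) {
    stop("`n_perm` must be at least 100", call. = FALSE)
  }
  pa <- align_pairs(scores_a, means)
  pb <- align_pairs(scores_b, means)
  common <- intersect(pa$units, pb$units)
  if (length(common) < 3L) {
    stop("need at least 3 units where both models are defined", call. = FALSE)
  }
  a <- pa$x[match(common, pa$units)]
  b <- pb$x[match(common, pb$units)]
  y <- pa$y[match(common, pa$units)]
  k <- length(common)

  r_a <- stats::cor(a, y)
  r_b <- stats::cor(b, y)
  t_obs <- abs(r_a) - abs(r_b)

  t_perm <- local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      swap <- stats::runif(k) < 0.5
      ap <- ifelse(swap, b, a)
      bp <- ifelse(swap, a, b)
      abs(stats::cor(ap, y)) - abs(stats::cor(bp, y))
    }, numeric(1))
  })
  p <- (1 + sum(abs(t_perm) >= abs(t_obs))) / (1 + n_perm)
  list(
    t_obs = t_obs, r_a = r_a, r_b = r_b, p = p,
    n_units = k, n_perm = n_perm,
    scheme = "per-unit swap of model labels; statistic |r_A| - |r_B|"
  )
}

# internal: z-score (sample SD)
zscore <- function(x) {
  s <- stats::sd(x)
  if (s == 0) stop("cannot z-score a constant predictor", call. = FALSE)
  (x - mean(x)) / s
}

#' Standardized multiple regression of means on a score plus covariates
#'
#' OLS after z-scoring the outcome and every predictor, so the coefficients
#' are standardized betas comparable across predictors. Listwise-complete
#' cases; perfect collinearity is an error.
#'
#' @param means A [state_means()] data frame or named vector (the outcome).
#' @param score Named score vector, the focal predictor.
#' @param covariates Named list of named per-unit covariate vectors (e.g.
#'   prior win probability, electoral votes).
#' @return Data frame with one row per predictor: `predictor`, `beta`, `p`,
#'   plus attribute `n`.
#' @export
partial_regression <- function(means, score, covariates = list()) {
  pr <- align_pairs(score, means)
  dat <- data.frame(.outcome = pr$y, score = pr$x, row.names = pr$units)
  for (nm in names(covariates)) {
    cv <- covariates[[nm]]
    if (is.null(names(cv))) {
      stop("covariates must be named by unit", call. = FALSE)
    }
    dat[[nm]] <- unname(cv[rownames(dat)])
  }
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < ncol(dat) + 2L) {
    stop("too few complete cases for the regression", call. = FALSE)
  }
  dat[] <- lapply(dat, zscore)
  fit <- stats::lm(.outcome ~ . + 0, data = dat)
  if (any(is.na(stats::coef(fit)))) {
    stop("perfectly collinear predictors", call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  out <- data.frame(
    predictor = rownames(sm), beta = sm[, 1L], p = sm[, 4L],
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "n") <- nrow(dat)
  out
}

#' Regress per-unit values on prior probability and electoral votes
#'
#' The decomposition used to understand what drives each model: standardized
#' betas from regressing a per-unit target (human means or a model's scores)
#' on the prior win probability of the unit and its electoral votes.
#' Measures that track outcome uncertainty show a dominant (negative)
#' probability beta; measures that track vote weight show a dominant votes
#' beta.
#'
#' @param target Named per-unit numeric vector (NA allowed; listwise
#'   dropped).
#' @param ensemble A [world_ensemble] supplying the win probabilities.
#' @param map Electoral map supplying the vote counts; defaults to the
#'   ensemble's map.
#' @return Data frame with rows `prob` and `votes`: `predictor`, `beta`,
#'   `p`; attribute `n`.
#' @export
prior_votes_regression <- function(target, ensemble, map = ensemble$map) {
  stopifnot(inherits(ensemble, "world_ensemble"))
  if (is.null(names(target))) {
    stop("`target` must be named by unit", call. = FALSE)
  }
  units <- names(target)
  p_win <- vapply(units, function(u) unit_stats(ensemble, u)$p_win, numeric(1))
  votes <- map$votes[units]
  dat <- data.frame(
    .outcome = unname(target), prob = unname(p_win),
    votes = as.numeric(votes), row.names = units
  )
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (nrow(dat) < 4L) {
    stop("too few complete cases for the regression", call. = FALSE)
  }
  dat[] <- lapply(dat, zscore)
  fit <- stats::lm(.outcome ~ prob + votes + 0, data = dat)
  sm <- summary(fit)$coefficients
  out <- data.frame(
    predictor = rownames(sm), beta = sm[, 1L], p = sm[, 4L],
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "n") <- nrow(dat)
  out
}

#' Subgroup invariance of causal ratings
#'
#' Splits participants by a metadata field, computes per-group unit means,
#' and reports (a) the Pearson correlation between the two groups' mean
#' vectors — near 1 when the groups rank units the same way even if their
#' levels differ — and (b) a Welch two-sample t-test on participant-level
#' overall mean ratings, which picks up additive level shifts between the
#' groups.
#'
#' @param ratings A [ratings_table].
#' @param grouping Metadata column name (default `"voted_for"`).
#' @param groups The two group labels to compare; default the two largest.
#' @return List with `groups`, `r`, `r_p`, `t`, `df`, `p`, `group_means`
#'   (unit x group matrix), `overall_means` (named per-group participant-
#'   level means).
#' @export
subgroup_invariance <- function(ratings, grouping = "voted_for",
                                groups = NULL) {
  stopifnot(inherits(ratings, "ratings_table"))
  g <- ratings$meta[[grouping]]
  if (is.null(g)) {
    stop(sprintf("no metadata field '%s'", grouping), call. = FALSE)
  }
  g <- as.character(g)
  if (is.null(groups)) {
    tab <- sort(table(g), decreasing = TRUE)
    if (length(tab) < 2L) {
      stop("need at least two groups", call. = FALSE)
    }
    groups <- names(tab)[1:2]
  }
  idx <- lapply(groups, function(lv) which(g == lv))
  if (any(lengths(idx) < 2L)) {
    stop("each group needs at least 2 participants", call. = FALSE)
  }

  gm <- vapply(idx, function(ix) {
    colMeans(ratings$ratings[ix, , drop = FALSE])
  }, numeric(ncol(ratings$ratings)))
  colnames(gm) <- groups

  ct <- stats::cor.test(gm[, 1L], gm[, 2L])
  pm1 <- rowMeans(ratings$ratings[idx[[1L]], , drop = FALSE])
  pm2 <- rowMeans(ratings$ratings[idx[[2L]], , drop = FALSE])
  tt <- stats::t.test(pm1, pm2, var.equal = FALSE)

  list(
    groups = groups,
    r = unname(ct$estimate), r_p = ct$p.value,
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    group_means = gm,
    overall_means = stats::setNames(c(mean(pm1), mean(pm2)), groups)
  )
}
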