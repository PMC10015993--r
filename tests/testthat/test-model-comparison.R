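test_that("state means and t-based confidence intervals", {
  rt <- toy_ratings(c(GA = 7L, AZ = 7L, PA = 7L))
  sm <- state_means(rt)
  expect_equal(sm$mean, rep(7, 3))
  expect_equal(sm$ci_hi - sm$ci_lo, rep(0, 3))
  # ratings {0, 10} -> mean 5, CI from the t quantile
  m <- matrix(c(0L, 10L), 2, 1, dimnames = list(c("p1", "p2"), "GA"))
  rt2 <- ratings_table(m, data.frame(participant = c("p1", "p2")))
  sm2 <- state_means(rt2)
  expect_equal(sm2$mean, 5)
  expect_equal(sm2$ci_hi, 5 + qt(.975, 1) * sd(c(0, 10)) / sqrt(2))
  # single participant: CI flagged undefined
  m1 <- matrix(3L, 1, 1, dimnames = list("p1", "GA"))
  expect_warning(
    sm1 <- state_means(ratings_table(m1, data.frame(participant = "p1"))),
    "single participant"
  )
  expect_true(is.na(sm1$ci_lo))
})

test_that("state means of a synthetic table match generator expectations", {
  scores <- c(GA = 2, AZ = 1, PA = 0, CA = -1, WI = -2)
  spec <- rating_spec(scores,
    n_participants = 500L, seed = 2, intercept = 5, slope = 1.5,
    participant_sd = 0.5, residual_sd = 1,
    groups = data.frame(group = "biden", fraction = 1, offset = 0)
  )
  sm <- state_means(simulate_ratings(spec))
  expected <- 5 + 1.5 * as.vector(scale(scores))
  expect_lt(max(abs(sm$mean - expected[match(sm$unit, names(scores))])), 0.2)
})

test_that("model-human correlation with df bookkeeping over NA patterns", {
  means <- c(GA = 6, AZ = 5, PA = 4, CA = 2, WI = 5.5)
  expect_equal(model_human_correlation(means, means)$r, 1)
  expect_equal(model_human_correlation(-means, means)$r, -1)
  scores <- c(GA = .5, AZ = .4, PA = NA, CA = .1, WI = .45)
  fit <- model_human_correlation(scores, means)
  expect_identical(fit$n_used, 4L)
  expect_identical(fit$df, 2L)
  expect_error(
    model_human_correlation(c(GA = 1, AZ = 2), means), "at least 3"
  )
  # p-value agrees with the t transform
  expect_equal(
    fit$p,
    2 * pt(abs(fit$r) * sqrt(fit$df / (1 - fit$r^2)), fit$df,
      lower.tail = FALSE
    )
  )
})

test_that("per-participant correlations exclude zero-variance raters", {
  scores <- c(GA = .9, AZ = .6, PA = .3, CA = .1)
  m <- rbind(
    p1 = c(9L, 6L, 3L, 1L), # perfect monotone copy
    p2 = c(8L, 5L, 2L, 0L),
    p3 = c(5L, 5L, 5L, 5L) # no variance
  )
  colnames(m) <- names(scores)
  rt <- ratings_table(m, data.frame(participant = rownames(m)))
  ic <- individual_correlations(rt, scores)
  expect_identical(ic$n_excluded, 1L)
  expect_equal(unname(ic$r), rep(cor(c(9, 6, 3, 1), scores), 2),
    tolerance = 1e-12
  )
  expect_equal(ic$median, ic$r[["p1"]])
})

test_that("paired permutation test: identity, power, and symmetry", {
  means <- c(
    GA = 6.1, AZ = 5.2, PA = 4.9, CA = 2.2, WI = 5.6, MI = 5.1,
    NV = 4.4, NY = 1.8, VA = 3.1, CO = 3.4
  )
  a <- means / 10
  expect_equal(
    paired_permutation_test(a, a, means, n_perm = 200, seed = 1)$p, 1
  )
  set.seed(9)
  noise <- setNames(rnorm(10), names(means))
  res <- paired_permutation_test(a, noise, means, n_perm = 2000, seed = 2)
  expect_lt(res$p, 0.05)
  flipped <- paired_permutation_test(noise, a, means, n_perm = 2000, seed = 2)
  expect_equal(res$p, flipped$p)
  expect_error(
    paired_permutation_test(a, noise, means, n_perm = 50, seed = 1),
    "at least 100"
  )
})

test_that("permutation p-values are valid under exchangeable models", {
  set.seed(123)
  reject <- vapply(1:120, function(i) {
    truth <- rnorm(12)
    names(truth) <- paste0("u", 1:12)
    a <- truth + rnorm(12)
    b <- truth + rnorm(12)
    y <- truth + rnorm(12, sd = .5)
    paired_permutation_test(a, b, y, n_perm = 300, seed = i)$p < 0.05
  }, logical(1))
  expect_lte(mean(reject), 0.12) # near-nominal size on 120 replicates
})

test_that("standardized partial regression recovers known structure", {
  set.seed(5)
  units <- paste0("u", 1:40)
  score <- setNames(rnorm(40), units)
  orth <- setNames(rnorm(40), units)
  orth <- setNames(resid(lm(orth ~ score)), units) # orthogonal covariate
  means <- setNames(0.7 * as.vector(scale(score)) + rnorm(40, sd = .3), units)
  fit_simple <- partial_regression(means, score)
  fit_ctrl <- partial_regression(means, score, covariates = list(z = orth))
  b_simple <- fit_simple$beta[fit_simple$predictor == "score"]
  b_ctrl <- fit_ctrl$beta[fit_ctrl$predictor == "score"]
  expect_lt(abs(b_simple - b_ctrl), 1e-6)
  expect_lt(abs(b_ctrl - 0.7 / sqrt(0.7^2 + 0.09)), 0.15)
  expect_error(
    partial_regression(means, score, covariates = list(dup = score)),
    "collinear"
  )
})

test_that("prior/votes regression isolates what each target tracks", {
  # exact orthogonal design: votes and win probability uncorrelated
  p <- c(.2, .2, .5, .5, .8, .8)
  votes <- c(3, 5, 3, 5, 3, 5)
  ens <- enumerate_independent_ensemble(p, votes, threshold = 12)
  target <- setNames(p, ens$map$units)
  rg <- suppressWarnings(prior_votes_regression(target, ens))
  expect_equal(rg$beta[rg$predictor == "prob"], 1, tolerance = 1e-9)
  expect_equal(rg$beta[rg$predictor == "votes"], 0, tolerance = 1e-9)
})

test_that("subgroup invariance separates ranking from level", {
  scores <- c(GA = .9, AZ = .6, PA = .3, CA = .1)
  base <- rbind(
    p1 = c(9L, 6L, 4L, 2L), p2 = c(8L, 5L, 3L, 1L),
    p3 = c(8L, 5L, 3L, 1L), p4 = c(7L, 4L, 2L, 0L)
  )
  colnames(base) <- names(scores)
  rt <- ratings_table(base, data.frame(
    participant = rownames(base),
    voted_for = c("biden", "biden", "trump", "trump")
  ))
  sub <- subgroup_invariance(rt)
  # trump rows are biden rows shifted by -1: perfect between-group r
  expect_equal(sub$r, 1, tolerance = 1e-12)
  expect_equal(
    sub$overall_means[["biden"]] - sub$overall_means[["trump"]], 1
  )
  expect_error(
    subgroup_invariance(rt, groups = c("biden", "green")),
    "at least 2"
  )
  expect_error(subgroup_invariance(rt, grouping = "nope"), "no metadata")
})

test_that("comparison statistics ignore participant and unit order", {
  scores <- c(GA = .9, AZ = .6, PA = .3, CA = .1)
  spec <- rating_spec(scores, n_participants = 40L, seed = 6)
  rt <- simulate_ratings(spec)
  perm_p <- sample(nrow(rt$ratings))
  perm_u <- sample(ncol(rt$ratings))
  rt2 <- ratings_table(
    rt$ratings[perm_p, perm_u],
    rt$meta[perm_p, , drop = FALSE]
  )
  sm <- state_means(rt)
  sm2 <- state_means(rt2)
  expect_equal(
    sm$mean[match(sm2$unit, sm$unit)], sm2$mean
  )
  expect_equal(
    model_human_correlation(scores, sm)$r,
    model_human_correlation(scores, sm2)$r
  )
  expect_equal(
    individual_correlations(rt, scores)$median,
    individual_correlations(rt2, scores)$median
  )
})
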