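test_that("conjunctive toy reproduces the enumeration-derived scores", {
  ens <- conjunctive_toy()
  # frozen values from the closed-form weighted correlation of S with P
  # under independence (cov/sd ratio worked by hand on the 4-world table)
  expect_equal(cesm_exhaustive(ens, "u1"), 0.3015113, tolerance = 1e-6)
  expect_equal(cesm_exhaustive(ens, "u2"), 0.9045340, tolerance = 1e-6)
  # qualifying worlds for u1 sufficiency: (0,0) and (0,1); winning u1 wins
  # the presidency only when u2 is won -> P(u2) = 0.5
  expect_equal(sufficiency_strength(ens, "u1", min_sims = 1), 0.5)
  expect_equal(delta_p_observational(ens, "u1"), 0.5)
  expect_equal(delta_p_interventional(ens, "u1"), 0.5)
  expect_equal(power_pc(ens, "u1"), 0.5)
})

test_that("CESM is zero for never-varying units and bounded by [-1, 1]", {
  map <- electoral_map(c("A", "B"), c(2, 1), threshold = 2)
  ens <- world_ensemble(map, cbind(A = rep(1L, 6), B = rbinom(6, 1, .5)))
  expect_identical(cesm_exhaustive(ens, "A"), 0)
  expect_identical(cesm(ens, "A", seed = 1), 0)
  set.seed(31)
  for (i in 1:20) {
    e <- enumerate_independent_ensemble(runif(3, .1, .9),
      sample.int(5, 3, replace = TRUE),
      threshold = NULL
    )
    for (u in e$map$units) {
      s <- cesm_exhaustive(e, u)
      expect_gte(s, -1)
      expect_lte(s, 1)
    }
  }
})

test_that("exhaustive CESM equals the weighted Pearson correlation under
           independence", {
  set.seed(17)
  for (i in 1:25) {
    k <- sample(2:6, 1)
    ens <- enumerate_independent_ensemble(runif(k, .05, .95),
      sample.int(9, k, replace = TRUE),
      threshold = NULL
    )
    for (u in ens$map$units) {
      s <- cesm_exhaustive(ens, u)
      st <- unit_stats(ens, u)
      if (st$sd_unit == 0 || st$sd_presidency == 0) next
      r <- causalworlds:::weighted_cor(
        ens$outcomes[, u], ens$presidency, ens$weights
      )
      expect_lt(abs(s - r), 1e-12)
    }
  }
})

test_that("sampled CESM is an unbiased, seed-reproducible estimator of the
           exhaustive form", {
  ens <- enumerate_independent_ensemble(c(.7, .4, .6), c(4, 3, 2))
  expect_identical(cesm(ens, "u1", seed = 5), cesm(ens, "u1", seed = 5))
  exact <- cesm_exhaustive(ens, "u1")
  draws <- vapply(1:40, function(s) cesm(ens, "u1", seed = s), numeric(1))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - exact), 4 * se)
})

test_that("necessity matches the single-flip counterfactual", {
  m <- electoral_map(c("A", "B"), c(2, 1), threshold = 2)
  w <- c(A = 1L, B = 1L)
  expect_true(necessity(w, "A", m))
  expect_false(necessity(w, "B", m))
  expect_error(necessity(c(A = 0L, B = 1L), "A", m), "occurred")
  # exactly k yes votes under k-of-n: every yes voter necessary
  vm <- electoral_map(paste0("v", 1:7), rep(1, 7), threshold = 4)
  wv <- setNames(c(rep(1L, 4), rep(0L, 3)), vm$units)
  for (u in paste0("v", 1:4)) expect_true(necessity(wv, u, vm))
})

test_that("sufficiency strength handles dominant units and the
           qualifying-count filter", {
  # a unit whose votes alone meet the threshold is sufficient wherever the
  # question arises
  ens <- enumerate_independent_ensemble(c(.5, .5), c(5, 2), threshold = 5)
  expect_equal(sufficiency_strength(ens, "u1", min_sims = 1), 1)
  # fewer qualifying simulations than the cut-off -> NA
  map <- electoral_map(c("A", "B"), c(2, 1), threshold = 3)
  out <- cbind(A = c(rep(0L, 9), rep(1L, 11)), B = rep(1L, 20))
  e2 <- world_ensemble(map, out) # 9 sims with A lost & presidency lost
  expect_identical(sufficiency_strength(e2, "A", min_sims = 10), NA_real_)
  expect_equal(sufficiency_strength(e2, "A", min_sims = 9), 1)
})

test_that("necessity-sufficiency combination follows the configured rule", {
  ens <- conjunctive_toy()
  actual <- c(u1 = 1L, u2 = 1L)
  p1 <- unit_stats(ens, "u1")$p_win
  s1 <- sufficiency_strength(ens, "u1", min_sims = 1)
  # both units necessary under the conjunctive threshold
  expect_equal(
    as.numeric(nsm_score(ens, "u1", actual, min_sims = 1)),
    1 + p1 * s1
  )
  # non-necessary unit: indicator drops out
  dis <- disjunctive_toy()
  expect_equal(
    as.numeric(nsm_score(dis, "u1", actual, min_sims = 1)),
    unit_stats(dis, "u1")$p_win *
      sufficiency_strength(dis, "u1", min_sims = 1)
  )
  # NA sufficiency propagates
  expect_identical(
    as.numeric(nsm_score(ens, "u1", actual, min_sims = 1000)), NA_real_
  )
  expect_match(attr(nsm_score(ens, "u1", actual, min_sims = 1), "combination"),
    "Pr\\(S\\)"
  )
})

test_that("pivotality distance matches the committee worked examples", {
  vm <- electoral_map(paste0("v", 1:11), rep(1, 11))
  w6 <- setNames(c(rep(1L, 6), rep(0L, 5)), vm$units)
  w7 <- setNames(c(rep(1L, 7), rep(0L, 4)), vm$units)
  for (u in paste0("v", 1:6)) {
    pv <- pivotality(w6, u, vm)
    expect_identical(pv$k, 0L)
    expect_equal(pv$strength, 1)
  }
  pv7 <- pivotality(w7, "v3", vm)
  expect_identical(pv7$k, 1L)
  expect_equal(pv7$strength, 0.5)
  expect_error(pivotality(w6, "v11", vm), "not won")
})

test_that("pivotality DP agrees with brute-force subset search", {
  # weighted worked example: won (5,3,2), lost 4, threshold 6, focal = the
  # 2-vote unit; shedding the 3-vote unit lands the rest in [4,5] -> k = 1
  m <- electoral_map(c("A", "B", "F", "L"), c(5, 3, 2, 4), threshold = 6)
  w <- c(A = 1L, B = 1L, F = 1L, L = 0L)
  pv <- pivotality(w, "F", m)
  expect_identical(pv$k, 1L)
  expect_identical(pv$k, brute_pivotality_k(w, "F", m))
  set.seed(77)
  for (i in 1:40) {
    rw <- random_map_world(sample(3:9, 1))
    won <- rw$map$units[rw$world == 1L]
    u <- sample(won, 1)
    expect_identical(
      pivotality(rw$world, u, rw$map)$k,
      brute_pivotality_k(rw$world, u, rw$map)
    )
  }
})

test_that("observational Delta-P strata and guards", {
  map <- electoral_map(c("A", "B"), c(2, 1), threshold = 2)
  ens <- world_ensemble(map, cbind(A = rep(1L, 5), B = rbinom(5, 1, .5)))
  expect_identical(delta_p_observational(ens, "A"), NA_real_)
  expect_identical(power_pc(ens, "A"), NA_real_)
  # a unit independent of the outcome scores near zero
  big <- enumerate_independent_ensemble(c(.5, .5, .5), c(4, 4, 1),
    threshold = 4
  )
  # u3's single vote never matters next to threshold 4
  expect_equal(delta_p_interventional(big, "u3"), 0)
  expect_lt(abs(delta_p_observational(big, "u3")), 1e-12)
})

test_that("interventional and observational Delta-P coincide exactly under
           independence and diverge under a shared shock", {
  set.seed(23)
  for (i in 1:10) {
    k <- sample(2:5, 1)
    ens <- enumerate_independent_ensemble(runif(k, .2, .8),
      sample.int(7, k, replace = TRUE)
    )
    for (u in ens$map$units) {
      dpo <- delta_p_observational(ens, u)
      if (is.na(dpo)) next
      expect_lt(abs(dpo - delta_p_interventional(ens, u)), 1e-12)
    }
  }
  spec <- forecast_spec(rep(0, 4),
    electoral_map(paste0("u", 1:4), rep(3, 4)),
    seed = 9, sigma_nat = 2
  )
  ens <- simulate_forecast(spec, 5000L)
  expect_gt(
    abs(delta_p_observational(ens, "u1") - delta_p_interventional(ens, "u1")),
    0.05
  )
})

test_that("Power-PC rescales Delta-P by background headroom", {
  ens <- conjunctive_toy()
  # P(P | not u2) = 0, so power equals delta-p for u2
  expect_equal(power_pc(ens, "u2"), delta_p_observational(ens, "u2"))
  # an outcome-irrelevant unit has zero power
  big <- enumerate_independent_ensemble(c(.5, .5, .5), c(4, 4, 1),
    threshold = 4
  )
  expect_equal(power_pc(big, "u3"), 0)
})

test_that("scores are invariant to row order and simulation duplication", {
  set.seed(41)
  map <- electoral_map(c("A", "B", "C"), c(4, 3, 2))
  out <- matrix(rbinom(90, 1, .6), 30, 3, dimnames = list(NULL, map$units))
  ens <- world_ensemble(map, out)
  perm <- sample(30)
  ens_p <- world_ensemble(map, out[perm, ])
  ens_d <- world_ensemble(map, rbind(out, out))
  for (u in map$units) {
    for (f in list(
      cesm_exhaustive,
      function(e, u) sufficiency_strength(e, u, min_sims = 1),
      delta_p_observational, delta_p_interventional, power_pc
    )) {
      expect_equal(f(ens, u), f(ens_p, u), tolerance = 1e-12)
      expect_equal(f(ens, u), f(ens_d, u), tolerance = 1e-12)
    }
  }
})

test_that("conjunctive/disjunctive thresholds reverse the CESM ordering", {
  conj <- conjunctive_toy() # u1 likely (p=.9), u2 unlikely (p=.5)
  dis <- disjunctive_toy()
  # both needed: the less probable cause scores higher
  expect_gt(cesm_exhaustive(conj, "u2"), cesm_exhaustive(conj, "u1"))
  # either suffices: the more probable cause scores higher
  expect_gt(cesm_exhaustive(dis, "u1"), cesm_exhaustive(dis, "u2"))
})

test_that("score_all assembles the unit-by-measure table deterministically", {
  ens <- conjunctive_toy()
  actual <- c(u1 = 1L, u2 = 1L)
  cfg <- measure_config(min_sims = 1L)
  tab <- score_all(ens, actual, config = cfg)
  expect_identical(tab$unit, c("u1", "u2"))
  expect_identical(
    names(tab),
    c("unit", "cesm", "nsm", "pivotality", "delta_p_obs", "pns", "power_pc")
  )
  expect_identical(tab, score_all(ens, actual, config = cfg))
  sub <- score_all(ens, actual, measures = c("cesm", "pns"), config = cfg)
  expect_identical(names(sub), c("unit", "cesm", "pns"))
  # only won units are scored
  actual2 <- c(u1 = 1L, u2 = 0L)
  ens2 <- enumerate_independent_ensemble(c(.9, .5), c(2, 1), threshold = 2)
  tab2 <- score_all(ens2, actual2, measures = "cesm")
  expect_identical(tab2$unit, "u1")
  # sampled-CESM path is reproducible via its seed
  cfg_s <- measure_config("sampled", cesm_seed = 11L, min_sims = 1L)
  expect_identical(
    score_all(ens, actual, measures = "cesm", config = cfg_s),
    score_all(ens, actual, measures = "cesm", config = cfg_s)
  )
})
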