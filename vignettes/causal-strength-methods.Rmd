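---
title: "Causal strength over possible election worlds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal strength over possible election worlds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalworlds)
```

## The problem: causal selection among many actual causes

When a complex event happens — a candidate wins a presidential election —
every won state is, in some minimal sense, a cause of the victory. Yet
people single out a few states ("he won because he won Pennsylvania") and
ignore others. A family of computational theories holds that this *causal
selection* is governed by counterfactual reasoning: people implicitly
consider alternative ways the election could have gone and score each
factor by some statistic of its relationship to the outcome across those
alternatives.

`causalworlds` implements six such scoring rules over a common substrate: a
**world ensemble**, i.e. a weighted set of simulated complete election
outcomes standing in for the prior distribution over counterfactual worlds.
Professional election forecasts publish exactly this object (tens of
thousands of Monte-Carlo simulations drawn in proportion to estimated prior
probability), so a forecast's simulation file can be loaded directly as the
counterfactual sampler; a synthetic generator with the same statistical
skeleton is included so that every stage is testable without any download.

Throughout, outcomes are binary and coded for a single focal candidate:
$S_{ij} = 1$ iff the focal candidate wins unit $j$ in simulation $i$, and
the presidency indicator is the deterministic threshold rule

$$P_i = \mathbf{1}\!\left[\textstyle\sum_j v_j S_{ij} \ge T\right],$$

with $v_j$ the unit's electoral votes and $T$ the victory threshold (270 of
538 on the real map). An exact electoral-vote tie is counted as a loss for
the focal candidate: the threshold is "reach $T$", which matches the
majority framing and keeps the rule a pure threshold function. The
threshold is configurable for toy structures (e.g. disjunctive rules where
either cause suffices).

## The measures

### Counterfactual effect size (CESM)

The centerpiece measure treats causal strength as a standardized effect
size across counterfactuals. For a unit $S$ with ensemble win probability
$\Pr(S)$:

1. compute the population SDs $\sigma_S$ and $\sigma_P$ of the binary unit
   and presidency variables (for a binary variable,
   $\sigma = \sqrt{p(1-p)}$ exactly);
2. for each simulation, form a *twin* world by resampling the unit's value
   from Bernoulli($\Pr(S)$), holding all other units fixed, and — when the
   twin differs — record $\Delta_P/\Delta_S$, the change in presidency
   outcome over the change in unit outcome;
3. average $\Delta_P/\Delta_S$ over the differing pairs and multiply by
   $\sigma_S/\sigma_P$.

The result behaves like a correlation between $S$ and $P$, but because the
twin is produced by an *intervention*, a merely diagnostic association
(one that interventions cannot exploit) scores zero.

Two numerical conventions are pinned down. Pairs with $\Delta_S = 0$ carry
no ratio and are excluded from the average (the denominator is the count of
differing pairs). And if $\sigma_S = 0$ or $\sigma_P = 0$ the score is 0 by
convention: a never-varying factor has no effect size, and the convention
keeps the measure total.

`cesm()` implements the literal one-sampled-twin-per-simulation procedure
(seeded, reproducible); `cesm_exhaustive()` replaces the sampled twin by
both possible twin values weighted $\Pr(S)$ / $\Pr(\lnot S)$, which is the
exact expectation of the sampled estimator and is deterministic. Whether
the original analyses used one sampled twin or the analytic expectation is
not something the measure's definition fixes; the two agree in expectation,
so the package provides both and uses the variance-free form as the default
in `score_all()`. A useful identity anchors both: when unit outcomes are
mutually independent in the ensemble, the exhaustive form equals the
weighted Pearson correlation of $S$ with $P$ — the test suite asserts this
to $10^{-10}$ against enumerated ensembles, and checks that the sampled
form sits within Monte-Carlo error of the exhaustive one.

### Necessity–sufficiency

The necessity–sufficiency model scores an event by combining whether the
outcome would have failed without it (*necessity*, evaluated by a single
flip in the actual world) with how generally the event would have produced
the outcome (*sufficiency strength*): among simulations where the candidate
lost both the unit and the presidency, the weighted fraction in which
forcing a win in the unit would have won the presidency. Sufficiency is
modulated by $\Pr(S)$, the frequency with which the relevant
counterfactuals come to mind.

Because sufficiency conditions on the joint event "lost the unit and lost
the presidency", it is not estimable for units the candidate essentially
never loses; `sufficiency_strength()` returns `NA` when fewer than
`min_sims = 10` qualifying simulations exist. This cut-off is the reason a
necessity–sufficiency column can have fewer usable units than the other
measures, and the comparison statistics carry the degrees of freedom
explicitly so those subset fits remain interpretable.

The exact formula combining the two components is a genuinely open choice
(the components are standard; their combination is not uniquely fixed by
the model's verbal statement). The package uses

$$\mathrm{NSM}(S) = w_{\mathrm{nec}} \cdot \mathbf{1}[\text{necessary}] +
\Pr(S)\cdot \mathrm{sufficiency}(S), \qquad w_{\mathrm{nec}} = 1,$$

with the weight exposed as a config knob and the rule recorded in the
output's attributes rather than hard-coded silently. In the election
setting the indicator term is almost always 0 (only an extremely large unit
can be singly necessary), so results are dominated by the
probability-modulated sufficiency term regardless of $w_{\mathrm{nec}}$.

### Distance from pivotality

A won unit is *pivotal* if flipping it alone would flip the presidency
outcome. Its distance from pivotality $k$ is the minimal number of *other*
units whose outcomes must change before the focal unit becomes pivotal, and
causal strength is $1/(1+k)$. Equivalently, after the flips the focal
candidate's vote total excluding the focal unit must land in
$[T - v_j,\; T - 1]$. The classic intuition: with 6 of 11 committee
members voting yes under majority rule, each yes-voter is pivotal
($k = 0$); with 7 yes votes each is one step away ($k = 1$).

Finding $k$ is a minimal-cardinality subset problem (flipping a won unit
subtracts its votes; flipping a lost unit adds them). `pivotality()` solves
it by a 0/1-knapsack dynamic program over reachable vote totals, bounded by
the map's total votes; ties in flip count need no tie-breaking because only
the count enters the score. The test suite checks the DP against exhaustive
subset search on hundreds of random weighted maps of up to 15 units. Note
that pivotality consumes only the electoral map and the actual world — it
takes no probabilistic input, which is precisely what distinguishes its
predictions from the effect-size measure's.

### Delta-P, PNS, and causal power

Three further measures from the general causal-strength literature are
included for comparison:

* **Observational Delta-P**: $\Pr(P{=}1 \mid S{=}1) - \Pr(P{=}1 \mid
  S{=}0)$ under the ensemble weights; `NA` if either stratum is empty.
* **Interventional Delta-P / PNS**: within each simulation force the unit
  to a win and to a loss and average the outcome difference. This is the
  probability that the unit is necessary and sufficient for the outcome,
  always defined, and it backs the `pns` column of the score table. The two
  Delta-P variants coincide exactly under unit independence and diverge
  when a shared national swing correlates the states (the test suite
  asserts both).
* **Power-PC** (generative causal power): observational Delta-P rescaled by
  the background headroom, $\Delta P / (1 - \Pr(P{=}1 \mid S{=}0))$; `NA`
  when the background probability is 1.

`score_all()` assembles all requested measures into a unit-by-measure table
restricted to the units the focal candidate actually won — causal strength
of the event "won unit $j$" is only queried for events that occurred — with
`NA` appearing exactly where a measure's own precondition fails.

## Reading real forecast files

`read_simulations()` accepts wide vote-share CSVs, binary outcome CSVs, and
a JSON layout of simulated maps (a `states` name array plus a `maps` array
of per-simulation share vectors), behind a `dialect` flag with extension-
and-content auto-detection. Vote shares convert to binary outcomes by a
strict rule — a unit is won iff the two-party share exceeds 0.5; a share of
exactly 0.5 is not a win. Ties are measure-zero in real simulation files,
but the strictness must be pinned for bit-reproducibility. Files covering a
subset of units get a majority threshold over the units present, since the
270 rule is meaningful only on the full map. District-level units (names
like `ME-1`) can be passed through as units of their own or collapsed into
their parent state by share-averaging (`collapse_districts = TRUE`); how
published forecasts' district allocations map onto statewide ratings is not
fixed by the data, so both options are exposed and neither is asserted as
canonical. No function ever touches the network; real-file checks run only
against local paths.

## The synthetic generator: what it emulates, and what it does not

`simulate_forecast()` draws worlds from a latent-margin probit with one
shared factor:

$$S_{ij} = \mathbf{1}\left[\mu_j + \eta_i + \varepsilon_{ij} > 0\right],
\qquad \eta_i \sim N(0, \sigma_{\mathrm{nat}}^2),\;
\varepsilon_{ij} \sim N(0, \sigma_{\mathrm{unit}}^2),$$

so the marginal win probability is $\Phi\!\big(\mu_j / \sqrt{\sigma_{\mathrm
{nat}}^2 + \sigma_{\mathrm{unit}}^2}\big)$ (a closed form the tests use as
a convergence oracle) and the national shock induces the positive
cross-state outcome correlation real forecasts exhibit. This is the
simplest generator producing the two features the measures are sensitive
to — heterogeneous win probabilities and correlated outcomes. It does
*not* emulate poll aggregation, fundamentals models, regional or
demographic correlation blocks, or tail behavior of any real forecast;
passing tests on this generator therefore show that the pipeline computes
its measures correctly and recovers known structure, not that any
particular real-world fit would be obtained.

The `forecast_spec_2020()` preset places the generator on the real 51-unit
electoral map with round, plausible final-week win probabilities (safe
Democratic states near 0.99, Georgia near 0.58, and so on; the values are
synthetic stand-ins, not a copy of a published table) and
$\sigma_{\mathrm{nat}} = \sigma_{\mathrm{unit}} = 1$, an equal split that
puts roughly half the outcome variance on the shared swing. Under this
preset the ensemble's overall presidency win rate computes to about 0.89 —
the same ballpark real 2020 forecasts printed — and the qualitative
signature that separates the measures appears: the effect-size measure
ranks a competitive 16-vote state (Georgia-like) above the safest 55-vote
state (California-like), while pivotality does the reverse, because
$306 - 55 = 251$ already lies in California's pivotality window ($k = 0$)
while a Georgia-like unit needs two other states to move.

`simulate_ratings()` generates Likert-style 0–10 ratings from a chosen
generating model's scores:

$$r_{pj} = \mathrm{clip}\big(\mathrm{round}(\alpha + \beta\, z(s_j) + a_p +
\gamma_{g(p)} + e_{pj}),\, 0,\, 10\big),$$

with participant effects, additive group offsets, and residual noise.
Defaults are calibrated once to the published election-study conditions:
207 participants; $\beta = 2$ and $\sigma_e = 3$ put the expected
within-participant correlation with the generating scores near
$\beta/\sqrt{\beta^2 + \sigma_e^2} \approx 0.55$; the group mixture is
76/14/10 percent with the loser-voter latent offset at $-2.0$. That offset
is deliberately larger in magnitude than the observed mean difference it
mimics (about $1.7$ on the 0–10 scale): the floor at 0 compresses the
lower group's ratings, and $-2.0$ is the latent shift whose *observed*
group means land near the study's 4.6-vs-2.9 split. Ratings are integers
by round-then-clip, matching the discrete instrument. What the generator
deliberately omits: differential response styles beyond an additive shift,
participant-specific slopes, any dependence of noise on the score level,
and item-order effects.

## Comparison statistics

`state_means()` gives per-unit means with $t$-based 95% CIs (the $t$
quantile, not the normal, because subgroup splits can leave small $n$).
`model_human_correlation()` reports Pearson's $r$ on pairwise-complete
units with the $t$-transform $p$ and explicit $\mathrm{df} = n - 2$;
`individual_correlations()` gives the per-participant distribution and its
median, excluding (and counting) zero-variance raters. Pearson correlation
is the default throughout because that is the statistic the fits are
expressed in; rank-based alternatives can be computed by transforming the
inputs but are not silently substituted.

`paired_permutation_test()` compares two models against the same human
means with the statistic $T = |r_A| - |r_B|$, permuting by an independent
per-unit swap of which model contributed which prediction, and
$p = (1 + \#\{|T_{\mathrm{perm}}| \ge |T_{\mathrm{obs}}|\})/(1 +
n_{\mathrm{perm}})$. This is the standard paired scheme for two predictors
of one target; the scheme is recorded in the output rather than asserted
to match any particular prior analysis. Its validity is checked by
simulation: under exchangeable models the rejection rate at $\alpha = .05$
stays near nominal.

`partial_regression()` and `prior_votes_regression()` fit OLS after
z-scoring the outcome and every predictor, so coefficients are standardized
betas; cases are listwise-complete and perfect collinearity is an error.
Regressing each model's scores (and the human means) on prior win
probability and electoral votes is the package's diagnostic for *why*
models disagree: effect-size scores load on probability (negatively —
safer states are less decisive), necessity–sufficiency and pivotality
scores load on votes.

`subgroup_invariance()` separates ranking from level: the correlation
between two groups' per-unit mean vectors (near 1 when groups rank units
identically even at different levels) and a Welch unequal-variance $t$ test
on participant-level overall means (Welch, because group sizes and
variances differ markedly in data of this shape).

## Pipeline, problem sizes, and reproducibility

`run_simulate()` / `run_score()` / `run_compare()` / `run_recover()` chain
the stages under a single run seed from which every stage seed is derived
deterministically; outputs land in a run directory with a JSON manifest of
seeds and settings, and rerunning a config reproduces files bit for bit. A
thin command-line dispatcher over these functions ships in
`inst/cli/causalworlds.R`.

The package's own validation runs at deliberately chosen problem sizes:
enumerated ensembles of up to $2^{12}$ worlds for exactness checks (where
weighted enumeration makes oracles exact rather than approximate), 50,000
simulations for the 2020-style preset analyses (comparable to real
forecast files), and 100 seeded replicates for the model-recovery
experiment, in which ratings generated from the effect-size scores at the
default noise calibration are fed back through the comparison pipeline and
the generating model is expected to achieve the best fit in at least 95% of
replicates.

## Known limitations

* Pivotality's `NA` (no reachable pivotal configuration) can only occur on
  degenerate maps, but it is represented rather than silently coerced.
* The synthetic preset's win probabilities are hand-set plausible values;
  conclusions about any real forecast require loading that forecast's file.
* The necessity–sufficiency combination rule is one defensible choice among
  several; sensitivity to $w_{\mathrm{nec}}$ is trivial here (the indicator
  is almost always 0) but could matter in small maps.
* Weights support importance-weighted ensembles, but all shipped readers
  produce uniform weights; similarity-weighted counterfactual sampling is
  out of scope.
* The measures are computational-level models: nothing here bears on which
  algorithm human raters actually execute.
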