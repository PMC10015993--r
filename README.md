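# causalworlds

Counterfactual causal-strength measures over ensembles of simulated
election worlds, with the statistics needed to compare them against human
causal judgments.

## What problem this addresses

After a complex event like a presidential election, every won state is in
some sense a cause of the victory — yet people confidently single out a few
("he won because he won Pennsylvania"). Counterfactual theories of causal
selection propose that people score each factor by a statistic of its
relationship to the outcome across *possible worlds*: alternative ways the
election could have gone, weighted by prior probability. Election forecasts
publish exactly that object — tens of thousands of Monte-Carlo simulated
outcomes — so they can serve as the counterfactual sampler for testing such
theories at scale.

`causalworlds` is for computational cognitive scientists (and the curious
quantitative analyst) who want to compute these measures on forecast
simulation data or on synthetic ensembles with the same statistical
skeleton, and to run the model-vs-human comparison pipeline end to end.

## The measures

Over a weighted ensemble of binary world vectors $S_{ij}$ (focal candidate
wins unit $j$ in simulation $i$) with presidency outcome
$P_i = \mathbf{1}[\sum_j v_j S_{ij} \ge T]$:

| measure | idea |
|---|---|
| `cesm` | counterfactual effect size: average $\Delta_P/\Delta_S$ over intervention-generated twin worlds, times $\sigma_S/\sigma_P$ — a correlation that is zeroed for non-causal association |
| `nsm` | necessity in the actual world plus $\Pr(S)$-modulated sufficiency strength across worlds where unit and presidency were both lost |
| `pivotality` | $1/(1+k)$, $k$ = minimal number of *other* units to flip before this unit's flip decides the outcome (knapsack DP) |
| `delta_p_obs` | $\Pr(P\mid S) - \Pr(P\mid \lnot S)$, observational |
| `pns` | the same contrast under forced interventions; the probability of necessity and sufficiency |
| `power_pc` | Delta-P rescaled by background headroom $1 - \Pr(P\mid\lnot S)$ |

See the vignette (`vignettes/causal-strength-methods.Rmd`) for formulas,
conventions, and numerical choices.

## Worked example

Score every won unit of a 2020-style synthetic forecast (51 units, shared
national swing, 50,000 simulations), then generate human-like ratings from
the effect-size scores and run the comparison:

```r
library(causalworlds)

ens <- simulate_forecast(forecast_spec_2020(seed = 2020), 50000)
ens
#> <world_ensemble> 50000 simulations x 51 units; Pr(presidency) = 0.8936

actual <- actual_world_2020(ens$map)
scores <- score_all(ens, actual)
head(scores[order(-scores$cesm), ], 5)
#>    unit   cesm   nsm pivotality delta_p_obs    pns power_pc
#> 21   PA 0.1277 0.293        0.5       0.426 0.0701    0.918
#> 7    GA 0.0808 0.207        0.5       0.226 0.0451    0.955
#> 1    AZ 0.0675 0.172        0.5       0.259 0.0348    0.929
#> 13   MI 0.0653 0.180        0.5       0.586 0.0584    0.886
#> 14   MN 0.0612 0.159        0.5       0.457 0.0392    0.884
```

The ensemble's overall win rate (0.894) sits where a 2020-style forecast
put it, and the effect-size column ranks competitive, vote-rich states
(PA, GA, AZ, MI) at the top while safe California ranks low — even though
California is exactly pivotal (`pivotality = 1`, since 306 − 55 = 251 is
inside the 270-window).

```r
gen <- setNames(scores$cesm, scores$unit)
rt <- simulate_ratings(rating_spec(gen, seed = 7)) # 207 synthetic raters
means <- state_means(rt)

model_human_correlation(gen, means)
#>       r df        p n_used
#> 1 0.988 24 4.46e-21     26

individual_correlations(rt, gen)$median
#> [1] 0.543

paired_permutation_test(gen, setNames(scores$pivotality, scores$unit),
                        means, n_perm = 10000, seed = 1)$p
#> [1] 1e-04

prior_votes_regression(gen, ens)
#>   predictor beta       p
#> 1      prob -0.7 4.7e-05
#> 2     votes  0.2 1.8e-01
```

Ratings were generated from the effect-size scores with noise calibrated
so each rater correlates ~0.55 with them; the unit means then recover the
generating model almost perfectly (r = .99 on 26 units), the permutation
test rejects pivotality as an equally good account, and the regression
shows what the effect-size measure responds to: prior probability
(negatively — safe states are less decisive), much more than electoral
votes.

Real forecast simulation files load through `read_simulations()` (wide
vote-share CSV, binary CSV, or a simulated-maps JSON layout), and human
ratings through `read_ratings()`; nothing in the package touches the
network.

## Command line

A thin dispatcher over the pipeline functions ships in
`inst/cli/causalworlds.R`:

```sh
Rscript inst/cli/causalworlds.R simulate --config run.yaml --seed 11 --out runs/a
Rscript inst/cli/causalworlds.R score    --config run.yaml --out runs/a
Rscript inst/cli/causalworlds.R compare  --config run.yaml --out runs/a
Rscript inst/cli/causalworlds.R recover  --config run.yaml --replicates 100
```

Each stage writes its tables plus a `manifest.json` of derived seeds; a
fixed seed reproduces every file bit for bit.

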