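# commonsgame

Simulation and rank-based norm analysis of a four-player common-pool
resource dilemma.

## The problem

In a common-pool resource dilemma, a small group repeatedly harvests from a
shared, partially replenishable resource; over-use exhausts it for everyone
(the tragedy of the commons). A behavioural paradigm for studying this puts
one participant in a four-player group with three scripted co-players
("confederates") around a resource that starts at 230 points. On each
harvesting opportunity every player privately takes up to 20 points; the
resource is then replenished by an integer drawn uniformly between 17% and
23% of what remains, damped by mixing in one third of the value that opened
the trial:

    R[t+1] = round( w * R[t] + (1 - w) * (R[t] - H[t] + u[t]) ),   w = 1/3

where `H[t]` is the group's total harvest and `u[t]` the rectangular draw.
The game ends when the resource hits 0 or after 109 opportunities (5
warm-ups plus eight 13-trial blocks in which confederates over- or
under-harvest).

The analysis centres on *descriptive social norms*: the four players' last
harvests are summarised as a beta distribution scaled to \[0, 20\], and each
player's **relative rank** is the CDF position of their own last harvest in
that norm. Trial-to-trial harvest adjustments (ΔHarvest) are regressed on a
cubic polynomial of rank, the player's own preceding harvest, the current
resource, and the presence of over-harvesters, with treatment interactions
(a tryptophan-depleted group T− versus control T+):

    ΔHarvest ~ prev + resource + over + rank + rank² + rank³
               + T−·(rank + rank² + rank³)        (Model 2)

fitted by pooled OLS with participant-clustered bootstrap confidence
intervals. Because the original human data are unavailable, the package
ships a synthetic-participant generator whose treatment-dependent policies
reproduce the qualitative structure the analysis assumes, so the whole
pipeline is testable end-to-end.

## Worked example

```r
library(commonsgame)

cs <- simulate_cohort(n_per_group = 16, seed = 42)
cs
#> Simulated cohort: 32 games (T_minus n=16, T_plus n=16), 2645 trial rows
#>   exhaustion rate: T_minus 1.00, T_plus 0.06

chi_square_2x2(exhaustion_table(cs$outcomes))
#> 	Pearson chi-square (2x2, no continuity correction)
#> data:  2x2 table, N = 32
#> X-squared = 28.235, df = 1, p-value = 1.074e-07

fit <- harvest_lm(cs, model = "model2", n_boot = 500, seed = 43)
fit
#> Harvest-adjustment regression (model2), 2485 observations (T_minus: 839, T_plus: 1646)
#> Cluster bootstrap: 500 resamples, 95% studentized CIs
#>
#>                         estimate    se   lower  upper
#> (Intercept)                0.143 0.211  -0.297  0.614
#> treatment_T_minus          1.069 0.257   0.518  1.569
#> prev_harvest              -0.643 0.025  -0.679 -0.596
#> resource                   0.019 0.001   0.017  0.022
#> over_present               0.420 0.096   0.224  0.613
#> rank                      -7.398 2.027 -12.109 -3.085
#> rank2                     19.517 6.089   7.590 34.953
#> rank3                    -15.379 4.888 -29.257 -5.154
#> treatment_T_minus:rank     9.574 3.496   1.348 17.051
#> treatment_T_minus:rank2  -20.827 9.237 -40.744 -0.157
#> treatment_T_minus:rank3   15.361 6.631   0.387 29.814
```

Reading the output: control-group (T+) agents self-correct — a larger last
harvest predicts a downward adjustment (`prev_harvest` −0.64) — harvest
more from richer resources (`resource` +0.02), escalate when others
over-harvest (`over_present` +0.42), and show the S-shaped cubic rank
response (negative, positive, negative): the largest upward and downward
adjustments happen when the last harvest ranked at the bottom or top of the
group's norm. The T− interactions flatten that rank response, and every T−
game here exhausted the resource while only 1 of 16 T+ games did —
`summary(fit)` adds standardized coefficients, p-values and stars, and
`plot(fit)` draws the per-group cubic rank-response curves.

`run_full_analysis(run_config())` executes the whole pipeline (simulate →
tidy CSV → both models → outcome summary → contingency statistic) and
writes a manifest with seeds and file checksums. The same steps are
available from a shell via `scripts/run_experiment.R
<simulate|analyze|run|reproduce-targets>`.

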