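# harvestgame

Who manages a depletable resource well, and who runs it into the ground?
`harvestgame` implements, end to end, a study design built around a
single-player resource-management game: a pool of 60 reward points that
replenishes each round by a stochastic percentage of whatever is left, a
player who may harvest any amount each round, and outcome measures —
rounds sustained and total rewards harvested — that are then related to
individual characteristics (hazardous alcohol use, psychological distress,
well-being, financial literacy, delay discounting). It is aimed at
behavioural and health scientists who want to simulate the game, derive its
optimal policy, generate realistic synthetic cohorts, and run the full
non-parametric analysis pipeline.

## What is inside

**The game.** Each round, a harvest `h` is removed from the pool `s`; the
remainder `m = s - h` replenishes to

    m' = min(60, m + round(m * f)),   f ~ N(0.15, 0.03^2), clamped at 0,

until the pool is exhausted or 70 rounds pass. Harvested points pay $0.005
each (bonus capped at $3.00); exhausting the pool at round `r < 50` costs
`6 * (50 - r)` seconds of waiting.

**The optimal policy.** The game is a 61-state Markov decision process.
Solved under the long-run average-reward criterion (relative value
iteration), the optimal strategy is a threshold rule: *harvest nothing at
51 points or fewer; above 51, harvest down to 51*. Discounted and
finite-horizon solvers cover impatient agents and the known-termination
variant.

**Psychometrics.** Summated scoring for AUDIT, GHQ-12, WHO-5 and a
financial-literacy short form; the five-trial ED50 delay-discounting
staircase over a 31-step geometric delay ladder (1 hour to 25 years), with
`log k = ln(1/ED50)` in day units; Cronbach's alpha.

**Synthetic cohorts.** A Gaussian-copula trait sampler matched to the
study's printed score means/SDs and the 0.41 discounting-drinking rank
correlation, driving noisy-threshold harvesting agents whose planted
coefficients reproduce the published correlation sign pattern.

**Statistics.** Spearman and partial Spearman rank correlation, the
Breusch-Pagan heteroskedasticity test, and quantile regression over the
0.05-0.95 grid — pinball loss minimised exactly by an in-package
Frisch-Newton interior-point solver — with bootstrap confidence bands.

## Worked example

```r
library(harvestgame)

# Solve the game and check the policy by simulation
model  <- build_transition_model(game_config(), solver_config())
policy <- solve_mdp(model, solver_config(mode = "average_reward"))
policy
#> Dynamic-programming policy (average_reward mode, 50098 iterations)
#>   threshold form: harvest 0 at states <= 51, harvest down to 51 above
#>   long-run average harvest: 7.5185 points/round

policy_value_mc(policy, n_games = 5000, seed = 7)$mean          # 526.2
policy_value_mc(threshold_policy(40), n_games = 5000, seed = 7)$mean  # 433.9

# Generate and analyse a synthetic cohort
sim <- simulate_cohort(cohort_config(rng_seed = 1))
sim
#> Simulated cohort: 400 participants (preset 'exp1')
#>   rounds lasted: median 70, 51% full length, 26% exhausted by round 10
#>   total rewards: median 191 (range 60-447)

an <- analyze_cohort(sim, analyses = c("spearman", "partial", "breusch_pagan"))
subset(an$correlations, outcome == "rounds_lasted" & is.na(partial_covariate))
#>   trait    rho  df      p_value
#>   audit -0.601 398 1.40e-40
#>   ghq12 -0.285 398 6.42e-09
#>    who5  0.287 398 5.01e-09
#>  finlit  0.172 398 5.51e-04
#>   log_k -0.380 398 3.62e-15
an$heteroskedasticity      # Breusch-Pagan = 59.81, p = 1.04e-14
```

Reading the numbers: the solved policy sustains the pool near its cap and
harvests the replenishment (about 7.5 points per round, roughly 526 points
over a 70-round game — far above the 434 of a more aggressive
harvest-to-40 rule). In the synthetic cohort, higher alcohol-use and
distress scores go with fewer rounds sustained (negative rho), well-being
and financial literacy with more, and the rewards-versus-rounds relation is
strongly heteroskedastic — the statistical shape the analysis pipeline is
designed to detect.

A full seeded pipeline run (policy, cohort, trajectories, analyses,
manifest with file digests) is one call:

```r
replicate_study("exp1", out_dir = "run1", seed = 11)
```

A thin command-line wrapper with `simulate`, `solve-mdp`,
`generate-cohort`, `analyze` and `replicate` subcommands lives at
`inst/cli/harvestgame.R`.

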