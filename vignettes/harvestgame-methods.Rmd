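---
title: "Models and methods behind harvestgame"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind harvestgame}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the models it implements, the
parameters that matter, and the design choices made where more than one
reasonable implementation existed. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The game

A single player faces a pool of `initial_resource = 60` points (also the cap).
Each round they harvest any whole number of points up to the current pool;
the remainder `m` is then replenished by a Gaussian percentage of itself,

$$ m' = \min\{60,\; m + \mathrm{round}(m \cdot f)\}, \qquad
   f \sim \mathcal N(0.15,\, 0.03^2)\ \text{clamped below at } 0, $$

and the game ends when the pool is exhausted or after 70 rounds. Harvested
points are worth \$0.005 each, the bonus is capped at \$3.00, and exhausting
the pool at round $r < 50$ costs $6 \times (50 - r)$ seconds of enforced
waiting (recorded, never slept). All of this sits in `game_config()`;
`play_game()` produces a seeded, reproducible trajectory.

Two discretisation choices are deliberately pinned, because the source
design does not state them and reproducibility requires a committed rule:

* **Integer states.** The pool is displayed as discrete rewards, so resource
  and harvests are integers and the replenishment is rounded to the nearest
  integer with *ties to even* (R's `round()`). A continuous-state variant is
  available behind `integer_resource = FALSE` for sensitivity analysis.
* **Clamp at zero.** The replenishment fraction is clamped at 0 rather than
  resampled. At the default parameters the clamp sits $5\sigma$ below the
  mean and is never active in practice; the choice only matters for extreme
  user-supplied configurations.

`rounds_lasted` for a player who empties the pool on round $r$ counts $r$
(the round of the final harvest).

## The optimal policy

`build_transition_model()` frames the game as a finite Markov decision
process on states $0,\dots,60$. Because the next state depends on the
current state and the harvest only through the post-harvest remainder, the
kernel is stored as one probability row per remainder. The replenishment
fraction is discretised at 41 equally spaced quadrature nodes spanning
$\pm 4\sigma$, with Gaussian weights renormalised over the span; the tests
confirm the resulting policy is unchanged under much finer grids, and the
one place where discretisation bias is visible (comparing a discounted value
function against exact Monte-Carlo returns) uses 641 nodes.

`solve_mdp()` offers three optimality criteria:

* **Average reward** (the default): relative value iteration. Players were
  not told the horizon, and the published optimal strategy is stationary, so
  the long-run harvest rate is the natural criterion. The solved policy on
  the default game is of threshold form: harvest nothing at 51 points or
  fewer, harvest down to 51 otherwise. This is what the acceptance script
  recomputes.
* **Discounted**: standard value iteration, for impatient agents. The
  post-harvest target is non-increasing as the discount factor falls (tested
  over $\gamma \in \{0.999, 0.99, 0.9, 0.7\}$); at very low $\gamma$ the
  policy collapses to harvesting everything.
* **Finite horizon**: backward induction over 70 rounds, modelling the
  known-termination variant in which the remaining rounds are displayed. In
  the final round the whole pool is harvested at every state.

Three numerical details deserve a note:

* **Tie-breaking.** The greedy policy breaks value ties (within $10^{-9}$)
  toward the *smaller* harvest, which makes the policy unique and
  conservative.
* **The multichain wrinkle.** States 0 and 1 can never regrow under the
  default parameters: the replenishment of a remainder of 1 rounds to zero.
  Their long-run gain is therefore 0 while every other state attains the
  optimal positive gain, so the MDP is multichain and the value-iteration
  increments cannot converge to a single constant across *all* states.
  Relative value iteration consequently measures its convergence span over
  the positive-gain ("live") class, identified structurally from the kernel;
  the Bellman residual is guaranteed below tolerance there, while the dead
  states' relative values sink without affecting the policy. The test suite
  checks both halves of this statement.
* **The deterministic game is knife-edge.** With `replenish_sd = 0` the
  long-run harvest rate $\min\{60 - T,\ \mathrm{round}(0.15\,T)\}$ is
  maximised (at 8 points/round) by *three* targets, 50, 51 and 52, which
  differ only in transient rewards. The solver is gain-optimal, not
  bias-optimal: the tie-break selects the largest tied target, 52. The test
  asserts the gain against the independent steady-state oracle and the
  target against the tie-break rule, rather than pretending the
  deterministic game has a unique answer.

`policy_value_mc()` is the independent check on the dynamic programming: it
plays seeded ensembles of games (one replenishment draw per game per round)
and, in the tests, ranks the DP target above every other harvest-to-T
policy for $T \in \{45,\dots,55\}$.

## Psychometric scoring and the ED50 staircase

`score_instrument()` implements plain summated scales at score level only
(no item wordings): AUDIT 10 items 0--4 (total 0--40), GHQ-12 twelve items
Likert-scored 0--3 (total 0--36; the 0--36 scale is the one consistent with
a sample mean near 15), WHO-5 five items 0--5 reported raw (0--25). The
financial-literacy short form is the one instrument whose published total
scale cannot be reconciled with a 9-item OECD score (sample means in the
mid-30s exceed the standard 21-point maximum), so its per-item maximum is
configurable with a default of 7 (total 0--63); nothing downstream depends
on the choice because the analysis standardises trait scores.

`run_ed50_elicitation()` implements the five-trial adjusting-delay
staircase: 31 delays spaced geometrically from 1 hour to 25 years (the
ladder is both computed in code and committed as a plain-text fixture),
first probe at the midpoint (step 16), "now" answers move the probe to
shorter delays and "delayed" answers to longer ones with step sizes 8, 4,
2, 1, 1, clamped to the ladder. The final delay is the ED50; the hyperbolic
rate is $k = 1/\mathrm{ED50}$ in 1/days and is reported as $\log k$
(natural log). Day units with natural logs are the only convention under
which the instrument's bounds give $\log k \in [\ln(1/9125), \ln 24]
\approx [-9.12, 3.18]$, a range that brackets the trait means used by the
cohort generator; a base-10 convention would not.

`cronbach_alpha()` is the standard
$\frac{k}{k-1}\bigl(1 - \sum_i \sigma_i^2 / \sigma_{\text{total}}^2\bigr)$
with $n-1$ variances. Note that raw alpha is *not* invariant under
rescaling an item: three perfectly correlated items with scales 1, 2 and
0.5 give exactly $6/7$, and the tests assert that closed form rather than
the (incorrect) expectation of 1.

## The synthetic cohort

The generator emulates the statistical shape of the study samples; it makes
no claim of cognitive realism, and none of its parameters are fitted to the
deposited human data.

**Traits.** `sample_traits()` draws latent normals through a Gaussian
copula with pairwise latent correlation $2\sin(\pi\rho_s/6)$ — the exact
inverse of the bivariate-normal Spearman relation — then maps them to the
printed score-level marginals (first sample: AUDIT 9.8 (10.1), GHQ-12 14.7
(5.1), WHO-5 12.2 (6.5), financial literacy 34.3 (5.8), $\log k$ -4.4
(2.8); second sample: AUDIT 12.03 (11.05), $\log k$ -3.34 (3.27)), rounds
integer instruments and clips every trait to its feasible range. Clipping a
normal at zero when the SD is comparable to the mean (AUDIT) produces the
same kind of right-skewed, zero-inflated distribution the real scores have;
it also perturbs the realised moments and slightly attenuates rank
correlations, which is why the tests check the rank correlation of
$\log k$ with AUDIT within $\pm 0.03$ of the 0.41 design value at
$n = 10^4$ rather than exactly. Only that one cross-correlation is pinned
by evidence; distress--well-being defaults to $-0.45$ (opposed by
construction) and all other cross-correlations default to zero and are
configurable.

**Traits to behaviour.** Each participant gets a personal harvesting target

$$ T_i = \texttt{base\_target} - \textstyle\sum_t c_t z_{it} + \eta_i,
   \qquad \eta_i \sim \mathcal N(0, \texttt{target\_noise\_sd}^2), $$

with $z$ standardised against the preset (not sample) moments, clipped to
$[0, 60]$. On every round the *realised* target is jittered,
$T_{ir} = \mathrm{round}(T_i + \varepsilon_{ir})$ with $\varepsilon_{ir}
\sim \mathcal N(0, \texttt{harvest\_jitter\_sd}^2)$, and the agent harvests
$\max\{0, s - T_{ir}\}$. The within-round jitter is what makes the family
span the full outcome range: a pure threshold policy never exhausts the
pool, whereas a low-target noisy agent sooner or later draws
$T_{ir} \le 0$ and harvests everything. This is a declared generative
model, chosen as the minimal family that (i) spans instant exhaustion to
full-length sustain, (ii) lets single signed coefficients plant the
published correlation directions, and (iii) produces fan-shaped
(heteroskedastic) rewards against rounds lasted without any extra
machinery.

**Calibration.** The defaults (`base_target = 30`, slopes AUDIT 11, GHQ-12
3.5, WHO-5 -3, financial literacy -3.5, $\log k$ 6, target noise SD 7,
jitter SD 12) were fixed once so that the first-sample preset yields: the
published sign pattern of all five trait--outcome correlations; an
AUDIT-rounds rank correlation inside the design band $[-0.70, -0.45]$;
both outcome classes present (a ceiling mass of 70-round survivors of
roughly a half alongside a quarter of collapses within ten rounds); and a
Breusch--Pagan rejection driven by the construction. These are calibrated
reproductions of a statistical *shape*, not measurements of human
behaviour, and the tests treat them as such.

**What the generator does not emulate.** The two-wave structure of the
first study (half the participants took GHQ-12/AUDIT/WHO-5, the other half
financial literacy) is not reproduced — every synthetic participant carries
all preset traits, so synthetic degrees of freedom differ from some
published ones. Item-level responses are not generated (traits are sampled
at total-score level), learning within the game is absent, and the
replenishment-luck channel into total rewards is mechanical (rewards are
sums of harvested replenishments), which is why the
replenishment-experience control below is assessed across a panel of seeds.

## The analysis pipeline

* **Spearman correlation** is the Pearson correlation of mid-ranks, with a
  two-sided $t$ approximation on $n-2$ df. Exact permutation p-values are
  impractical at $n = 400$ and the $t$ approximation holds its nominal
  type-I error within $[0.035, 0.065]$ in the null simulations the tests
  run.
* **Partial Spearman correlation** rank-transforms all three variables,
  residualises the two of interest on the covariate's ranks by least
  squares, and correlates the residuals on $n-3$ df. A constant covariate
  degrades gracefully to the plain correlation with a warning.
* **Breusch--Pagan** is the studentised Lagrange-multiplier form
  $n R^2_{\text{aux}}$ from the regression of squared residuals on the
  predictors, against $\chi^2_p$. The preinstalled `lmtest::bptest()` is
  used in the tests as an independent oracle, never as the implementation.
* **Quantile regression** minimises the pinball loss
  $\sum_i \rho_\tau(y_i - a - b x_i)$ through its bounded-variable dual
  linear program, solved by a Frisch--Newton interior-point method
  (Mehrotra predictor--corrector, duality-gap tolerance $10^{-12}n$,
  iterates clamped strictly interior). The tests pin the solver against
  both a brute-force grid search on small fixtures and an exact
  linear-programming reference on random datasets to $10^{-6}$. The fitted
  solution satisfies the quantile balance condition: at most a fraction
  $\tau$ of residuals strictly negative, at least $\tau$ non-positive.
  `quantile_profile()` fits the 0.05--0.95 grid in steps of 0.05 with the
  predictor z-scored, so coefficients read as outcome units per predictor
  SD.
* **Confidence bands** for quantile coefficients come from a
  participant-resampling (pairs) bootstrap with percentile endpoints,
  sharing one resample set across the grid (default 1000 resamples,
  seeded). This is a deliberate methodological substitution for rank-based
  inversion intervals: the bootstrap is transparent, assumption-light, and
  its resample count and seed live in the run configuration. It is
  documented as a substitution, not presumed numerically equivalent.
* **Outcomes are left untransformed.** Rounds lasted lives on $[1, 70]$
  with a mass at the ceiling; quantile regression tolerates the censoring,
  but coefficient profiles flatten above roughly the 0.75 quantile because
  the best performers sit at 70 rounds regardless of traits. Interpret the
  upper tail accordingly.
* **Replenishment-experience control.** For each participant the mean drawn
  replenishment fraction over the first 1, 2, 3, 5, 10, 20, 50 and 70
  rounds (truncated at their rounds lasted) is correlated with both
  outcomes. In the generator, depletion never depends on the draws, so
  these correlations are sampling noise plus a weak mechanical rewards
  channel; the tests therefore require the pooled distribution to
  concentrate well below $|\rho| = 0.1$ and most seeded cohorts to clear
  that bound everywhere, rather than asserting a single cohort does.

## Reproducibility

`replicate_study()` chains solve → generate → simulate → analyse, derives
one RNG stream per stage from the master seed (so changing the cohort size
does not perturb the bootstrap draws), and writes every table as CSV plus a
manifest with the configuration snapshot, stage seeds, package version and
MD5 digests. Re-running with the same configuration and seed reproduces
byte-identical CSVs, and the tests verify that digest-for-digest. Presets
cover the first sample (five traits, $n = 400$), the second (AUDIT and
$\log k$, $n = 381$) and the known-termination variant ($n = 100$,
finite-horizon solver, rounds remaining shown to policies that accept
them). There is no command-line requirement for using any of this — the
exported functions are the interface — but a thin script with
`simulate` / `solve-mdp` / `generate-cohort` / `analyze` / `replicate`
subcommands ships under `inst/cli/` for shell use.

## Problem sizes

The shipped test-suite and acceptance computations use: the full 61-state
MDP (exact, not scaled down); Monte-Carlo policy evaluation at 1500--5000
games per policy; cohorts of 400 (the study's own size) with panels of up
to 11 seeds; 2000-replicate null calibrations at $n = 200$; 50-dataset
oracle comparisons for the quantile solver; and bootstrap sizes of 40--200
inside tests (1000 as the user-facing default). These sizes were chosen so
each check is statistically decisive for the property it tests.

## Known limitations

* Average-reward optimality ignores transient rewards; in the deterministic
  game this leaves a genuine three-way tie resolved by the tie-break (see
  above), and a bias-optimal refinement is not implemented.
* The trait-to-behaviour map is linear in z-scores with Gaussian noise;
  real heterogeneity in harvesting strategies (learning, probing, rounding
  to salient numbers) is out of scope.
* Bootstrap percentile intervals can under-cover at extreme quantiles with
  small samples; the coverage test exercises the interior of the grid.
* The optional loader for externally collected data expects the cohort CSV
  schema; no import filters for survey-platform exports are provided.
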