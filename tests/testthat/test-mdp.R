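test_that("transition model rows are probability vectors with the right support", {
  tm <- build_transition_model(game_config(), solver_config())
  expect_equal(unname(rowSums(tm$Q)), rep(1, 61), tolerance = 1e-12)
  # Remainder 0 is absorbing: state 0 (and a full harvest from 60) lands on 0.
  expect_equal(unname(transition_row(tm, 0, 0)), c(1, rep(0, 60)))
  expect_equal(unname(transition_row(tm, 60, 60)), c(1, rep(0, 60)))
  # Deterministic replenishment: remainder 51 moves to 59 with certainty.
  tm0 <- build_transition_model(game_config(replenish_sd = 0))
  expect_equal(which(transition_row(tm0, 60, 9) > 0) - 1L, 59L)
  # Continuous-state configs are rejected.
  expect_error(build_transition_model(game_config(integer_resource = FALSE)),
               class = "harvestgame_domain_error")
})

test_that("average-reward DP reproduces the harvest-to-51 policy", {
  pol <- solved_default_policy()
  expect_true(attr(pol, "is_threshold_form"))
  expect_equal(attr(pol, "threshold"), 51)
  expect_equal(attr(pol, "target"), 51)
  expect_equal(pol$harvest, pmax(0, 0:60 - 51))
})

test_that("Bellman residual of the returned solution is below tolerance on the live class", {
  tm <- build_transition_model(game_config(), solver_config())
  pol <- solved_default_policy()
  v <- pol$value
  W <- drop(tm$Q %*% v)
  Tv <- vapply(0:60, function(s) {
    m <- 0:s
    max((s - m) + W[m + 1])
  }, numeric(1))
  g <- attr(pol, "gain")
  expect_lt(max(abs((Tv - v - g)[tm$live])), 1e-6)
  # The non-live states (an emptied or unrecoverable pool) have zero gain:
  # their Bellman increment under the converged relative values is ~0, not g.
  expect_lt(max(abs((Tv - v)[!tm$live])), 1e-6)
})

test_that("deterministic replenishment solves to the steady-state oracle", {
  # Independent oracle: under sigma = 0 a maintain-at-m policy harvests
  # min(cap - m, round(0.15 * m)) per round in steady state; the maximal
  # rate over integer targets bounds the achievable gain.
  rate <- vapply(0:60, function(m) min(60 - m, round(0.15 * m)), numeric(1))
  best_rate <- max(rate)       # 8 points per round
  oracle_targets <- which(rate == best_rate) - 1L  # gain-optimal targets
  tm0 <- build_transition_model(game_config(replenish_sd = 0))
  p0 <- solve_mdp(tm0, solver_config(mode = "average_reward"))
  expect_equal(attr(p0, "gain"), best_rate, tolerance = 1e-8)
  expect_true(attr(p0, "target") %in% oracle_targets)
  # The tie-break toward smaller harvests picks the largest tied target.
  expect_equal(attr(p0, "target"), max(oracle_targets))
  expect_equal(attr(p0, "target"), 52)
})

test_that("discounted targets shrink with impatience and values match simulation", {
  tm <- build_transition_model(game_config(), solver_config())
  targets <- vapply(c(0.999, 0.99, 0.9, 0.7), function(g) {
    pd <- solve_mdp(tm, solver_config(mode = "discounted",
                                      discount_gamma = g,
                                      tolerance = 1e-10))
    attr(pd, "target")
  }, numeric(1))
  expect_true(all(diff(targets) <= 0))  # more impatient => lower target

  # DP-vs-simulation consistency at gamma = 0.95: the discounted value at
  # the initial state agrees with a Monte-Carlo discounted return. The DP
  # value is for the unbounded-round game, so the simulation horizon is
  # extended until the discount tail is negligible (0.95^600 ~ 4e-14), and
  # the replenishment quadrature refined so discretisation bias is well
  # below the Monte-Carlo standard error.
  tm_fine <- build_transition_model(game_config(),
                                    solver_config(quadrature_points = 641))
  pd <- solve_mdp(tm_fine, solver_config(mode = "discounted",
                                         discount_gamma = 0.95,
                                         tolerance = 1e-10))
  mc <- policy_value_mc(pd, game_config(max_rounds = 600), n_games = 4000,
                        seed = 42, discount = 0.95)
  expect_lt(abs(pd$value[61] - mc$mean), 3 * mc$se)
})

test_that("finite-horizon induction harvests everything in the last round", {
  tm <- build_transition_model(game_config(), solver_config())
  pf <- solve_mdp(tm, solver_config(mode = "finite_horizon", horizon = 70))
  hb <- attr(pf, "harvest_by_round")
  expect_equal(hb[, 70], 0:60)
  # Far from the horizon the prescription matches the stationary policy.
  expect_equal(hb[, 1], pmax(0, 0:60 - 51))
})

test_that("Monte-Carlo evaluation is seeded, exact for degenerate policies, and ranks the DP target top", {
  # Harvest-everything gives exactly the initial pool.
  mc <- policy_value_mc(function(s) s, n_games = 50, seed = 3)
  expect_equal(mc$mean, 60)
  expect_equal(mc$se, 0)
  # Same seed, same estimate.
  a <- policy_value_mc(threshold_policy(48), n_games = 200, seed = 11)
  b <- policy_value_mc(threshold_policy(48), n_games = 200, seed = 11)
  expect_identical(a$totals, b$totals)

  # Exhaustive threshold sweep: the DP policy's mean reward is at least that
  # of every harvest-to-T policy, and mean reward is unimodal in T with the
  # maximum at the DP target.
  pol <- solved_default_policy()
  sweep <- vapply(45:55, function(T) {
    policy_value_mc(threshold_policy(T), n_games = 1500,
                    seed = 9000 + T)$mean
  }, numeric(1))
  dp <- policy_value_mc(pol, n_games = 1500, seed = 8999)
  expect_gte(dp$mean + 1.96 * dp$se, max(sweep))
  peak <- which.max(sweep)
  expect_equal((45:55)[peak], attr(pol, "target"))
  expect_true(all(diff(sweep[seq_len(peak)]) > 0))
  expect_true(all(diff(sweep[peak:length(sweep)]) < 0))
})
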