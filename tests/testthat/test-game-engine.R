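test_that("replenishment draws match the stated Gaussian law", {
  # Degenerate distribution: sd = 0 always returns the mean.
  cfg0 <- game_config(replenish_sd = 0)
  expect_equal(draw_replenish_fraction(cfg0, 10), rep(0.15, 10))

  # Monte-Carlo check of the stated moments: the sample mean of 1e5 draws
  # lies within 3 standard errors of 0.15.
  withr::with_seed(101, {
    d <- draw_replenish_fraction(game_config(), 1e5)
    expect_lt(abs(mean(d) - 0.15), 3 * 0.03 / sqrt(1e5))
    expect_lt(abs(sd(d) - 0.03), 0.001)
  })

  # Clamp contract: no draw is ever negative, even when the law itself puts
  # substantial mass below zero.
  withr::with_seed(102, {
    expect_true(all(draw_replenish_fraction(game_config(), 1e6) >= 0))
    heavy <- game_config(replenish_mean = 0.02, replenish_sd = 0.5)
    expect_true(all(draw_replenish_fraction(heavy, 1e5) >= 0))
  })
})

test_that("the round update removes, replenishes and truncates correctly", {
  cfg <- game_config()
  # Full harvest empties an absorbing pool.
  expect_equal(step_resource(60, 60, cfg)$next_resource, 0)
  # No harvest: replenishment is truncated at the cap.
  expect_equal(step_resource(60, 0, cfg)$next_resource, 60)
  # Direct evaluation of the update rule: remainder 51, fraction 0.15 gives
  # replenishment round(7.65) = 8, hence 59.
  expect_equal(step_resource(60, 9, cfg, fraction = 0.15)$next_resource, 59)
  # Round-half-to-even at the replenishment rounding.
  expect_equal(step_resource(60, 10, cfg, fraction = 0.15)$next_resource, 58)
  # Continuous mode keeps fractions.
  ccfg <- game_config(integer_resource = FALSE)
  expect_equal(step_resource(60, 9, ccfg, fraction = 0.15)$next_resource,
               51 * 1.15)
  # Domain errors.
  expect_error(step_resource(10, 11, cfg), class = "harvestgame_domain_error")
  expect_error(step_resource(10, -1, cfg), class = "harvestgame_domain_error")
})

test_that("play_game terminates, summarises and reproduces trajectories", {
  cfg <- game_config()
  greedy <- play_game(function(s) s, cfg, seed = 1)
  expect_equal(greedy$rounds_lasted, 1)
  expect_equal(greedy$total_rewards, 60)
  expect_true(greedy$exhausted)

  idle <- play_game(function(s) 0, cfg, seed = 1)
  expect_equal(idle$rounds_lasted, 70)
  expect_equal(idle$total_rewards, 0)
  expect_false(idle$exhausted)
  expect_equal(idle$penalty_seconds, 0)

  # Fixed seed reproducibility: identical event tables.
  t1 <- play_game(threshold_policy(51), cfg, seed = 99)
  t2 <- play_game(threshold_policy(51), cfg, seed = 99)
  expect_identical(t1$events, t2$events)

  # Infeasible policy names the round.
  expect_error(play_game(function(s) s + 1, cfg, seed = 1),
               "round 1", class = "harvestgame_domain_error")
})

test_that("threshold 51 beats nearby and distant harvest-to-T policies", {
  means <- vapply(c(40, 45, 51, 60), function(T) {
    policy_value_mc(threshold_policy(T), game_config(), n_games = 2000,
                    seed = 500 + T)$mean
  }, numeric(1))
  expect_true(all(means[3] > means[-3]))
})

test_that("resource stays within bounds and zero is absorbing under random play", {
  cfg <- game_config()
  withr::with_seed(7, {
    shares <- runif(20)
    for (i in seq_along(shares)) {
      tr <- play_game(random_share_policy(shares[i]), cfg,
                      seed = sample.int(1e6, 1))
      ev <- tr$events
      expect_true(all(ev$pre_harvest >= 0 & ev$pre_harvest <= 60))
      expect_true(all(ev$post_replenish >= 0 & ev$post_replenish <= 60))
      expect_true(all(ev$harvest >= 0 & ev$harvest <= ev$pre_harvest))
      # Conservation: harvested total cannot exceed the initial pool plus
      # everything that was replenished.
      repl <- ev$post_replenish - (ev$pre_harvest - ev$harvest)
      expect_lte(tr$total_rewards, 60 + sum(pmax(repl, 0)))
      # Zero absorbing: the game ends exactly when the pool empties.
      expect_true(all(ev$post_replenish[-tr$rounds_lasted] > 0))
      expect_equal(tr$total_rewards, sum(ev$harvest))
      expect_equal(tr$rounds_lasted, nrow(ev))
    }
  })
})

test_that("time penalty and bonus payment follow the payment rules", {
  expect_equal(time_penalty(10), 240)  # 40 rounds x 6 s
  expect_equal(time_penalty(50), 0)
  expect_equal(time_penalty(49), 6)
  expect_equal(time_penalty(70), 0)
  expect_error(time_penalty(0), class = "harvestgame_domain_error")

  expect_equal(bonus_payment(100), 0.50)
  expect_equal(bonus_payment(600), 3.00)
  expect_equal(bonus_payment(10000), 3.00)
})

test_that("the known-termination variant exposes rounds remaining to policies", {
  cfg <- game_config(show_rounds_remaining = TRUE, replenish_sd = 0)
  seen <- integer(0)
  pol <- function(state, rounds_remaining) {
    seen <<- c(seen, rounds_remaining)
    0
  }
  play_game(pol, cfg, seed = 1)
  expect_equal(seen, 70:1)
})
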