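test_that("copula sampling hits the requested rank-correlation structure", {
  # Identity matrix: all pairwise sample Spearman correlations near 0.
  trait_names <- c("audit", "ghq12", "who5", "finlit", "log_k")
  idR <- diag(5)
  dimnames(idR) <- list(trait_names, trait_names)
  cfg <- cohort_config(n_participants = 10000, rank_correlations = idR,
                       rng_seed = 12)
  tr <- sample_traits(cfg)
  cols <- setdiff(names(tr), "participant_id")
  cm <- cor(tr[cols], method = "spearman")
  expect_lt(max(abs(cm[upper.tri(cm)])), 0.03)

  # Default structure: the discounting/alcohol-use rank correlation lands
  # within 0.41 +/- 0.03 despite rounding and clipping of the marginals.
  tr2 <- sample_traits(cohort_config(n_participants = 10000, rng_seed = 13))
  expect_lt(abs(cor(tr2$log_k, tr2$audit, method = "spearman") - 0.41), 0.03)

  # Zero-SD trait collapses to a constant at its mean.
  tr3 <- sample_traits(cohort_config(n_participants = 50,
                                     trait_sds = list(ghq12 = 0),
                                     rng_seed = 14))
  expect_true(all(tr3$ghq12 == 15))  # rounded preset mean

  # Traits respect their score ranges.
  expect_true(all(tr2$audit >= 0 & tr2$audit <= 40))
  expect_true(all(tr2$who5 >= 0 & tr2$who5 <= 25))
  b <- log_k_bounds()
  expect_true(all(tr2$log_k >= b[1] & tr2$log_k <= b[2]))

  # Ill-shaped and non-PSD matrices are rejected, the latter with a
  # nearest-PSD suggestion.
  expect_error(cohort_config(preset = "exp2", rank_correlations = diag(3)),
               class = "harvestgame_validation_error")
  bad2 <- diag(2)
  bad2[1, 2] <- bad2[2, 1] <- 1.2
  expect_error(cohort_config(preset = "exp2", rank_correlations = bad2),
               "positive semi-definite",
               class = "harvestgame_validation_error")
})

test_that("trait effects move policy targets in the declared directions", {
  cfg <- cohort_config(n_participants = 500, rng_seed = 2)
  tr <- sample_traits(cfg)
  # No effects, no noise: everyone sits at the base target.
  flat <- cohort_config(n_participants = 500,
                        effect_coefficients = c(audit = 0),
                        target_noise_sd = 0, rng_seed = 2)
  pol0 <- traits_to_policy(tr, flat, seed = 1)
  expect_true(all(pol0$target == flat$base_target))
  # A positive alcohol-use coefficient lowers targets as scores rise.
  pol <- traits_to_policy(tr, cfg, seed = 1)
  expect_lt(unname(spearman_cor(tr$audit, pol$target)$estimate), 0)
  # Targets stay inside the state space.
  expect_true(all(pol$target >= 0 & pol$target <= 60))
})

test_that("simulated cohorts reproduce the qualitative outcome structure", {
  sim <- simulate_cohort(cohort_config(rng_seed = 401))
  r <- sim$records
  expect_equal(nrow(r), 400)
  # Both outcome classes are present: full-length survivors and early
  # collapses.
  expect_gt(sum(r$rounds_lasted == 70), 0)
  expect_gt(sum(r$exhausted & r$rounds_lasted < 10), 0)
  expect_true(all(r$rounds_lasted >= 1 & r$rounds_lasted <= 70))
  expect_true(all(r$total_rewards >= 0))
  # Summaries agree with the trajectories.
  agg <- aggregate(harvest ~ participant_id, sim$trajectories, sum)
  expect_equal(agg$harvest[order(agg$participant_id)], r$total_rewards)
  nr <- aggregate(round ~ participant_id, sim$trajectories, max)
  expect_equal(nr$round[order(nr$participant_id)], r$rounds_lasted)
  # Penalties only for early exhaustion.
  expect_true(all((r$penalty_seconds > 0) == (r$exhausted & r$rounds_lasted < 50)))

  # Determinism: same seed, same table.
  sim2 <- simulate_cohort(cohort_config(rng_seed = 401))
  expect_identical(sim$records, sim2$records)
  expect_identical(sim$trajectories, sim2$trajectories)

  # Degenerate generator: no effects and no noise collapse the cohort onto
  # one policy, and with deterministic replenishment all games coincide.
  flat <- cohort_config(n_participants = 30,
                        effect_coefficients = c(audit = 0),
                        target_noise_sd = 0, harvest_jitter_sd = 0,
                        rng_seed = 5)
  sflat <- simulate_cohort(flat, game_config(replenish_sd = 0))
  expect_equal(length(unique(sflat$records$rounds_lasted)), 1L)
  expect_equal(length(unique(sflat$records$total_rewards)), 1L)
})

test_that("planted trait effects are recovered by the analysis pipeline", {
  sim <- simulate_cohort(cohort_config(rng_seed = 77))
  r <- sim$records
  # Negative planted effects on rounds for alcohol use, recovered strongly.
  ct <- spearman_cor(r$audit, r$rounds_lasted)
  expect_lt(unname(ct$estimate), -0.3)
  expect_lt(ct$p.value, 1e-3)
  # Partial correlation controlling discounting stays negative.
  ps <- partial_spearman(r$audit, r$rounds_lasted, r$log_k)
  expect_lt(unname(ps$estimate), -0.2)

  # Doubling a planted coefficient does not weaken the recovered
  # correlation (tested over seeds).
  for (sd_ in c(301, 302, 303)) {
    co1 <- cohort_config(effect_coefficients = c(audit = 5), rng_seed = sd_)
    co2 <- cohort_config(effect_coefficients = c(audit = 10), rng_seed = sd_)
    r1 <- simulate_cohort(co1)$records
    r2 <- simulate_cohort(co2)$records
    e1 <- unname(spearman_cor(r1$audit, r1$rounds_lasted)$estimate)
    e2 <- unname(spearman_cor(r2$audit, r2$rounds_lasted)$estimate)
    expect_gte(abs(e2) + 0.03, abs(e1))
  }
})

test_that("behaviour noise induces detectable heteroskedasticity in rewards", {
  sim <- simulate_cohort(cohort_config(rng_seed = 55))
  r <- sim$records
  bp <- breusch_pagan(r$total_rewards, r$rounds_lasted)
  expect_lt(bp$p.value, 0.001)
  # Conditional spread of rewards grows with rounds lasted.
  lo <- r$total_rewards[r$rounds_lasted <= 20]
  hi <- r$total_rewards[r$rounds_lasted >= 60]
  expect_gt(sd(hi), 2 * sd(lo))
})
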