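#' Draw replenishment fractions
#'
#' Draws from the Gaussian replenishment law of the game (mean
#' `replenish_mean`, sd `replenish_sd`), clamped below at zero. At the
#' default parameters (0.15, 0.03) the clamp sits five standard deviations
#' below the mean and is never active in practice.
#'
#' @param config A [game_config()].
#' @param n Number of draws.
#' @return Numeric vector of `n` non-negative fractions.
#' @examples
#' set.seed(1)
#' draw_replenish_fraction(game_config(), 5)
#' @export
draw_replenish_fraction <- function(config = game_config(), n = 1) {
  validate_game_config(config)
  check_scalar_number(n, "n", min = 1, integer = TRUE)
  pmax(0, stats::rnorm(n, config$replenish_mean, config$replenish_sd))
}

#' Advance the resource by one harvesting round
#'
#' Applies the round update: the harvest is removed, the remainder is
#' replenished by a (drawn or supplied) fraction of itself, and the result is
#' truncated at the cap. In integer mode the replenishment is rounded to the
#' nearest integer with ties to even. An emptied pool stays empty: zero is
#' absorbing.
#'
#' @param resource Current pre-harvest pool value.
#' @param harvest Amount to harvest; must lie in `[0, resource]`.
#' @param config A [game_config()].
#' @param fraction Optional replenishment fraction; drawn from the game's law
#'   when `NULL`.
#' @return A list with `next_resource` and a one-row data frame `event`
#'   (`pre_harvest`, `harvest`, `fraction_drawn`, `post_replenish`).
#' @examples
#' step_resource(60, 9, game_config(), fraction = 0.15)$next_resource  # 59
#' @export
step_resource <- function(resource, harvest, config = game_config(),
                          fraction = NULL) {
  validate_game_config(config)
  check_scalar_number(resource, "resource", min = 0,
                      max = config$max_resource)
  if (!is.numeric(harvest) || length(harvest) != 1L || !is.finite(harvest) ||
      harvest < 0 || harvest > resource) {
    stop_domain(sprintf(
      "harvest must lie in [0, %g], got %s", resource, format(harvest)))
  }
  if (config$integer_resource && harvest != round(harvest)) {
    stop_domain("harvest must be a whole number in integer mode")
  }
  if (is.null(fraction)) fraction <- draw_replenish_fraction(config, 1)
  remainder <- resource - harvest
  replenishment <- remainder * fraction
  if (config$integer_resource) replenishment <- round(replenishment)
  next_resource <- min(config$max_resource, remainder + replenishment)
  if (remainder == 0) next_resource <- 0
  list(next_resource = next_resource,
       event = data.frame(pre_harvest = resource,
                          harvest = harvest,
                          fraction_drawn = fraction,
                          post_replenish = next_resource))
}

#' Threshold harvesting policy
#'
#' The policy family the optimal strategy belongs to: harvest
#' `max(0, state - target)`, i.e. harvest the pool down to `target` whenever
#' it exceeds `target` and otherwise wait.
#'
#' @param target Post-harvest level the policy leaves behind.
#' @return A function of the resource state, of class `harvest_policy`.
#' @examples
#' pol <- threshold_policy(51)
#' pol(60)  # 9
#' pol(40)  # 0
#' @export
threshold_policy <- function(target) {
  check_scalar_number(target, "target", min = 0)
  f <- function(state) pmax(0, state - target)
  structure(f, class = c("threshold_policy", "harvest_policy"),
            target = target)
}

#' Coerce an object to a harvest-policy function
#'
#' Accepts a plain function of the state (optionally of
#' `(state, rounds_remaining)` for the known-termination game variant), a
#' [threshold_policy()], a numeric scalar (interpreted as a threshold
#' target), or a solved [solve_mdp()] policy table.
#'
#' @param x Object to coerce.
#' @return A function `(state, rounds_remaining)` returning a harvest.
#' @export
as_harvest_policy <- function(x) {
  if (inherits(x, "policy_table")) {
    harvest <- x$harvest
    return(function(state, rounds_remaining = NA) harvest[state + 1L])
  }
  if (is.function(x)) {
    if (length(formals(x)) >= 2L) return(x)
    return(function(state, rounds_remaining = NA) x(state))
  }
  if (is.numeric(x) && length(x) == 1L) {
    return(as_harvest_policy(threshold_policy(x)))
  }
  stop_validation("cannot interpret 'policy' as a harvesting policy")
}

#' Play one game
#'
#' Iterates [step_resource()] from the initial pool under a policy until the
#' resource is exhausted or the maximum number of rounds is reached, and
#' summarises the run: rounds lasted, total rewards, exhaustion flag,
#' waiting-time penalty and bonus payment. Identical seed and policy give an
#' identical trajectory.
#'
#' @param policy Anything accepted by [as_harvest_policy()].
#' @param config A [game_config()].
#' @param seed Optional seed; defaults to `config$rng_seed`.
#' @return An object of class `game_trajectory` with elements `events` (one
#'   row per round), `rounds_lasted`, `total_rewards`, `exhausted`,
#'   `penalty_seconds` and `bonus_usd`.
#' @examples
#' traj <- play_game(threshold_policy(51), game_config(), seed = 1)
#' traj
#' @export
play_game <- function(policy, config = game_config(),
                      seed = config$rng_seed) {
  validate_game_config(config)
  pol <- as_harvest_policy(policy)
  maybe_with_seed(seed, {
    n_max <- config$max_rounds
    pre <- h <- fr <- post <- numeric(n_max)
    resource <- config$initial_resource
    r <- 0L
    while (r < n_max && resource > 0) {
      r <- r + 1L
      rounds_remaining <- if (config$show_rounds_remaining) {
        n_max - r + 1L
      } else NA_integer_
      harvest <- pol(resource, rounds_remaining)
      if (!is.numeric(harvest) || length(harvest) != 1L ||
          !is.finite(harvest) || harvest < 0 || harvest > resource ||
          (config$integer_resource && harvest != round(harvest))) {
        stop_domain(sprintf(
          "policy returned infeasible harvest %s at round %d (resource %g)",
          format(harvest), r, resource))
      }
      stepped <- step_resource(resource, harvest, config)
      pre[r] <- resource
      h[r] <- harvest
      fr[r] <- stepped$event$fraction_drawn
      post[r] <- stepped$next_resource
      resource <- stepped$next_resource
    }
    events <- data.frame(round = seq_len(r), pre_harvest = pre[seq_len(r)],
                         harvest = h[seq_len(r)],
                         fraction_drawn = fr[seq_len(r)],
                         post_replenish = post[seq_len(r)])
    new_trajectory(events, config)
  })
}

# Build the trajectory summary object from an event table.
new_trajectory <- function(events, config) {
  rounds_lasted <- nrow(events)
  total_rewards <- sum(events$harvest)
  exhausted <- events$post_replenish[rounds_lasted] == 0
  penalty <- if (exhausted) time_penalty(rounds_lasted, config) else 0
  structure(
    list(events = events,
         rounds_lasted = rounds_lasted,
         total_rewards = total_rewards,
         exhausted = exhausted,
         penalty_seconds = penalty,
         bonus_usd = bonus_payment(total_rewards, config)),
    class = "game_trajectory")
}

#' @export
print.game_trajectory <- function(x, ...) {
  cat(sprintf(
    "Game trajectory: %d round(s), %g points harvested (%s), bonus $%.2f%s\n",
    x$rounds_lasted, x$total_rewards,
    if (x$exhausted) "resource exhausted" else "resource sustained",
    x$bonus_usd,
    if (x$penalty_seconds > 0) {
      sprintf(", %g s waiting penalty", x$penalty_seconds)
    } else ""))
  invisible(x)
}

#' Waiting-time penalty for early depletion
#'
#' A participant who exhausts the pool at `depletion_round` waits
#' `penalty_per_round` seconds for every round remaining up to the cutoff
#' round: `penalty_per_round * max(0, penalty_cutoff_round -
#' depletion_round)`. Depleting at round 10 under the defaults costs
#' 40 x 6 = 240 seconds.
#'
#' @param depletion_round Round at which the pool reached zero (1-based).
#' @param config A [game_config()].
#' @return Penalty in seconds.
#' @examples
#' time_penalty(10)  # 240
#' @export
time_penalty <- function(depletion_round, config = game_config()) {
  validate_game_config(config)
  if (!is.numeric(depletion_round) || length(depletion_round) != 1L ||
      !is.finite(depletion_round) || depletion_round < 1 ||
      depletion_round != round(depletion_round)) {
    stop_domain("'depletion_round' must be a positive whole number")
  }
  config$penalty_per_round *
    max(0, config$penalty_cutoff_round - depletion_round)
}

#' Bonus payment for harvested rewards
#'
#' `min(bonus_cap, total_rewards * reward_value)`.
#'
#' @param total_rewards Total points harvested.
#' @param config A [game_config()].
#' @return Bonus in dollars.
#' @examples
#' bonus_payment(100)    # 0.50
#' bonus_payment(10000)  # capped at 3.00
#' @export
bonus_payment <- function(total_rewards, config = game_config()) {
  validate_game_config(config)
  check_scalar_number(total_rewards, "total_rewards", min = 0)
  min(config$bonus_cap, total_rewards * config$reward_value)
}
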