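#' Game configuration
#'
#' Bundles every parameter of the single-player resource-harvesting game.
#' The defaults reproduce the study conditions: a pool of 60 points (also the
#' cap), at most 70 rounds, proportional Gaussian replenishment with mean 15%
#' and standard deviation 3% of the post-harvest remainder (truncated at the
#' cap and clamped below at zero), a reward value of $0.005 per harvested
#' point with the bonus capped at $3.00, and a waiting-time penalty of 6
#' seconds for every round between the round of depletion and round 50.
#'
#' @param initial_resource Starting pool size in resource points.
#' @param max_resource Cap on the pool; replenishment is truncated here.
#' @param max_rounds Maximum number of harvesting rounds.
#' @param replenish_mean Mean of the Gaussian replenishment fraction.
#' @param replenish_sd Standard deviation of the replenishment fraction.
#' @param reward_value Dollar value of one harvested point.
#' @param bonus_cap Maximum bonus payment in dollars.
#' @param penalty_cutoff_round Round before which early depletion accrues a
#'   waiting-time penalty.
#' @param penalty_per_round Seconds of waiting per round short of the cutoff.
#' @param show_rounds_remaining If `TRUE`, policies that accept a second
#'   argument are told how many rounds remain (the known-termination variant
#'   of the game).
#' @param integer_resource If `TRUE` (the default) the pool and all harvests
#'   are integers and replenishment is rounded to the nearest integer, ties
#'   to even. `FALSE` gives a continuous-state variant for sensitivity
#'   analysis.
#' @param rng_seed Optional integer seed used by [play_game()] when no
#'   explicit seed is passed.
#'
#' @return An object of class `game_config`.
#' @examples
#' cfg <- game_config()
#' cfg
#' @export
game_config <- function(initial_resource = 60,
                        max_resource = 60,
                        max_rounds = 70,
                        replenish_mean = 0.15,
                        replenish_sd = 0.03,
                        reward_value = 0.005,
                        bonus_cap = 3.00,
                        penalty_cutoff_round = 50,
                        penalty_per_round = 6,
                        show_rounds_remaining = FALSE,
                        integer_resource = TRUE,
                        rng_seed = NULL) {
  cfg <- structure(
    list(initial_resource = initial_resource,
         max_resource = max_resource,
         max_rounds = max_rounds,
         replenish_mean = replenish_mean,
         replenish_sd = replenish_sd,
         reward_value = reward_value,
         bonus_cap = bonus_cap,
         penalty_cutoff_round = penalty_cutoff_round,
         penalty_per_round = penalty_per_round,
         show_rounds_remaining = isTRUE(show_rounds_remaining),
         integer_resource = isTRUE(integer_resource),
         rng_seed = rng_seed),
    class = "game_config")
  validate_game_config(cfg)
  cfg
}

#' @rdname game_config
#' @param config A `game_config` object to validate.
#' @export
validate_game_config <- function(config) {
  if (!inherits(config, "game_config")) {
    stop_validation("'config' must be a game_config object")
  }
  check_scalar_number(config$initial_resource, "initial_resource", min = 1e-9)
  check_scalar_number(config$max_resource, "max_resource", min = 1e-9)
  if (config$initial_resource > config$max_resource) {
    stop_validation("'initial_resource' must not exceed 'max_resource'")
  }
  check_scalar_number(config$max_rounds, "max_rounds", min = 1, integer = TRUE)
  check_scalar_number(config$replenish_mean, "replenish_mean", min = 1e-12)
  check_scalar_number(config$replenish_sd, "replenish_sd", min = 0)
  check_scalar_number(config$reward_value, "reward_value", min = 0)
  check_scalar_number(config$bonus_cap, "bonus_cap", min = 0)
  check_scalar_number(config$penalty_cutoff_round, "penalty_cutoff_round",
                      min = 0, integer = TRUE)
  check_scalar_number(config$penalty_per_round, "penalty_per_round", min = 0)
  if (config$integer_resource &&
      (config$initial_resource != round(config$initial_resource) ||
       config$max_resource != round(config$max_resource))) {
    stop_validation("integer_resource = TRUE requires integer pool sizes")
  }
  check_scalar_number(config$rng_seed, "rng_seed", integer = TRUE,
                      allow_null = TRUE)
  invisible(config)
}

#' @export
print.game_config <- function(x, ...) {
  cat("Resource-harvesting game configuration\n")
  cat(sprintf("  pool: %g points (cap %g), up to %d rounds%s\n",
              x$initial_resource, x$max_resource, x$max_rounds,
              if (x$show_rounds_remaining) " (rounds remaining shown)" else ""))
  cat(sprintf("  replenishment: Gaussian fraction, mean %.3f, sd %.3f%s\n",
              x$replenish_mean, x$replenish_sd,
              if (x$integer_resource) ", integer states" else ", continuous states"))
  cat(sprintf("  payment: $%.3f per point, bonus cap $%.2f\n",
              x$reward_value, x$bonus_cap))
  cat(sprintf("  penalty: %g s per round short of round %d\n",
              x$penalty_per_round, x$penalty_cutoff_round))
  invisible(x)
}
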