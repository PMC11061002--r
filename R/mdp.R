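#' Dynamic-programming solver configuration
#'
#' Controls how the game is framed and solved as a Markov decision process.
#' The primary mode is `average_reward` (relative value iteration): players
#' were not told the horizon, and the stationary harvest-to-a-target policy
#' is the natural average-reward solution. `discounted` value iteration and
#' `finite_horizon` backward induction (the known-termination variant) are
#' provided for agent modelling.
#'
#' @param mode One of `"average_reward"`, `"discounted"`, `"finite_horizon"`.
#' @param discount_gamma Discount factor in (0, 1], discounted mode only.
#' @param horizon Number of rounds, finite-horizon mode only.
#' @param tolerance Convergence bound on the value-iteration step.
#' @param max_iterations Iteration cap before a convergence error is raised.
#' @param quadrature_points Number of nodes used to discretise the Gaussian
#'   replenishment fraction (default 41).
#' @param quadrature_span Half-width of the quadrature grid in standard
#'   deviations (default 4); weights are renormalised over the span.
#' @return An object of class `solver_config`.
#' @export
solver_config <- function(mode = c("average_reward", "discounted",
                                   "finite_horizon"),
                          discount_gamma = 0.99,
                          horizon = 70,
                          tolerance = 1e-9,
                          max_iterations = 100000,
                          quadrature_points = 41,
                          quadrature_span = 4) {
  mode <- match.arg(mode)
  check_scalar_number(discount_gamma, "discount_gamma", min = 1e-9, max = 1)
  check_scalar_number(horizon, "horizon", min = 1, integer = TRUE)
  check_scalar_number(tolerance, "tolerance", min = 1e-15)
  check_scalar_number(max_iterations, "max_iterations", min = 1,
                      integer = TRUE)
  check_scalar_number(quadrature_points, "quadrature_points", min = 11,
                      integer = TRUE)
  check_scalar_number(quadrature_span, "quadrature_span", min = 0.5)
  structure(list(mode = mode, discount_gamma = discount_gamma,
                 horizon = horizon, tolerance = tolerance,
                 max_iterations = max_iterations,
                 quadrature_points = quadrature_points,
                 quadrature_span = quadrature_span),
            class = "solver_config")
}

#' Build the transition model of the game
#'
#' Discretises the clamped Gaussian replenishment fraction at
#' `quadrature_points` equally spaced nodes over `+/- quadrature_span`
#' standard deviations (Gaussian weights renormalised over the span) and
#' evaluates the round update of [step_resource()] at each node. Because the
#' next state depends on the pre-harvest state and action only through the
#' post-harvest remainder, the kernel is stored as one probability row per
#' remainder value; `transition_row()` expands it per (state, action).
#'
#' @param config An integer-mode [game_config()].
#' @param solver A [solver_config()].
#' @return An object of class `transition_model` with the
#'   `(max_resource + 1) x (max_resource + 1)` matrix `Q` (row `m + 1` is the
#'   distribution of the next state given remainder `m`), the quadrature
#'   `nodes` and `weights`, and a `live` logical marking states from which
#'   the pool can still grow (states below the growth threshold are
#'   effectively dead: replenishment rounds to zero there).
#' @examples
#' tm <- build_transition_model(game_config(), solver_config())
#' range(rowSums(tm$Q))  # rows are probability vectors
#' @export
build_transition_model <- function(config = game_config(),
                                   solver = solver_config()) {
  validate_game_config(config)
  if (!config$integer_resource) {
    stop_domain("the tabular MDP requires integer_resource = TRUE")
  }
  S <- as.integer(config$max_resource)
  if (config$replenish_sd == 0) {
    nodes <- config$replenish_mean
    weights <- 1
  } else {
    z <- seq(-solver$quadrature_span, solver$quadrature_span,
             length.out = solver$quadrature_points)
    weights <- stats::dnorm(z)
    weights <- weights / sum(weights)
    nodes <- pmax(0, config$replenish_mean + config$replenish_sd * z)
  }
  Q <- matrix(0, S + 1L, S + 1L)
  for (m in 0:S) {
    nxt <- pmin(S, m + round(m * nodes))
    for (j in seq_along(nodes)) {
      Q[m + 1L, nxt[j] + 1L] <- Q[m + 1L, nxt[j] + 1L] + weights[j]
    }
  }
  # A state is "live" when some replenishment draw can move the pool upward
  # from its remainder; below that the pool can never recover and the
  # long-run harvest rate from the state is zero.
  can_grow <- vapply(0:S, function(m) {
    m < S && any(Q[m + 1L, (m + 2L):(S + 1L)] > 0)
  }, logical(1))
  live <- if (any(can_grow)) (0:S) >= min(which(can_grow) - 1L) else rep(TRUE, S + 1L)
  structure(list(Q = Q, states = 0:S, nodes = nodes, weights = weights,
                 live = live, config = config),
            class = "transition_model")
}

#' @rdname build_transition_model
#' @param model A `transition_model`.
#' @param state,action Pre-harvest state and harvest action.
#' @return `transition_row()`: the probability vector over next states.
#' @export
transition_row <- function(model, state, action) {
  S <- max(model$states)
  check_scalar_number(state, "state", min = 0, max = S, integer = TRUE)
  check_scalar_number(action, "action", min = 0, max = state, integer = TRUE)
  model$Q[state - action + 1L, ]
}

# One synchronous Bellman sweep. The value of harvesting state s down to
# remainder m is (s - m) + beta * E[v(next) | m], so with
# cand(m) = beta * E[v | m] - m the update is v'(s) = s + max_{m <= s} cand(m),
# a running maximum over remainders. When `policy = TRUE` the greedy harvest
# is also returned, breaking ties (within tie_tol) toward the smaller
# harvest, i.e. the larger remainder.
bellman_sweep <- function(v, Q, beta, policy = FALSE, tie_tol = 1e-9) {
  S <- length(v) - 1L
  W <- beta * drop(Q %*% v)
  cand <- W - (0:S)
  M <- cummax(cand)
  out <- list(values = (0:S) + M)
  if (policy) {
    # Largest remainder whose candidate value ties the running maximum.
    ok <- cand >= M - tie_tol
    m_star <- cummax(ifelse(ok, 0:S, -1L))
    out$harvest <- as.integer((0:S) - m_star)
  }
  out
}

#' Solve the game MDP by dynamic programming
#'
#' Average-reward mode runs relative value iteration: synchronous Bellman
#' sweeps, renormalised at the top state, stopped when the span of the value
#' increments over the live states falls below `tolerance` (the handful of
#' depleted or unrecoverable low states have zero long-run gain, so their
#' increments converge to zero rather than to the gain; see the methods
#' vignette). Discounted mode runs standard value iteration to a sup-norm
#' increment below `tolerance`; finite-horizon mode runs backward induction
#' over `horizon` rounds. The greedy policy breaks ties toward the smaller
#' harvest.
#'
#' @param model A [build_transition_model()] result.
#' @param solver A [solver_config()].
#' @return An object of class `policy_table`: a data frame with columns
#'   `state`, `harvest`, `value`, plus attributes `threshold` (largest state
#'   prescribed a zero harvest), `target` (common post-harvest level above
#'   the threshold, `NA` if the policy is not of threshold form),
#'   `is_threshold_form`, `gain` (average-reward mode), `iterations`,
#'   `residual` and, for finite-horizon mode, the full `harvest_by_round`
#'   matrix (states x rounds).
#' @examples
#' \donttest{
#' pol <- solve_mdp(build_transition_model(), solver_config("average_reward"))
#' attr(pol, "threshold")  # 51
#' }
#' @export
solve_mdp <- function(model, solver = solver_config()) {
  if (!inherits(model, "transition_model")) {
    stop_validation("'model' must be a transition_model")
  }
  Q <- model$Q
  S <- nrow(Q) - 1L
  tol <- solver$tolerance
  if (solver$mode == "finite_horizon") {
    H <- solver$horizon
    v <- numeric(S + 1L)
    harvest_by_round <- matrix(NA_integer_, S + 1L, H)
    for (t in H:1) {
      sw <- bellman_sweep(v, Q, beta = if (t == H) 0 else 1, policy = TRUE)
      harvest_by_round[, t] <- sw$harvest
      v <- sw$values
    }
    return(new_policy_table(harvest_by_round[, 1L], v, model, solver,
                            gain = NA_real_, iterations = H, residual = 0,
                            harvest_by_round = harvest_by_round))
  }

  beta <- if (solver$mode == "discounted") solver$discount_gamma else 1
  live <- model$live
  v <- numeric(S + 1L)
  gain <- 0
  for (it in seq_len(solver$max_iterations)) {
    sw <- bellman_sweep(v, Q, beta)
    delta <- sw$values - v
    if (solver$mode == "discounted") {
      resid <- max(abs(delta))
      v <- sw$values
      if (resid < tol) {
        harvest <- bellman_sweep(v, Q, beta, policy = TRUE)$harvest
        return(new_policy_table(harvest, v, model, solver,
                                gain = NA_real_, iterations = it,
                                residual = resid))
      }
    } else {
      d_live <- delta[live]
      gain <- (max(d_live) + min(d_live)) / 2
      span <- max(d_live) - min(d_live)
      v <- sw$values - sw$values[S + 1L]
      if (span < tol) {
        harvest <- bellman_sweep(v, Q, beta, policy = TRUE)$harvest
        return(new_policy_table(harvest, v, model, solver, gain = gain,
                                iterations = it, residual = span))
      }
    }
  }
  stop_domain(sprintf(
    "dynamic programming failed to converge in %d iterations (residual %.3g)",
    solver$max_iterations,
    if (solver$mode == "discounted") resid else span),
    class = "harvestgame_convergence_error")
}

new_policy_table <- function(harvest, values, model, solver, gain,
                             iterations, residual, harvest_by_round = NULL) {
  S <- length(harvest) - 1L
  states <- 0:S
  zero_states <- states[harvest == 0]
  threshold <- if (length(zero_states)) max(zero_states) else NA_integer_
  above <- states > threshold
  targets <- states[above] - harvest[above]
  target <- if (any(above) && length(unique(targets)) == 1L) {
    targets[1L]
  } else if (!any(above)) {
    threshold
  } else NA_integer_
  is_threshold_form <- !is.na(target) &&
    all(harvest == pmax(0, states - target))
  tab <- data.frame(state = states, harvest = as.integer(harvest),
                    value = values)
  structure(tab, class = c("policy_table", "data.frame"),
            threshold = threshold, target = target,
            is_threshold_form = is_threshold_form, gain = gain,
            mode = solver$mode, iterations = iterations, residual = residual,
            harvest_by_round = harvest_by_round,
            game_config = model$config)
}

#' @export
print.policy_table <- function(x, ...) {
  cat(sprintf("Dynamic-programming policy (%s mode, %d iterations)\n",
              attr(x, "mode"), attr(x, "iterations")))
  if (isTRUE(attr(x, "is_threshold_form"))) {
    cat(sprintf(
      "  threshold form: harvest 0 at states <= %d, harvest down to %d above\n",
      attr(x, "threshold"), attr(x, "target")))
  } else {
    cat(sprintf(
      "  not of pure threshold form (largest zero-harvest state: %s)\n",
      format(attr(x, "threshold"))))
  }
  if (!is.na(attr(x, "gain"))) {
    cat(sprintf("  long-run average harvest: %.4f points/round\n",
                attr(x, "gain")))
  }
  invisible(x)
}

#' Monte-Carlo policy evaluation
#'
#' Estimates the mean total reward (or discounted return) of a policy by
#' simulating `n_games` seeded games with the game engine's round update.
#' Games are simulated as a vectorised ensemble: one replenishment fraction
#' is drawn per game per round, so the per-game reward distribution is
#' identical to [play_game()]'s.
#'
#' @param policy Anything accepted by [as_harvest_policy()].
#' @param config A [game_config()].
#' @param n_games Number of simulated games.
#' @param seed Optional RNG seed.
#' @param discount Optional discount factor; when supplied the per-game
#'   return is the discounted sum of harvests, for comparison with the
#'   discounted-mode value function.
#' @return A list with `mean`, `se`, `ci` (95% normal interval), `n_games`
#'   and the per-game `totals`.
#' @examples
#' policy_value_mc(threshold_policy(51), n_games = 200, seed = 1)$mean
#' @export
policy_value_mc <- function(policy, config = game_config(), n_games = 1000,
                            seed = NULL, discount = NULL) {
  validate_game_config(config)
  check_scalar_number(n_games, "n_games", min = 1, integer = TRUE)
  if (!is.null(discount)) {
    check_scalar_number(discount, "discount", min = 1e-9, max = 1)
  }
  pol <- as_harvest_policy(policy)
  maybe_with_seed(seed, {
    n <- n_games
    S <- config$max_resource
    states <- rep(config$initial_resource, n)
    active <- rep(TRUE, n)
    totals <- numeric(n)
    wgt <- 1
    for (r in seq_len(config$max_rounds)) {
      h <- pol(states, config$max_rounds - r + 1L)
      h <- pmin(pmax(h, 0), states)
      h[!active] <- 0
      f <- pmax(0, stats::rnorm(n, config$replenish_mean,
                                config$replenish_sd))
      rem <- states - h
      repl <- if (config$integer_resource) round(rem * f) else rem * f
      nxt <- pmin(S, rem + repl)
      nxt[rem == 0] <- 0
      totals <- totals + wgt * h
      states <- nxt
      active <- active & states > 0
      if (!is.null(discount)) wgt <- wgt * discount
      if (!any(active)) break
    }
    m <- mean(totals)
    se <- stats::sd(totals) / sqrt(n)
    list(mean = m, se = se, ci = m + c(-1, 1) * 1.96 * se,
         n_games = n, totals = totals)
  })
}
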