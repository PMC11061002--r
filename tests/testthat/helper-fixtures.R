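# Shared fixtures. The default MDP solve is cached so that the several test
# files that need the solved policy do not each pay for relative value
# iteration.

solved_default_policy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- solve_mdp(build_transition_model(game_config(),
                                                 solver_config()),
                          solver_config(mode = "average_reward"))
    }
    cache
  }
})

# Independent brute-force pinball-loss minimiser over a coefficient grid,
# used as the oracle for small quantile-regression fixtures: an exhaustive
# coarse sweep followed by a fine sweep around the coarse optimum, with no
# reuse of the package's solver.
grid_search_rq_once <- function(y, x, tau, av, bv) {
  grid <- expand.grid(a = av, b = bv)
  U <- matrix(y, nrow(grid), length(y), byrow = TRUE) -
    grid$a - outer(grid$b, x)
  loss <- rowSums(U * (tau - (U < 0)))
  i <- which.min(loss)
  list(coef = c(grid$a[i], grid$b[i]), loss = loss[i])
}

grid_search_rq <- function(y, x, tau, a_range, b_range, step) {
  coarse <- grid_search_rq_once(
    y, x, tau,
    seq(a_range[1], a_range[2], by = 20 * step),
    seq(b_range[1], b_range[2], by = 20 * step))
  grid_search_rq_once(
    y, x, tau,
    seq(coarse$coef[1] - 50 * step, coarse$coef[1] + 50 * step, by = step),
    seq(coarse$coef[2] - 50 * step, coarse$coef[2] + 50 * step, by = step))
}

# Random feasible policy for property tests: harvests a random share of the
# current pool.
random_share_policy <- function(share) {
  function(state) floor(state * share)
}
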