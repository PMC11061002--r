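#' Replenishment-experience control analysis
#'
#' Tests whether outcome differences merely reflect luck in the replenishment
#' draws participants happened to experience. For each participant the mean
#' drawn replenishment fraction over the first `min(window, rounds_lasted)`
#' rounds is computed for each window, and Spearman-correlated with rounds
#' lasted and with total rewards. In a cohort whose behaviour is driven by
#' traits rather than by the draws, all of these correlations should be
#' negligible.
#'
#' @param trajectories Long event table with `participant_id`, `round` and
#'   `fraction_drawn` (as produced by [simulate_cohort()]).
#' @param records Participant table with `participant_id`, `rounds_lasted`
#'   and `total_rewards`.
#' @param windows Round windows over which to average the drawn fractions.
#' @return Data frame with one row per window x outcome: `window`,
#'   `outcome`, `rho`, `df`, `p_value`, `n` and `note` (`"undefined"` when
#'   the mean fraction is constant across participants, as in a
#'   deterministic-replenishment game).
#' @export
mean_replenishment_control <- function(trajectories, records,
                                       windows = c(1, 2, 3, 5, 10, 20, 50, 70)) {
  need <- c("participant_id", "round", "fraction_drawn")
  if (!all(need %in% names(trajectories))) {
    stop_validation("'trajectories' must have participant_id, round, fraction_drawn")
  }
  if (!all(c("participant_id", "rounds_lasted", "total_rewards") %in%
           names(records))) {
    stop_validation("'records' must have participant_id, rounds_lasted, total_rewards")
  }
  empty <- setdiff(records$participant_id, trajectories$participant_id)
  if (length(empty) > 0) {
    warning(sprintf("excluding %d participant(s) with empty trajectories",
                    length(empty)))
    records <- records[!records$participant_id %in% empty, ]
  }
  split_fr <- split(trajectories$fraction_drawn[order(trajectories$participant_id,
                                                      trajectories$round)],
                    trajectories$participant_id[order(trajectories$participant_id,
                                                      trajectories$round)])
  split_fr <- split_fr[as.character(records$participant_id)]
  out <- do.call(rbind, lapply(windows, function(wn) {
    mf <- vapply(split_fr, function(f) mean(f[seq_len(min(wn, length(f)))]),
                 numeric(1))
    do.call(rbind, lapply(c("rounds_lasted", "total_rewards"), function(oc) {
      y <- records[[oc]]
      if (stats::sd(mf) == 0 || stats::sd(y) == 0) {
        data.frame(window = wn, outcome = oc, rho = NA_real_,
                   df = length(mf) - 2L, p_value = NA_real_, n = length(mf),
                   note = "undefined")
      } else {
        ct <- spearman_cor(mf, y)
        data.frame(window = wn, outcome = oc, rho = unname(ct$estimate),
                   df = unname(ct$parameter), p_value = ct$p.value,
                   n = length(mf), note = "")
      }
    }))
  }))
  rownames(out) <- NULL
  out
}
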