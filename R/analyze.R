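#' Run the full individual-differences analysis on a cohort
#'
#' Applies the non-parametric pipeline of the study to an analysis-ready
#' cohort: Spearman correlations between every trait and both resource
#' outcomes (rounds lasted, total rewards); partial Spearman correlations
#' controlling for the delay-discounting rate; the Breusch-Pagan test of
#' whether total rewards are heteroskedastic in rounds lasted; quantile
#' regression profiles (0.05-0.95 grid, z-scored traits) per trait/outcome
#' pair; and, when trajectories are available, the replenishment-experience
#' control.
#'
#' @param cohort A [simulate_cohort()] result, or a list with `records` (and
#'   optionally `trajectories`) data frames with the same columns.
#' @param analyses Subset of `c("spearman", "partial", "breusch_pagan",
#'   "quantile", "replenishment")`.
#' @param covariate Trait controlled for in the partial correlations
#'   (default `"log_k"`).
#' @param taus Quantile grid for the regression profiles.
#' @param n_boot Bootstrap resamples per quantile profile.
#' @param seed Optional master seed (used by the bootstrap).
#' @return An object of class `cohort_analysis`: a list of tidy data frames
#'   `correlations`, `heteroskedasticity`, `quantile`, `replenishment`
#'   (those requested), plus the trait and outcome names used.
#' @examples
#' sim <- simulate_cohort(cohort_config(n_participants = 60, rng_seed = 1))
#' an <- analyze_cohort(sim, analyses = c("spearman", "breusch_pagan"))
#' an$correlations
#' @export
analyze_cohort <- function(cohort,
                           analyses = c("spearman", "partial",
                                        "breusch_pagan", "quantile",
                                        "replenishment"),
                           covariate = "log_k",
                           taus = seq(0.05, 0.95, by = 0.05),
                           n_boot = 200, seed = NULL) {
  analyses <- match.arg(analyses, several.ok = TRUE)
  records <- if (is.data.frame(cohort)) cohort else cohort$records
  trajectories <- if (is.data.frame(cohort)) NULL else cohort$trajectories
  outcomes <- c("rounds_lasted", "total_rewards")
  if (!all(outcomes %in% names(records))) {
    stop_validation("records must contain rounds_lasted and total_rewards")
  }
  reserved <- c("participant_id", "target", outcomes, "exhausted",
                "penalty_seconds", "bonus_usd")
  trait_names <- setdiff(names(records), reserved)
  out <- list(traits = trait_names, outcomes = outcomes)
  boot_seed <- if (!is.null(seed)) derive_seeds(seed, 1L) else NULL

  if (any(c("spearman", "partial") %in% analyses)) {
    rows <- list()
    for (tr in trait_names) {
      for (oc in outcomes) {
        if ("spearman" %in% analyses) {
          ct <- spearman_cor(records[[tr]], records[[oc]])
          rows[[length(rows) + 1L]] <- data.frame(
            trait = tr, outcome = oc, rho = unname(ct$estimate),
            df = unname(ct$parameter), p_value = ct$p.value,
            partial_covariate = NA_character_)
        }
        if ("partial" %in% analyses && tr != covariate &&
            covariate %in% trait_names) {
          ct <- partial_spearman(records[[tr]], records[[oc]],
                                 records[[covariate]])
          rows[[length(rows) + 1L]] <- data.frame(
            trait = tr, outcome = oc, rho = unname(ct$estimate),
            df = unname(ct$parameter), p_value = ct$p.value,
            partial_covariate = covariate)
        }
      }
    }
    out$correlations <- do.call(rbind, rows)
  }

  if ("breusch_pagan" %in% analyses) {
    bp <- breusch_pagan(records$total_rewards, records$rounds_lasted)
    out$heteroskedasticity <- data.frame(
      outcome = "total_rewards", predictor = "rounds_lasted",
      statistic = unname(bp$statistic), df = unname(bp$parameter),
      p_value = bp$p.value)
  }

  if ("quantile" %in% analyses) {
    rows <- list()
    for (tr in trait_names) {
      for (oc in outcomes) {
        prof <- quantile_profile(records[[oc]],
                                 stats::setNames(records[, tr, drop = FALSE],
                                                 tr),
                                 taus = taus, n_boot = n_boot,
                                 seed = boot_seed)
        prof <- prof[prof$term != "(Intercept)", ]
        rows[[length(rows) + 1L]] <- data.frame(
          trait = tr, outcome = oc, tau = prof$tau, coef = prof$estimate,
          ci_low = prof$ci_low, ci_high = prof$ci_high, n = prof$n)
      }
    }
    out$quantile <- do.call(rbind, rows)
    rownames(out$quantile) <- NULL
  }

  if ("replenishment" %in% analyses && !is.null(trajectories)) {
    out$replenishment <- mean_replenishment_control(trajectories, records)
  }
  structure(out, class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("Cohort analysis\n")
  if (!is.null(x$correlations)) {
    plain <- x$correlations[is.na(x$correlations$partial_covariate), ]
    cat(sprintf("  %d Spearman correlation(s); e.g.\n", nrow(plain)))
    utils::head(plain, 4L) |> print()
  }
  if (!is.null(x$heteroskedasticity)) {
    cat(sprintf("  Breusch-Pagan (rewards ~ rounds): %.2f, p = %.3g\n",
                x$heteroskedasticity$statistic,
                x$heteroskedasticity$p_value))
  }
  if (!is.null(x$quantile)) {
    cat(sprintf("  quantile profiles for %d trait-outcome pair(s)\n",
                nrow(unique(x$quantile[, c("trait", "outcome")]))))
  }
  invisible(x)
}
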