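# Five-trial adjusting-delay (ED50) elicitation.
#
# The instrument asks five forced choices between $500 now and $1,000 after a
# delay, and titrates the delay over a fixed geometric ladder until it
# brackets the delay at which the delayed reward has lost half its value.
# The hyperbolic discount rate is then k = 1 / ED50 (per day), reported as
# the natural log of k.

#' The 31-step delay ladder of the ED50 elicitation
#'
#' Thirty-one delays spaced geometrically from 1 hour (1/24 day) to 25 years
#' (9125 days). A copy is shipped as a plain-text fixture at
#' `system.file("extdata", "ed50_ladder.csv", package = "harvestgame")` so
#' that staircase traces are reproducible by inspection.
#'
#' @return Numeric vector of 31 delays in days.
#' @examples
#' range(ed50_ladder())  # 1/24 to 9125
#' @export
ed50_ladder <- function() {
  d_min <- 1 / 24
  d_max <- 25 * 365
  exp(seq(log(d_min), log(d_max), length.out = 31L))
}

#' Feasible range of log k under the ladder bounds
#'
#' `k = 1/ED50` with ED50 between 1 hour and 25 years confines the natural
#' log discount rate to `[ln(1/9125), ln(24)]`, roughly `[-9.12, 3.18]`.
#'
#' @return Length-2 numeric vector `c(min, max)`.
#' @export
log_k_bounds <- function() {
  c(log(1 / (25 * 365)), log(24))
}

#' Run the five-trial ED50 staircase
#'
#' Adaptive bisection over the 31-delay ladder: the first probe sits at the
#' ladder midpoint (index 16); each "now" answer (impulsive) moves the next
#' probe to a shorter delay and each "delayed" answer to a longer one, with
#' step sizes 8, 4, 2, 1, 1 ladder positions and the index clamped to the
#' ladder. The delay indexed after the fifth answer is the indifference
#' delay ED50; the hyperbolic rate is `k = 1/ED50` (1/days) and `log_k` its
#' natural log.
#'
#' @param answers Length-5 character vector of `"now"`/`"delayed"`, or a
#'   logical vector where `TRUE` means the delayed reward was chosen.
#' @return An object of class `ed50_profile`: `ed50_days`, `k`, `log_k`,
#'   final ladder `index`, and the per-trial `trace` data frame.
#' @examples
#' run_ed50_elicitation(rep("now", 5))$log_k      # ln(24)
#' run_ed50_elicitation(rep("delayed", 5))$log_k  # ln(1/9125)
#' @export
run_ed50_elicitation <- function(answers) {
  if (is.character(answers)) {
    if (!all(answers %in% c("now", "delayed"))) {
      stop_validation("answers must be \"now\" or \"delayed\"")
    }
    delayed <- answers == "delayed"
  } else if (is.logical(answers)) {
    delayed <- answers
  } else {
    stop_validation("answers must be a character or logical vector")
  }
  if (length(delayed) != 5L || anyNA(delayed)) {
    stop_validation("the elicitation takes exactly 5 complete answers")
  }
  ladder <- ed50_ladder()
  steps <- c(8L, 4L, 2L, 1L, 1L)
  idx <- 16L
  trace <- data.frame(trial = 1:5, probe_index = NA_integer_,
                      probe_delay_days = NA_real_,
                      choice = ifelse(delayed, "delayed", "now"))
  for (i in 1:5) {
    trace$probe_index[i] <- idx
    trace$probe_delay_days[i] <- ladder[idx]
    idx <- idx + if (delayed[i]) steps[i] else -steps[i]
    idx <- min(31L, max(1L, idx))
  }
  ed50 <- ladder[idx]
  structure(list(ed50_days = ed50, k = 1 / ed50, log_k = log(1 / ed50),
                 index = idx, trace = trace),
            class = "ed50_profile")
}

#' @export
print.ed50_profile <- function(x, ...) {
  cat(sprintf(
    "ED50 profile: indifference delay %.3f days (ladder step %d), log k = %.3f\n",
    x$ed50_days, x$index, x$log_k))
  invisible(x)
}
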