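# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' If `seed` is `NULL` the expression is evaluated against the current RNG
#' stream; otherwise the stream is seeded, the expression evaluated, and the
#' caller's RNG state restored afterwards.
#' @noRd
maybe_with_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(seed, expr)
}

#' Derive independent per-stage seeds from one master seed
#'
#' Each pipeline stage (policy solve, trait sampling, game play, bootstrap)
#' consumes its own stream so that, e.g., changing the cohort size does not
#' perturb the bootstrap draws. Seeds are kept below `.Machine$integer.max`.
#' @noRd
derive_seeds <- function(master_seed, n) {
  withr::with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

# Scalar validators: all raise classed errors so callers/tests can match on
# the condition class rather than message text.
stop_domain <- function(msg, class = "harvestgame_domain_error") {
  stop(errorCondition(msg, class = c(class, "harvestgame_error")))
}

stop_validation <- function(msg, class = "harvestgame_validation_error") {
  stop(errorCondition(msg, class = c(class, "harvestgame_error")))
}

check_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                integer = FALSE, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(NULL))
    stop_validation(sprintf("'%s' must be supplied", name))
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_validation(sprintf("'%s' must be a single finite number", name))
  }
  if (integer && x != round(x)) {
    stop_validation(sprintf("'%s' must be a whole number", name))
  }
  if (x < min || x > max) {
    stop_validation(sprintf("'%s' must be in [%s, %s]", name,
                            format(min), format(max)))
  }
  invisible(x)
}
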