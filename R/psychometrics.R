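#' Instrument specification
#'
#' Score-level description of the self-report instruments used alongside the
#' game: the 10-item AUDIT (items 0-4, total 0-40), the 12-item GHQ-12
#' (Likert 0-3 scoring, total 0-36), the 5-item WHO-5 (raw 0-25), and a
#' 9-item financial-literacy short form whose per-item maximum is
#' configurable (the published total scale for this short form is not
#' standardised, so the default item maximum of 7 gives a 0-63 total range
#' wide enough to accommodate reported means in the mid-30s). Item wordings
#' are not reproduced; only scoring rules are represented.
#'
#' @param name One of `"AUDIT"`, `"GHQ12"`, `"WHO5"`, `"FINLIT"`.
#' @param item_min,item_max Optional per-item range overrides (mainly for
#'   `FINLIT`).
#' @return An object of class `instrument_spec` with fields `name`,
#'   `n_items`, `item_min`, `item_max`, `total_min`, `total_max`.
#' @examples
#' instrument_spec("AUDIT")
#' @export
instrument_spec <- function(name = c("AUDIT", "GHQ12", "WHO5", "FINLIT"),
                            item_min = NULL, item_max = NULL) {
  name <- match.arg(name)
  base <- switch(name,
    AUDIT  = list(n_items = 10L, item_min = 0, item_max = 4),
    GHQ12  = list(n_items = 12L, item_min = 0, item_max = 3),
    WHO5   = list(n_items = 5L,  item_min = 0, item_max = 5),
    FINLIT = list(n_items = 9L,  item_min = 0, item_max = 7))
  if (!is.null(item_min)) base$item_min <- check_scalar_number(item_min, "item_min")
  if (!is.null(item_max)) base$item_max <- check_scalar_number(item_max, "item_max")
  if (base$item_max <= base$item_min) {
    stop_validation("'item_max' must exceed 'item_min'")
  }
  structure(list(name = name, n_items = base$n_items,
                 item_min = base$item_min, item_max = base$item_max,
                 total_min = base$n_items * base$item_min,
                 total_max = base$n_items * base$item_max),
            class = "instrument_spec")
}

#' @export
print.instrument_spec <- function(x, ...) {
  cat(sprintf("%s: %d items scored %g-%g (total %g-%g)\n", x$name,
              x$n_items, x$item_min, x$item_max, x$total_min, x$total_max))
  invisible(x)
}

#' Score an instrument by summation
#'
#' Totals complete, in-range item responses. A vector scores one
#' participant; a matrix (participants x items) scores each row.
#'
#' @param responses Integer vector of length `n_items`, or a matrix with
#'   `n_items` columns.
#' @param spec An [instrument_spec()].
#' @return Total score(s), guaranteed to lie in the instrument's total range.
#' @examples
#' score_instrument(rep(1, 12), instrument_spec("GHQ12"))  # 12
#' @export
score_instrument <- function(responses, spec) {
  if (!inherits(spec, "instrument_spec")) {
    stop_validation("'spec' must be an instrument_spec")
  }
  m <- if (is.matrix(responses)) responses else matrix(responses, nrow = 1L)
  if (ncol(m) != spec$n_items) {
    stop_validation(sprintf("%s expects %d items, got %d", spec$name,
                            spec$n_items, ncol(m)))
  }
  bad <- which(is.na(m) | m < spec$item_min | m > spec$item_max,
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_validation(sprintf(
      "%s item %d is missing or outside [%g, %g] (participant row %d)",
      spec$name, bad[1L, "col"], spec$item_min, spec$item_max,
      bad[1L, "row"]))
  }
  totals <- rowSums(m)
  if (!is.matrix(responses)) totals <- unname(totals[1L])
  totals
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' `alpha = k/(k - 1) * (1 - sum(item variances) / variance of totals)`,
#' with sample (n - 1) variances.
#'
#' @param item_matrix Numeric matrix, participants in rows, items in columns.
#' @return The alpha coefficient.
#' @examples
#' m <- cbind(c(1, 2, 3), c(1, 2, 4))
#' cronbach_alpha(m)  # 18/19
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (!is.numeric(m) || ncol(m) < 2L || nrow(m) < 2L) {
    stop_validation("need a numeric matrix with >= 2 items and >= 2 participants")
  }
  if (anyNA(m)) stop_validation("item matrix contains missing values")
  k <- ncol(m)
  var_total <- stats::var(rowSums(m))
  if (var_total <= 0) {
    stop_domain("total-score variance is zero; alpha is undefined",
                class = "harvestgame_alpha_undefined")
  }
  item_vars <- apply(m, 2L, stats::var)
  (k / (k - 1)) * (1 - sum(item_vars) / var_total)
}
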