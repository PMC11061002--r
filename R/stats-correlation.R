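#' Spearman rank correlation with a t-approximation p-value
#'
#' The rank correlation is the Pearson correlation of mid-ranks (average
#' ranks for ties); the p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom,
#' which is the practical choice at the cohort sizes used here (exact
#' permutation is infeasible at n = 400).
#'
#' @param x,y Numeric vectors of equal length (n >= 3), not constant.
#' @return An object of class `htest` with `estimate` (rho), `parameter`
#'   (df) and `p.value`.
#' @examples
#' spearman_cor(1:4, c(1, 3, 2, 4))$estimate  # 0.8
#' @export
spearman_cor <- function(x, y) {
  check_cor_input(x, y)
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  n <- length(x)
  build_cor_htest(rho, df = n - 2L,
                  method = "Spearman rank correlation (t approximation)",
                  data_name = paste(deparse1(substitute(x)), "and",
                                    deparse1(substitute(y))))
}

#' Partial Spearman rank correlation
#'
#' Rank-transforms all three vectors, removes the linear effect of the
#' covariate's ranks from the ranks of `x` and `y` by least squares, and
#' correlates the residuals; degrees of freedom are `n - 3`. A constant
#' covariate carries no information, so the function falls back to the plain
#' Spearman correlation with a warning.
#'
#' @param x,y Numeric vectors of equal length (n >= 4).
#' @param z Covariate vector to control for.
#' @return An object of class `htest`.
#' @export
partial_spearman <- function(x, y, z) {
  check_cor_input(x, y, n_min = 4L)
  if (length(z) != length(x)) {
    stop_validation("'z' must have the same length as 'x' and 'y'")
  }
  if (stats::sd(z) == 0) {
    warning("constant covariate: falling back to the plain Spearman correlation")
    out <- spearman_cor(x, y)
    out$method <- paste(out$method, "(degenerate covariate)")
    return(out)
  }
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  ex <- stats::lm.fit(cbind(1, rz), rx)$residuals
  ey <- stats::lm.fit(cbind(1, rz), ry)$residuals
  rho <- stats::cor(ex, ey)
  build_cor_htest(rho, df = length(x) - 3L,
                  method = "partial Spearman rank correlation (one covariate)",
                  data_name = paste(deparse1(substitute(x)), "and",
                                    deparse1(substitute(y)), "given",
                                    deparse1(substitute(z))))
}

check_cor_input <- function(x, y, n_min = 3L) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    stop_validation("'x' and 'y' must be numeric vectors of equal length")
  }
  if (anyNA(x) || anyNA(y)) stop_validation("missing values are not supported")
  if (length(x) < n_min) {
    stop_validation(sprintf("need at least %d observations", n_min))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_domain("correlation is undefined for constant input",
                class = "harvestgame_constant_input")
  }
}

build_cor_htest <- function(rho, df, method, data_name) {
  rho <- max(-1, min(1, rho))
  tstat <- if (abs(rho) >= 1) Inf * sign(rho) else {
    rho * sqrt(df / (1 - rho^2))
  }
  p <- 2 * stats::pt(-abs(tstat), df)
  structure(list(estimate = c(rho = rho), parameter = c(df = df),
                 statistic = c(t = tstat), p.value = p, method = method,
                 data.name = data_name),
            class = "htest")
}
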