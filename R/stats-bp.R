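#' Breusch-Pagan test for heteroskedasticity
#'
#' Lagrange-multiplier form: regress `y` on the predictors by least squares,
#' regress the squared residuals on the same predictors, and take
#' `LM = n * R_aux^2`, referred to a chi-squared distribution with as many
#' degrees of freedom as there are predictors (the studentised/Koenker
#' version of the test).
#'
#' @param y Outcome vector.
#' @param x Predictor vector or matrix (without intercept column).
#' @return An object of class `htest` with `statistic`, `parameter` (df) and
#'   `p.value`.
#' @examples
#' set.seed(1)
#' x <- runif(200)
#' y <- x + rnorm(200, sd = x)  # variance grows with x
#' breusch_pagan(y, x)
#' @export
breusch_pagan <- function(y, x) {
  x <- as.matrix(x)
  if (!is.numeric(y) || !is.numeric(x) || nrow(x) != length(y)) {
    stop_validation("'y' and rows of 'x' must be numeric and conformable")
  }
  if (anyNA(y) || anyNA(x)) stop_validation("missing values are not supported")
  n <- length(y)
  p <- ncol(x)
  if (n <= p + 1L) stop_validation("need n > number of predictors + 1")
  X <- cbind(Intercept = 1, x)
  if (qr(X)$rank < ncol(X)) {
    stop_domain("rank-deficient design matrix",
                class = "harvestgame_rank_deficient")
  }
  u2 <- stats::lm.fit(X, y)$residuals^2
  aux <- stats::lm.fit(X, u2)
  tss <- sum((u2 - mean(u2))^2)
  r2 <- if (tss == 0) 0 else 1 - sum(aux$residuals^2) / tss
  stat <- n * r2
  structure(list(statistic = c(BP = stat), parameter = c(df = p),
                 p.value = stats::pchisq(stat, df = p, lower.tail = FALSE),
                 method = "Breusch-Pagan test (studentised LM form)",
                 data.name = paste(deparse1(substitute(y)), "on",
                                   deparse1(substitute(x)))),
            class = "htest")
}
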