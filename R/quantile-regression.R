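# Linear quantile regression by interior-point minimisation of the pinball
# loss. The primal problem min_b sum(rho_tau(y - X b)) is solved through its
# bounded-variable dual max{ y'a : X'a = (1 - tau) X'1, a in [0,1]^n } with
# a Mehrotra-style predictor-corrector (the Frisch-Newton scheme); the
# regression coefficients are the multipliers of the equality constraint.

#' Pinball (check) loss
#'
#' `rho_tau(u) = u * (tau - 1[u < 0])`; its minimiser over a location model
#' is the tau-th sample quantile.
#'
#' @param u Residual vector.
#' @param tau Quantile level in (0, 1).
#' @return Vector of losses.
#' @export
pinball_loss <- function(u, tau) {
  check_scalar_number(tau, "tau", min = 1e-12, max = 1 - 1e-12)
  u * (tau - (u < 0))
}

# Core interior-point fit. X must include the intercept column.
#
# KKT system for the dual: X'a = (1 - tau) X'1 with 0 <= a <= 1, slack
# s = 1 - a; stationarity y - Xb + z - w = 0 where z >= 0 pairs with the
# lower bound (z_i > 0 forces a_i = 0, at negative residuals) and w >= 0
# with the upper bound (w_i > 0 forces a_i = 1, at positive residuals), so
# the regression residual is w - z; complementarity a.z = s.w = mu -> 0.
rq_fit_ip <- function(X, y, tau, tol = 1e-12, max_iter = 200) {
  n <- nrow(X)
  a <- rep(1 - tau, n)
  s <- 1 - a
  b <- qr.coef(qr(X), y)
  b[is.na(b)] <- 0
  rr <- drop(y - X %*% b)
  eps0 <- max(1e-5, 1e-5 * stats::sd(rr))
  w <- pmax(rr, 0) + eps0
  z <- w - rr
  t_eq <- (1 - tau) * colSums(X)
  scale <- 1 + sum(abs(y)) / n

  solve_dirs <- function(q, u_vec, rho1) {
    AQ <- crossprod(X, q * X)
    diag(AQ) <- diag(AQ) + 1e-12 * max(diag(AQ), 1)
    db <- solve(AQ, crossprod(X, q * u_vec)[, 1L] - rho1)
    da <- q * (u_vec - drop(X %*% db))
    list(db = db, da = da)
  }
  step_len <- function(v, dv) {
    neg <- dv < 0
    if (!any(neg)) 1 else min(1, 0.9995 * min(-v[neg] / dv[neg]))
  }

  gap <- Inf
  for (it in seq_len(max_iter)) {
    rr <- drop(y - X %*% b)
    gap <- sum(a * z) + sum(s * w)
    rho1 <- t_eq - crossprod(X, a)[, 1L]
    if (gap < tol * n * scale && max(abs(rho1)) < 1e-9 * n) break
    # Degenerate or fully converged iterates (e.g. an exactly fitted
    # bootstrap resample) leave no centring direction; stop rather than
    # divide by a vanished complementarity gap.
    if (!is.finite(gap) || gap <= .Machine$double.eps * n) break

    q <- 1 / (z / a + w / s)
    q[!is.finite(q)] <- 0
    # Affine (predictor) direction, mu = 0.
    dir <- solve_dirs(q, rr, rho1)
    da <- dir$da
    dz <- -z - (z / a) * da
    dw <- -w + (w / s) * da
    ap <- min(step_len(a, da), step_len(s, -da))
    ad <- min(step_len(z, dz), step_len(w, dw))
    mu_aff <- (sum((a + ap * da) * (z + ad * dz)) +
               sum((s - ap * da) * (w + ad * dw))) / (2 * n)
    mu_c <- gap / (2 * n)
    sigma <- min(1, max(0, (mu_aff / mu_c)))^3
    mu <- sigma * mu_c

    # Corrector direction with centring and second-order terms.
    g3 <- mu - a * z - da * dz
    g4 <- mu - s * w + da * dw
    u_vec <- rr + g3 / a - g4 / s + z - w
    dir <- solve_dirs(q, u_vec, rho1)
    da <- dir$da
    db <- dir$db
    dz <- g3 / a - (z / a) * da
    dw <- g4 / s + (w / s) * da
    ap <- min(step_len(a, da), step_len(s, -da))
    ad <- min(step_len(z, dz), step_len(w, dw))

    a <- a + ap * da
    # Keep the iterate strictly interior: long stalls on degenerate
    # resamples can otherwise underflow a bound to exactly 0 and poison the
    # complementarity ratios.
    a <- pmin(pmax(a, 1e-14), 1 - 1e-14)
    s <- 1 - a
    b <- b + ad * db
    z <- pmax(z + ad * dz, 1e-14)
    w <- pmax(w + ad * dw, 1e-14)
  }
  b <- drop(b)
  names(b) <- colnames(X)
  list(coefficients = b, residuals = drop(y - X %*% b), iterations = it,
       gap = gap)
}

#' Fit one quantile regression
#'
#' Minimises the pinball loss `sum(pinball_loss(y - a - x %*% beta, tau))`
#' by the interior-point method. At the solution the balance condition
#' holds: at most a fraction `tau` of residuals are strictly negative and at
#' least a fraction `tau` are non-positive. Optional 95% confidence
#' intervals come from a participant-resampling (pairs) bootstrap with
#' percentile endpoints.
#'
#' @param y Outcome vector.
#' @param x Predictor vector or matrix; `NULL` fits an intercept-only model
#'   (the tau-th sample quantile).
#' @param tau Quantile level in (0, 1).
#' @param normalize If `TRUE`, predictors are z-scored so coefficients are
#'   in outcome units per predictor SD (the convention used by the cohort
#'   analysis). Default `FALSE`.
#' @param ci `"none"` or `"bootstrap"`.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param conf_level Confidence level for the percentile interval.
#' @param seed Optional seed for the bootstrap.
#' @return An object of class `quantile_fit`: `tau`, `coefficients` (named,
#'   `(Intercept)` first), `ci` (matrix or `NULL`), `n`, `residuals`,
#'   `loss`, and the `balance` fractions.
#' @examples
#' quantile_regression(c(1, 2, 9), tau = 0.5)$coefficients  # median 2
#' @export
quantile_regression <- function(y, x = NULL, tau, normalize = FALSE,
                                ci = c("none", "bootstrap"), n_boot = 1000,
                                conf_level = 0.95, seed = NULL) {
  ci <- match.arg(ci)
  check_scalar_number(tau, "tau", min = 1e-9, max = 1 - 1e-9)
  if (tau <= 0 || tau >= 1) stop_domain("'tau' must lie strictly in (0, 1)")
  y <- as.numeric(y)
  if (anyNA(y)) stop_validation("missing values are not supported")
  if (!is.null(x)) {
    x <- as.matrix(x)
    if (nrow(x) != length(y)) stop_validation("'x' and 'y' lengths differ")
    if (is.null(colnames(x))) {
      colnames(x) <- if (ncol(x) == 1L) "x" else paste0("x", seq_len(ncol(x)))
    }
    if (normalize) x <- scale(x)
    if (any(apply(x, 2L, stats::sd) == 0)) {
      stop_domain("degenerate design: a predictor is constant",
                  class = "harvestgame_rank_deficient")
    }
  }
  X <- cbind("(Intercept)" = rep(1, length(y)), x)
  if (length(y) < ncol(X)) stop_validation("need at least as many points as parameters")
  fit <- rq_fit_ip(X, y, tau)
  res <- fit$residuals
  zero_tol <- 1e-7 * (1 + max(abs(y)))
  balance <- c(frac_negative = mean(res < -zero_tol),
               frac_nonpositive = mean(res <= zero_tol))
  ci_mat <- NULL
  if (ci == "bootstrap") {
    ci_mat <- maybe_with_seed(seed, {
      boot <- replicate(n_boot, {
        idx <- sample.int(length(y), replace = TRUE)
        rq_fit_ip(X[idx, , drop = FALSE], y[idx], tau)$coefficients
      })
      boot <- matrix(boot, nrow = ncol(X))
      alpha <- (1 - conf_level) / 2
      t(apply(boot, 1L, stats::quantile, probs = c(alpha, 1 - alpha)))
    })
    dimnames(ci_mat) <- list(colnames(X), c("ci_low", "ci_high"))
  }
  structure(list(tau = tau, coefficients = fit$coefficients, ci = ci_mat,
                 n = length(y), residuals = res,
                 loss = sum(pinball_loss(res, tau)), balance = balance,
                 iterations = fit$iterations),
            class = "quantile_fit")
}

#' @export
print.quantile_fit <- function(x, ...) {
  cat(sprintf("Quantile regression at tau = %.2f (n = %d)\n", x$tau, x$n))
  co <- x$coefficients
  for (i in seq_along(co)) {
    if (!is.null(x$ci)) {
      cat(sprintf("  %s = %.4f [%.4f, %.4f]\n", names(co)[i], co[i],
                  x$ci[i, 1L], x$ci[i, 2L]))
    } else {
      cat(sprintf("  %s = %.4f\n", names(co)[i], co[i]))
    }
  }
  invisible(x)
}

#' Quantile-regression profile over the 0.05-0.95 grid
#'
#' One fit per quantile from 0.05 to 0.95 in increments of 0.05 (19 fits),
#' with the predictor z-scored by default so each coefficient is the change
#' in the outcome per 1 SD of the predictor, and bootstrap confidence bands
#' sharing one set of resamples across the grid.
#'
#' @inheritParams quantile_regression
#' @param taus Quantile grid.
#' @return An object of class `quantile_profile`: a data frame with columns
#'   `tau`, `term`, `estimate`, `ci_low`, `ci_high`, `n`.
#' @export
quantile_profile <- function(y, x, taus = seq(0.05, 0.95, by = 0.05),
                             normalize = TRUE, ci = c("bootstrap", "none"),
                             n_boot = 1000, conf_level = 0.95, seed = NULL) {
  ci <- match.arg(ci)
  x <- as.matrix(x)
  if (is.null(colnames(x))) {
    colnames(x) <- if (ncol(x) == 1L) "x" else paste0("x", seq_len(ncol(x)))
  }
  if (normalize) x <- scale(x)
  X <- cbind("(Intercept)" = 1, x)
  n <- length(y)
  fits <- lapply(taus, function(tt) rq_fit_ip(X, y, tt)$coefficients)
  est <- do.call(rbind, fits)
  out <- data.frame(tau = rep(taus, each = ncol(X)),
                    term = rep(colnames(X), times = length(taus)),
                    estimate = as.vector(t(est)),
                    ci_low = NA_real_, ci_high = NA_real_, n = n)
  if (ci == "bootstrap") {
    alpha <- (1 - conf_level) / 2
    boots <- maybe_with_seed(seed, {
      idx_mat <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
      vapply(seq_len(n_boot), function(bb) {
        idx <- idx_mat[, bb]
        Xb <- X[idx, , drop = FALSE]
        yb <- y[idx]
        vapply(taus, function(tt) rq_fit_ip(Xb, yb, tt)$coefficients,
               numeric(ncol(X)))
      }, matrix(0, ncol(X), length(taus)))
    })
    # boots: coefficients x taus x resamples
    for (ti in seq_along(taus)) {
      for (ci_idx in seq_len(ncol(X))) {
        qs <- stats::quantile(boots[ci_idx, ti, ], probs = c(alpha, 1 - alpha))
        row <- (ti - 1L) * ncol(X) + ci_idx
        out$ci_low[row] <- qs[1L]
        out$ci_high[row] <- qs[2L]
      }
    }
  }
  structure(out, class = c("quantile_profile", "data.frame"),
            normalize = normalize, n_boot = if (ci == "bootstrap") n_boot else 0L)
}

#' Plot a quantile-regression profile
#'
#' Coefficient-versus-quantile plot with the confidence band, analogous to
#' the coefficient figures of individual-differences studies; requires
#' ggplot2.
#'
#' @param profile A [quantile_profile()].
#' @param terms Terms to show (default: everything but the intercept).
#' @return A ggplot object.
#' @export
plot_quantile_profile <- function(profile,
                                  terms = setdiff(unique(profile$term),
                                                  "(Intercept)")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_validation("plot_quantile_profile() requires the ggplot2 package")
  }
  d <- profile[profile$term %in% terms, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tau, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         alpha = 0.25, na.rm = TRUE) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "red") +
    ggplot2::facet_wrap(~term) +
    ggplot2::labs(x = "quantile", y = "coefficient (outcome per predictor SD)")
}
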