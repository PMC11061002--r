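test_that("quantile fits satisfy the textbook special cases", {
  # Intercept-only at the median is the sample median.
  f <- quantile_regression(c(1, 2, 9), tau = 0.5)
  expect_equal(unname(f$coefficients), 2, tolerance = 1e-8)
  # A perfect linear relationship is fitted exactly at any tau.
  x <- seq(-3, 3, length.out = 25)
  for (tt in c(0.1, 0.5, 0.9)) {
    ff <- quantile_regression(2 * x, x, tau = tt)
    expect_equal(unname(ff$coefficients), c(0, 2), tolerance = 1e-7)
    expect_lt(ff$loss, 1e-6)
  }
  expect_error(quantile_regression(1:5, tau = 1.2))
  expect_error(quantile_regression(1:5, rep(1, 5), tau = 0.5),
               class = "harvestgame_rank_deficient")
})

test_that("the interior-point solution matches a brute-force pinball grid search", {
  # Eight-point fixture; oracle is exhaustive search over (a, b) on a fine
  # grid, independent of the solver.
  y <- c(2.1, 0.7, 3.9, 3.0, 5.6, 4.4, 7.2, 5.9)
  x <- c(0.2, 0.6, 1.0, 1.5, 2.1, 2.4, 3.0, 3.3)
  for (tt in c(0.25, 0.5, 0.75)) {
    fit <- quantile_regression(y, x, tau = tt)
    oracle <- grid_search_rq(y, x, tt, a_range = c(-2, 4),
                             b_range = c(0, 4), step = 0.001)
    expect_lte(fit$loss, oracle$loss + 1e-9)
    expect_equal(unname(fit$coefficients), oracle$coef, tolerance = 2e-3)
  }
})

test_that("the solver agrees with an exact linear-programming reference to 1e-6", {
  # Reference: scipy's HiGHS simplex/IPM on the standard LP formulation of
  # pinball-loss minimisation, run through the system python; 50 random
  # datasets of varying size, tail weight and quantile level.
  withr::with_seed(42, {
    cases <- lapply(1:50, function(i) {
      n <- sample(30:200, 1)
      x <- rnorm(n)
      list(x = x,
           y = 1 + 2 * x + rt(n, df = 3) * (1 + 0.5 * abs(x)),
           tau = sample(seq(0.1, 0.9, 0.1), 1))
    })
  })
  ours <- t(vapply(cases, function(cs) {
    quantile_regression(cs$y, cs$x, cs$tau)$coefficients
  }, numeric(2)))
  tmp <- tempfile(fileext = ".csv")
  long <- do.call(rbind, lapply(seq_along(cases), function(i) {
    data.frame(case = i, y = cases[[i]]$y, x = cases[[i]]$x,
               tau = cases[[i]]$tau)
  }))
  write.csv(long, tmp, row.names = FALSE)
  out <- tempfile(fileext = ".csv")
  script <- sprintf("
import pandas as pd, numpy as np
from scipy.optimize import linprog
d = pd.read_csv('%s')
rows = []
for case, g in d.groupby('case'):
    y = g['y'].values; x = g['x'].values; tau = g['tau'].iloc[0]
    n = len(y); X = np.column_stack([np.ones(n), x]); p = 2
    c = np.concatenate([np.zeros(2*p), tau*np.ones(n), (1-tau)*np.ones(n)])
    A = np.hstack([X, -X, np.eye(n), -np.eye(n)])
    r = linprog(c, A_eq=A, b_eq=y, method='highs')
    b = r.x[:p] - r.x[p:2*p]
    rows.append([case, b[0], b[1]])
pd.DataFrame(rows, columns=['case','b0','b1']).to_csv('%s', index=False)
", tmp, out)
  status <- system2("python", "-", input = script)
  expect_equal(status, 0L)
  ref <- read.csv(out)
  expect_equal(nrow(ref), 50)
  expect_lt(max(abs(ours - as.matrix(ref[, c("b0", "b1")]))), 1e-6)
})

test_that("fitted residuals satisfy the quantile balance condition", {
  withr::with_seed(77, {
    for (i in 1:10) {
      n <- sample(40:150, 1)
      x <- rnorm(n)
      y <- 1 - x + rnorm(n) * (1 + abs(x))
      tt <- runif(1, 0.05, 0.95)
      fit <- quantile_regression(y, x, tau = tt)
      expect_lte(fit$balance["frac_negative"], tt + 1e-9)
      expect_gte(fit$balance["frac_nonpositive"], tt - 1e-9)
    }
  })
})

test_that("the 0.05-0.95 profile has 19 fits with honest confidence bands", {
  withr::with_seed(55, {
    x <- rnorm(120)
    y <- 3 + 0 * x + rnorm(120)
    prof <- quantile_profile(y, x, n_boot = 150, seed = 9)
    slope <- prof[prof$term != "(Intercept)", ]
    expect_equal(nrow(slope), 19)
    expect_equal(slope$tau, seq(0.05, 0.95, by = 0.05))
    expect_true(all(slope$ci_low <= slope$estimate + 1e-9))
    expect_true(all(slope$ci_high >= slope$estimate - 1e-9))
  })

  # Coverage under independence: across seeded simulations, at least 90%
  # of the 19 slope intervals contain 0.
  withr::with_seed(66, {
    cover <- vapply(1:10, function(i) {
      x <- rnorm(80)
      y <- rnorm(80)
      prof <- quantile_profile(y, x, n_boot = 150, seed = 100 + i)
      sl <- prof[prof$term != "(Intercept)", ]
      mean(sl$ci_low <= 0 & sl$ci_high >= 0)
    }, numeric(1))
    expect_gte(mean(cover), 0.9)
  })

  # Recovery of a planted uniform slope: the median-tau interval covers it.
  withr::with_seed(88, {
    x <- rnorm(200)
    y <- 1 + 4 * x + rnorm(200)
    prof <- quantile_profile(y, x, normalize = FALSE, n_boot = 200, seed = 3)
    sl <- prof[prof$term != "(Intercept)" & abs(prof$tau - 0.5) < 1e-9, ]
    expect_gte(4, sl$ci_low)
    expect_lte(4, sl$ci_high)
  })
})
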