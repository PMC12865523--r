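test_that("intercept-only check-loss fits equal sample quantiles", {
  set.seed(61)
  y <- rnorm(101)
  for (q in c(0.1, 0.25, 0.5, 0.9)) {
    b <- .rq_ip(matrix(1, length(y), 1), y, q)
    # 101*q is never an integer here, so the minimizer is the unique
    # type-1 sample quantile, which the brute-force oracle also finds
    expect_equal(b, brute_force_quantile(y, q), tolerance = 1e-10)
    expect_equal(b, unname(stats::quantile(y, q, type = 1)),
                 tolerance = 1e-10)
  }
  # integer n*q: the minimizer is an interval; objectives must still agree
  y100 <- as.numeric(1:100)
  b <- .rq_ip(matrix(1, 100, 1), y100, 0.25)
  expect_equal(sum(check_loss(y100 - b, 0.25)),
               sum(check_loss(y100 - brute_force_quantile(y100, 0.25),
                              0.25)),
               tolerance = 1e-9)
  expect_true(b >= 25 - 1e-9 && b <= 26 + 1e-9)
})

test_that("lasso solver at vanishing penalty matches the exact solver", {
  set.seed(62)
  t <- runif(200, 79, 99)
  y <- 0.1 + 0.003 * t + 1e-4 * t^2 + rnorm(200, 0, 0.05)
  d <- data.frame(t = t, y = y)
  for (bs in c("linear", "poly2", "natural_spline")) {
    m_ex <- fit_quantile_curves(d, bs, "exact_L1", c(0.25, 0.5, 0.75))
    m_l0 <- fit_quantile_curves(d, bs, "lasso_penalized", c(0.25, 0.5, 0.75),
                                lambda = 1e-9)
    expect_lt(max(abs(m_ex$coef - m_l0$coef)), 1e-4)
  }
})

test_that("a heavy lasso penalty shrinks to the intercept-only fit", {
  set.seed(63)
  # odd n keeps the intercept-only median unique
  d <- data.frame(t = runif(301, 79, 99), y = rnorm(301, 10, 1))
  m <- fit_quantile_curves(d, "linear", "lasso_penalized", 0.5, lambda = 1e4)
  expect_lt(abs(m$coef[2, 1]), 1e-6)
  expect_equal(m$coef[1, 1], unname(stats::quantile(d$y, 0.5, type = 1)),
               tolerance = 1e-6)
})

test_that("surrogate AIC penalizes useless structure and rewards real structure", {
  set.seed(64)
  t <- runif(2000, 79, 99)
  # null data: no age trend, so richer bases only add parameters
  d0 <- data.frame(t = t, y = rnorm(2000))
  m_lin <- fit_quantile_curves(d0, "linear", "exact_L1", c(0.25, 0.5, 0.75))
  m_p2 <- fit_quantile_curves(d0, "poly2", "exact_L1", c(0.25, 0.5, 0.75))
  per_level_rise <- mean(m_p2$aic_per_level$aic - m_lin$aic_per_level$aic)
  expect_gt(per_level_rise, -0.5)   # roughly +2 per useless column
  expect_lt(per_level_rise, 5)
  # quadratic truth: the richer basis wins decisively
  d2 <- data.frame(t = t, y = 0.002 * (t - 89)^2 + rnorm(2000, 0, 0.3))
  m_lin2 <- fit_quantile_curves(d2, "linear", "exact_L1", 0.5)
  m_p22 <- fit_quantile_curves(d2, "poly2", "exact_L1", 0.5)
  expect_lt(m_p22$aic, m_lin2$aic)
  # pure function: identical input, identical AIC
  expect_identical(qr_aic(m_lin, d0)$total, qr_aic(m_lin, d0)$total)
})

test_that("degenerate designs are rejected with informative errors", {
  d <- data.frame(t = rep(5, 100), y = rnorm(100))
  expect_error(fit_quantile_curves(d, "linear", "exact_L1", 0.5), "singular")
  dsmall <- data.frame(t = 1:3, y = rnorm(3))
  expect_error(fit_quantile_curves(dsmall, "poly2", "exact_L1", 0.5),
               "basis dimension")
  # exact interpolation makes the surrogate AIC undefined
  dint <- data.frame(t = c(1, 2), y = c(1, 2))
  m <- structure(list(basis = "linear", solver = "exact_L1",
                      quantile_levels = 0.5,
                      coef = matrix(c(0, 1), 2), n = 2,
                      design_meta = list(basis = "linear")),
                 class = "quantile_curve_model")
  expect_error(qr_aic(m, dint), "zero check loss")
})

test_that("rearranged quantile curve predictions never cross", {
  set.seed(65)
  d <- data.frame(t = runif(150, 79, 99), y = rnorm(150))
  m <- fit_quantile_curves(d, "poly3", "exact_L1", c(0.1, 0.5, 0.9))
  pr <- predict(m, 79:99, rearrange = TRUE)
  expect_true(all(apply(pr, 1, function(r) all(diff(r) >= 0))))
})
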