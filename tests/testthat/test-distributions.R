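test_that("densities are nonnegative and integrate to one across the grid", {
  for (p in dist_grid()) {
    lo <- dist_support_lower(p)
    I <- stats::integrate(function(y) dist_pdf(y, p), lo, Inf,
                          rel.tol = 1e-10)$value
    expect_equal(I, 1, tolerance = 1e-6,
                 label = sprintf("integral for %s(nu=%g,tau=%g)",
                                 p$family, p$nu, p$tau))
    ys <- dist_quantile(seq(0.01, 0.99, by = 0.07), p)
    expect_true(all(dist_pdf(ys, p) >= 0))
  }
})

test_that("cdf inverts the quantile function and both are monotone", {
  alphas <- c(0.01, 0.1, 0.5, 0.9, 0.99)
  for (p in dist_grid()) {
    q <- dist_quantile(alphas, p)
    expect_true(all(diff(q) > 0))
    expect_equal(dist_cdf(q, p), alphas, tolerance = 1e-8)
    ys <- dist_quantile(seq(0.05, 0.95, by = 0.05), p)
    expect_true(all(diff(dist_cdf(ys, p)) > 0))
  }
  expect_error(dist_quantile(0, dist_grid()[[1]]), "strictly in")
  expect_error(dist_quantile(1.2, dist_grid()[[1]]), "strictly in")
})

test_that("cdf is the antiderivative of the density", {
  h <- 1e-5
  for (p in dist_grid()) {
    ys <- dist_quantile(c(0.2, 0.5, 0.8), p)
    num <- (dist_cdf(ys + h, p) - dist_cdf(ys - h, p)) / (2 * h)
    expect_equal(num, dist_pdf(ys, p), tolerance = 1e-4)
  }
})

test_that("BCPEo at tau = 2 coincides with BCCGo", {
  for (nu in c(-1, 0, 0.5, 2)) {
    p_pe <- dist_params("BCPEo", 0.2, 0.4, nu, 2)
    p_cg <- dist_params("BCCGo", 0.2, 0.4, nu)
    ys <- dist_quantile(seq(0.02, 0.98, by = 0.06), p_cg)
    expect_equal(dist_pdf(ys, p_pe), dist_pdf(ys, p_cg), tolerance = 1e-12)
    expect_equal(dist_cdf(ys, p_pe), dist_cdf(ys, p_cg), tolerance = 1e-10)
  }
})

test_that("SEP families reduce to the symmetric power exponential", {
  # SEP1 at nu = 0: exactly the variance-standardized PE kernel
  p1 <- dist_params("SEP1", 0.3, 0.15, 0, 1.5)
  zs <- seq(-3, 3, by = 0.5)
  expect_equal(dist_pdf(0.3 + 0.15 * zs, p1),
               exp(.pe_logpdf(zs, 1.5)) / 0.15, tolerance = 1e-12)
  # SEP3 at nu = 1: symmetric about mu
  p3 <- dist_params("SEP3", 0.3, 0.15, 1, 3)
  d <- seq(0.01, 0.4, by = 0.05)
  expect_equal(dist_pdf(0.3 + d, p3), dist_pdf(0.3 - d, p3),
               tolerance = 1e-12)
  expect_equal(dist_cdf(0.3, p3), 0.5, tolerance = 1e-12)
})

test_that("box-cox transform handles its special cases and is continuous", {
  p <- dist_params("BCCGo", 0.2, 0.5, 1)
  expect_equal(box_cox_z(0.2, p), 0)
  expect_equal(box_cox_z(0.3, p), 1.0)  # ((0.3/0.2) - 1) / 0.5
  p_eps <- dist_params("BCCGo", 0.2, 0.5, 1e-9)
  p_zero <- dist_params("BCCGo", 0.2, 0.5, 0)
  expect_equal(box_cox_z(0.3, p_eps), box_cox_z(0.3, p_zero),
               tolerance = 1e-6)
  expect_error(box_cox_z(-1, p), "finite and > 0")
  expect_error(dist_params("BCCGo", 0.2, -0.5, 1), "sigma")
  expect_error(dist_params("SEP3", 0.2, 0.5, -1, 2), "nu > 0")
})

test_that("median and upper centile follow the Gaussian closed form when truncation is negligible", {
  p <- dist_params("BCCGo", 1, 0.1, 1)  # truncation mass pnorm(-10)
  expect_lt(truncation_mass(p), 1e-6)
  expect_equal(dist_cdf(1, p), 0.5, tolerance = 1e-9)
  expect_equal(dist_quantile(0.5, p), 1, tolerance = 1e-9)
  expect_equal(dist_quantile(0.975, p), 1 + 0.1 * stats::qnorm(0.975),
               tolerance = 1e-9)
  # strongly skewed parameter sets do truncate, and the diagnostic says so
  expect_gt(truncation_mass(dist_params("BCPEo", 0.2, 0.5, -2, 1.5)), 1e-3)
})

test_that("seeded sampling is reproducible and matches the model quantiles", {
  p <- dist_params("BCPEo", 0.15, 0.4, 0.3, 2)
  x1 <- dist_rvs(1000, p, seed = 99)
  x2 <- dist_rvs(1000, p, seed = 99)
  expect_identical(x1, x2)
  for (p in list(dist_params("BCPEo", 0.15, 0.4, 0.3, 2),
                 dist_params("SEP1", 0.2, 0.1, 3, 1.5))) {
    x <- dist_rvs(50000, p, seed = 123)
    expect_equal(stats::median(x), dist_quantile(0.5, p), tolerance = 0.01)
    expect_lt(abs(mean(x < dist_quantile(0.1, p)) - 0.1), 0.005)
  }
})
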