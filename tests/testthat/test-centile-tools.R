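test_that("centile curves and individual centiles are mutually inverse", {
  fit <- fixture_model()
  for (a in c(0.03, 0.5, 0.9)) {
    tg <- c(80, 89, 98)
    cv <- centile_curve(fit, a, tg)
    expect_equal(individual_centile(fit, tg, cv), rep(100 * a, 3),
                 tolerance = 1e-6)
  }
  # z at the 90th centile curve is the standard normal 90th quantile
  z90 <- z_score(fit, 89, centile_curve(fit, 0.9, 89))
  expect_equal(z90, stats::qnorm(0.9), tolerance = 1e-6)
})

test_that("centile tables are strictly ordered and never cross", {
  fit <- fixture_model()
  tab <- centile_table(fit)
  vals <- as.matrix(tab[, -1])
  expect_true(all(vals > 0))
  expect_true(all(apply(vals, 1, function(r) all(diff(r) > 0))))
  c3 <- centile_curve(fit, 0.03, tab$t)
  c97 <- centile_curve(fit, 0.97, tab$t)
  expect_true(all(c97 > c3))
})

test_that("ages outside the fitted range are refused unless allowed", {
  fit <- fixture_model()
  expect_error(centile_curve(fit, 0.5, 120), "extrapolation")
  expect_error(individual_centile(fit, 60, 0.2), "extrapolation")
  v <- centile_curve(fit, 0.5, 120, allow_extrapolation = TRUE)
  expect_true(attr(v, "extrapolated"))
})

test_that("z-scores of model-simulated data are standard normal", {
  fit <- fixture_model()
  set.seed(71)
  t <- sample(80:98, 2500, replace = TRUE)
  y <- simulate_from_model(fit, t, seed = 72)
  z <- z_score(fit, t, y)
  expect_lt(abs(mean(z)), 0.05)
  expect_lt(abs(stats::sd(z) - 1), 0.05)
  ks <- suppressWarnings(stats::ks.test(z, "pnorm"))
  expect_gt(ks$p.value, 0.01)
})

test_that("extreme observations clamp to |Z| = 8 with a warning", {
  fit <- fixture_model()
  expect_warning(zlo <- z_score(fit, 89, 1e-8), "clamped")
  expect_equal(zlo, -8)
})

test_that("calibration against model-simulated data shows minimal deviation", {
  fit <- fixture_model()
  set.seed(73)
  t <- sample(80:98, 2500, replace = TRUE)
  y <- simulate_from_model(fit, t, seed = 74)
  rep_ <- calibration_table(fit, data.frame(t = t, y = y))
  expect_s3_class(rep_, "calibration_report")
  expect_true(all(rep_$table$predicted >= 0 & rep_$table$predicted <= 100))
  # predicted coverage within binomial 99.9% bounds of the nominal level
  bound <- 329 * sqrt(TARGET_CENTILES * (1 - TARGET_CENTILES) / 2500)
  expect_true(all(abs(rep_$table$predicted_raw - rep_$table$centile) <
                    bound))
  expect_lt(abs(rep_$z_diagnostics$mean), 0.05)
  expect_lt(abs(rep_$z_diagnostics$sd - 1), 0.05)
})

test_that("attainable coverage is the empirical-quantile rank fraction", {
  fit <- fixture_model()
  sim <- fixture_sim()
  dat2547 <- sim$data[rep(seq_len(nrow(sim$data)), length.out = 2547), ]
  rep_ <- calibration_table(fit, dat2547, target_centiles = 0.01)
  expect_equal(rep_$table$attainable, round(100 * 26 / 2547, 2))  # 1.02
  expect_error(calibration_table(fit, data.frame(t = numeric(0),
                                                 y = numeric(0))), "empty")
})
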