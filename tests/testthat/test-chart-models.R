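test_that("fit_lms recovers the truth curves from simulated cohorts", {
  sim <- simulate_bcpe_data(2000, seed = 21)
  fit <- fit_lms(sim$data, "BCPEo",
                 edf_grid = list(mu = 3, sigma = 2, nu = 1, tau = 1),
                 select = "none")
  expect_true(fit$fit_meta$converged)
  t_int <- 82:96
  pa <- params_at(fit, t_int)
  med_hat <- centile_curve(fit, 0.5, t_int)
  med_true <- vapply(t_int, function(tt)
    dist_quantile(0.5, dist_params("BCPEo", sim$truth_median(tt),
                                   sim$truth$sigma, sim$truth$nu,
                                   sim$truth$tau)), numeric(1))
  expect_lt(max(abs(med_hat / med_true - 1)), 0.03)
  expect_lt(max(abs(pa$sigma / sim$truth$sigma - 1)), 0.10)
})

test_that("penalized log-likelihood never decreases across backfitting cycles", {
  fit <- fixture_model()
  tr <- fit$fit_meta$penalized_loglik_trace
  # cycle 1 recalibrates the smoothing parameters, so compare from cycle 2 on
  expect_true(all(diff(tr[-1]) > -1e-6))
})

test_that("nested families agree on data where the extra parameter is redundant", {
  sim <- simulate_bcpe_data(1500, seed = 31, nu = 1, tau = 2)
  f_cg <- fit_lms(sim$data, "BCCGo",
                  edf_grid = list(mu = 3, sigma = 2, nu = 1), select = "none")
  f_pe <- fit_lms(sim$data, "BCPEo",
                  edf_grid = list(mu = 3, sigma = 2, nu = 1, tau = 1),
                  select = "none")
  edf_diff <- abs(f_pe$total_edf - f_cg$total_edf)
  expect_lt(abs(f_pe$aic - f_cg$aic), 2 * edf_diff + 0.5)
})

test_that("undersized or degenerate inputs are rejected", {
  expect_error(fit_lms(data.frame(t = 1:30, y = runif(30) + 1), "BCPEo"),
               "n >= 50")
  expect_error(fit_lms(data.frame(t = 1:100, y = rep(1, 100)), "BCPEo"),
               "constant")
  expect_error(fit_lms(data.frame(t = 79:99, y = -(1:21)), "BCPEo"))
})

test_that("screening the four families on Box-Cox truth selects a Box-Cox family", {
  co <- generate_cohort(n = 2500, seed = 41)
  dat <- data.frame(t = co$ga_days, y = co$svfmbv1)
  grids <- list(BCCGo = list(mu = 3, sigma = 2, nu = 1),
                BCPEo = list(mu = 3, sigma = 2, nu = 1, tau = 1),
                SEP1 = list(mu = 3, sigma = 2, nu = 1, tau = 1),
                SEP3 = list(mu = 3, sigma = 2, nu = 1, tau = 1))
  cand <- lapply(names(grids), function(fam)
    fit_lms(dat, fam, edf_grid = grids[[fam]], select = "none"))
  names(cand) <- names(grids)
  sel <- select_best_model(cand)
  expect_true(sel$best$family %in% c("BCCGo", "BCPEo"))
})

test_that("AIC selection returns the argmin and breaks ties by parsimony", {
  mk <- function(aic, edf, fam = "BCPEo")
    structure(list(family = fam, aic = aic, total_edf = edf,
                   fit_meta = list(converged = TRUE, n = 100)),
              class = "fitted_chart_model")
  sel <- select_best_model(list(mk(-10, 5), mk(-12, 5), mk(-11, 5)))
  expect_equal(sel$index, 2L)
  sel2 <- select_best_model(list(a = mk(-12, 7), b = mk(-12, 5)))
  expect_equal(sel2$index, 2L)
  expect_error(select_best_model(list()), "empty")
})

test_that("greedy smoothness selection explores the edf grid and returns valid edf", {
  sim <- simulate_bcpe_data(800, seed = 51)
  fit <- fit_lms(sim$data, "BCPEo",
                 edf_grid = list(mu = c(2, 4), sigma = 2, nu = 1, tau = 1),
                 select = "greedy")
  expect_true(fit$fit_meta$converged)
  expect_gte(fit$total_edf, 4)  # at least one df per parameter curve
  expect_true(is.finite(fit$aic))
})

test_that("fitted models survive a JSON round trip exactly", {
  fit <- fixture_model()
  path <- withr::local_tempfile(fileext = ".json")
  chart_model_to_json(fit, path)
  back <- chart_model_from_json(path)
  tg <- c(80.5, 89, 97.2)
  expect_equal(params_at(back, tg), params_at(fit, tg), tolerance = 1e-12)
  expect_equal(back$aic, fit$aic)
})
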