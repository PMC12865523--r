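# Shared fixtures, built in code at test time.

# parameter grid spanning strong skew and light/heavy tails
dist_grid <- function() {
  list(
    dist_params("BCCGo", mu = 0.2, sigma = 0.4, nu = -1),
    dist_params("BCCGo", mu = 0.2, sigma = 0.4, nu = 2),
    dist_params("BCCGo", mu = 1.0, sigma = 0.1, nu = 0),
    dist_params("BCPEo", mu = 0.2, sigma = 0.5, nu = -2, tau = 1.5),
    dist_params("BCPEo", mu = 0.3, sigma = 0.3, nu = 3, tau = 5),
    dist_params("BCPEo", mu = 0.15, sigma = 0.4, nu = 0.3, tau = 2),
    dist_params("SEP1", mu = 0.2, sigma = 0.1, nu = 3, tau = 1.5),
    dist_params("SEP1", mu = 0.2, sigma = 0.1, nu = -2, tau = 4),
    dist_params("SEP3", mu = 0.2, sigma = 0.1, nu = 0.5, tau = 1.2),
    dist_params("SEP3", mu = 0.2, sigma = 0.1, nu = 2.5, tau = 3)
  )
}

dist_support_lower <- function(params) {
  if (params$family %in% c("BCCGo", "BCPEo")) 1e-12 else -Inf
}

# age-structured data from a known Box-Cox power exponential truth
simulate_bcpe_data <- function(n, seed, mu0 = 0.15, mu_slope = 0.01,
                               sigma = 0.4, nu = 0.3, tau = 2) {
  set.seed(seed)
  t <- sample(79:99, n, replace = TRUE,
              prob = stats::dnorm(79:99, 89, 4.5))
  mu_t <- exp(log(mu0) + mu_slope * (t - 89))
  u <- stats::runif(n)
  y <- vapply(seq_len(n), function(i)
    dist_quantile(u[i], dist_params("BCPEo", mu_t[i], sigma, nu, tau)),
    numeric(1))
  list(data = data.frame(t = t, y = y),
       truth_median = function(tt) exp(log(mu0) + mu_slope * (tt - 89)),
       truth = list(mu0 = mu0, mu_slope = mu_slope, sigma = sigma,
                    nu = nu, tau = tau))
}

# one moderately sized fitted model, cached across test files
.fixture_cache <- new.env(parent = emptyenv())
fixture_model <- function() {
  if (is.null(.fixture_cache$model)) {
    sim <- simulate_bcpe_data(1500, seed = 11)
    .fixture_cache$model <- fit_lms(
      sim$data, "BCPEo",
      edf_grid = list(mu = 3, sigma = 2, nu = 1, tau = 1), select = "none")
    .fixture_cache$sim <- sim
  }
  .fixture_cache$model
}
fixture_sim <- function() {
  fixture_model()
  .fixture_cache$sim
}

# draw model-consistent data at the ages of `data` from a fitted model
simulate_from_model <- function(model, t, seed) {
  set.seed(seed)
  pa <- params_at(model, t)
  u <- stats::runif(length(t))
  vapply(seq_along(t), function(i)
    dist_quantile(u[i], dist_params(model$family, pa$mu[i], pa$sigma[i],
                                    pa$nu[i], pa$tau[i])), numeric(1))
}

# brute-force check-loss minimizer over the observed values
brute_force_quantile <- function(y, q) {
  cand <- sort(unique(y))
  obj <- vapply(cand, function(c) sum(check_loss(y - c, q)), numeric(1))
  cand[which.min(obj)]
}
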