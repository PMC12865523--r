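# Age-conditional distribution models: the LMS/GAMLSS path (smooth
# mu/sigma/nu/tau curves by penalized maximum likelihood) and quantile
# regression comparators, compared by AIC.

.FAMILY_LINKS <- list(
  BCCGo = c(mu = "log", sigma = "log", nu = "identity"),
  BCPEo = c(mu = "log", sigma = "log", nu = "identity", tau = "log"),
  SEP1  = c(mu = "log", sigma = "log", nu = "identity", tau = "log"),
  # SEP3's skewness parameter is strictly positive, hence the log link
  SEP3  = c(mu = "log", sigma = "log", nu = "log", tau = "log")
)

.default_edf_grid <- function() {
  list(mu = 2:6, sigma = 2:4, nu = 1:2, tau = 1:2)
}

.check_chart_data <- function(data) {
  stopifnot(is.data.frame(data), all(c("t", "y") %in% names(data)))
  data <- data[stats::complete.cases(data[, c("t", "y")]), , drop = FALSE]
  if (nrow(data) < 50) stop("fit_lms requires n >= 50 observations")
  if (stats::sd(data$y) < 1e-12) stop("degenerate data: y is constant")
  data
}

# evaluate all parameter curves at t -> list of numeric vectors
.curves_eval <- function(curves, t) {
  lapply(curves, .curve_value, t = t)
}

.model_loglik <- function(y, family, th) {
  sum(.ll_vec(y, family, th$mu, th$sigma, th$nu, th$tau))
}

# penalized log-likelihood given coefficient state
.pen_loglik <- function(y, family, curves, t) {
  th <- .curves_eval(curves, t)
  ll <- .model_loglik(y, family, th)
  pen <- 0
  for (cv in curves) {
    if (!is.null(cv$type) && cv$type == "pspline" && is.finite(cv$lambda))
      pen <- pen + 0.5 * cv$lambda * drop(crossprod(cv$coef, cv$P %*% cv$coef))
  }
  ll - pen
}

# Single backfitting update of one parameter curve by penalized
# Fisher-scoring with numerically differentiated per-observation score and
# curvature with respect to the curve's linear predictor.
.update_curve <- function(par, curves, y, family, t, B, h = 1e-4) {
  cv <- curves[[par]]
  eta <- .curve_eta(cv, t)
  th <- .curves_eval(curves, t)
  ll0 <- .ll_vec(y, family, th$mu, th$sigma, th$nu, th$tau)

  perturb <- function(d) {
    thp <- th
    thp[[par]] <- .linkinv(eta + d, cv$link)
    .ll_vec(y, family, thp$mu, thp$sigma, thp$nu, thp$tau)
  }
  lp <- perturb(h); lm <- perturb(-h)
  u <- (lp - lm) / (2 * h)
  w <- -(lp - 2 * ll0 + lm) / h^2
  bad <- !is.finite(u) | !is.finite(w)
  u[bad] <- 0; w[bad] <- 1
  w <- pmin(pmax(w, 1e-4), 1e6)
  step <- pmin(pmax(u / w, -5), 5)       # damp the working response
  z <- eta + step

  lambda <- if (cv$type == "pspline") cv$lambda else 0
  P <- if (cv$type == "pspline") cv$P else matrix(0, 1, 1)
  A <- crossprod(B * w, B) + lambda * P
  beta_new <- tryCatch(drop(solve(A, crossprod(B * w, z))),
                       error = function(e) cv$coef)

  pen0 <- .pen_loglik(y, family, curves, t)
  beta_old <- cv$coef
  s <- 1
  for (half in 1:12) {
    curves[[par]]$coef <- beta_old + s * (beta_new - beta_old)
    pen1 <- .pen_loglik(y, family, curves, t)
    if (is.finite(pen1) && pen1 >= pen0 - 1e-10) return(curves)
    s <- s / 2
  }
  curves[[par]]$coef <- beta_old
  curves
}

.init_curves <- function(t, y, family, edf_targets, n_interior) {
  links <- .FAMILY_LINKS[[family]]
  pars <- names(links)
  curves <- list()
  for (par in pars) {
    curves[[par]] <- .curve_new(t, links[[par]], edf_targets[[par]],
                                n_interior)
  }
  # lambda from the edf target under unit weights
  for (par in pars) {
    cv <- curves[[par]]
    if (cv$type == "pspline") {
      B <- .curve_design(cv, t)
      curves[[par]]$lambda <-
        .ps_lambda_for_edf(B, cv$P, rep(1, length(t)), cv$edf_target)
    }
  }
  # mu: penalized least squares of log(y) (the location is within the bulk
  # of a positive response, so log(y) is a serviceable start for all links)
  target_mu <- if (links[["mu"]] == "log") log(y) else y
  cvm <- curves$mu
  Bm <- .curve_design(cvm, t)
  lam <- if (cvm$type == "pspline") cvm$lambda else 0
  Pm <- if (cvm$type == "pspline") cvm$P else matrix(0, 1, 1)
  curves$mu$coef <- drop(solve(crossprod(Bm) + lam * Pm,
                               crossprod(Bm, target_mu)))
  eta_mu <- .curve_eta(curves$mu, t)
  res <- target_mu - eta_mu
  s0 <- max(stats::sd(res), 1e-3)
  sig0 <- if (family %in% BOX_COX_FAMILIES) s0 else
    max(stats::sd(y - exp(eta_mu)), 1e-4)
  # a constant curve on a partition-of-unity B-spline basis has ALL
  # coefficients equal to the constant
  set_const <- function(cv, val) {
    cv$coef <- rep(val, length(cv$coef))
    cv
  }
  curves$sigma <- set_const(curves$sigma, log(sig0))  # sigma link always log
  if ("nu" %in% pars)
    curves$nu <- set_const(curves$nu,
                           switch(family, BCCGo = 1, BCPEo = 1, SEP1 = 0,
                                  SEP3 = 0))          # SEP3: log(1) = 0
  if ("tau" %in% pars) curves$tau <- set_const(curves$tau, log(2))
  curves
}

# core fit at fixed edf targets
.lms_fit_fixed <- function(t, y, family, edf_targets, k, max_cycles, tol,
                           n_interior) {
  curves <- .init_curves(t, y, family, edf_targets, n_interior)
  pars <- names(curves)
  designs <- lapply(curves, .curve_design, t = t)
  trace <- numeric(0)
  pen_prev <- .pen_loglik(y, family, curves, t)
  converged <- FALSE
  cycles <- 0L
  for (cycle in seq_len(max_cycles)) {
    cycles <- cycle
    for (par in pars) {
      curves <- .update_curve(par, curves, y, family, t, designs[[par]])
    }
    pen <- .pen_loglik(y, family, curves, t)
    trace <- c(trace, pen)
    if (cycle == 1) {
      # recalibrate lambda once with likelihood-based weights
      for (par in pars) {
        cv <- curves[[par]]
        if (cv$type != "pspline") next
        w <- .curve_weights(par, curves, y, family, t)
        curves[[par]]$lambda <-
          .ps_lambda_for_edf(designs[[par]], cv$P, w, cv$edf_target)
      }
      pen_prev <- .pen_loglik(y, family, curves, t)
      next
    }
    if (abs(pen - pen_prev) < tol) { converged <- TRUE; break }
    pen_prev <- pen
  }
  # realized edf with final weights
  total_edf <- 0
  for (par in pars) {
    cv <- curves[[par]]
    if (cv$type == "pspline") {
      w <- .curve_weights(par, curves, y, family, t)
      curves[[par]]$edf <- .ps_edf(designs[[par]], cv$P, w, cv$lambda)
    }
    total_edf <- total_edf + curves[[par]]$edf
  }
  if (family == "BCCGo")
    curves$tau <- list(type = "fixed", value = 2, link = "identity", edf = 0)
  th <- .curves_eval(curves, t)
  ll <- .model_loglik(y, family, th)
  structure(list(
    family = family,
    curves = curves,
    loglik = ll,
    total_edf = total_edf,
    k = k,
    aic = -2 * ll + k * total_edf,
    fit_meta = list(cycles = cycles, converged = converged, n = length(y),
                    t_range = range(t), edf_targets = edf_targets,
                    penalized_loglik_trace = trace)
  ), class = "fitted_chart_model")
}

.curve_weights <- function(par, curves, y, family, t, h = 1e-4) {
  cv <- curves[[par]]
  eta <- .curve_eta(cv, t)
  th <- .curves_eval(curves, t)
  ll0 <- .ll_vec(y, family, th$mu, th$sigma, th$nu, th$tau)
  f <- function(d) {
    thp <- th; thp[[par]] <- .linkinv(eta + d, cv$link)
    .ll_vec(y, family, thp$mu, thp$sigma, thp$nu, thp$tau)
  }
  w <- -(f(h) - 2 * ll0 + f(-h)) / h^2
  w[!is.finite(w)] <- 1
  pmin(pmax(w, 1e-4), 1e6)
}

#' Fit an age-conditional LMS distribution model
#'
#' Maximizes the penalized log-likelihood of a four-parameter response
#' family whose parameters vary smoothly with gestational age, by cyclic
#' backfitting: each parameter's P-spline curve is updated in turn by a
#' penalized Fisher-scoring step holding the others fixed, with step-halving
#' so the penalized log-likelihood never decreases. Smoothness (effective
#' degrees of freedom per curve) is chosen on a per-parameter grid by
#' minimizing AIC with complexity penalty `k`.
#'
#' @param data Data frame with columns `t` (gestational age, days) and `y`
#'   (response, positive).
#' @param family Response family, one of `"BCCGo"`, `"BCPEo"`, `"SEP1"`,
#'   `"SEP3"`.
#' @param edf_grid Named list of candidate effective-df values per parameter
#'   (`mu`, `sigma`, `nu`, `tau`); a length-1 entry fixes that parameter's
#'   smoothness. Default `mu` 2:6, `sigma` 2:4, `nu` 1:2, `tau` 1:2; edf 1
#'   denotes a constant.
#' @param k AIC complexity multiplier (default 2).
#' @param max_cycles Maximum backfitting cycles (default 1000).
#' @param tol Convergence tolerance on the penalized log-likelihood change
#'   between cycles (default 1e-4).
#' @param select `"greedy"` (coordinate search over `edf_grid`, default),
#'   `"grid"` (full cartesian grid) or `"none"` (first grid value of each).
#' @param n_interior Interior knots of each P-spline basis (default 6).
#' @return A `fitted_chart_model` with parameter curves, log-likelihood,
#'   total effective df and AIC.
#' @export
fit_lms <- function(data, family = c("BCPEo", "BCCGo", "SEP1", "SEP3"),
                    edf_grid = NULL, k = 2, max_cycles = 1000, tol = 1e-4,
                    select = c("greedy", "grid", "none"), n_interior = 6L) {
  family <- match.arg(family)
  select <- match.arg(select)
  data <- .check_chart_data(data)
  if (family %in% BOX_COX_FAMILIES && any(data$y <= 0))
    stop("y must be > 0 for Box-Cox families")
  t <- data$t; y <- data$y
  grid <- .default_edf_grid()
  if (!is.null(edf_grid)) grid[names(edf_grid)] <- edf_grid
  if (family == "BCCGo") grid$tau <- NULL
  pars <- names(.FAMILY_LINKS[[family]])
  grid <- grid[pars]

  fit_at <- function(targets)
    .lms_fit_fixed(t, y, family, targets, k, max_cycles, tol, n_interior)

  mid <- lapply(grid, function(g) g[ceiling(length(g) / 2)])
  if (select == "none" || all(lengths(grid) == 1L)) {
    targets <- lapply(grid, `[`, 1L)
    fit <- fit_at(targets)
  } else if (select == "greedy") {
    targets <- mid
    fit <- fit_at(targets)
    for (par in pars) {
      if (length(grid[[par]]) == 1L) next
      for (val in grid[[par]]) {
        if (identical(val, targets[[par]])) next
        cand_t <- targets; cand_t[[par]] <- val
        cand <- fit_at(cand_t)
        if (cand$fit_meta$converged && cand$aic < fit$aic) {
          fit <- cand; targets <- cand_t
        }
      }
    }
  } else {
    combos <- expand.grid(grid)
    fit <- NULL
    for (i in seq_len(nrow(combos))) {
      cand <- fit_at(as.list(combos[i, , drop = FALSE]))
      if (!cand$fit_meta$converged) next
      if (is.null(fit) || cand$aic < fit$aic) fit <- cand
    }
    if (is.null(fit)) stop("no candidate converged on the edf grid")
  }
  if (!fit$fit_meta$converged)
    warning(sprintf("fit_lms (%s) did not converge within %d cycles",
                    family, max_cycles))
  fit
}

#' @export
print.fitted_chart_model <- function(x, ...) {
  cat(sprintf("<fitted_chart_model> family=%s n=%d loglik=%.3f edf=%.2f aic=%.3f\n",
              x$family, x$fit_meta$n, x$loglik, x$total_edf, x$aic))
  cat(sprintf("  converged=%s after %d cycles; t range [%g, %g]\n",
              x$fit_meta$converged, x$fit_meta$cycles,
              x$fit_meta$t_range[1], x$fit_meta$t_range[2]))
  invisible(x)
}

#' Evaluate the fitted parameter curves at given ages
#'
#' @param model A `fitted_chart_model`.
#' @param t Gestational ages (days).
#' @param allow_extrapolation Permit `t` outside the fitted range?
#' @return A tibble with columns `t`, `mu`, `sigma`, `nu`, `tau`.
#' @export
params_at <- function(model, t, allow_extrapolation = FALSE) {
  stopifnot(inherits(model, "fitted_chart_model"))
  rng <- model$fit_meta$t_range
  out_of_range <- t < rng[1] | t > rng[2]
  if (any(out_of_range) && !allow_extrapolation)
    stop("t outside the fitted gestational-age range; ",
         "set allow_extrapolation = TRUE to override")
  tc <- pmin(pmax(t, rng[1]), rng[2])  # spline bases evaluated in-range
  vals <- lapply(model$curves, .curve_value, t = tc)
  tibble::tibble(t = t, mu = vals$mu, sigma = vals$sigma, nu = vals$nu,
                 tau = if (is.null(vals$tau)) rep(2, length(t)) else vals$tau,
                 extrapolated = out_of_range)
}

#' Pick the AIC-best model from a candidate list
#'
#' Returns the candidate with the lowest AIC together with a comparison
#' grid. Ties (within `tie_tol`) are broken by fewer effective degrees of
#' freedom, then by declaration order.
#'
#' @param candidates List of `fitted_chart_model` and/or
#'   `quantile_curve_model` objects (optionally named).
#' @param tie_tol Absolute AIC difference treated as a tie (default 1e-8).
#' @return List with `best`, `index` and a tibble `table`.
#' @export
select_best_model <- function(candidates, tie_tol = 1e-8) {
  if (length(candidates) == 0) stop("empty candidate list")
  desc <- function(m) {
    if (inherits(m, "fitted_chart_model"))
      c(label = m$family, kind = "LMS", aic = m$aic, edf = m$total_edf)
    else if (inherits(m, "quantile_curve_model"))
      c(label = paste(m$basis, m$solver, sep = "/"), kind = "QR",
        aic = m$aic, edf = m$n_params)
    else stop("unsupported candidate class")
  }
  info <- do.call(rbind, lapply(candidates, desc))
  tab <- tibble::tibble(
    model = if (!is.null(names(candidates)) && any(nzchar(names(candidates))))
      names(candidates) else info[, "label"],
    label = info[, "label"], kind = info[, "kind"],
    aic = as.numeric(info[, "aic"]), edf = as.numeric(info[, "edf"]))
  best_aic <- min(tab$aic)
  tied <- which(tab$aic <= best_aic + tie_tol)
  idx <- tied[order(tab$edf[tied], tied)][1]
  list(best = candidates[[idx]], index = idx, table = tab)
}
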