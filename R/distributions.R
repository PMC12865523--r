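# Response families for age-conditional reference charts.
#
# All four families follow the GAMLSS catalog parameterizations:
#
# BCCGo  (Box-Cox Cole-Green, "original"): y > 0,
#   z = ((y/mu)^nu - 1) / (nu*sigma)   (log(y/mu)/sigma at nu = 0),
#   f(y) = phi(z) * y^(nu-1) / (mu^nu * sigma * Phi(1/(sigma*|nu|)))
#   where phi/Phi are the standard normal pdf/cdf and the last factor
#   renormalizes the latent normal over the z-range attainable from y > 0.
#
# BCPEo  (Box-Cox power exponential, "original"): as BCCGo but the latent
#   standardized distribution is the power exponential PE(0, 1, tau) with
#   variance 1:  f_Z(z) = tau * exp(-0.5*|z/c|^tau) / (c * 2^(1+1/tau) *
#   Gamma(1/tau)),  c^2 = 2^(-2/tau) * Gamma(1/tau) / Gamma(3/tau).
#   tau = 2 recovers the Gaussian latent, i.e. BCCGo.
#
# SEP1  (skew exponential power, Azzalini-type skewing): y real,
#   z = (y - mu)/sigma,  f(y) = (2/sigma) * f_PE(z; tau) * F_PE(nu*z; tau).
#   nu = 0 gives the symmetric power exponential.
#
# SEP3  (skew exponential power, two-piece scale skewing): y real, nu > 0,
#   z = (y - mu)/sigma,
#   f(y) = (c/sigma) * exp(-0.5*|nu*z|^tau)        for z < 0
#          (c/sigma) * exp(-0.5*|z/nu|^tau)        for z >= 0
#   with c = tau*nu / ((1 + nu^2) * 2^(1/tau) * Gamma(1/tau)).
#   nu = 1 gives the symmetric power exponential (up to its natural scale).

FAMILIES <- c("BCCGo", "BCPEo", "SEP1", "SEP3")
BOX_COX_FAMILIES <- c("BCCGo", "BCPEo")

#' Construct a validated four-parameter distribution state
#'
#' Bundles the family name with the (mu, sigma, nu, tau) values that define
#' the response distribution at one gestational age. For the Box-Cox families
#' mu is (approximately) the median on the response scale, sigma the
#' coefficient of variation and nu the Box-Cox power; tau controls the
#' kurtosis of the latent power exponential and is fixed at 2 for BCCGo.
#'
#' @param family One of `"BCCGo"`, `"BCPEo"`, `"SEP1"`, `"SEP3"`.
#' @param mu Location, `> 0`.
#' @param sigma Scale, `> 0`.
#' @param nu Skewness; any finite real (strictly positive for SEP3).
#' @param tau Kurtosis/shape, `> 0`; ignored (forced to 2) for BCCGo.
#' @return An object of class `dist_params`.
#' @export
#' @examples
#' p <- dist_params("BCPEo", mu = 0.2, sigma = 0.4, nu = 0.5, tau = 2)
#' dist_quantile(0.5, p)
dist_params <- function(family, mu, sigma, nu, tau = 2) {
  family <- match.arg(family, FAMILIES)
  stopifnot(length(mu) == 1L, length(sigma) == 1L, length(nu) == 1L,
            length(tau) == 1L)
  if (!is.finite(mu) || mu <= 0) stop("mu must be finite and > 0")
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be finite and > 0")
  if (!is.finite(nu)) stop("nu must be finite")
  if (family == "BCCGo") tau <- 2
  if (!is.finite(tau) || tau <= 0) stop("tau must be finite and > 0")
  if (family == "SEP3" && nu <= 0) stop("SEP3 requires nu > 0")
  structure(list(family = family, mu = mu, sigma = sigma, nu = nu, tau = tau),
            class = "dist_params")
}

#' @export
print.dist_params <- function(x, ...) {
  cat(sprintf("<%s> mu=%.6g sigma=%.6g nu=%.6g tau=%.6g\n",
              x$family, x$mu, x$sigma, x$nu, x$tau))
  invisible(x)
}

# nu treated as zero below this, so the Box-Cox transform stays continuous
NU_EPS <- 1e-7

## ---- standardized power exponential PE(0, 1, tau), variance 1 ----

.pe_c <- function(tau) sqrt(2^(-2 / tau) * gamma(1 / tau) / gamma(3 / tau))

.pe_logpdf <- function(z, tau) {
  cc <- .pe_c(tau)
  log(tau) - log(cc) - 0.5 * abs(z / cc)^tau - (1 + 1 / tau) * log(2) -
    lgamma(1 / tau)
}

.pe_cdf <- function(z, tau) {
  cc <- .pe_c(tau)
  s <- 0.5 * abs(z / cc)^tau
  0.5 * (1 + sign(z) * stats::pgamma(s, shape = 1 / tau))
}

.pe_quantile <- function(p, tau) {
  cc <- .pe_c(tau)
  s <- stats::qgamma(abs(2 * p - 1), shape = 1 / tau)
  sign(p - 0.5) * cc * (2 * s)^(1 / tau)
}

.pe_rvs <- function(n, tau) {
  cc <- .pe_c(tau)
  g <- stats::rgamma(n, shape = 1 / tau)
  sample(c(-1, 1), n, replace = TRUE) * cc * (2 * g)^(1 / tau)
}

## ---- Box-Cox transform ----

#' Box-Cox z transform underlying the LMS families
#'
#' Maps a positive response onto the latent standardized scale:
#' `((y/mu)^nu - 1)/(nu*sigma)` for `nu != 0` and `log(y/mu)/sigma` at
#' `nu = 0`; the two branches agree in the limit and the `nu = 0` branch is
#' taken for `|nu| < 1e-7`.
#'
#' @param y Positive response values.
#' @param params A [dist_params()] object for a Box-Cox family.
#' @return Numeric vector of latent z values.
#' @export
box_cox_z <- function(y, params) {
  stopifnot(inherits(params, "dist_params"))
  if (!params$family %in% BOX_COX_FAMILIES)
    stop("box_cox_z is defined for the Box-Cox families only")
  if (any(!is.finite(y)) || any(y <= 0)) stop("y must be finite and > 0")
  mu <- params$mu; sigma <- params$sigma; nu <- params$nu
  if (abs(nu) < NU_EPS) {
    log(y / mu) / sigma
  } else {
    ((y / mu)^nu - 1) / (nu * sigma)
  }
}

# latent half-range bound 1/(sigma*|nu|); Inf when nu ~ 0
.bc_bound <- function(params) {
  if (abs(params$nu) < NU_EPS) Inf else 1 / (params$sigma * abs(params$nu))
}

.latent_cdf <- function(z, params) {
  if (params$family == "BCCGo") stats::pnorm(z) else .pe_cdf(z, params$tau)
}

.latent_quantile <- function(p, params) {
  if (params$family == "BCCGo") stats::qnorm(p) else .pe_quantile(p, params$tau)
}

.latent_logpdf <- function(z, params) {
  if (params$family == "BCCGo") stats::dnorm(z, log = TRUE)
  else .pe_logpdf(z, params$tau)
}

#' Probability mass lost to Box-Cox truncation
#'
#' The Box-Cox transform maps (0, Inf) onto a half-bounded latent interval
#' when `nu != 0`; the latent distribution is renormalized over that
#' interval. This diagnostic returns the latent mass outside it (0 for the
#' SEP families and for `nu = 0`), so callers can assert it is negligible.
#'
#' @param params A [dist_params()] object.
#' @return Truncated probability mass in `[0, 1)`.
#' @export
truncation_mass <- function(params) {
  stopifnot(inherits(params, "dist_params"))
  if (!params$family %in% BOX_COX_FAMILIES) return(0)
  a <- .bc_bound(params)
  if (!is.finite(a)) return(0)
  1 - .latent_cdf(a, params)
}

## ---- density ----

.logpdf <- function(y, params) {
  fam <- params$family
  mu <- params$mu; sigma <- params$sigma; nu <- params$nu; tau <- params$tau
  if (fam %in% BOX_COX_FAMILIES) {
    out <- rep(-Inf, length(y))
    ok <- is.finite(y) & y > 0
    z <- ((if (abs(nu) < NU_EPS) log(y[ok] / mu) / sigma
           else ((y[ok] / mu)^nu - 1) / (nu * sigma)))
    a <- .bc_bound(params)
    lnorm <- if (is.finite(a)) log(.latent_cdf(a, params)) else 0
    out[ok] <- .latent_logpdf(z, params) +
      (nu - 1) * log(y[ok]) - nu * log(mu) - log(sigma) - lnorm
    out
  } else if (fam == "SEP1") {
    z <- (y - mu) / sigma
    log(2) - log(sigma) + .pe_logpdf(z, tau) +
      log(pmax(.pe_cdf(nu * z, tau), 1e-300))
  } else { # SEP3
    z <- (y - mu) / sigma
    lc <- log(tau) + log(nu) - log1p(nu^2) - (1 / tau) * log(2) -
      lgamma(1 / tau)
    lc - log(sigma) + ifelse(z < 0, -0.5 * abs(nu * z)^tau,
                             -0.5 * abs(z / nu)^tau)
  }
}

#' Density of a chart response family
#'
#' @param y Response values (positive for the Box-Cox families; any real for
#'   the SEP families).
#' @param params A [dist_params()] object.
#' @param log Return the log-density?
#' @return Numeric vector of (log-)density values.
#' @export
dist_pdf <- function(y, params, log = FALSE) {
  stopifnot(inherits(params, "dist_params"), is.numeric(y))
  if (params$family %in% BOX_COX_FAMILIES && any(y <= 0))
    stop("y must be > 0 for Box-Cox families")
  lp <- .logpdf(y, params)
  if (log) lp else exp(lp)
}

# Per-observation log-likelihood, vectorized over observations AND
# parameters (used by the LMS fitter, where every observation has its own
# age-dependent mu/sigma/nu/tau).
.ll_vec <- function(y, family, mu, sigma, nu, tau) {
  if (family %in% BOX_COX_FAMILIES) {
    near0 <- abs(nu) < NU_EPS
    z <- suppressWarnings(
      ifelse(near0, log(y / mu) / sigma, ((y / mu)^nu - 1) / (nu * sigma)))
    a <- ifelse(near0, Inf, 1 / (sigma * abs(nu)))
    if (family == "BCCGo") {
      lz <- stats::dnorm(z, log = TRUE)
      lnorm <- ifelse(is.finite(a), stats::pnorm(a, log.p = TRUE), 0)
    } else {
      lz <- .pe_logpdf(z, tau)
      lnorm <- ifelse(is.finite(a), log(.pe_cdf(a, tau)), 0)
    }
    lz + (nu - 1) * log(y) - nu * log(mu) - log(sigma) - lnorm
  } else if (family == "SEP1") {
    z <- (y - mu) / sigma
    log(2) - log(sigma) + .pe_logpdf(z, tau) +
      log(pmax(.pe_cdf(nu * z, tau), 1e-300))
  } else {
    z <- (y - mu) / sigma
    lc <- log(tau) + log(nu) - log1p(nu^2) - (1 / tau) * log(2) -
      lgamma(1 / tau)
    lc - log(sigma) + ifelse(z < 0, -0.5 * abs(nu * z)^tau,
                             -0.5 * abs(z / nu)^tau)
  }
}

## ---- cdf ----

.sep1_cdf_one <- function(z, params) {
  nu <- params$nu; tau <- params$tau
  # integrate the skewed kernel from -Inf; switch tail for accuracy
  f <- function(u) exp(.pe_logpdf(u, tau)) * .pe_cdf(nu * u, tau) * 2
  if (z <= 0) {
    stats::integrate(f, -Inf, z, rel.tol = 1e-11, abs.tol = 1e-13)$value
  } else {
    1 - stats::integrate(f, z, Inf, rel.tol = 1e-11, abs.tol = 1e-13)$value
  }
}

#' Cumulative distribution function of a chart response family
#'
#' @inheritParams dist_pdf
#' @return Probabilities in `[0, 1]`.
#' @export
dist_cdf <- function(y, params) {
  stopifnot(inherits(params, "dist_params"), is.numeric(y))
  fam <- params$family
  mu <- params$mu; sigma <- params$sigma; nu <- params$nu
  if (fam %in% BOX_COX_FAMILIES) {
    if (any(y <= 0)) stop("y must be > 0 for Box-Cox families")
    z <- box_cox_z(y, params)
    a <- .bc_bound(params)
    Fz <- .latent_cdf(z, params)
    if (!is.finite(a)) return(Fz)
    Fa <- .latent_cdf(a, params)
    p <- if (nu > 0) (Fz - (1 - Fa)) / Fa else Fz / Fa
    pmin(pmax(p, 0), 1)
  } else if (fam == "SEP1") {
    z <- (y - mu) / sigma
    vapply(z, .sep1_cdf_one, numeric(1), params = params)
  } else { # SEP3
    z <- (y - mu) / sigma
    tau <- params$tau
    p0 <- 1 / (1 + nu^2)
    lower <- p0 * (1 - stats::pgamma(0.5 * (nu * pmax(-z, 0))^tau,
                                     shape = 1 / tau))
    upper <- p0 + (1 - p0) * stats::pgamma(0.5 * (pmax(z, 0) / nu)^tau,
                                           shape = 1 / tau)
    ifelse(z < 0, lower, upper)
  }
}

## ---- quantile ----

.sep1_quantile_one <- function(alpha, params) {
  mu <- params$mu; sigma <- params$sigma; tau <- params$tau
  # bracket on the latent z scale using symmetric PE quantiles, then bisect
  lo <- .pe_quantile(min(alpha, 1 - alpha) / 2, tau) - 1
  hi <- -lo
  flo <- .sep1_cdf_one(lo, params); fhi <- .sep1_cdf_one(hi, params)
  while (flo > alpha) { lo <- lo * 2 - 1; flo <- .sep1_cdf_one(lo, params) }
  while (fhi < alpha) { hi <- hi * 2 + 1; fhi <- .sep1_cdf_one(hi, params) }
  r <- stats::uniroot(function(z) .sep1_cdf_one(z, params) - alpha,
                      lower = lo, upper = hi, tol = 1e-13)
  mu + sigma * r$root
}

#' Quantile function of a chart response family
#'
#' Closed-form inversion through the latent symmetric distribution for the
#' Box-Cox families and SEP3; bracketed root-finding on the CDF for SEP1
#' (tolerance 1e-10 on the probability scale).
#'
#' @param alpha Probabilities in `(0, 1)`.
#' @param params A [dist_params()] object.
#' @return Response-scale quantiles, strictly increasing in `alpha`.
#' @export
dist_quantile <- function(alpha, params) {
  stopifnot(inherits(params, "dist_params"), is.numeric(alpha))
  if (any(alpha <= 0 | alpha >= 1)) stop("alpha must lie strictly in (0, 1)")
  fam <- params$family
  mu <- params$mu; sigma <- params$sigma; nu <- params$nu
  if (fam %in% BOX_COX_FAMILIES) {
    a <- .bc_bound(params)
    p <- if (!is.finite(a)) alpha
         else if (nu > 0) 1 - .latent_cdf(a, params) * (1 - alpha)
         else alpha * .latent_cdf(a, params)
    z <- .latent_quantile(p, params)
    if (abs(nu) < NU_EPS) mu * exp(sigma * z)
    else mu * (1 + sigma * nu * z)^(1 / nu)
  } else if (fam == "SEP1") {
    vapply(alpha, .sep1_quantile_one, numeric(1), params = params)
  } else { # SEP3
    tau <- params$tau
    p0 <- 1 / (1 + nu^2)
    z <- numeric(length(alpha))
    lo <- alpha < p0
    z[lo] <- -(2 * stats::qgamma(1 - alpha[lo] / p0,
                                 shape = 1 / tau))^(1 / tau) / nu
    z[!lo] <- nu * (2 * stats::qgamma((alpha[!lo] - p0) / (1 - p0),
                                      shape = 1 / tau))^(1 / tau)
    mu + sigma * z
  }
}

## ---- random generation ----

#' Seeded random sampling from a chart response family
#'
#' Inverse-CDF sampling through the closed-form quantile function where one
#' exists; SEP1 uses the exact skew-symmetric representation (sample the
#' symmetric power exponential, flip the sign with probability
#' `1 - F_PE(nu*z)`).
#'
#' @param n Number of draws.
#' @param params A [dist_params()] object.
#' @param seed Optional integer; when supplied the draw is reproducible.
#' @return Numeric vector of length `n`.
#' @export
dist_rvs <- function(n, params, seed = NULL) {
  stopifnot(inherits(params, "dist_params"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (params$family == "SEP1") {
    w <- .pe_rvs(n, params$tau)
    u <- stats::runif(n)
    z <- ifelse(u <= .pe_cdf(params$nu * w, params$tau), w, -w)
    params$mu + params$sigma * z
  } else {
    dist_quantile(stats::runif(n), params)
  }
}
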