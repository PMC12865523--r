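# P-spline parameter curves: cubic B-spline basis with interior knots at
# quantiles of the covariate, smoothness controlled by a ridge penalty on
# second differences of the coefficients. The effective degrees of freedom
# of a penalized fit, tr[(B'WB + lambda*P)^-1 B'WB], is matched to a target
# by solving for lambda; edf target 1 means a constant curve and edf -> K
# (the basis dimension) an unpenalized spline.

.ps_basis <- function(t, spec) {
  splines::bs(t, knots = spec$knots, degree = spec$degree, intercept = TRUE,
              Boundary.knots = spec$boundary)
}

.ps_spec <- function(t, n_interior = 6L, degree = 3L) {
  ut <- sort(unique(t))
  n_interior <- min(n_interior, max(length(ut) - 2L, 1L))
  probs <- seq_len(n_interior) / (n_interior + 1)
  knots <- unname(stats::quantile(t, probs, type = 7))
  knots <- knots[knots > min(ut) & knots < max(ut)]
  list(knots = unique(knots), degree = degree,
       boundary = range(ut), K = length(unique(knots)) + degree + 1L)
}

.ps_penalty <- function(K) {
  if (K <= 2L) return(diag(0, K))
  D <- diff(diag(K), differences = 2L)
  crossprod(D)
}

.ps_edf <- function(B, P, w, lambda) {
  BtWB <- crossprod(B * w, B)
  sum(diag(solve(BtWB + lambda * P, BtWB)))
}

# solve for lambda giving the target edf under weights w (monotone in
# -log lambda); second-difference penalty leaves a 2-dim null space so
# edf(lambda -> Inf) = 2
.ps_lambda_for_edf <- function(B, P, w, target) {
  K <- ncol(B)
  if (target >= K - 1e-8) return(0)
  f <- function(loglam) .ps_edf(B, P, w, exp(loglam)) - target
  lo <- -15; hi <- 25
  if (f(hi) > 0) return(exp(hi))  # target at/below the penalty null space
  if (f(lo) < 0) return(exp(lo))
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-6)$root)
}

# A parameter curve is either a constant (edf 1) or a penalized spline.
.curve_new <- function(t, link, edf_target, n_interior = 6L) {
  if (edf_target <= 1 + 1e-8) {
    list(type = "constant", link = link, coef = 0, edf_target = 1, edf = 1)
  } else {
    spec <- .ps_spec(t, n_interior)
    list(type = "pspline", link = link, spec = spec,
         coef = numeric(spec$K), lambda = NA_real_,
         P = .ps_penalty(spec$K), edf_target = edf_target, edf = NA_real_)
  }
}

.curve_design <- function(curve, t) {
  if (curve$type == "constant") matrix(1, length(t), 1L)
  else unclass(.ps_basis(t, curve$spec))
}

.curve_eta <- function(curve, t) {
  if (curve$type == "fixed") return(rep(curve$value, length(t)))
  drop(.curve_design(curve, t) %*% curve$coef)
}

.linkinv <- function(eta, link) if (link == "log") exp(eta) else eta

.curve_value <- function(curve, t) {
  if (curve$type == "fixed") rep(curve$value, length(t))
  else .linkinv(.curve_eta(curve, t), curve$link)
}
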