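# Centile charts, individual centiles / Z-scores, and coverage calibration
# from a fitted age-conditional distribution model.

TARGET_CENTILES <- c(0.01, 0.03, 0.10, 0.25, 0.50, 0.75, 0.90, 0.97, 0.99)

.params_list <- function(model, t, allow_extrapolation = FALSE) {
  pa <- params_at(model, t, allow_extrapolation)
  lapply(seq_len(nrow(pa)), function(i)
    dist_params(model$family, pa$mu[i], pa$sigma[i], pa$nu[i], pa$tau[i]))
}

#' Evaluate one centile curve over an age grid
#'
#' `C_alpha(t)` is the alpha-quantile of the fitted response distribution at
#' age `t`.
#'
#' @param model A `fitted_chart_model`.
#' @param alpha Centile as a probability in (0, 1).
#' @param t_grid Gestational ages (days) within the fitted range.
#' @param allow_extrapolation Permit ages outside the fitted range (flagged
#'   in the output attribute `extrapolated`)?
#' @return Numeric vector of curve values along `t_grid`.
#' @export
centile_curve <- function(model, alpha, t_grid, allow_extrapolation = FALSE) {
  stopifnot(length(alpha) == 1L, alpha > 0, alpha < 1)
  pl <- .params_list(model, t_grid, allow_extrapolation)
  out <- vapply(pl, function(p) dist_quantile(alpha, p), numeric(1))
  rng <- model$fit_meta$t_range
  attr(out, "extrapolated") <- t_grid < rng[1] | t_grid > rng[2]
  out
}

#' Build the full centile table over an age grid
#'
#' @param model A `fitted_chart_model`.
#' @param t_grid Age grid in days (default: every day of the fitted range).
#' @param target_centiles Centiles to tabulate (default the chart set
#'   1st/3rd/10th/25th/50th/75th/90th/97th/99th).
#' @return A tibble with column `t` and one `p<centile>` column per target,
#'   strictly increasing across centiles at each age.
#' @export
centile_table <- function(model, t_grid = NULL,
                          target_centiles = TARGET_CENTILES) {
  if (is.null(t_grid)) {
    rng <- model$fit_meta$t_range
    t_grid <- seq(ceiling(rng[1]), floor(rng[2]))
  }
  cols <- lapply(target_centiles, function(a) centile_curve(model, a, t_grid))
  names(cols) <- paste0("p", formatC(100 * target_centiles))
  tibble::as_tibble(c(list(t = t_grid), lapply(cols, as.numeric)))
}

#' Individual centile and Z-score
#'
#' The centile is `100 * F(y; params(t))`; the Z-score is the standard
#' normal quantile of the same CDF value, so model-consistent data yield
#' standard-normal Z-scores. CDF values indistinguishable from 0 or 1 are
#' clamped to |Z| = 8 with a warning.
#'
#' @param model A `fitted_chart_model`.
#' @param t Gestational ages (days), recycled against `y`.
#' @param y Measured values.
#' @param allow_extrapolation Permit ages outside the fitted range?
#' @return `individual_centile`: centiles in (0, 100); `z_score`: numeric
#'   Z-scores.
#' @export
individual_centile <- function(model, t, y, allow_extrapolation = FALSE) {
  n <- max(length(t), length(y))
  t <- rep_len(t, n); y <- rep_len(y, n)
  pl <- .params_list(model, t, allow_extrapolation)
  100 * vapply(seq_len(n), function(i) dist_cdf(y[i], pl[[i]]), numeric(1))
}

#' @rdname individual_centile
#' @export
z_score <- function(model, t, y, allow_extrapolation = FALSE) {
  p <- individual_centile(model, t, y, allow_extrapolation) / 100
  z <- stats::qnorm(p)
  clip <- !is.finite(z) | abs(z) > 8
  if (any(clip)) {
    warning(sprintf("%d Z-score(s) clamped to +/-8 (CDF underflow)",
                    sum(clip)))
    z[clip] <- ifelse(p[clip] <= 0.5, -8, 8)
  }
  z
}

#' Predicted vs attainable centile coverage (calibration)
#'
#' For each target centile alpha the predicted coverage is the percentage of
#' observations strictly below their age-specific curve value
#' `C_alpha(t_i)`; the attainable (observed) coverage is `100 * k*/n` where
#' `k*` is the number of sample points strictly below the empirical
#' linear-interpolation (type-7) alpha-quantile — `floor(h)` with
#' `h = 1 + (n-1)*alpha`, or `h - 1` when `h` is an integer — the best any
#' continuous model could do on a finite sample. Z-score moment and
#' normality diagnostics accompany the table.
#'
#' @param model A `fitted_chart_model`.
#' @param data Data frame with columns `t` and `y` (training or held-out).
#' @param target_centiles Centiles to assess.
#' @return A `calibration_report`: list with `table` (tibble: centile,
#'   predicted, attainable, gap, all in percent, rounded to 2 dp with
#'   unrounded columns retained) and `z_diagnostics`.
#' @export
calibration_table <- function(model, data,
                              target_centiles = TARGET_CENTILES) {
  stopifnot(is.data.frame(data), all(c("t", "y") %in% names(data)))
  n <- nrow(data)
  if (n == 0) stop("empty data")
  pl <- .params_list(model, data$t)
  cdfs <- vapply(seq_len(n), function(i) dist_cdf(data$y[i], pl[[i]]),
                 numeric(1))
  pred <- vapply(target_centiles, function(a) 100 * sum(cdfs < a) / n,
                 numeric(1))
  attain <- vapply(target_centiles, function(a) {
    h <- 1 + (n - 1) * a   # type-7 quantile position
    k <- if (abs(h - round(h)) < 1e-9) round(h) - 1 else floor(h)
    100 * k / n
  }, numeric(1))
  z <- stats::qnorm(pmin(pmax(cdfs, 1e-15), 1 - 1e-15))
  m <- mean(z); s <- stats::sd(z)
  skew <- mean((z - m)^3) / s^3
  kurt <- mean((z - m)^4) / s^4
  sw <- if (n >= 3 && n <= 5000) stats::shapiro.test(z) else NULL
  structure(list(
    table = tibble::tibble(
      centile = 100 * target_centiles,
      predicted = round(pred, 2),
      attainable = round(attain, 2),
      gap = round(abs(pred - attain), 2),
      predicted_raw = pred,
      attainable_raw = attain),
    z_diagnostics = list(mean = m, sd = s, skewness = skew, kurtosis = kurt,
                         shapiro_W = if (is.null(sw)) NA_real_
                                     else unname(sw$statistic),
                         shapiro_p = if (is.null(sw)) NA_real_
                                     else sw$p.value,
                         n = n),
    z_scores = z
  ), class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat("<calibration_report>\n")
  print(x$table[, c("centile", "predicted", "attainable", "gap")])
  d <- x$z_diagnostics
  cat(sprintf("Z: mean=%.3f sd=%.3f skew=%.3f kurt=%.3f (n=%d)\n",
              d$mean, d$sd, d$skewness, d$kurtosis, d$n))
  invisible(x)
}

#' Plot a centile chart
#'
#' Renders the conventional chart layout: solid 50th centile, shaded
#' 25th-75th band, dashed 10th/90th and dotted 3rd/97th curves, with the
#' raw observations underneath when supplied.
#'
#' @param model A `fitted_chart_model`.
#' @param data Optional data frame with `t`, `y` to overlay.
#' @param t_grid Age grid (default daily over the fitted range).
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_centile_chart <- function(model, data = NULL, t_grid = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_centile_chart requires ggplot2")
  tab <- centile_table(model, t_grid,
                       target_centiles = c(0.03, 0.10, 0.25, 0.50, 0.75,
                                           0.90, 0.97))
  gg <- ggplot2::ggplot(tab, ggplot2::aes(x = t))
  if (!is.null(data))
    gg <- gg + ggplot2::geom_point(data = data,
                                   ggplot2::aes(x = t, y = y),
                                   alpha = 0.15, size = 0.4)
  gg +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = p25, ymax = p75),
                         alpha = 0.25, fill = "grey50") +
    ggplot2::geom_line(ggplot2::aes(y = p50), linewidth = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = p10), linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = p90), linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = p3), linetype = "dotted") +
    ggplot2::geom_line(ggplot2::aes(y = p97), linetype = "dotted") +
    ggplot2::labs(x = "Gestational age (days)", y = "Value")
}
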