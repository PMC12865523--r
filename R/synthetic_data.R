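# Synthetic cohorts with the statistical structure the chart pipeline
# assumes: gestational ages concentrated mid-window and sparse at the
# extremes, five positively skewed perfusion series whose four-parameter
# truth curves vary smoothly with age, placental volumes with injected
# fence-busting outliers, paired Dice values with rare triage failures, and
# rare clinical outcome flags.

# Parameter curves are linear in centered age (t - 89) on the link scale
# (log for mu/sigma/tau, identity for nu except SEP3), so a TruthSpec is a
# plain serializable list.

.default_series <- function() {
  mk <- function(mu0, mus, sg0, sgs, nu0, tau0 = 2)
    list(family = "BCPEo",
         mu = c(log(mu0), mus), sigma = c(log(sg0), sgs),
         nu = c(nu0, 0), tau = c(log(tau0), 0))
  list(
    svfmbv1 = mk(0.20, 0.008, 0.40, 0.002, 0.30),
    svfmbv2 = mk(0.12, 0.006, 0.45, 0.000, 0.10),
    svfmbv3 = mk(0.30, 0.005, 0.35, 0.002, 0.50),
    svfmbv4 = mk(0.07, 0.010, 0.55, 0.003, -0.40),  # most prominent skew
    svfmbv5 = mk(0.28, 0.004, 0.35, 0.000, 0.50)
  )
}

#' Construct the truth specification for synthetic cohorts
#'
#' Defaults encode the study conditions the generator emulates: scans at
#' 79-99 days with few cases at the extremes (truncated-normal age weights
#' peaked near day 89), five positively skewed series (Box-Cox power below
#' 1, most negative for series 4), rare outcome flags, sparse volume
#' outliers and rare Dice triage failures.
#'
#' @param series Named list of per-series truth curves (family plus
#'   link-scale `c(intercept, slope)` for mu, sigma, nu, tau in centered age
#'   `t - 89`).
#' @param ga_range Gestational-age range in days.
#' @param ga_peak,ga_sd Location and spread of the age-sampling weights.
#' @param prevalence Named outcome-flag probabilities.
#' @param volume Volume model: `meanlog0` (log-ml at day 89), `slope` per
#'   day, `sdlog`, and `outlier_rate` of injected fence-busting values.
#' @param dice_rates Injection rates for triage rounds 1-3.
#' @return A `truth_spec` list.
#' @export
truth_spec <- function(series = .default_series(),
                       ga_range = c(79L, 99L), ga_peak = 89, ga_sd = 4.5,
                       prevalence = c(
                         miscarriage = 0.008, stillbirth = 0.003,
                         termination = 0.004, neonatal_death = 0.002,
                         anomaly = 0.010, nnu_admission = 0.030,
                         diabetes = 0.040, hypertensive = 0.030,
                         aps_sle = 0.002, incomplete_outcome = 0.010,
                         bw_lt10 = 0.0479, smoker = 0.0181,
                         previous_pe = 0.0157, female = 0.4963),
                       volume = c(meanlog0 = log(45), slope = 0.04,
                                  sdlog = 0.25, outlier_rate = 0.005),
                       dice_rates = c(r1 = 0.010, r2 = 0.005, r3 = 0.005)) {
  stopifnot(all(prevalence >= 0 & prevalence <= 1),
            all(dice_rates >= 0 & dice_rates <= 1))
  structure(list(series = series, ga_range = as.integer(ga_range),
                 ga_peak = ga_peak, ga_sd = ga_sd,
                 prevalence = as.list(prevalence),
                 volume = as.list(volume),
                 dice_rates = as.list(dice_rates)),
            class = "truth_spec")
}

#' True distribution parameters of a synthetic series at given ages
#'
#' @param spec A [truth_spec()].
#' @param series Series name, e.g. `"svfmbv1"`.
#' @param t Gestational ages (days).
#' @return A tibble of `t`, `mu`, `sigma`, `nu`, `tau`.
#' @export
truth_params <- function(spec, series, t) {
  s <- spec$series[[series]]
  if (is.null(s)) stop("unknown series: ", series)
  tc <- t - 89
  ev <- function(co, link) {
    eta <- co[1] + co[2] * tc
    if (link == "log") exp(eta) else eta
  }
  nu_link <- if (s$family == "SEP3") "log" else "identity"
  tibble::tibble(t = t, mu = ev(s$mu, "log"), sigma = ev(s$sigma, "log"),
                 nu = ev(s$nu, nu_link), tau = ev(s$tau, "log"))
}

#' True centile curve of a synthetic series
#'
#' @inheritParams truth_params
#' @param alpha Centile as probability.
#' @return Numeric vector along `t`.
#' @export
truth_quantile <- function(spec, series, alpha, t) {
  pa <- truth_params(spec, series, t)
  fam <- spec$series[[series]]$family
  vapply(seq_len(nrow(pa)), function(i)
    dist_quantile(alpha, dist_params(fam, pa$mu[i], pa$sigma[i], pa$nu[i],
                                     pa$tau[i])), numeric(1))
}

.sample_series <- function(spec, series, t) {
  pa <- truth_params(spec, series, t)
  fam <- spec$series[[series]]$family
  y <- vapply(seq_len(nrow(pa)), function(i) {
    p <- dist_params(fam, pa$mu[i], pa$sigma[i], pa$nu[i], pa$tau[i])
    for (tries in 1:100) {
      v <- dist_rvs(1, p)
      if (v > 0 && v < 1) return(v)   # physical range of a volume fraction
    }
    stop("rejection sampling failed for ", series)
  }, numeric(1))
  y
}

#' Generate a synthetic pregnancy cohort
#'
#' Draws gestational ages from the truncated-normal weight vector, each
#' perfusion series from its truth distribution at the drawn age (values
#' outside (0, 1) rejected and redrawn), log-normal placental volumes with
#' an age-increasing mean and a small injected fraction of fence-busting
#' outliers, paired Dice values with rare triage failures, and independent
#' rare outcome flags. The truth specification and seed are embedded as
#' attributes for recovery scoring; regeneration with the same spec and
#' seed is identical.
#'
#' @param spec A [truth_spec()].
#' @param n Number of pregnancies.
#' @param seed Integer seed.
#' @return A tibble of class `synthetic_cohort` with attributes `truth` and
#'   `seed`.
#' @export
generate_cohort <- function(spec = truth_spec(), n = 2500, seed = 1) {
  stopifnot(inherits(spec, "truth_spec"), n >= 1)
  set.seed(seed)
  days <- seq(spec$ga_range[1], spec$ga_range[2])
  w <- stats::dnorm(days, spec$ga_peak, spec$ga_sd)
  ga <- sample(days, n, replace = TRUE, prob = w / sum(w))

  sv <- lapply(names(spec$series), function(s) .sample_series(spec, s, ga))
  names(sv) <- names(spec$series)

  vol <- exp(stats::rnorm(n, spec$volume$meanlog0 +
                            spec$volume$slope * (ga - 89),
                          spec$volume$sdlog))
  n_out <- stats::rbinom(1, n, spec$volume$outlier_rate)
  vol_outlier <- rep(FALSE, n)
  if (n_out > 0) {
    idx <- sample.int(n, n_out)
    fac <- stats::runif(n_out, 4, 8)
    flip <- stats::runif(n_out) < 0.5
    vol[idx] <- ifelse(flip, vol[idx] * fac, vol[idx] / fac)
    vol_outlier[idx] <- TRUE
  }

  pv <- spec$prevalence
  flag <- function(p) stats::runif(n) < p
  # pregnancy ending: mutually exclusive rare losses, otherwise live birth
  ptype <- stats::runif(n)
  miscarriage <- ptype < pv$miscarriage
  stillbirth <- !miscarriage & ptype < pv$miscarriage + pv$stillbirth
  termination <- !miscarriage & !stillbirth &
    ptype < pv$miscarriage + pv$stillbirth + pv$termination
  live <- !(miscarriage | stillbirth | termination)
  delivery_ga_days <- as.integer(round(stats::rnorm(n, 280, 10)))
  delivery_ga_days[delivery_ga_days > 295] <- 295L
  delivery_ga_days[miscarriage] <-
    as.integer(sample(90:167, sum(miscarriage), replace = TRUE))
  delivery_ga_days[stillbirth] <- pmax(delivery_ga_days[stillbirth], 168L)
  delivery_ga_days[live] <- pmax(delivery_ga_days[live], 200L)
  signs_of_life <- live | termination

  bw_lt10 <- flag(pv$bw_lt10)
  bw_centile <- ifelse(bw_lt10, stats::runif(n, 0, 10),
                       stats::runif(n, 10, 100))

  dr <- spec$dice_rates
  placenta_dice <- 0.60 + 0.38 * stats::rbeta(n, 8, 2)
  fluid_dice <- 0.40 + 0.58 * stats::rbeta(n, 6, 2)
  dtype <- stats::runif(n)
  i1 <- dtype < dr$r1
  i2 <- !i1 & dtype < dr$r1 + dr$r2
  i3 <- !i1 & !i2 & dtype < dr$r1 + dr$r2 + dr$r3
  placenta_dice[i1] <- stats::runif(sum(i1), 0.30, 0.599)
  placenta_dice[i2] <- stats::runif(sum(i2), 0.601, 0.749)
  fluid_dice[i2] <- stats::runif(sum(i2), 0.10, 0.399)
  fluid_dice[i3] <- stats::runif(sum(i3), 0.10, 0.399)

  out <- tibble::tibble(
    case_id = seq_len(n),
    ga_days = as.integer(ga),
    svfmbv1 = sv$svfmbv1, svfmbv2 = sv$svfmbv2, svfmbv3 = sv$svfmbv3,
    svfmbv4 = sv$svfmbv4, svfmbv5 = sv$svfmbv5,
    placental_volume = vol,
    volume_outlier_injected = vol_outlier,
    placenta_dice = placenta_dice,
    fluid_dice = fluid_dice,
    maternal_age = round(stats::rnorm(n, 33.3, 4.3), 1),
    maternal_weight = round(exp(stats::rnorm(n, log(66.6), 0.17)), 1),
    female_sex = flag(pv$female),
    smoker = flag(pv$smoker),
    previous_pe = flag(pv$previous_pe),
    miscarriage = miscarriage,
    stillbirth = stillbirth,
    termination = termination,
    neonatal_death = live & flag(pv$neonatal_death),
    anomaly = flag(pv$anomaly),
    delivery_ga_days = delivery_ga_days,
    signs_of_life = signs_of_life,
    bw_centile = bw_centile,
    ua_pi_centile = stats::runif(n, 0, 100),
    cpr_centile = stats::runif(n, 0, 100),
    nnu_admission = flag(pv$nnu_admission),
    diabetes = flag(pv$diabetes),
    hypertensive = flag(pv$hypertensive),
    aps_sle = flag(pv$aps_sle),
    incomplete_outcome = flag(pv$incomplete_outcome)
  )
  attr(out, "truth") <- spec
  attr(out, "seed") <- seed
  class(out) <- c("synthetic_cohort", class(out))
  out
}

#' Paired binary masks with a target Dice coefficient
#'
#' Constructs two equally sized voxel sets as shifted windows in a linear
#' ordering of the array, so the achieved Dice equals the target up to
#' integer rounding (well within 0.02 for any non-trivial shape).
#'
#' @param shape Integer array dimensions, e.g. `c(20, 20, 20)`.
#' @param overlap_target Desired Dice coefficient in `[0, 1]`.
#' @param seed Optional seed (the construction is deterministic; the seed
#'   only randomizes the voxel ordering).
#' @return List with `mask_a`, `mask_b` (integer arrays) and `dice`.
#' @export
generate_mask_pair <- function(shape, overlap_target, seed = NULL) {
  stopifnot(overlap_target >= 0, overlap_target <= 1)
  N <- prod(shape)
  m <- floor(N / (2 - overlap_target))
  if (m < 50) stop("shape too small for a reliable mask pair")
  if (!is.null(seed)) set.seed(seed)
  ord <- if (is.null(seed)) seq_len(N) else sample.int(N)
  k <- round((1 - overlap_target) * m)
  a <- integer(N); b <- integer(N)
  a[ord[seq_len(m)]] <- 1L
  b[ord[seq.int(k + 1, k + m)]] <- 1L
  dim(a) <- shape; dim(b) <- shape
  list(mask_a = a, mask_b = b, dice = (m - k) / m)
}

#' Write / read a truth specification as editable JSON
#'
#' @param spec A [truth_spec()].
#' @param path File path.
#' @return `read_truth_spec` returns a `truth_spec`.
#' @export
write_truth_spec <- function(spec, path) {
  stopifnot(inherits(spec, "truth_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_spec
#' @export
read_truth_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$series <- lapply(x$series, function(s) {
    s$mu <- as.numeric(s$mu); s$sigma <- as.numeric(s$sigma)
    s$nu <- as.numeric(s$nu); s$tau <- as.numeric(s$tau)
    s
  })
  truth_spec(series = x$series, ga_range = x$ga_range, ga_peak = x$ga_peak,
             ga_sd = x$ga_sd, prevalence = unlist(x$prevalence),
             volume = unlist(x$volume), dice_rates = unlist(x$dice_rates))
}
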