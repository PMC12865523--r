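# End-to-end orchestration: outcome definitions, healthy-cohort exclusions,
# QC stages, per-series model fitting and AIC selection, chart and
# calibration outputs.

#' Convert "weeks+days" gestational notation to days
#'
#' Accepts `"24+0"` strings, or numbers already in days (returned as-is).
#'
#' @param x Character `"w+d"` vector or numeric days.
#' @return Integer days.
#' @export
ga_to_days <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  m <- regmatches(x, regexec("^\\s*(\\d+)\\s*\\+\\s*(\\d)\\s*$", x))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) stop("malformed gestational age: ", paste(x[bad], collapse = ", "))
  vapply(m, function(p) as.integer(p[2]) * 7L + as.integer(p[3]), integer(1))
}

#' Classify fetal growth restriction from centile inputs
#'
#' FGR is a birth weight below the 3rd centile, or below the 10th centile
#' together with a Doppler abnormality (umbilical-artery pulsatility index
#' above the 95th centile or cerebroplacental ratio below the 5th centile).
#'
#' @param bw_centile Birth-weight centile in (0, 100); `NA` makes the case
#'   unresolvable (returned as `NA`).
#' @param ua_pi_centile,cpr_centile Optional Doppler centiles.
#' @return Logical vector (`NA` where unresolvable).
#' @export
classify_fgr <- function(bw_centile, ua_pi_centile = NA_real_,
                         cpr_centile = NA_real_) {
  n <- max(length(bw_centile), length(ua_pi_centile), length(cpr_centile))
  bw <- rep_len(bw_centile, n)
  ua <- rep_len(ua_pi_centile, n)
  cpr <- rep_len(cpr_centile, n)
  doppler <- (!is.na(ua) & ua > 95) | (!is.na(cpr) & cpr < 5)
  out <- bw < 3 | (bw < 10 & doppler)
  out[is.na(bw)] <- NA
  out
}

#' Classify pregnancy ending from delivery gestation and signs of life
#'
#' Live births before 37+0 weeks are preterm, otherwise term; births
#' without signs of life at or after 24+0 weeks are stillbirths and at or
#' before 23+6 weeks miscarriages.
#'
#' @param delivery_ga Delivery gestational age: days, or `"w+d"` strings.
#' @param signs_of_life Logical.
#' @return Character vector: `"term"`, `"preterm"`, `"stillbirth"` or
#'   `"miscarriage"` (`NA` where inputs are missing).
#' @export
classify_timing <- function(delivery_ga, signs_of_life) {
  d <- ga_to_days(delivery_ga)
  n <- max(length(d), length(signs_of_life))
  d <- rep_len(d, n); sol <- rep_len(signs_of_life, n)
  out <- rep(NA_character_, n)
  ok <- !is.na(d) & !is.na(sol)
  out[ok & sol & d >= 259L] <- "term"       # 37+0 weeks
  out[ok & sol & d < 259L] <- "preterm"
  out[ok & !sol & d >= 168L] <- "stillbirth"  # 24+0 weeks
  out[ok & !sol & d <= 167L] <- "miscarriage" # 23+6 weeks
  out
}

.EXCLUSION_ORDER <- c("miscarriage", "stillbirth", "termination",
                      "neonatal_death", "preterm", "anomaly", "fgr",
                      "nnu_admission", "diabetes", "hypertensive",
                      "aps_sle", "incomplete_outcome")

.exclusion_flags <- function(records) {
  n <- nrow(records)
  get <- function(col, default = rep(FALSE, n)) {
    if (col %in% names(records)) records[[col]] else default
  }
  timing <- classify_timing(get("delivery_ga_days", rep(NA_integer_, n)),
                            get("signs_of_life", rep(NA, n)))
  termination <- get("termination")
  fgr <- classify_fgr(get("bw_centile", rep(NA_real_, n)),
                      get("ua_pi_centile", rep(NA_real_, n)),
                      get("cpr_centile", rep(NA_real_, n)))
  incomplete <- get("incomplete_outcome") | is.na(fgr) |
    (is.na(timing) & !termination)
  list(
    miscarriage = !is.na(timing) & timing == "miscarriage" & !termination,
    stillbirth = !is.na(timing) & timing == "stillbirth" & !termination,
    termination = termination,
    neonatal_death = get("neonatal_death"),
    preterm = !is.na(timing) & timing == "preterm" & !termination,
    anomaly = get("anomaly"),
    fgr = !is.na(fgr) & fgr,
    nnu_admission = get("nnu_admission"),
    diabetes = get("diabetes"),
    hypertensive = get("hypertensive"),
    aps_sle = get("aps_sle"),
    incomplete_outcome = incomplete
  )
}

#' Apply the healthy-cohort exclusion rules
#'
#' A pregnancy is excluded if any criterion matches: miscarriage,
#' stillbirth, termination, neonatal death, preterm birth, major fetal
#' anomaly, FGR (via [classify_fgr()]), neonatal-unit admission, maternal
#' diabetes, maternal hypertensive disease, antiphospholipid syndrome or
#' SLE, or incomplete outcome data (including unresolvable FGR/timing).
#' The ledger reports per-criterion counts both as any-match and as a
#' flowchart-style first-match sequence in the order listed.
#'
#' @param records Cohort data frame (see [generate_cohort()] columns).
#' @return List with `included`, `excluded`, and `ledger` (tibble:
#'   criterion, n_any, n_first).
#' @export
healthy_cohort_filter <- function(records) {
  stopifnot(is.data.frame(records))
  fl <- .exclusion_flags(records)
  mat <- do.call(cbind, fl)[, .EXCLUSION_ORDER, drop = FALSE]
  any_excl <- rowSums(mat) > 0
  first <- apply(mat, 1L, function(r) if (any(r)) which(r)[1] else NA_integer_)
  ledger <- tibble::tibble(
    criterion = .EXCLUSION_ORDER,
    n_any = unname(colSums(mat)),
    n_first = vapply(seq_along(.EXCLUSION_ORDER),
                     function(i) sum(first == i, na.rm = TRUE), numeric(1)))
  list(included = records[!any_excl, , drop = FALSE],
       excluded = records[any_excl, , drop = FALSE],
       ledger = ledger,
       n_input = nrow(records), n_included = sum(!any_excl),
       n_excluded = sum(any_excl))
}

.pct2 <- function(count, n) round(100 * count / n, 2)

#' Cohort characteristics summary
#'
#' Continuous variables as median (interquartile range, linear-interpolation
#' quantiles), categorical as n (%) with percentages to 2 decimals.
#'
#' @param records Cohort data frame.
#' @param continuous,categorical Variable names; defaults pick the standard
#'   demographic columns present.
#' @return Tibble with one row per variable.
#' @export
cohort_summary <- function(records,
                           continuous = intersect(
                             c("maternal_age", "maternal_weight",
                               "placental_volume", "bw_centile"),
                             names(records)),
                           categorical = intersect(
                             c("female_sex", "smoker", "previous_pe",
                               "diabetes", "hypertensive"),
                             names(records))) {
  if (nrow(records) == 0) stop("empty cohort")
  n <- nrow(records)
  rows <- list()
  for (v in continuous) {
    x <- records[[v]]
    qs <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7,
                          names = FALSE)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      variable = v, type = "continuous",
      summary = sprintf("%.1f (%.1f-%.1f)", qs[2], qs[1], qs[3]),
      median = qs[2], q1 = qs[1], q3 = qs[3],
      count = NA_real_, pct = NA_real_)
  }
  for (v in categorical) {
    cnt <- sum(records[[v]], na.rm = TRUE)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      variable = v, type = "categorical",
      summary = sprintf("%d (%.2f)", cnt, .pct2(cnt, n)),
      median = NA_real_, q1 = NA_real_, q3 = NA_real_,
      count = cnt, pct = .pct2(cnt, n))
  }
  out <- do.call(rbind, rows)
  attr(out, "n") <- n
  out
}

#' Compare included and excluded groups variable-by-variable
#'
#' Continuous variables are compared with the Wilcoxon rank-sum test and
#' categorical variables with Fisher's exact test (standard tests delegated
#' to stats). Variables constant across both groups are skipped with a
#' note. No multiplicity adjustment is applied.
#'
#' @param included,excluded Nonempty data frames with shared columns.
#' @param continuous,categorical Variable names (defaults as in
#'   [cohort_summary()]).
#' @return Tibble: variable, per-group summaries, test, statistic, p_value,
#'   note.
#' @export
compare_excluded <- function(included, excluded,
                             continuous = intersect(
                               c("maternal_age", "maternal_weight",
                                 "placental_volume"), names(included)),
                             categorical = intersect(
                               c("female_sex", "smoker", "previous_pe"),
                               names(included))) {
  if (nrow(included) == 0 || nrow(excluded) == 0)
    stop("both groups must be nonempty")
  n1 <- nrow(included); n2 <- nrow(excluded)
  rows <- list()
  for (v in continuous) {
    x <- included[[v]]; y <- excluded[[v]]
    if (stats::sd(c(x, y), na.rm = TRUE) < 1e-12) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variable = v, included = NA_character_, excluded = NA_character_,
        test = "wilcoxon", statistic = NA_real_, p_value = NA_real_,
        note = "constant variable; test skipped")
      next
    }
    wt <- suppressWarnings(stats::wilcox.test(x, y))
    fmt <- function(z) sprintf("%.1f (%.1f-%.1f)",
                               stats::median(z, na.rm = TRUE),
                               stats::quantile(z, 0.25, na.rm = TRUE),
                               stats::quantile(z, 0.75, na.rm = TRUE))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      variable = v, included = fmt(x), excluded = fmt(y),
      test = "wilcoxon", statistic = unname(wt$statistic),
      p_value = wt$p.value, note = "")
  }
  for (v in categorical) {
    c1 <- sum(included[[v]], na.rm = TRUE)
    c2 <- sum(excluded[[v]], na.rm = TRUE)
    if ((c1 + c2) %in% c(0L, n1 + n2)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        variable = v,
        included = sprintf("%d/%d (%.1f%%)", c1, n1, 100 * c1 / n1),
        excluded = sprintf("%d/%d (%.1f%%)", c2, n2, 100 * c2 / n2),
        test = "fisher", statistic = NA_real_, p_value = NA_real_,
        note = "constant variable; test skipped")
      next
    }
    ft <- stats::fisher.test(matrix(c(c1, n1 - c1, c2, n2 - c2), 2L))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      variable = v,
      included = sprintf("%d/%d (%.1f%%)", c1, n1, 100 * c1 / n1),
      excluded = sprintf("%d/%d (%.1f%%)", c2, n2, 100 * c2 / n2),
      test = "fisher", statistic = unname(ft$estimate),
      p_value = ft$p.value, note = "")
  }
  do.call(rbind, rows)
}

#' Read / write a cohort as tab-delimited text
#'
#' Header row, tab separator, missing values as empty fields.
#'
#' @param records Cohort data frame.
#' @param path File path.
#' @return `read_cohort` returns a tibble.
#' @export
write_cohort <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  tibble::as_tibble(utils::read.delim(path, sep = "\t", na.strings = "",
                                      check.names = FALSE))
}

#' Serialize / restore a fitted chart model as versioned JSON
#'
#' The document carries the family, per-parameter link names, knot vectors,
#' coefficients, smoothing parameters and effective df, plus log-likelihood,
#' AIC and fit metadata — everything needed for exact re-evaluation of the
#' curves.
#'
#' @param model A `fitted_chart_model`.
#' @param path File path.
#' @return `chart_model_from_json` returns the restored model.
#' @export
chart_model_to_json <- function(model, path) {
  stopifnot(inherits(model, "fitted_chart_model"))
  curves <- lapply(model$curves, function(cv) {
    out <- list(type = cv$type, link = cv$link)
    if (cv$type == "pspline") {
      out$knots <- cv$spec$knots; out$degree <- cv$spec$degree
      out$boundary <- cv$spec$boundary
      out$coef <- cv$coef; out$lambda <- cv$lambda; out$edf <- cv$edf
    } else if (cv$type == "constant") {
      out$coef <- cv$coef; out$edf <- cv$edf
    } else out$value <- cv$value
    out
  })
  doc <- list(format = "placentile-chart-model", version = 1L,
              family = model$family, loglik = model$loglik,
              total_edf = model$total_edf, k = model$k, aic = model$aic,
              fit_meta = model$fit_meta[c("cycles", "converged", "n",
                                          "t_range", "edf_targets")],
              curves = curves)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname chart_model_to_json
#' @export
chart_model_from_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "placentile-chart-model"))
    stop("not a chart-model document")
  curves <- lapply(doc$curves, function(cv) {
    if (cv$type == "pspline") {
      list(type = "pspline", link = cv$link,
           spec = list(knots = as.numeric(cv$knots),
                       degree = as.integer(cv$degree),
                       boundary = as.numeric(cv$boundary),
                       K = length(cv$coef)),
           coef = as.numeric(cv$coef), lambda = cv$lambda, edf = cv$edf)
    } else if (cv$type == "constant") {
      list(type = "constant", link = cv$link, coef = as.numeric(cv$coef),
           edf = cv$edf)
    } else list(type = "fixed", link = cv$link, value = cv$value, edf = 0)
  })
  meta <- doc$fit_meta
  meta$t_range <- as.numeric(meta$t_range)
  structure(list(family = doc$family, curves = curves, loglik = doc$loglik,
                 total_edf = doc$total_edf, k = doc$k, aic = doc$aic,
                 fit_meta = meta),
            class = "fitted_chart_model")
}

#' Pipeline run configuration
#'
#' @param series Response columns to model.
#' @param families LMS families to screen.
#' @param edf_grid Per-parameter effective-df grids (see [fit_lms()]).
#' @param k AIC complexity multiplier.
#' @param max_cycles Backfitting cycle cap.
#' @param select Smoothness selection mode for [fit_lms()].
#' @param qr Fit the quantile-regression comparators?
#' @param qr_bases,qr_solvers QR grid (defaults: all six bases, both
#'   solvers).
#' @param target_centiles Chart centiles.
#' @param qc_thresholds Dice triage thresholds.
#' @param iqr_k Tukey fence multiplier.
#' @param seed Seed recorded with outputs.
#' @param out_dir Optional output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(series = paste0("svfmbv", 1:5),
                       families = c("BCPEo", "BCCGo", "SEP1", "SEP3"),
                       edf_grid = NULL, k = 2, max_cycles = 1000,
                       select = "greedy", qr = TRUE,
                       qr_bases = QR_BASES, qr_solvers = QR_SOLVERS,
                       target_centiles = TARGET_CENTILES,
                       qc_thresholds = c(placenta_r1 = 0.60,
                                         placenta_r2 = 0.75, fluid = 0.40),
                       iqr_k = 1.5, seed = 1, out_dir = NULL) {
  structure(list(series = series, families = families, edf_grid = edf_grid,
                 k = k, max_cycles = max_cycles, select = select, qr = qr,
                 qr_bases = qr_bases, qr_solvers = qr_solvers,
                 target_centiles = target_centiles,
                 qc_thresholds = qc_thresholds, iqr_k = iqr_k, seed = seed,
                 out_dir = out_dir),
            class = "run_config")
}

.stage_error <- function(stage, msg) {
  stop(sprintf("[stage: %s] %s", stage, msg), call. = FALSE)
}

#' Run the full chart-construction pipeline
#'
#' Filter to the healthy cohort, apply QC (Dice triage then per-day volume
#' fences), fit the configured LMS and quantile-regression candidates per
#' series, select by AIC, and emit centile tables, calibration reports,
#' Z-scores, the cohort summary and the exclusion ledger. Deterministic for
#' a fixed cohort and configuration.
#'
#' @param cohort Cohort data frame or path to a delimited cohort file.
#' @param config A [run_config()].
#' @return A `pipeline_result` list.
#' @export
run_pipeline <- function(cohort, config = run_config()) {
  set.seed(config$seed)
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (nrow(cohort) == 0) .stage_error("input", "empty cohort")

  filt <- healthy_cohort_filter(cohort)
  if (nrow(filt$included) == 0)
    .stage_error("cohort_filter", "no records pass the healthy-cohort filter")

  qc_in <- filt$included
  triage <- if (all(c("placenta_dice", "fluid_dice") %in% names(qc_in)))
    triage_rounds(qc_in, config$qc_thresholds) else NULL
  keep <- if (is.null(triage)) rep(TRUE, nrow(qc_in))
          else triage$status == "pass"
  qc2 <- qc_in[keep, , drop = FALSE]
  outl <- if ("placental_volume" %in% names(qc2))
    iqr_outliers(qc2$placental_volume, qc2$ga_days, k = config$iqr_k)
    else NULL
  keep2 <- if (is.null(outl)) rep(TRUE, nrow(qc2)) else !outl$outlier
  analysis <- qc2[keep2, , drop = FALSE]
  if (nrow(analysis) == 0) .stage_error("qc", "no records survive QC")

  series_out <- list()
  for (s in config$series) {
    if (!s %in% names(analysis))
      .stage_error("fit", paste("missing series column", s))
    dat <- data.frame(t = analysis$ga_days, y = analysis[[s]])
    cand <- list()
    for (fam in config$families) {
      fit <- tryCatch(
        fit_lms(dat, fam, edf_grid = config$edf_grid, k = config$k,
                max_cycles = config$max_cycles, select = config$select),
        error = function(e) {
          warning(sprintf("LMS %s failed for %s: %s", fam, s,
                          conditionMessage(e)))
          NULL
        })
      if (!is.null(fit) && fit$fit_meta$converged)
        cand[[paste0("LMS_", fam)]] <- fit
    }
    if (isTRUE(config$qr)) {
      for (bs in config$qr_bases) for (sv in config$qr_solvers) {
        m <- tryCatch(
          fit_quantile_curves(dat, bs, sv,
                              quantile_levels = setdiff(
                                config$target_centiles, c(0.01, 0.99))),
          error = function(e) NULL)
        if (!is.null(m)) cand[[paste0("QR_", bs, "_", sv)]] <- m
      }
    }
    if (length(cand) == 0) .stage_error("fit", paste("no candidate for", s))
    sel <- select_best_model(cand)
    best <- sel$best
    chart <- calib <- zs <- NULL
    if (inherits(best, "fitted_chart_model")) {
      chart <- centile_table(best, target_centiles = config$target_centiles)
      calib <- calibration_table(best, dat, config$target_centiles)
      zs <- suppressWarnings(z_score(best, dat$t, dat$y))
    }
    series_out[[s]] <- list(candidates = sel$table, best = best,
                            best_name = sel$table$model[sel$index],
                            centile_table = chart, calibration = calib,
                            z_scores = zs)
  }

  result <- structure(list(
    config = config,
    exclusion = filt[c("ledger", "n_input", "n_included", "n_excluded")],
    triage = triage,
    volume_outliers = outl,
    n_analysis = nrow(analysis),
    analysis_cohort = analysis,
    summary = cohort_summary(analysis),
    series = series_out
  ), class = "pipeline_result")

  if (!is.null(config$out_dir)) .write_pipeline_outputs(result, config$out_dir)
  result
}

.write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(result$exclusion$ledger,
                     file.path(out_dir, "exclusion_ledger.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(result$summary, file.path(out_dir, "cohort_summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  for (s in names(result$series)) {
    so <- result$series[[s]]
    utils::write.table(so$candidates,
                       file.path(out_dir, paste0(s, "_candidates.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (inherits(so$best, "fitted_chart_model")) {
      chart_model_to_json(so$best, file.path(out_dir, paste0(s, "_model.json")))
      utils::write.table(so$centile_table,
                         file.path(out_dir, paste0(s, "_centiles.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(so$calibration$table,
                         file.path(out_dir, paste0(s, "_calibration.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(data.frame(z = so$z_scores),
                         file.path(out_dir, paste0(s, "_zscores.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> input=%d included=%d analysis=%d\n",
              x$exclusion$n_input, x$exclusion$n_included, x$n_analysis))
  for (s in names(x$series))
    cat(sprintf("  %s: best = %s (AIC %.2f)\n", s, x$series[[s]]$best_name,
                if (inherits(x$series[[s]]$best, "fitted_chart_model"))
                  x$series[[s]]$best$aic else x$series[[s]]$best$aic))
  invisible(x)
}
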