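# Segmentation and volumetry quality control: Dice-coefficient triage of
# paired segmentations and per-gestational-day Tukey-fence outlier
# detection on placental volume.

#' Dice similarity coefficient of two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`. Defined as 1 when both masks are empty
#' (logged via message), since two empty segmentations agree perfectly.
#'
#' @param mask_a,mask_b Arrays of identical shape; nonzero entries are
#'   foreground.
#' @return Coefficient in `[0, 1]`.
#' @export
dice <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a), dim(mask_b)) ||
      length(mask_a) != length(mask_b))
    stop("mask shapes differ")
  a <- mask_a != 0; b <- mask_b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) {
    message("dice: both masks empty; returning 1")
    return(1)
  }
  2 * sum(a & b) / denom
}

#' Dice triage of paired segmentations
#'
#' Flags cases for review in three sequential rounds (first match wins):
#' round 1, placental agreement < 0.60 irrespective of fluid agreement;
#' round 2, placental agreement < 0.75 and amniotic-fluid agreement < 0.40;
#' round 3, fluid agreement < 0.40 irrespective of placental agreement.
#' Cases matching no round pass. Missing Dice values make a case
#' unresolvable.
#'
#' @param pairs Data frame with columns `case_id` (optional),
#'   `placenta_dice` and `fluid_dice` in `[0, 1]`.
#' @param thresholds Named numeric: `placenta_r1` (0.60), `placenta_r2`
#'   (0.75), `fluid` (0.40).
#' @return A tibble with per-case `round` (1, 2, 3 or NA for pass),
#'   `status` ("review", "pass" or "unresolvable") and `reason`.
#' @export
triage_rounds <- function(pairs,
                          thresholds = c(placenta_r1 = 0.60,
                                         placenta_r2 = 0.75,
                                         fluid = 0.40)) {
  stopifnot(is.data.frame(pairs),
            all(c("placenta_dice", "fluid_dice") %in% names(pairs)))
  ids <- if ("case_id" %in% names(pairs)) pairs$case_id
         else seq_len(nrow(pairs))
  pd <- pairs$placenta_dice; fd <- pairs$fluid_dice
  ok <- is.finite(pd) & is.finite(fd)
  if (any(ok & (pd < 0 | pd > 1 | fd < 0 | fd > 1)))
    stop("Dice values must lie in [0, 1]")
  round_ <- rep(NA_integer_, length(pd))
  reason <- rep("above all review thresholds", length(pd))
  status <- rep("pass", length(pd))
  r1 <- ok & pd < thresholds[["placenta_r1"]]
  r2 <- ok & !r1 & pd < thresholds[["placenta_r2"]] &
    fd < thresholds[["fluid"]]
  r3 <- ok & !r1 & !r2 & fd < thresholds[["fluid"]]
  round_[r1] <- 1L; round_[r2] <- 2L; round_[r3] <- 3L
  status[r1 | r2 | r3] <- "review"
  reason[r1] <- sprintf("placental Dice < %.2f", thresholds[["placenta_r1"]])
  reason[r2] <- sprintf("placental Dice < %.2f and fluid Dice < %.2f",
                        thresholds[["placenta_r2"]], thresholds[["fluid"]])
  reason[r3] <- sprintf("fluid Dice < %.2f", thresholds[["fluid"]])
  status[!ok] <- "unresolvable"
  reason[!ok] <- "missing Dice value"
  round_[!ok] <- NA_integer_
  tibble::tibble(case_id = ids, placenta_dice = pd, fluid_dice = fd,
                 round = round_, status = status, reason = reason)
}

#' Per-gestational-day Tukey-fence outlier flags
#'
#' Within each day of gestation, computes Q1 and Q3 of placental volume by
#' linear-interpolation sample quantiles (type 7), `IQR = Q3 - Q1`, and
#' flags values strictly below `Q1 - 1.5*IQR` or strictly above
#' `Q3 + 1.5*IQR`. Values exactly on a fence are retained. Day groups
#' smaller than `min_group` are exempt from flagging (reported as such).
#'
#' @param volumes Numeric placental volumes.
#' @param ga_days Gestational day of each volume.
#' @param k Fence multiplier (default 1.5).
#' @param min_group Minimum group size for fences (default 4).
#' @return A tibble with per-observation `ga_days`, `volume`, group `q1`,
#'   `q3`, `fence_low`, `fence_high`, `outlier` flag and `exempt` flag.
#' @export
iqr_outliers <- function(volumes, ga_days, k = 1.5, min_group = 4L) {
  if (length(volumes) == 0) stop("empty input")
  stopifnot(length(volumes) == length(ga_days))
  out <- tibble::tibble(ga_days = ga_days, volume = volumes,
                        q1 = NA_real_, q3 = NA_real_,
                        fence_low = NA_real_, fence_high = NA_real_,
                        outlier = FALSE, exempt = FALSE)
  for (d in unique(ga_days)) {
    i <- which(ga_days == d)
    if (length(i) < min_group) {
      out$exempt[i] <- TRUE
      next
    }
    qs <- stats::quantile(volumes[i], c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- qs[2] - qs[1]
    lo <- qs[1] - k * iqr; hi <- qs[2] + k * iqr
    out$q1[i] <- qs[1]; out$q3[i] <- qs[2]
    out$fence_low[i] <- lo; out$fence_high[i] <- hi
    out$outlier[i] <- volumes[i] < lo | volumes[i] > hi
  }
  out
}
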