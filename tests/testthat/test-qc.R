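test_that("dice coefficient follows the overlap formula", {
  a <- array(0L, c(4, 5, 5)); a[1:2, , ] <- 1L
  expect_equal(dice(a, a), 1)
  b <- array(0L, c(4, 5, 5)); b[3:4, , ] <- 1L
  expect_equal(dice(a, b), 0)
  # |A| = 100, |B| = 100, overlap 50 -> 0.5
  x <- array(0L, c(10, 20)); x[1:100] <- 1L
  y <- array(0L, c(10, 20)); y[51:150] <- 1L
  expect_equal(dice(x, y), 0.5)
  expect_equal(dice(y, x), 0.5)
  expect_error(dice(a, array(0L, c(5, 5, 4))), "shapes differ")
  expect_message(d0 <- dice(array(0L, c(3, 3)), array(0L, c(3, 3))), "empty")
  expect_equal(d0, 1)
})

test_that("triage assigns the first matching round at the stated thresholds", {
  pairs <- data.frame(
    case_id = 1:8,
    placenta_dice = c(0.55, 0.599, 0.60, 0.70, 0.749, 0.75, 0.80, 0.80),
    fluid_dice    = c(0.90, 0.10, 0.39, 0.35, 0.399, 0.39, 0.399, 0.50))
  out <- triage_rounds(pairs)
  expect_equal(out$round, c(1L, 1L, 2L, 2L, 2L, 3L, 3L, NA_integer_))
  expect_equal(out$status,
               c(rep("review", 7), "pass"))
  # boundary values are not below the threshold
  ok <- triage_rounds(data.frame(placenta_dice = 0.60, fluid_dice = 0.40))
  expect_equal(ok$status, "pass")
  # missing values are unresolvable, not silently passed
  miss <- triage_rounds(data.frame(placenta_dice = NA_real_,
                                   fluid_dice = 0.9))
  expect_equal(miss$status, "unresolvable")
  expect_error(triage_rounds(data.frame(placenta_dice = 1.2,
                                        fluid_dice = 0.5)), "\\[0, 1\\]")
})

test_that("per-day fences match hand-computed interpolation quantiles", {
  v <- c(10, 12, 14, 16, 100)
  out <- iqr_outliers(v, rep(85L, 5))
  expect_equal(unique(out$q1), 12)
  expect_equal(unique(out$q3), 16)
  expect_equal(unique(out$fence_low), 6)
  expect_equal(unique(out$fence_high), 22)
  expect_equal(out$outlier, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # all-equal group: IQR 0, any deviant flagged
  out2 <- iqr_outliers(c(5, 5, 5, 5, 7), rep(90L, 5))
  expect_equal(out2$outlier, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # a value exactly on a fence is retained (strict inequality)
  out3 <- iqr_outliers(c(4, 10, 12, 14, 16), rep(91L, 5))
  expect_equal(unique(out3$fence_low), 4)
  expect_false(any(out3$outlier))
  expect_error(iqr_outliers(numeric(0), integer(0)), "empty")
})

test_that("small day groups are exempt and flags are permutation invariant", {
  out <- iqr_outliers(c(1, 2, 100), rep(80L, 3))
  expect_true(all(out$exempt))
  expect_false(any(out$outlier))
  set.seed(81)
  v <- c(rlnorm(40, 3, 0.2), 500)
  d <- rep(c(85L, 86L), length.out = 41)
  base <- iqr_outliers(v, d)
  perm <- sample(41)
  shuf <- iqr_outliers(v[perm], d[perm])
  expect_equal(shuf$outlier[order(perm)], base$outlier)
})
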