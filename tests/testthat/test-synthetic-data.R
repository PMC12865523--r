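test_that("cohort generation is bit-reproducible and respects its ranges", {
  a <- generate_cohort(n = 600, seed = 101)
  b <- generate_cohort(n = 600, seed = 101)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_true(all(a$ga_days >= 79 & a$ga_days <= 99))
  sv <- as.matrix(a[paste0("svfmbv", 1:5)])
  expect_true(all(sv > 0 & sv < 1))
  expect_true(all(a$placental_volume > 0))
  # sparse extremes: mid-window days dominate the tails
  expect_gt(sum(a$ga_days == 89), sum(a$ga_days == 79))
  expect_gt(sum(a$ga_days == 89), sum(a$ga_days == 99))
})

test_that("skewness is positive everywhere and strongest in series 4", {
  co <- generate_cohort(n = 2500, seed = 102)
  skew <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3
  s <- vapply(co[paste0("svfmbv", 1:5)], skew, numeric(1))
  expect_true(all(s > 0))
  expect_gt(s[["svfmbv4"]], s[["svfmbv1"]])
})

test_that("flag prevalences sit inside binomial 99% bounds of the spec", {
  spec <- truth_spec()
  co <- generate_cohort(spec, n = 2500, seed = 103)
  checks <- c(smoker = "smoker", previous_pe = "previous_pe",
              diabetes = "diabetes", nnu_admission = "nnu_admission")
  for (nm in names(checks)) {
    p <- spec$prevalence[[nm]]
    k <- sum(co[[checks[[nm]]]])
    expect_gte(k, stats::qbinom(0.005, 2500, p))
    expect_lte(k, stats::qbinom(0.995, 2500, p))
  }
  k10 <- sum(co$bw_centile < 10)
  expect_gte(k10, stats::qbinom(0.005, 2500, spec$prevalence$bw_lt10))
  expect_lte(k10, stats::qbinom(0.995, 2500, spec$prevalence$bw_lt10))
})

test_that("truth curves are recoverable quantities of the embedded spec", {
  spec <- truth_spec()
  pa <- truth_params(spec, "svfmbv1", c(79, 89, 99))
  expect_true(all(pa$mu > 0 & pa$sigma > 0))
  expect_equal(pa$mu[2], 0.20, tolerance = 1e-12)
  q50 <- truth_quantile(spec, "svfmbv1", 0.5, 89)
  expect_equal(q50, dist_quantile(0.5, dist_params("BCPEo", pa$mu[2],
                                                   pa$sigma[2], pa$nu[2],
                                                   pa$tau[2])))
  expect_error(truth_params(spec, "nope", 89), "unknown series")
})

test_that("mask pairs hit the requested Dice coefficient", {
  p1 <- generate_mask_pair(c(12, 12, 12), 1)
  expect_equal(dice(p1$mask_a, p1$mask_b), 1)
  p0 <- generate_mask_pair(c(12, 12, 12), 0)
  expect_equal(dice(p0$mask_a, p0$mask_b), 0)
  ph <- generate_mask_pair(c(12, 12, 12), 0.5, seed = 104)
  d <- dice(ph$mask_a, ph$mask_b)
  expect_gte(d, 0.48); expect_lte(d, 0.52)
  for (tgt in c(0.3, 0.75, 0.9)) {
    p <- generate_mask_pair(c(15, 10, 10), tgt, seed = 105)
    expect_lt(abs(dice(p$mask_a, p$mask_b) - tgt), 0.02)
  }
  expect_error(generate_mask_pair(c(2, 2, 2), 0.5), "too small")
})

test_that("truth specifications survive a JSON round trip", {
  spec <- truth_spec()
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_spec(spec, path)
  back <- read_truth_spec(path)
  expect_equal(back$series$svfmbv4$nu, spec$series$svfmbv4$nu)
  expect_equal(back$prevalence$smoker, spec$prevalence$smoker)
  co1 <- generate_cohort(spec, n = 50, seed = 106)
  co2 <- generate_cohort(back, n = 50, seed = 106)
  # decimal text serialization is exact only to the last ulp
  expect_equal(co1$svfmbv1, co2$svfmbv1, tolerance = 1e-12)
})
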