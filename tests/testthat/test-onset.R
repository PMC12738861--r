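test_that("onset extraction computes day differences with an exclusion log", {
  reports <- make_reports(
    make_report("1", pts = "A", therapy_start = "2019-01-01",
                event_date = "2019-01-01"),
    make_report("2", pts = "A", therapy_start = "2019-01-10",
                event_date = "2019-01-08"),
    make_report("3", pts = "A", therapy_start = "2019-01-01",
                event_date = "2019-01-15")
  )
  s <- compute_onset(reports)
  expect_equal(sort(s$values), c(0, 14))
  expect_equal(s$exclusions$negative, 1L)
  expect_equal(s$exclusions$raw, s$exclusions$kept +
                 s$exclusions$missing + s$exclusions$negative +
                 s$exclusions$outlier)

  ten <- dplyr::bind_rows(lapply(1:10, function(i) {
    if (i <= 3) make_report(as.character(i), pts = "A")
    else make_report(as.character(i), pts = "A",
                     therapy_start = "2019-01-01",
                     event_date = sprintf("2019-01-%02d", i))
  }))
  s10 <- compute_onset(deduplicate_cases(ten))
  expect_equal(s10$exclusions$kept, 7L)
  expect_equal(unlist(s10$exclusions[c("missing", "negative", "outlier")],
                      use.names = FALSE), c(3L, 0L, 0L))

  # outlier cap is applied and logged
  s_cap <- compute_onset(reports, outlier_cap = 10)
  expect_equal(s_cap$exclusions$outlier, 1L)
  expect_equal(s_cap$values, 0)

  # per-PT restriction
  mixed <- make_reports(
    make_report("1", pts = c("A", "B"), therapy_start = "2019-01-01",
                event_date = "2019-01-03"),
    make_report("2", pts = "B", therapy_start = "2019-01-01",
                event_date = "2019-01-06")
  )
  expect_equal(compute_onset(mixed, pt = "A")$values, 2)
  expect_equal(sort(compute_onset(mixed, pt = "B")$values), c(2, 5))
})

test_that("onset summaries use type-7 percentiles and left-closed first bin", {
  s <- onset_summary(c(0, 0, 1, 1, 2))
  expect_equal(s$summary$median, 1)
  expect_equal(s$summary$q1, 0)
  expect_equal(s$summary$q3, 1)
  expect_equal(s$summary$min, 0)
  expect_equal(s$summary$max, 2)

  one <- onset_summary(5)
  expect_equal(one$summary$median, 5)
  expect_equal(one$summary$min, 5)
  expect_equal(one$summary$max, 5)

  # 330 of 342 in the first bin
  vals <- c(rep(3, 330), rep(45, 12))
  b <- onset_summary(vals)$bins
  expect_equal(b$pct[b$bin == "0-30"], 96.49)
  expect_equal(b$n[b$bin == "31-60"], 12L)
  # day 30 falls in the first bin, day 31 in the second
  b2 <- onset_summary(c(30, 31))$bins
  expect_equal(b2$n[b2$bin == "0-30"], 1L)
  expect_equal(b2$n[b2$bin == "31-60"], 1L)

  expect_error(onset_summary(numeric(0)), class = "pvsignal_usage_error")
})

test_that("Weibull MLE recovers generating parameters", {
  set.seed(91)
  # exponential special case: shape 1
  x <- rexp(10000, rate = 1 / 3)
  fit <- fit_weibull(x, zero_policy = "exclude")
  expect_gt(fit$shape, 0.95)
  expect_lt(fit$shape, 1.05)
  expect_equal(fit$failure_type, "random")

  x2 <- rweibull(10000, shape = 0.597, scale = 4.193)
  fit2 <- fit_weibull(x2, zero_policy = "exclude")
  expect_lt(abs(fit2$shape - 0.597) / 0.597, 0.05)
  expect_lt(abs(fit2$scale - 4.193) / 4.193, 0.05)
  expect_equal(fit2$failure_type, "early")

  # independent MLE oracle (its general-purpose optimizer converges to ~1e-4)
  ref <- fitdistrplus::fitdist(x2, "weibull")
  expect_equal(fit2$shape, unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(fit2$scale, unname(ref$estimate["scale"]), tolerance = 1e-3)

  td <- tidy(fit2)
  expect_equal(td$term, c("scale", "shape"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
})

test_that("the fit is scale-equivariant and handles degenerate input", {
  set.seed(93)
  x <- rweibull(500, shape = 1.4, scale = 10)
  f1 <- fit_weibull(x, zero_policy = "exclude")
  f2 <- fit_weibull(7 * x, zero_policy = "exclude")
  expect_equal(f2$shape, f1$shape, tolerance = 1e-6)
  expect_equal(f2$scale, 7 * f1$scale, tolerance = 1e-6)

  small <- fit_weibull(c(1, 2, 3, 4, 5))
  expect_equal(small$failure_type, "undetermined")
  expect_true(is.na(small$scale))

  expect_error(fit_weibull(rep(2, 50), zero_policy = "exclude"),
               class = "pvsignal_fit_error")
})

test_that("zero handling follows the half-day convention by default", {
  vals <- c(rep(0, 40), rweibull(80, 0.6, 4))
  fit <- fit_weibull(vals)
  expect_equal(fit$n, 120)
  fit_ex <- fit_weibull(vals, zero_policy = "exclude")
  expect_equal(fit_ex$n, 80)
})

test_that("failure classification follows the shape CI rule exhaustively", {
  mk <- function(shape, lo, hi) {
    structure(list(scale = 1, scale_lo = 1, scale_hi = 1, shape = shape,
                   shape_lo = lo, shape_hi = hi, n = 100, loglik = 0,
                   failure_type = NA),
              class = "weibull_fit")
  }
  expect_equal(classify_failure(mk(0.597, 0.513, 0.694)), "early")
  expect_equal(classify_failure(mk(0.935, 0.295, 2.970)), "random")
  expect_equal(classify_failure(mk(2.0, 1.5, 2.5)), "wearout")
  expect_equal(classify_failure(mk(NA, NA, NA)), "undetermined")
  # mutually exclusive and exhaustive over a grid of CIs
  set.seed(95)
  for (i in 1:50) {
    lo <- runif(1, 0.1, 2); hi <- lo + runif(1, 0.01, 2)
    cls <- classify_failure(mk((lo + hi) / 2, lo, hi))
    expected <- if (hi < 1) "early" else if (lo > 1) "wearout" else "random"
    expect_equal(cls, expected)
  }
})

test_that("shape CIs have near-nominal coverage at the study sample size", {
  set.seed(97)
  hits <- vapply(1:500, function(i) {
    x <- rweibull(117, shape = 0.597, scale = 4.193)
    f <- fit_weibull(x, zero_policy = "exclude")
    f$shape_lo <= 0.597 && 0.597 <= f$shape_hi
  }, logical(1))
  expect_gte(mean(hits), 0.90)
  expect_lte(mean(hits), 0.98)
})

test_that("Kaplan-Meier equals the ECDF without censoring", {
  km <- km_estimate(c(1, 2, 3))
  expect_equal(km$cuminc[km$time == 2], 2 / 3)
  # product-limit with one censored subject, by hand:
  # S(1) = 1 - 1/2 = 0.5, flat afterwards
  km2 <- km_estimate(1, censor_times = 2)
  expect_equal(km2$cuminc[km2$time == 1], 0.5)
  expect_equal(max(km2$cuminc), 0.5)

  set.seed(99)
  x <- round(rweibull(200, 0.7, 5))
  km3 <- km_estimate(x)
  ecdf_x <- ecdf(x)
  expect_equal(km3$cuminc, unname(ecdf_x(km3$time)), tolerance = 1e-12)
  expect_true(all(diff(km3$cuminc) >= 0))

  expect_error(km_estimate(numeric(0)), class = "pvsignal_usage_error")
})
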