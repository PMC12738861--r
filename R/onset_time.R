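# Time-to-onset analysis: onset extraction with an auditable exclusion log,
# descriptive summaries, Weibull maximum-likelihood fitting with
# failure-type classification, and Kaplan-Meier cumulative incidence.

#' Extract onset durations from a report collection
#'
#' Onset is `event_date - therapy_start` in whole days. Reports missing
#' either date are excluded as `missing`, negative durations as `negative`,
#' and durations above `outlier_cap` as `outlier`; every exclusion is
#' counted so the rule applied is auditable (`raw = kept + excluded`).
#'
#' @param reports A `safety_reports` tibble.
#' @param pt Optional preferred term: restrict to reports mentioning it.
#' @param outlier_cap Upper cap in days (default `Inf`: no cap).
#' @return An `onset_sample`: list with `values` (days), `label`, and
#'   `exclusions` (tibble with `missing`, `negative`, `outlier`, `raw`,
#'   `kept`).
#' @export
compute_onset <- function(reports, pt = NULL, outlier_cap = Inf) {
  if (!is.null(pt)) {
    keep <- vapply(reports$pts, function(p) pt %in% p, logical(1))
    reports <- reports[keep, , drop = FALSE]
  }
  raw_n <- nrow(reports)
  onset <- as.numeric(reports$event_date - reports$therapy_start)
  missing <- is.na(onset)
  negative <- !missing & onset < 0
  outlier <- !missing & !negative & onset > outlier_cap
  values <- onset[!missing & !negative & !outlier]
  structure(
    list(
      values = values,
      label = pt %||% "all events",
      exclusions = tibble(
        missing = sum(missing), negative = sum(negative),
        outlier = sum(outlier), raw = raw_n, kept = length(values)
      )
    ),
    class = "onset_sample"
  )
}

#' @export
print.onset_sample <- function(x, ...) {
  ex <- x$exclusions
  cat("<onset_sample> '", x$label, "': ", ex$kept, " onsets kept of ", ex$raw,
      " reports (", ex$missing, " missing, ", ex$negative, " negative, ",
      ex$outlier, " outlier)\n", sep = "")
  invisible(x)
}

#' Summarize an onset sample
#'
#' Median, interquartile range, minimum and maximum use the type-7
#' (linear-interpolation) percentile convention. Binning is closed on both
#' ends for the first bin and on the right thereafter:
#' `[0, 30], (30, 60], ...` days.
#'
#' @param sample An `onset_sample` (or numeric vector of days).
#' @param bins Upper bin edges in days; a final open-ended bin is added.
#' @return List with `summary` (tibble: `n`, `median`, `q1`, `q3`, `min`,
#'   `max`) and `bins` (tibble: `bin`, `n`, `pct` with `pct` rounded to 2
#'   decimals).
#' @export
onset_summary <- function(sample, bins = c(30, 60, 90, 180, 360)) {
  values <- if (inherits(sample, "onset_sample")) sample$values else sample
  if (length(values) == 0) {
    abort("cannot summarize an empty onset sample",
          class = "pvsignal_usage_error")
  }
  qs <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  breaks <- c(-Inf, bins, Inf)
  labels <- c(
    paste0("0-", bins[1]),
    if (length(bins) > 1) {
      paste0(bins[-length(bins)] + 1, "-", bins[-1])
    },
    paste0(">", bins[length(bins)])
  )
  cut_bins <- cut(values, breaks = breaks, labels = labels, right = TRUE)
  bin_tbl <- tibble(bin = labels) |>
    dplyr::left_join(
      tibble(bin = as.character(cut_bins)) |> dplyr::count(bin),
      by = "bin"
    ) |>
    dplyr::mutate(
      n = dplyr::coalesce(n, 0L),
      pct = round(100 * n / length(values), 2)
    )
  list(
    summary = tibble(n = length(values), median = qs[2], q1 = qs[1],
                     q3 = qs[3], min = min(values), max = max(values)),
    bins = bin_tbl
  )
}

# profile log-likelihood machinery for the two-parameter Weibull
weibull_profile_shape <- function(x) {
  lx <- log(x)
  # x^k written via exp(k log x - max) so large shapes do not overflow
  score <- function(k) {
    w <- exp(k * lx - max(k * lx))
    1 / k + mean(lx) - sum(w * lx) / sum(w)
  }
  uniroot(score, lower = 1e-3, upper = 500, tol = 1e-10)$root
}

weibull_negloglik_logpar <- function(theta, x) {
  scale <- exp(theta[1]); shape <- exp(theta[2])
  -sum(stats::dweibull(x, shape = shape, scale = scale, log = TRUE))
}

#' Fit a Weibull distribution to onset durations by maximum likelihood
#'
#' The shape is found by Newton-bracketed root-finding on the profile score
#' (the scale has a closed form given the shape). 95% confidence intervals
#' come from the observed information on the log-parameters, exponentiated
#' back, which keeps bounds positive and yields the asymmetric intervals
#' typical of reported onset-time fits. Day-zero onsets are shifted to half
#' a day by default: dates have day resolution, so a same-day event is
#' best represented as 12 hours, and Weibull support is positive.
#'
#' Samples with fewer than `min_n` usable values are not fitted and return
#' an `undetermined` classification, mirroring the usual "too few cases to
#' analyze" footnote.
#'
#' @param sample An `onset_sample` or numeric vector of days.
#' @param zero_policy `"half_day"` (0 becomes 0.5) or `"exclude"` (zeros
#'   dropped before fitting).
#' @param min_n Minimum usable sample size (default 10).
#' @param conf_level Confidence level for the intervals.
#' @return A `weibull_fit`: `scale`, `shape` with `*_lo`/`*_hi` bounds,
#'   `n`, `loglik`, and `failure_type` from [classify_failure()].
#' @export
fit_weibull <- function(sample, zero_policy = c("half_day", "exclude"),
                        min_n = 10, conf_level = 0.95) {
  zero_policy <- rlang::arg_match(zero_policy)
  x <- if (inherits(sample, "onset_sample")) sample$values else as.numeric(sample)
  x <- x[!is.na(x)]
  if (zero_policy == "half_day") {
    x[x == 0] <- 0.5
  } else {
    x <- x[x > 0]
  }
  if (length(x) < min_n) {
    fit <- structure(
      list(scale = NA_real_, scale_lo = NA_real_, scale_hi = NA_real_,
           shape = NA_real_, shape_lo = NA_real_, shape_hi = NA_real_,
           n = length(x), loglik = NA_real_, failure_type = "undetermined"),
      class = "weibull_fit"
    )
    return(fit)
  }
  if (length(unique(x)) == 1) {
    abort("all onset values identical: Weibull fit is degenerate",
          class = "pvsignal_fit_error")
  }
  shape <- weibull_profile_shape(x)
  scale <- mean(x^shape)^(1 / shape)
  theta <- c(log(scale), log(shape))
  H <- optimHess(theta, weibull_negloglik_logpar, x = x)
  se <- sqrt(diag(solve(H)))
  z <- qnorm(1 - (1 - conf_level) / 2)
  fit <- structure(
    list(
      scale = scale,
      scale_lo = exp(theta[1] - z * se[1]), scale_hi = exp(theta[1] + z * se[1]),
      shape = shape,
      shape_lo = exp(theta[2] - z * se[2]), shape_hi = exp(theta[2] + z * se[2]),
      n = length(x),
      loglik = -weibull_negloglik_logpar(theta, x),
      failure_type = NA_character_
    ),
    class = "weibull_fit"
  )
  fit$failure_type <- classify_failure(fit)
  fit
}

#' Classify the hazard-over-time pattern from the Weibull shape CI
#'
#' `early` when the shape's CI upper bound is below 1 (decreasing hazard),
#' `wearout` when its lower bound exceeds 1 (increasing hazard), `random`
#' when the CI contains 1 (constant hazard), `undetermined` when there is
#' no fit. The rule is exhaustive and mutually exclusive over valid CIs.
#'
#' @param fit A `weibull_fit`.
#' @return One of `"early"`, `"random"`, `"wearout"`, `"undetermined"`.
#' @export
classify_failure <- function(fit) {
  if (is.na(fit$shape) || is.na(fit$shape_lo) || is.na(fit$shape_hi)) {
    return("undetermined")
  }
  if (fit$shape_hi < 1) return("early")
  if (fit$shape_lo > 1) return("wearout")
  "random"
}

#' @export
print.weibull_fit <- function(x, ...) {
  if (is.na(x$scale)) {
    cat("<weibull_fit> not fitted (n = ", x$n, "), failure type undetermined\n",
        sep = "")
    return(invisible(x))
  }
  cat(sprintf(
    "<weibull_fit> n = %d\n  scale %.3f (%.3f, %.3f) days\n  shape %.3f (%.3f, %.3f)\n  failure type: %s\n",
    x$n, x$scale, x$scale_lo, x$scale_hi, x$shape, x$shape_lo, x$shape_hi,
    x$failure_type))
  invisible(x)
}

#' @method tidy weibull_fit
#' @export
tidy.weibull_fit <- function(x, ...) {
  tibble(
    term = c("scale", "shape"),
    estimate = c(x$scale, x$shape),
    conf.low = c(x$scale_lo, x$shape_lo),
    conf.high = c(x$scale_hi, x$shape_hi)
  )
}

#' @method glance weibull_fit
#' @export
glance.weibull_fit <- function(x, ...) {
  tibble(n = x$n, logLik = x$loglik, failure_type = x$failure_type)
}

#' Kaplan-Meier cumulative incidence of onset
#'
#' Product-limit estimate via [survival::survfit()]. With no censoring the
#' cumulative incidence at `t` equals the empirical CDF at `t` exactly.
#'
#' @param sample An `onset_sample` or numeric vector of event times (days).
#' @param censor_times Optional numeric vector of right-censoring times
#'   contributing risk but no events.
#' @return A `km_curve` tibble: `time`, `n_risk`, `n_event`, `surv`,
#'   `cuminc` (`= 1 - surv`, nondecreasing).
#' @export
km_estimate <- function(sample, censor_times = NULL) {
  values <- if (inherits(sample, "onset_sample")) sample$values else sample
  if (length(values) == 0) {
    abort("cannot estimate a survival curve from an empty sample",
          class = "pvsignal_usage_error")
  }
  time <- c(values, censor_times)
  status <- c(rep(1, length(values)), rep(0, length(censor_times)))
  sf <- survival::survfit(survival::Surv(time, status) ~ 1)
  out <- tibble(
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
    surv = sf$surv, cuminc = 1 - sf$surv
  )
  class(out) <- c("km_curve", class(tibble()))
  out
}
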