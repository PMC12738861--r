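# The four disproportionality statistics and the joint signal criterion.
#
# On the 2x2 table (a, b; c, d) with N = a + b + c + d and expected count
# E = (a + b)(a + c) / N:
#   ROR = (a d) / (b c),  95% CI exp(ln ROR +/- 1.96 sqrt(1/a+1/b+1/c+1/d))
#   PRR = [a / (a + b)] / [c / (c + d)],  with the Pearson chi-squared
#   IC  = shrunk log2 observed-to-expected (two standard variants below)
#   EBGM = posterior geometric mean of the relative reporting rate under the
#          two-component gamma mixture prior (see mgps.R)
# A preferred term is a signal when it passes all four method thresholds.

as_abcd <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.data.frame(a) || is.list(a)) {
    stopifnot(all(c("a", "b", "c", "d") %in% names(a)))
    list(a = as.numeric(a$a), b = as.numeric(a$b),
         c = as.numeric(a$c), d = as.numeric(a$d))
  } else {
    list(a = as.numeric(a), b = as.numeric(b),
         c = as.numeric(c), d = as.numeric(d))
  }
}

expected_count <- function(t) (t$a + t$b) * (t$a + t$c) / (t$a + t$b + t$c + t$d)

#' Reporting odds ratio with Woolf confidence interval
#'
#' `ROR = (a d)/(b c)` with the log-normal (Woolf) interval
#' `exp(ln ROR +/- z sqrt(1/a + 1/b + 1/c + 1/d))`. With any zero cell the
#' estimate is undefined-flagged (`NA`) unless the Haldane-Anscombe 0.5
#' correction is requested; undefined results fail signal criteria closed.
#'
#' @param a Either the `a` cell (with `b`, `c`, `d` supplied) or a
#'   data-frame-like object with columns `a`, `b`, `c`, `d` (e.g. a
#'   `table_set`). Vectorized.
#' @param b,c,d Remaining cells when `a` is numeric.
#' @param conf_level Confidence level (default 0.95).
#' @param haldane Add 0.5 to every cell when any cell is zero?
#' @return Tibble with columns `ror`, `ror_lo`, `ror_hi`.
#' @export
#' @examples
#' compute_ror(5, 5, 5, 45) # ROR = 9
compute_ror <- function(a, b = NULL, c = NULL, d = NULL,
                        conf_level = 0.95, haldane = FALSE) {
  t <- as_abcd(a, b, c, d)
  z <- qnorm(1 - (1 - conf_level) / 2)
  zero <- t$a == 0 | t$b == 0 | t$c == 0 | t$d == 0
  aa <- t$a; bb <- t$b; cc <- t$c; dd <- t$d
  if (haldane) {
    aa <- ifelse(zero, aa + 0.5, aa); bb <- ifelse(zero, bb + 0.5, bb)
    cc <- ifelse(zero, cc + 0.5, cc); dd <- ifelse(zero, dd + 0.5, dd)
    zero <- rep(FALSE, length(aa))
  }
  ror <- (aa * dd) / (bb * cc)
  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  out <- tibble(
    ror = ifelse(zero, NA_real_, ror),
    ror_lo = ifelse(zero, NA_real_, exp(log(ror) - z * se)),
    ror_hi = ifelse(zero, NA_real_, exp(log(ror) + z * se))
  )
  out
}

#' Proportional reporting ratio with Pearson chi-squared
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`; the chi-squared statistic is the
#' uncorrected Pearson statistic on the 2x2,
#' `(ad - bc)^2 N / ((a+b)(c+d)(a+c)(b+d))`, with an optional Yates
#' continuity correction. `c = 0` (or an empty margin) gives an
#' undefined-flagged result.
#'
#' @inheritParams compute_ror
#' @param yates Apply the Yates continuity correction to the chi-squared?
#' @return Tibble with columns `prr`, `chi2`.
#' @export
compute_prr <- function(a, b = NULL, c = NULL, d = NULL, yates = FALSE) {
  t <- as_abcd(a, b, c, d)
  N <- t$a + t$b + t$c + t$d
  undef <- t$c == 0 | (t$a + t$b) == 0 | (t$c + t$d) == 0
  prr <- (t$a / (t$a + t$b)) / (t$c / (t$c + t$d))
  dev <- abs(t$a * t$d - t$b * t$c)
  if (yates) dev <- pmax(dev - N / 2, 0)
  chi2 <- dev^2 * N /
    ((t$a + t$b) * (t$c + t$d) * (t$a + t$c) * (t$b + t$d))
  tibble(
    prr = ifelse(undef, NA_real_, prr),
    chi2 = ifelse(undef, NA_real_, chi2)
  )
}

#' Bayesian confidence propagation neural network information component
#'
#' Two standard formulations of the shrunk log2 observed-to-expected
#' measure are provided:
#'
#' * `"noren_closed_form"` (default): `IC = log2((a + 0.5)/(E + 0.5))` with
#'   the closed-form credibility bound
#'   `IC025 = IC - 3.3 (a + 0.5)^(-1/2) - 2 (a + 0.5)^(-3/2)`.
#' * `"bate_gaussian"`: the posterior expectation and variance of
#'   `log2[P(x, y) / (P(x) P(y))]` under the original Beta/Dirichlet priors,
#'   with `IC025` the Gaussian lower 95% bound.
#'
#' Both converge to `log2(a / E)` as the count grows with `a / E` fixed.
#'
#' @inheritParams compute_ror
#' @param variant Which formulation to use.
#' @return Tibble with columns `ic`, `ic025`.
#' @export
compute_ic <- function(a, b = NULL, c = NULL, d = NULL,
                       variant = c("noren_closed_form", "bate_gaussian")) {
  variant <- rlang::arg_match(variant)
  t <- as_abcd(a, b, c, d)
  N <- t$a + t$b + t$c + t$d
  E <- expected_count(t)
  if (any(E <= 0)) {
    abort("information component requires expected count E > 0",
          class = "pvsignal_usage_error")
  }
  if (variant == "noren_closed_form") {
    ic <- log2((t$a + 0.5) / (E + 0.5))
    ic025 <- ic - 3.3 * (t$a + 0.5)^(-0.5) - 2 * (t$a + 0.5)^(-1.5)
    return(tibble(ic = ic, ic025 = ic025))
  }
  # Bate et al. Gaussian approximation with the customary priors
  # alpha1 = beta1 = 1 (margins), alpha = beta = 2, gamma11 = 1
  a1 <- 1; b1 <- 1; al <- 2; be <- 2; g11 <- 1
  nx <- t$a + t$b; ny <- t$a + t$c
  g <- g11 * (N + al) * (N + be) / ((nx + a1) * (ny + b1))
  e_ic <- log2(((t$a + g11) * (N + al) * (N + be)) /
                 ((N + g) * (nx + a1) * (ny + b1)))
  v_ic <- ((N - t$a + g - g11) / ((t$a + g11) * (1 + N + g)) +
             (N - nx + al - a1) / ((nx + a1) * (1 + N + al)) +
             (N - ny + be - b1) / ((ny + b1) * (1 + N + be))) / log(2)^2
  tibble(ic = e_ic, ic025 = e_ic - qnorm(0.975) * sqrt(v_ic))
}

#' Signal thresholds for the four disproportionality methods
#'
#' Defaults are the standard published criteria: ROR requires at least 3
#' target-drug reports of the event and a 95% CI lower bound above 1; PRR
#' requires `PRR >= 2`, `chi-squared >= 4` and `a >= 3`; BCPNN requires
#' `IC025 > 0`; MGPS requires `EBGM05 > 2`. All are configurable.
#'
#' @param ror_min_a,ror_ci_lower ROR rule: minimum count, CI lower bound.
#' @param prr_min,prr_chi2_min,prr_min_a PRR rule.
#' @param ic025_min BCPNN rule on the IC credibility lower bound.
#' @param ebgm05_min MGPS rule on the posterior 5th percentile.
#' @return A `signal_thresholds` list.
#' @export
signal_thresholds <- function(ror_min_a = 3, ror_ci_lower = 1,
                              prr_min = 2, prr_chi2_min = 4, prr_min_a = 3,
                              ic025_min = 0, ebgm05_min = 2) {
  structure(
    list(ror_min_a = ror_min_a, ror_ci_lower = ror_ci_lower,
         prr_min = prr_min, prr_chi2_min = prr_chi2_min, prr_min_a = prr_min_a,
         ic025_min = ic025_min, ebgm05_min = ebgm05_min),
    class = "signal_thresholds"
  )
}

#' Compute all four disproportionality statistics for a table set
#'
#' Runs ROR, PRR + chi-squared, the information component, and (when a prior
#' is supplied or fittable) the empirical-Bayes geometric mean for every
#' event in the set.
#'
#' @param table_set A `table_set` from [build_pt_tables()] /
#'   [build_soc_tables()].
#' @param prior An `mgps_prior`; `NULL` fits one on the set when it holds at
#'   least 10 events (otherwise EBGM columns are `NA`, marked unavailable).
#' @param ic_variant Passed to [compute_ic()].
#' @return A `signal_result` tibble: the table cells plus `expected`, `ror`,
#'   `ror_lo`, `ror_hi`, `prr`, `chi2`, `ic`, `ic025`, `ebgm`, `ebgm05`.
#' @export
signal_stats <- function(table_set, prior = NULL,
                         ic_variant = "noren_closed_form") {
  out <- as_tibble(table_set)
  if (nrow(out) == 0) {
    out <- tibble(event = character(), level = character(), a = integer(),
                  b = integer(), c = integer(), d = integer())
  }
  t <- as_abcd(out)
  out$expected <- if (nrow(out)) expected_count(t) else double()
  out <- dplyr::bind_cols(
    out,
    compute_ror(out),
    compute_prr(out),
    if (nrow(out)) compute_ic(out, variant = ic_variant)
    else tibble(ic = double(), ic025 = double())
  )
  if (is.null(prior) && nrow(out) >= 10) {
    prior <- fit_mgps_prior(table_set)
  }
  if (!is.null(prior) && nrow(out) > 0) {
    eb <- compute_ebgm(out$a, out$expected, prior)
    out$ebgm <- eb$ebgm
    out$ebgm05 <- eb$ebgm05
  } else {
    out$ebgm <- NA_real_
    out$ebgm05 <- NA_real_
  }
  class(out) <- c("signal_result", class(tibble()))
  attr(out, "drug") <- attr(table_set, "drug")
  attr(out, "prior") <- prior
  out
}

#' Apply the per-method and joint signal criteria
#'
#' Adds one logical column per method and the joint verdict (the AND of the
#' four). Undefined-flagged statistics (`NA`) fail their rule: a zero-cell
#' table can never be declared a signal by accident.
#'
#' @param results A `signal_result` tibble from [signal_stats()].
#' @param thresholds A [signal_thresholds()].
#' @return `results` with added columns `ror_pos`, `prr_pos`, `bcpnn_pos`,
#'   `mgps_pos`, `joint`.
#' @export
apply_thresholds <- function(results, thresholds = signal_thresholds()) {
  th <- thresholds
  results$ror_pos <- !is.na(results$ror_lo) &
    results$a >= th$ror_min_a & results$ror_lo > th$ror_ci_lower
  results$prr_pos <- !is.na(results$prr) &
    results$prr >= th$prr_min & results$chi2 >= th$prr_chi2_min &
    results$a >= th$prr_min_a
  results$bcpnn_pos <- !is.na(results$ic025) & results$ic025 > th$ic025_min
  results$mgps_pos <- !is.na(results$ebgm05) & results$ebgm05 > th$ebgm05_min
  results$joint <- results$ror_pos & results$prr_pos & results$bcpnn_pos &
    results$mgps_pos
  results
}

#' Detect signals: events passing all four method criteria
#'
#' @inheritParams signal_stats
#' @inheritParams apply_thresholds
#' @return A `signal_result` tibble restricted to joint-positive events,
#'   sorted by count then EBGM descending (deterministic; event name breaks
#'   remaining ties).
#' @export
detect_signals <- function(table_set, thresholds = signal_thresholds(),
                           prior = NULL, ic_variant = "noren_closed_form") {
  res <- signal_stats(table_set, prior = prior, ic_variant = ic_variant)
  res <- apply_thresholds(res, thresholds)
  out <- res[res$joint, , drop = FALSE]
  out[order(-out$a, -xtfrm(out$ebgm), out$event), , drop = FALSE]
}

#' Intersect signal lists across databases
#'
#' @param x,y Signal lists: `signal_result` tibbles (keyed on `event`) or
#'   character vectors of event names, in the same vocabulary.
#' @return A `signal_overlap` list: `shared`, `only_x`, `only_y` (sorted
#'   character vectors) and their counts `n_shared`, `n_only_x`, `n_only_y`.
#' @export
intersect_signals <- function(x, y) {
  ev <- function(z) {
    if (is.character(z)) unique(z) else unique(as_tibble(z)$event)
  }
  ex <- ev(x); ey <- ev(y)
  structure(
    list(
      shared = sort(intersect(ex, ey)),
      only_x = sort(setdiff(ex, ey)),
      only_y = sort(setdiff(ey, ex)),
      n_shared = length(intersect(ex, ey)),
      n_only_x = length(setdiff(ex, ey)),
      n_only_y = length(setdiff(ey, ex))
    ),
    class = "signal_overlap"
  )
}

#' @export
print.signal_overlap <- function(x, ...) {
  cat("<signal_overlap> shared ", x$n_shared, ", first-only ", x$n_only_x,
      ", second-only ", x$n_only_y, "\n", sep = "")
  invisible(x)
}
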