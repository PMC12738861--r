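# Multi-item gamma-Poisson shrinker: DuMouchel's two-component gamma
# mixture empirical-Bayes model. The observed count a for an event with
# expected count E is modelled as Poisson(lambda E) with the relative
# reporting rate lambda drawn from
#   w Gamma(alpha1, beta1) + (1 - w) Gamma(alpha2, beta2)   (rate form),
# so marginally a is a two-component negative-binomial mixture. The
# hyperparameters are fitted by maximizing the marginal likelihood across
# all events of a table set; the posterior for each event is again a
# two-gamma mixture with updated shapes/rates and weight, from which the
# geometric mean (EBGM) and posterior percentiles (EBGM05) follow.

#' Construct gamma-mixture prior parameters
#'
#' @param alpha1,beta1 Shape and rate of the first gamma component.
#' @param alpha2,beta2 Shape and rate of the second component.
#' @param w Mixture weight on the first component, in `(0, 1]`; `w = 1`
#'   degenerates to a single gamma (useful as a closed-form oracle).
#' @param converged,loglik,n_events Fit metadata (filled by
#'   [fit_mgps_prior()]).
#' @return An `mgps_prior` object.
#' @export
mgps_prior <- function(alpha1, beta1, alpha2 = alpha1, beta2 = beta1,
                       w = 1, converged = NA, loglik = NA_real_,
                       n_events = NA_integer_) {
  if (any(c(alpha1, beta1, alpha2, beta2) <= 0) || w <= 0 || w > 1) {
    abort("gamma hyperparameters must be positive and w in (0, 1]",
          class = "pvsignal_usage_error")
  }
  structure(
    list(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2, beta2 = beta2,
         w = w, converged = converged, loglik = loglik, n_events = n_events),
    class = "mgps_prior"
  )
}

#' @export
print.mgps_prior <- function(x, ...) {
  cat(sprintf(
    "<mgps_prior> w = %.3f, Gamma(%.3f, %.3f) (mean %.2f) + Gamma(%.3f, %.3f) (mean %.2f)\n",
    x$w, x$alpha1, x$beta1, x$alpha1 / x$beta1,
    x$alpha2, x$beta2, x$alpha2 / x$beta2))
  if (!is.na(x$converged)) {
    cat("  fitted on ", x$n_events, " events, logLik ", round(x$loglik, 3),
        if (isTRUE(x$converged)) ", converged" else ", NOT converged", "\n",
        sep = "")
  }
  invisible(x)
}

# log marginal likelihood of counts a with expecteds E under the mixture
mgps_logmarg <- function(a, E, alpha1, beta1, alpha2, beta2, w) {
  l1 <- dnbinom(a, size = alpha1, prob = beta1 / (beta1 + E), log = TRUE)
  l2 <- dnbinom(a, size = alpha2, prob = beta2 / (beta2 + E), log = TRUE)
  m <- pmax(l1, l2)
  m + log(w * exp(l1 - m) + (1 - w) * exp(l2 - m))
}

#' Fit the two-gamma empirical-Bayes prior over a table set
#'
#' Maximizes the marginal (negative-binomial mixture) likelihood of the
#' observed counts given their expecteds across all events. The optimizer
#' runs from the canonical starting values `(0.2, 0.1, 2, 4, 1/3)` plus
#' four fixed perturbed restarts, on log/logit-transformed parameters, and
#' keeps the best converged solution (tolerance 1e-8 on the relative change
#' of the negative log marginal likelihood).
#'
#' @param table_set A `table_set`, or any data frame with columns `a` and
#'   either `expected` or the cells `b`, `c`, `d`; at least 10 events with
#'   positive expected count are required.
#' @return An `mgps_prior` with fit metadata. If no start converges the fit
#'   errors, carrying the best-so-far parameters in the condition.
#' @export
fit_mgps_prior <- function(table_set) {
  df <- as_tibble(table_set)
  if (!"expected" %in% names(df)) {
    df$expected <- expected_count(as_abcd(df))
  }
  df <- df[is.finite(df$expected) & df$expected > 0, , drop = FALSE]
  if (nrow(df) < 10) {
    abort("MGPS prior fit needs at least 10 events with positive expected count",
          class = "pvsignal_usage_error")
  }
  a <- as.numeric(df$a)
  E <- as.numeric(df$expected)

  nll <- function(theta) {
    p <- exp(theta[1:4])
    w <- stats::plogis(theta[5])
    if (any(!is.finite(p)) || any(p > 1e6) || any(p < 1e-8)) return(1e12)
    val <- -sum(mgps_logmarg(a, E, p[1], p[2], p[3], p[4], w))
    if (!is.finite(val)) 1e12 else val
  }

  canonical <- c(0.2, 0.1, 2, 4, 1 / 3)
  # fixed multiplicative jitters: deterministic restarts, no RNG involved
  jitters <- list(
    c(1, 1, 1, 1, 1),
    c(2.5, 2.5, 0.5, 0.5, 1.5),
    c(0.4, 0.4, 2, 2, 0.6),
    c(1, 0.2, 4, 1, 1),
    c(3, 1, 0.8, 3, 0.9)
  )
  best <- NULL
  for (jt in jitters) {
    start <- canonical * jt
    theta0 <- c(log(start[1:4]), stats::qlogis(min(start[5], 0.9)))
    fit <- tryCatch(
      optim(theta0, nll, method = "Nelder-Mead",
            control = list(maxit = 5000, reltol = 1e-8)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) {
      best <- fit
    }
  }
  if (is.null(best)) {
    abort("MGPS prior fit failed from every start",
          class = "pvsignal_fit_error")
  }
  p <- exp(best$par[1:4])
  w <- stats::plogis(best$par[5])
  converged <- best$convergence == 0
  prior <- mgps_prior(p[1], p[2], p[3], p[4], w,
                      converged = converged, loglik = -best$value,
                      n_events = length(a))
  if (!converged) {
    abort("MGPS prior fit did not converge from any start",
          class = "pvsignal_fit_error", prior = prior)
  }
  prior
}

#' Empirical-Bayes geometric mean and posterior 5th percentile
#'
#' The posterior of the relative reporting rate given `(a, E)` is the
#' two-gamma mixture with components `Gamma(alpha_j + a, beta_j + E)` and
#' updated weight proportional to the component marginal likelihoods. Then
#' `EBGM = 2^(E[log2 lambda | a, E]) = exp(E[ln lambda])` using
#' `E[ln Gamma(s, r)] = digamma(s) - ln r`, and `EBGM05` is the posterior
#' 5th percentile, located by bracketed root-finding on the mixture CDF.
#' (By the "lower limit of the 95% interval" convention of the field's
#' tabulations this is the one-sided EB05 bound; set `percentile = 0.025`
#' for the two-sided variant.)
#'
#' @param a Observed counts (vectorized).
#' @param E Expected counts.
#' @param prior An `mgps_prior`.
#' @param percentile Lower-tail probability for the bound (default 0.05).
#' @return Tibble with columns `ebgm`, `ebgm05`.
#' @export
compute_ebgm <- function(a, E, prior, percentile = 0.05) {
  stopifnot(inherits(prior, "mgps_prior"))
  if (any(E <= 0)) {
    abort("EBGM requires expected count E > 0", class = "pvsignal_usage_error")
  }
  a <- as.numeric(a); E <- as.numeric(E)
  s1 <- prior$alpha1 + a; r1 <- prior$beta1 + E
  s2 <- prior$alpha2 + a; r2 <- prior$beta2 + E
  if (prior$w == 1) {
    q <- rep(1, length(a))
  } else {
    l1 <- log(prior$w) +
      dnbinom(a, size = prior$alpha1, prob = prior$beta1 / (prior$beta1 + E),
              log = TRUE)
    l2 <- log(1 - prior$w) +
      dnbinom(a, size = prior$alpha2, prob = prior$beta2 / (prior$beta2 + E),
              log = TRUE)
    m <- pmax(l1, l2)
    q <- exp(l1 - m) / (exp(l1 - m) + exp(l2 - m))
  }
  ebgm <- exp(q * (digamma(s1) - log(r1)) + (1 - q) * (digamma(s2) - log(r2)))
  ebgm05 <- vapply(seq_along(a), function(i) {
    if (q[i] >= 1 - 1e-12) {
      return(qgamma(percentile, shape = s1[i], rate = r1[i]))
    }
    if (q[i] <= 1e-12) {
      return(qgamma(percentile, shape = s2[i], rate = r2[i]))
    }
    cdf <- function(x) {
      q[i] * pgamma(x, shape = s1[i], rate = r1[i]) +
        (1 - q[i]) * pgamma(x, shape = s2[i], rate = r2[i]) - percentile
    }
    lo <- min(qgamma(percentile, shape = s1[i], rate = r1[i]),
              qgamma(percentile, shape = s2[i], rate = r2[i]))
    hi <- max(qgamma(percentile, shape = s1[i], rate = r1[i]),
              qgamma(percentile, shape = s2[i], rate = r2[i]))
    if (hi <= lo) return(lo)
    uniroot(cdf, lower = lo, upper = hi, tol = 1e-10)$root
  }, numeric(1))
  tibble(ebgm = ebgm, ebgm05 = ebgm05)
}

#' @method tidy mgps_prior
#' @export
tidy.mgps_prior <- function(x, ...) {
  tibble(
    term = c("alpha1", "beta1", "alpha2", "beta2", "w"),
    estimate = c(x$alpha1, x$beta1, x$alpha2, x$beta2, x$w)
  )
}

#' @method glance mgps_prior
#' @export
glance.mgps_prior <- function(x, ...) {
  tibble(logLik = x$loglik, n_events = x$n_events,
         converged = isTRUE(x$converged))
}
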