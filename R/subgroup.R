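# Stratified sensitivity analyses: two-group comparison of a preferred
# term's reporting between strata (sex, age bands, reporter type), with the
# Cochran expected-cell cascade choosing between the Pearson, Yates and
# Fisher tests, plus full within-stratum reruns of the signal pipeline.

#' Build the two-group 2x2 summary for a preferred term
#'
#' `a1`/`a2` are the PT's report counts in each stratum, `n1`/`n2` the
#' strata's total PT-level report counts. The underlying 2x2 for testing is
#' `(a1, n1 - a1; a2, n2 - a2)`.
#'
#' @param strata Named list of exactly two `safety_reports` subsets (from
#'   [stratify()]); order defines group 1 and group 2.
#' @param pt The preferred term.
#' @return A `group_table`: tibble with `pt`, `group1`, `group2`, `a1`,
#'   `n1`, `a2`, `n2`.
#' @export
build_group_table <- function(strata, pt) {
  if (length(strata) != 2) {
    abort("grouping must yield exactly two strata", class = "pvsignal_usage_error")
  }
  if (any(vapply(strata, nrow, integer(1)) == 0)) {
    abort("empty stratum", class = "pvsignal_usage_error")
  }
  count_in <- function(reports) {
    pairs <- sum(lengths(reports$pts))
    hits <- sum(vapply(reports$pts, function(p) pt %in% p, logical(1)))
    c(hits, pairs)
  }
  g1 <- count_in(strata[[1]]); g2 <- count_in(strata[[2]])
  out <- tibble(
    pt = pt,
    group1 = names(strata)[1], group2 = names(strata)[2],
    a1 = g1[1], n1 = g1[2], a2 = g2[1], n2 = g2[2]
  )
  class(out) <- c("group_table", class(tibble()))
  out
}

group_table_cells <- function(table) {
  list(a = table$a1, b = table$n1 - table$a1,
       c = table$a2, d = table$n2 - table$a2)
}

#' Choose the comparison test from expected cell counts
#'
#' The Cochran cascade on the minimum expected cell of the 2x2:
#' `>= 5` Pearson chi-squared, in `[1, 5)` Yates continuity-corrected
#' chi-squared, `< 1` Fisher's exact test. The rule is total: every valid
#' table maps to exactly one test.
#'
#' @param table A `group_table` (single row).
#' @return One of `"pearson"`, `"yates"`, `"fisher"`.
#' @export
select_test <- function(table) {
  t <- group_table_cells(table)
  m <- matrix(c(t$a, t$b, t$c, t$d), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  min_e <- min(expected)
  if (min_e >= 5) "pearson" else if (min_e >= 1) "yates" else "fisher"
}

#' Two-tailed Fisher exact p-value for a 2x2 table
#'
#' The two-sided p sums the hypergeometric probabilities of all tables (at
#' fixed margins) no more probable than the observed one — the convention
#' of [stats::fisher.test()], which this wraps.
#'
#' @param table A `group_table`, or a 2x2 matrix, or the four cells
#'   `c(a, b, c, d)` row-wise.
#' @return The two-tailed p-value.
#' @export
fisher_exact_two_tailed <- function(table) {
  m <- if (is.data.frame(table) &&
             all(c("a1", "n1", "a2", "n2") %in% names(table))) {
    t <- group_table_cells(table)
    matrix(c(t$a, t$b, t$c, t$d), nrow = 2, byrow = TRUE)
  } else if (is.matrix(table)) {
    table
  } else {
    matrix(as.numeric(table), nrow = 2, byrow = TRUE)
  }
  min(fisher.test(m)$p.value, 1)
}

#' Compare a preferred term's reporting between two strata
#'
#' The between-group reporting odds ratio is
#' `(a1/(n1 - a1)) / (a2/(n2 - a2))` with the Woolf 95% interval; the
#' p-value comes from the test chosen by [select_test()]. A zero cell
#' leaves the ROR undefined-flagged while the (Fisher) p-value is still
#' reported.
#'
#' @param table A `group_table`.
#' @param conf_level Confidence level for the ROR interval.
#' @param alpha Two-tailed significance level (default 0.05).
#' @return A `subgroup_result` tibble: the input columns plus `ror`,
#'   `ror_lo`, `ror_hi`, `test_used`, `statistic`, `p`, `significant`.
#' @export
compare_groups <- function(table, conf_level = 0.95, alpha = 0.05) {
  t <- group_table_cells(table)
  ror <- compute_ror(t$a, t$b, t$c, t$d, conf_level = conf_level)
  # a zero observed cell leaves the ROR undefined; the exact test is then
  # reported regardless of the expected-cell cascade
  test <- if (any(c(t$a, t$b, t$c, t$d) == 0)) "fisher" else select_test(table)
  m <- matrix(c(t$a, t$b, t$c, t$d), nrow = 2, byrow = TRUE)
  if (test == "pearson") {
    ct <- suppressWarnings(chisq.test(m, correct = FALSE))
    statistic <- unname(ct$statistic); p <- unname(ct$p.value)
  } else if (test == "yates") {
    ct <- suppressWarnings(chisq.test(m, correct = TRUE))
    statistic <- unname(ct$statistic); p <- unname(ct$p.value)
  } else {
    statistic <- NA_real_
    p <- fisher_exact_two_tailed(m)
  }
  out <- dplyr::bind_cols(
    as_tibble(table), ror,
    tibble(test_used = test, statistic = statistic, p = p,
           significant = p < alpha)
  )
  class(out) <- c("subgroup_result", class(tibble()))
  out
}

#' Rerun the full signal pipeline within a stratum
#'
#' Builds PT-level tables from the stratum's reports and applies the four
#' disproportionality methods with the same thresholds as the full-data
#' analysis. When the stratum holds too few events for the empirical-Bayes
#' prior fit, per-method results are still returned with the MGPS columns
#' marked unavailable (`NA`), and no event can then pass the joint
#' criterion.
#'
#' @param reports A `safety_reports` stratum (from [stratify()]).
#' @param drug Target drug name.
#' @param thresholds A [signal_thresholds()].
#' @param synonyms Optional drug synonyms.
#' @return A `signal_result` tibble with verdict columns, in
#'   [detect_signals()] output format (all events, not only joint
#'   positives, so partial per-method results remain visible).
#' @export
rerun_stratified_signals <- function(reports, drug,
                                     thresholds = signal_thresholds(),
                                     synonyms = character()) {
  if (nrow(reports) == 0) {
    abort("stratum contains no reports", class = "pvsignal_usage_error")
  }
  tables <- build_pt_tables(reports, drug, synonyms = synonyms)
  prior <- if (nrow(tables) >= 10) fit_mgps_prior(tables) else NULL
  res <- signal_stats(tables, prior = prior)
  res <- apply_thresholds(res, thresholds)
  res[order(-res$a, -xtfrm(res$ebgm), res$event), , drop = FALSE]
}

#' Age-stratified comparison table across preferred terms
#'
#' Convenience wrapper reproducing the usual stratified sensitivity table:
#' one [compare_groups()] row per PT.
#'
#' @param strata Named list of exactly two strata.
#' @param pts Character vector of preferred terms to compare.
#' @return A `subgroup_result` tibble, one row per PT.
#' @export
subgroup_table <- function(strata, pts) {
  purrr::map(pts, function(p) compare_groups(build_group_table(strata, p))) |>
    list_rbind()
}
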