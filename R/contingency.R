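# 2x2 disproportionality tables at the preferred-term and
# system-organ-class level. The counting unit is the drug-event pair: one
# deduplicated case contributes one pair per distinct event for each of its
# primary-suspect drugs. The cells for target drug D and event E are
#   a = pairs (D, E)        b = pairs (D, not E)
#   c = pairs (other, E)    d = pairs (other, not E)
# with N = a + b + c + d the total pair count database-wide. This
# pair-level convention (reports, not patients, in the margins) is the one
# under which the usual printed ROR/PRR/EBGM relationships hold.

new_table_set <- function(df, drug, level, N, drug_margin) {
  df <- as_tibble(df)
  stopifnot(all(c("event", "a", "b", "c", "d") %in% names(df)))
  df$level <- level
  df <- df[c("event", "level", "a", "b", "c", "d")]
  attr(df, "drug") <- drug
  attr(df, "N") <- N
  attr(df, "drug_margin") <- drug_margin
  class(df) <- c("table_set", class(tibble()))
  df
}

#' @export
print.table_set <- function(x, ...) {
  cat("<table_set> drug '", attr(x, "drug"), "', level ",
      if (nrow(x)) x$level[1] else "?", ", ", nrow(x),
      " events, N = ", attr(x, "N"), "\n", sep = "")
  NextMethod()
}

pair_counts_from_reports <- function(reports, by_soc = NULL) {
  pairs <- tibble(
    case_id = rep(reports$case_id, lengths(reports$pts)),
    pt = unlist(reports$pts, use.names = FALSE),
    drug = rep(
      vapply(reports$drugs, function(d) {
        ps <- d$drug[d$role == "primary_suspect"]
        if (length(ps) == 0) NA_character_
        else normalize_drug_name(ps[[1]])
      }, character(1)),
      lengths(reports$pts)
    )
  ) |>
    dplyr::filter(!is.na(drug))
  if (!is.null(by_soc)) {
    pairs$event <- by_soc$soc[match(pairs$pt, by_soc$pt)]
    unmapped <- unique(pairs$pt[is.na(pairs$event)])
    if (length(unmapped) > 0) {
      warn(paste0("SOC map does not cover ", length(unmapped),
                  " observed PT(s); assigned to 'unmapped'"))
      pairs$event[is.na(pairs$event)] <- "unmapped"
    }
    # a report counts at most once per SOC however many of its PTs map there
    pairs <- dplyr::distinct(pairs, .data$case_id, .data$drug, .data$event)
  } else {
    pairs$event <- pairs$pt
    pairs <- dplyr::distinct(pairs, .data$case_id, .data$drug, .data$event)
  }
  pairs
}

table_set_from_margins <- function(event_counts, event_totals, drug_total,
                                   grand_total, drug, level,
                                   include_zero = FALSE) {
  df <- dplyr::full_join(event_counts, event_totals, by = "event",
                         suffix = c("_a", "_tot")) |>
    dplyr::mutate(n_a = dplyr::coalesce(.data$n_a, 0L))
  if (!include_zero) df <- dplyr::filter(df, .data$n_a > 0)
  out <- tibble(
    event = df$event,
    a = as.integer(df$n_a),
    b = as.integer(drug_total - df$n_a),
    c = as.integer(df$n_tot - df$n_a),
    d = as.integer(grand_total - drug_total - (df$n_tot - df$n_a))
  ) |>
    dplyr::arrange(dplyr::desc(a), event)
  if (any(out$b < 0 | out$c < 0 | out$d < 0)) {
    abort("negative contingency cell: margins inconsistent with pair counts",
          class = "pvsignal_integrity_error")
  }
  new_table_set(out, drug = drug, level = level, N = grand_total,
                drug_margin = drug_total)
}

#' Build preferred-term level 2x2 tables for a target drug
#'
#' Works from either a deduplicated report collection or a VigiAccess-style
#' [read_aggregate_counts()] object; both construction paths give identical
#' tables on the same underlying counts.
#'
#' @param source A `safety_reports` tibble or an `aggregate_counts` object.
#' @param drug Target drug name (normalized internally).
#' @param synonyms Optional synonym list for report-level matching.
#' @param include_zero Keep events never reported with the target drug
#'   (`a = 0`)? Default drops them: no signal is possible at `a = 0` and the
#'   empirical-Bayes fit is run on observed events.
#' @return A `table_set` tibble with columns `event`, `level`, `a`, `b`,
#'   `c`, `d` and attributes `drug`, `N`, `drug_margin`.
#' @export
build_pt_tables <- function(source, drug, synonyms = character(),
                            include_zero = FALSE) {
  drug_norm <- normalize_drug_name(drug)
  if (inherits(source, "aggregate_counts")) {
    event_counts <- source$pairs |>
      dplyr::filter(.data$drug == drug_norm) |>
      dplyr::transmute(event = pt, n_a = count)
    if (nrow(event_counts) == 0) {
      warn(paste0("drug '", drug, "' absent from aggregate counts"))
    }
    event_totals <- dplyr::transmute(source$pt_totals, event = pt, n_tot = count)
    drug_total <- source$drug_totals$count[match(drug_norm, source$drug_totals$drug)]
    if (is.na(drug_total)) drug_total <- 0L
    return(table_set_from_margins(event_counts, event_totals, drug_total,
                                  source$grand_total, drug_norm, "PT",
                                  include_zero))
  }
  pairs <- pair_counts_from_reports(source)
  build_from_pairs(pairs, drug_norm, c(drug_norm, normalize_drug_name(synonyms)),
                   "PT", include_zero)
}

build_from_pairs <- function(pairs, drug_norm, names_norm, level, include_zero) {
  is_target <- pairs$drug %in% names_norm
  if (!any(is_target)) {
    warn(paste0("drug '", drug_norm, "' is not a primary suspect in any report"))
  }
  event_counts <- pairs[is_target, ] |> dplyr::count(event, name = "n_a")
  event_totals <- pairs |> dplyr::count(event, name = "n_tot")
  table_set_from_margins(event_counts, event_totals,
                         drug_total = sum(is_target),
                         grand_total = nrow(pairs),
                         drug = drug_norm, level = level,
                         include_zero = include_zero)
}

#' Build system-organ-class level 2x2 tables for a target drug
#'
#' PTs are rolled up to their primary SOC. At report level a case counts at
#' most once per SOC regardless of how many of its PTs map there; with an
#' aggregate-count source (no within-report information) PT counts are
#' summed per SOC, which is an upper bound on the deduplicated count.
#'
#' @inheritParams build_pt_tables
#' @param soc_map Tibble with columns `pt`, `soc` ([read_soc_map()]).
#'   Uncovered PTs are assigned to an `"unmapped"` SOC with a warning.
#' @return A `table_set` at SOC level.
#' @export
build_soc_tables <- function(source, drug, soc_map, synonyms = character(),
                             include_zero = FALSE) {
  drug_norm <- normalize_drug_name(drug)
  if (inherits(source, "aggregate_counts")) {
    soc_of <- function(pt) {
      s <- soc_map$soc[match(pt, soc_map$pt)]
      s[is.na(s)] <- "unmapped"
      s
    }
    pairs <- source$pairs |> dplyr::mutate(event = soc_of(pt))
    event_counts <- pairs |>
      dplyr::filter(.data$drug == drug_norm) |>
      dplyr::count(event, wt = count, name = "n_a")
    event_totals <- source$pt_totals |>
      dplyr::mutate(event = soc_of(pt)) |>
      dplyr::count(event, wt = count, name = "n_tot")
    drug_total <- source$drug_totals$count[match(drug_norm, source$drug_totals$drug)]
    if (is.na(drug_total)) drug_total <- 0L
    return(table_set_from_margins(event_counts, event_totals, drug_total,
                                  source$grand_total, drug_norm, "SOC",
                                  include_zero))
  }
  pairs <- pair_counts_from_reports(source, by_soc = soc_map)
  build_from_pairs(pairs, drug_norm, c(drug_norm, normalize_drug_name(synonyms)),
                   "SOC", include_zero)
}

#' Partition reports into analysis strata
#'
#' Reports with the stratification field unknown are excluded; the returned
#' subsets are disjoint and their union is the set of reports with the field
#' known.
#'
#' @param reports A `safety_reports` tibble.
#' @param by One of `"sex"` (male vs female), `"age65"` (`<65` vs `>=65` on
#'   age in years), `"reporter_type"` (healthcare: physician, pharmacist or
#'   other health professional; vs non-healthcare: consumer).
#' @return Named list of `safety_reports` subsets.
#' @export
stratify <- function(reports, by = c("sex", "age65", "reporter_type")) {
  by <- rlang::arg_match(by)
  key <- switch(by,
    sex = ifelse(reports$sex %in% c("male", "female"), reports$sex, NA),
    age65 = dplyr::case_when(
      is.na(reports$age_years) ~ NA_character_,
      reports$age_years >= 65 ~ ">=65",
      TRUE ~ "<65"
    ),
    reporter_type = dplyr::case_when(
      reports$reporter %in% c("physician", "pharmacist",
                              "other_health_professional") ~ "healthcare",
      reports$reporter == "consumer" ~ "non_healthcare",
      TRUE ~ NA_character_
    )
  )
  keep <- !is.na(key)
  lapply(split(seq_len(nrow(reports))[keep], key[keep]),
         function(idx) as_safety_reports(reports[idx, , drop = FALSE]))
}

#' Export a table set as TSV
#' @param table_set A `table_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_set <- function(table_set, path) {
  out <- as_tibble(table_set)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Import a table set written by [write_table_set()]
#' @param path TSV path with columns `event`, `level`, `a`, `b`, `c`, `d`.
#' @param drug Drug label to attach.
#' @return A `table_set`.
#' @export
read_table_set <- function(path, drug = NA_character_) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = "cciiii")
  N <- if (nrow(df)) df$a[1] + df$b[1] + df$c[1] + df$d[1] else 0L
  new_table_set(df, drug = drug, level = if (nrow(df)) df$level[1] else "PT",
                N = N, drug_margin = if (nrow(df)) df$a[1] + df$b[1] else 0L)
}
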