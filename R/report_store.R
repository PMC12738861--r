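# Normalized spontaneous-report store: deduplication, primary-suspect
# filtering, and demographic summaries.

REPORT_COLUMNS <- c(
  "case_id", "primaryid", "version_date", "event_date", "sex", "age_years",
  "reporter", "country", "age_group", "continent", "drugs", "pts",
  "therapy_start", "outcomes", "indication"
)

as_safety_reports <- function(x) {
  x <- as_tibble(x)
  missing <- setdiff(REPORT_COLUMNS, names(x))
  if (length(missing) > 0) {
    abort(paste0("report collection is missing field(s): ",
                 paste(missing, collapse = ", ")),
          class = "pvsignal_format_error")
  }
  x <- x[REPORT_COLUMNS]
  class(x) <- c("safety_reports", class(tibble()))
  x
}

#' @export
print.safety_reports <- function(x, ...) {
  cat("<safety_reports> ", nrow(x), " deduplicated case reports\n", sep = "")
  NextMethod()
}

#' Deduplicate raw case records into one report per case
#'
#' Spontaneous-report extracts contain multiple versions of a case and
#' withdrawn/deleted cases. Following the FDA-style cleaning convention,
#' this keeps, for each case identifier, the record with the latest version
#' date (ties broken by the largest report identifier), then removes cases
#' on the deleted list. Records left with no preferred terms after cleaning
#' are dropped and counted (a case must describe at least one event).
#'
#' The operation is idempotent: applying it to its own output is a no-op.
#'
#' @param records Raw records from [parse_faers_tables()] (or an already
#'   deduplicated collection).
#' @param deleted_case_ids Character vector of case identifiers to remove.
#' @return A `safety_reports` tibble with attribute `cleaning_log`
#'   (versions dropped, deleted cases removed, empty-PT records dropped).
#' @export
deduplicate_cases <- function(records, deleted_case_ids = character()) {
  records <- as_tibble(records)
  if (nrow(records) == 0) {
    empty <- tibble(
      case_id = character(), primaryid = character(), version_date = integer(),
      event_date = as.Date(character()), sex = character(), age_years = double(),
      reporter = character(), country = character(), age_group = character(),
      continent = character(), drugs = list(), pts = list(),
      therapy_start = as.Date(character()), outcomes = list(),
      indication = character()
    )
    return(as_safety_reports(empty))
  }
  n_raw <- nrow(records)
  ord <- order(records$case_id,
               -xtfrm(records$version_date),
               -xtfrm(records$primaryid))
  kept <- records[ord, , drop = FALSE]
  kept <- kept[!duplicated(kept$case_id), , drop = FALSE]
  n_versions_dropped <- n_raw - nrow(kept)

  deleted <- kept$case_id %in% as.character(deleted_case_ids)
  kept <- kept[!deleted, , drop = FALSE]

  no_pt <- lengths(kept$pts) == 0
  kept <- kept[!no_pt, , drop = FALSE]

  kept <- kept[order(kept$case_id), , drop = FALSE]
  out <- as_safety_reports(kept)
  attr(out, "cleaning_log") <- tibble(
    raw_records = n_raw,
    versions_dropped = n_versions_dropped,
    deleted_removed = sum(deleted),
    empty_pt_dropped = sum(no_pt),
    reports = nrow(kept)
  )
  out
}

#' Keep reports naming a drug as the primary suspect
#'
#' Matching is exact on the normalized name ([normalize_drug_name()]) against
#' the target name and any synonyms; the drug must carry the
#' `primary_suspect` role in the report.
#'
#' @param reports A `safety_reports` tibble.
#' @param drug_name Target drug name.
#' @param synonyms Optional character vector of alternative names.
#' @return The filtered `safety_reports` tibble. An unknown drug yields an
#'   empty collection with a warning, not an error.
#' @export
filter_primary_suspect <- function(reports, drug_name, synonyms = character()) {
  names_norm <- normalize_drug_name(c(drug_name, synonyms))
  seen_anywhere <- FALSE
  hit <- vapply(reports$drugs, function(d) {
    m <- normalize_drug_name(d$drug) %in% names_norm
    if (any(m)) seen_anywhere <<- TRUE
    any(m & d$role == "primary_suspect")
  }, logical(1))
  if (!seen_anywhere && nrow(reports) > 0) {
    warn(paste0("drug '", drug_name, "' not found in any report"))
  }
  out <- reports[hit, , drop = FALSE]
  as_safety_reports(out)
}

#' Summarize report demographics by field and category
#'
#' Counts and percentages per category of sex, age group, continent and
#' reporter type, with `unknown` as its own category. Percentages are
#' 100 * count / N rounded to 2 decimals, N the full collection size
#' (unknowns included), mirroring the usual characteristics table of a
#' pharmacovigilance study.
#'
#' @param reports A nonempty `safety_reports` tibble.
#' @param fields Demographic fields to tabulate.
#' @return Tibble with columns `field`, `category`, `n`, `percentage`.
#' @export
summarize_demographics <- function(reports,
                                   fields = c("sex", "age_group", "continent",
                                              "reporter")) {
  if (nrow(reports) == 0) {
    abort("cannot summarize an empty report collection",
          class = "pvsignal_usage_error")
  }
  N <- nrow(reports)
  order_map <- list(
    sex = c("female", "male", "unknown"),
    age_group = c("<18", "18-44", "45-64", ">=65", "unknown"),
    continent = c("Asia", "Americas", "Europe", "Africa", "Oceania", "unknown"),
    reporter = c("physician", "pharmacist", "other_health_professional",
                 "consumer", "unknown")
  )
  purrr::map(fields, function(f) {
    tab <- reports |>
      dplyr::count(category = .data[[f]]) |>
      dplyr::mutate(field = f, percentage = round(100 * n / N, 2))
    lev <- order_map[[f]]
    if (!is.null(lev)) {
      tab <- tab[order(match(tab$category, lev)), , drop = FALSE]
    }
    tab[c("field", "category", "n", "percentage")]
  }) |>
    list_rbind()
}
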