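# Reading and writing the FAERS-style quarterly ASCII dialect
# ("$"-delimited, header row, one file per table) plus VigiAccess-style
# aggregate count exports and the package's own normalized report export.

#' Default column map for FAERS-style quarterly ASCII tables
#'
#' FAERS table schemas drift across quarters; the column map resolves the
#' package's canonical field names to the column headers actually present in
#' a given quarter's files. The defaults match the modern (post-2012)
#' quarterly ASCII layout.
#'
#' @param ... Named overrides, e.g. `demo = list(sex = "gndr_cod")` for
#'   quarters where sex was coded under a legacy header.
#' @return A nested named list mapping, per table, canonical field -> column
#'   header.
#' @export
#' @examples
#' faers_column_map()
#' faers_column_map(demo = list(sex = "gndr_cod"))
faers_column_map <- function(...) {
  map <- list(
    demo = list(
      primaryid = "primaryid", case_id = "caseid", version_date = "fda_dt",
      event_date = "event_dt", sex = "sex", age = "age", age_unit = "age_cod",
      reporter = "occp_cod", country = "reporter_country"
    ),
    drug = list(primaryid = "primaryid", drug_name = "drugname", role = "role_cod"),
    reac = list(primaryid = "primaryid", pt = "pt"),
    ther = list(primaryid = "primaryid", therapy_start = "start_dt"),
    outc = list(primaryid = "primaryid", outcome = "outc_cod"),
    indi = list(primaryid = "primaryid", indication = "indi_pt")
  )
  overrides <- list(...)
  for (tab in names(overrides)) {
    map[[tab]] <- modifyList(map[[tab]], as.list(overrides[[tab]]))
  }
  map
}

read_dollar_table <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("cannot read FAERS table file: ", path), class = "pvsignal_io_error")
  }
  df <- utils::read.delim(path, sep = "$", header = TRUE, quote = "",
                          colClasses = "character", strip.white = TRUE,
                          check.names = FALSE, na.strings = c("", "NA"))
  as_tibble(df)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(unlist(cols), names(df))
  if (length(missing) > 0) {
    abort(
      paste0("file '", path, "' is missing mandatory column(s): ",
             paste(missing, collapse = ", ")),
      class = "pvsignal_format_error"
    )
  }
}

role_from_code <- function(code) {
  dplyr::case_match(
    toupper(trimws(code)),
    "PS" ~ "primary_suspect",
    "SS" ~ "secondary_suspect",
    "C"  ~ "concomitant",
    "I"  ~ "interacting",
    .default = "concomitant"
  )
}

role_to_code <- function(role) {
  dplyr::case_match(
    role,
    "primary_suspect"   ~ "PS",
    "secondary_suspect" ~ "SS",
    "concomitant"       ~ "C",
    "interacting"       ~ "I",
    .default = "C"
  )
}

sex_from_code <- function(code) {
  dplyr::case_match(
    toupper(trimws(code %||% NA_character_)),
    "M" ~ "male", "F" ~ "female",
    .default = "unknown"
  )
}

reporter_from_code <- function(code) {
  dplyr::case_match(
    toupper(trimws(code %||% NA_character_)),
    "MD" ~ "physician", "PH" ~ "pharmacist", "HP" ~ "other_health_professional",
    "CN" ~ "consumer", "OT" ~ "consumer",
    .default = "unknown"
  )
}

outcome_from_code <- function(code) {
  dplyr::case_match(
    toupper(trimws(code)),
    "DE" ~ "death", "LT" ~ "life_threatening", "HO" ~ "hospitalization",
    "DS" ~ "disability", "OT" ~ "other",
    .default = "other"
  )
}

#' Derive the age group used in demographic summaries
#'
#' Bands are `<18`, `18-44`, `45-64`, `>=65`; missing age maps to `"unknown"`.
#'
#' @param age_years Numeric vector of ages in years (NA allowed).
#' @return Character vector of age-group labels.
#' @export
age_group_of <- function(age_years) {
  dplyr::case_when(
    is.na(age_years) ~ "unknown",
    age_years < 18 ~ "<18",
    age_years < 45 ~ "18-44",
    age_years < 65 ~ "45-64",
    TRUE ~ ">=65"
  )
}

age_to_years <- function(age, unit) {
  x <- suppressWarnings(as.numeric(age))
  u <- toupper(trimws(ifelse(is.na(unit), "YR", unit)))
  factor_ <- dplyr::case_match(u,
    "YR" ~ 1, "DEC" ~ 10, "MON" ~ 1 / 12, "WK" ~ 1 / 52.18,
    "DY" ~ 1 / 365.25, "HR" ~ 1 / 8766,
    .default = 1
  )
  out <- x * factor_
  out[!is.na(out) & out < 0] <- NA_real_
  out
}

yyyymmdd_to_date <- function(x) {
  x <- trimws(as.character(x))
  x[!grepl("^[0-9]{8}$", x)] <- NA_character_
  as.Date(x, format = "%Y%m%d")
}

date_to_yyyymmdd <- function(d) {
  ifelse(is.na(d), NA_character_, format(d, "%Y%m%d"))
}

#' Parse FAERS-style quarterly ASCII tables into raw case records
#'
#' Reads the dollar-sign-delimited DEMO/DRUG/REAC (mandatory) and
#' THER/OUTC/INDI (optional) tables and assembles one raw record per DEMO
#' row. Records are not yet deduplicated; feed the result to
#' [deduplicate_cases()]. Rows missing the case identifier or the report
#' identifier are rejected and counted, never silently dropped.
#'
#' @param paths Named list of file paths with elements `demo`, `drug`,
#'   `reac` and optionally `ther`, `outc`, `indi`.
#' @param column_map Column map from [faers_column_map()].
#' @return A tibble of raw records (one per DEMO row) with list-columns
#'   `drugs` (tibble of `drug`, `role`) and `pts` (character), plus an
#'   attribute `rejects`: a tibble of per-table rejected-row counts.
#' @export
parse_faers_tables <- function(paths, column_map = faers_column_map()) {
  for (tab in c("demo", "drug", "reac")) {
    if (is.null(paths[[tab]])) {
      abort(paste0("paths must name a '", tab, "' file"),
            class = "pvsignal_format_error")
    }
  }
  rejects <- tibble(table = character(), rejected = integer())
  note_rejects <- function(tab, n) {
    rejects <<- dplyr::bind_rows(rejects, tibble(table = tab, rejected = as.integer(n)))
  }

  cm <- column_map$demo
  demo <- read_dollar_table(paths$demo)
  require_columns(demo, cm[c("primaryid", "case_id", "version_date")], paths$demo)
  bad <- is.na(demo[[cm$primaryid]]) | is.na(demo[[cm$case_id]])
  note_rejects("demo", sum(bad))
  demo <- demo[!bad, , drop = FALSE]
  pick <- function(df, col) if (!is.null(col) && col %in% names(df)) df[[col]] else NA_character_
  records <- tibble(
    primaryid = as.character(demo[[cm$primaryid]]),
    case_id = as.character(demo[[cm$case_id]]),
    version_date = suppressWarnings(as.integer(demo[[cm$version_date]])),
    event_date = yyyymmdd_to_date(pick(demo, cm$event_date)),
    sex = sex_from_code(pick(demo, cm$sex)),
    age_years = age_to_years(pick(demo, cm$age), pick(demo, cm$age_unit)),
    reporter = reporter_from_code(pick(demo, cm$reporter)),
    country = dplyr::coalesce(toupper(trimws(pick(demo, cm$country))), "unknown")
  )
  records$age_group <- age_group_of(records$age_years)
  records$continent <- country_to_continent(records$country)

  cm <- column_map$drug
  drug <- read_dollar_table(paths$drug)
  require_columns(drug, cm[c("primaryid", "drug_name", "role")], paths$drug)
  bad <- is.na(drug[[cm$primaryid]]) | is.na(drug[[cm$drug_name]])
  note_rejects("drug", sum(bad))
  drug <- drug[!bad, , drop = FALSE]
  drug_ids <- as.character(drug[[cm$primaryid]])
  drug_names <- normalize_drug_name(drug[[cm$drug_name]])
  drug_roles <- role_from_code(drug[[cm$role]])
  drug_tbl <- tibble(primaryid = drug_ids, drug = drug_names,
                     role = drug_roles)

  cm <- column_map$reac
  reac <- read_dollar_table(paths$reac)
  require_columns(reac, cm[c("primaryid", "pt")], paths$reac)
  bad <- is.na(reac[[cm$primaryid]]) | is.na(reac[[cm$pt]])
  note_rejects("reac", sum(bad))
  reac <- reac[!bad, , drop = FALSE]
  pt_tbl <- tibble(
    primaryid = as.character(reac[[cm$primaryid]]),
    pt = trimws(reac[[cm$pt]])
  )

  drugs_by_id <- split(drug_tbl[c("drug", "role")], drug_tbl$primaryid)
  pts_by_id <- lapply(split(pt_tbl$pt, pt_tbl$primaryid), function(x) sort(unique(x)))
  empty_drugs <- tibble(drug = character(), role = character())
  records$drugs <- lapply(records$primaryid, function(id) {
    x <- drugs_by_id[[id]]
    if (is.null(x)) empty_drugs else as_tibble(x)
  })
  records$pts <- lapply(records$primaryid, function(id) {
    pts_by_id[[id]] %||% character()
  })

  records$therapy_start <- as.Date(rep(NA, nrow(records)))
  if (!is.null(paths$ther)) {
    cm <- column_map$ther
    ther <- read_dollar_table(paths$ther)
    require_columns(ther, cm[c("primaryid", "therapy_start")], paths$ther)
    ther_tbl <- tibble(
      primaryid = as.character(ther[[cm$primaryid]]),
      therapy_start = yyyymmdd_to_date(ther[[cm$therapy_start]])
    ) |>
      dplyr::filter(!is.na(.data$therapy_start)) |>
      dplyr::group_by(.data$primaryid) |>
      dplyr::summarise(therapy_start = min(.data$therapy_start), .groups = "drop")
    idx <- match(records$primaryid, ther_tbl$primaryid)
    records$therapy_start <- ther_tbl$therapy_start[idx]
  }

  records$outcomes <- rep(list(character()), nrow(records))
  if (!is.null(paths$outc)) {
    cm <- column_map$outc
    outc <- read_dollar_table(paths$outc)
    require_columns(outc, cm[c("primaryid", "outcome")], paths$outc)
    oc <- split(outcome_from_code(outc[[cm$outcome]]),
                as.character(outc[[cm$primaryid]]))
    oc <- lapply(oc, function(x) sort(unique(x)))
    hit <- records$primaryid %in% names(oc)
    records$outcomes[hit] <- oc[records$primaryid[hit]]
  }

  records$indication <- NA_character_
  if (!is.null(paths$indi)) {
    cm <- column_map$indi
    indi <- read_dollar_table(paths$indi)
    require_columns(indi, cm[c("primaryid", "indication")], paths$indi)
    first_indi <- indi |>
      as_tibble() |>
      dplyr::distinct(primaryid = as.character(.data[[cm$primaryid]]),
                      .keep_all = TRUE)
    idx <- match(records$primaryid, first_indi$primaryid)
    records$indication <- trimws(first_indi[[cm$indication]][idx])
  }

  bad_date <- is.na(records$version_date) | is.na(yyyymmdd_to_date(records$version_date))
  note_rejects("demo_version_date", sum(bad_date))
  records <- records[!bad_date, , drop = FALSE]

  attr(records, "rejects") <- rejects
  records
}

#' Read a deleted-case list file
#'
#' One case identifier per line; a header line named `caseid` (any case) is
#' skipped if present.
#'
#' @param path Path to the deleted-case list.
#' @return Character vector of case identifiers.
#' @export
read_deleted_cases <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x)]
  x[!tolower(x) %in% c("caseid", "case_id")]
}

#' Normalize a drug name for matching
#'
#' Case-folds, trims, and collapses internal whitespace. Matching elsewhere
#' in the package is exact on the normalized form (optionally extended by a
#' synonym list); no fuzzy matching is performed, so every match is
#' auditable.
#'
#' @param x Character vector of drug names.
#' @return Normalized character vector.
#' @export
normalize_drug_name <- function(x) {
  stringr::str_squish(tolower(trimws(x)))
}

#' Map country names to continents
#'
#' Uses the bundled country-to-continent table (ISO-3166 alpha-2 codes and
#' common English names). Unmapped values return `"unknown"`.
#'
#' @param country Character vector of country codes or names.
#' @return Character vector of continent labels
#'   (`Asia`, `Americas`, `Europe`, `Africa`, `Oceania`, `unknown`).
#' @export
country_to_continent <- function(country) {
  tbl <- country_continent_table()
  key <- toupper(trimws(country))
  out <- tbl$continent[match(key, tbl$country)]
  out[is.na(out)] <- "unknown"
  out
}

country_continent_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "country_continent.csv", package = "pvsignal")
      cache <<- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
      cache$country <<- toupper(cache$country)
    }
    cache
  }
})

#' Read VigiAccess-style aggregate drug-event counts
#'
#' Expects a CSV/TSV with columns `drug`, `pt`, `count` giving per-drug
#' per-preferred-term report counts. Totals may be supplied as special rows:
#' an empty `pt` gives a drug total, an empty `drug` a PT total, and a row
#' with both empty the grand total. Absent totals are derived by summation
#' and flagged as derived.
#'
#' @param path Path to the counts file (delimiter sniffed from extension:
#'   `.tsv` tab, otherwise comma).
#' @return An `aggregate_counts` object: a list with `pairs` (tibble of
#'   `drug`, `pt`, `count`), `drug_totals`, `pt_totals`, `grand_total`, and
#'   `derived_totals` (logical flag).
#' @export
read_aggregate_counts <- function(path) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, trim_ws = TRUE)
  need <- c("drug", "pt", "count")
  if (!all(need %in% names(raw))) {
    abort(paste0("aggregate counts file '", path,
                 "' must have columns drug, pt, count"),
          class = "pvsignal_format_error")
  }
  raw$drug <- ifelse(is.na(raw$drug) | raw$drug == "", NA_character_,
                     normalize_drug_name(raw$drug))
  raw$pt <- ifelse(is.na(raw$pt) | raw$pt == "", NA_character_, trimws(raw$pt))
  raw$count <- as.numeric(raw$count)
  if (any(is.na(raw$count)) || any(raw$count < 0) || any(raw$count != round(raw$count))) {
    abort("aggregate counts must be nonnegative integers",
          class = "pvsignal_integrity_error")
  }
  raw$count <- as.integer(raw$count)

  pairs <- raw |> dplyr::filter(!is.na(drug), !is.na(pt))
  drug_tot_rows <- raw |> dplyr::filter(!is.na(drug), is.na(pt))
  pt_tot_rows <- raw |> dplyr::filter(is.na(drug), !is.na(pt))
  grand_rows <- raw |> dplyr::filter(is.na(drug), is.na(pt))

  derived <- nrow(drug_tot_rows) == 0 && nrow(pt_tot_rows) == 0 && nrow(grand_rows) == 0
  drug_totals <- pairs |> dplyr::count(drug, wt = count, name = "count")
  pt_totals <- pairs |> dplyr::count(pt, wt = count, name = "count")
  grand_total <- sum(pairs$count)

  # stated totals may exceed the within-file pair sums (an export restricted
  # to one drug still carries database-wide margins) but never undercut them
  check_tot <- function(given, derived_tbl, key, what) {
    merged <- dplyr::left_join(given, derived_tbl, by = key,
                               suffix = c("_given", "_derived"))
    bad <- !is.na(merged$count_derived) &
      merged$count_given < merged$count_derived
    if (any(bad)) {
      abort(paste0(what, " totals inconsistent with pair rows (e.g. ",
                   merged[[key]][which(bad)[1]], ")"),
            class = "pvsignal_integrity_error")
    }
  }
  if (nrow(drug_tot_rows) > 0) {
    check_tot(drug_tot_rows[c("drug", "count")], drug_totals, "drug", "drug")
  }
  if (nrow(pt_tot_rows) > 0) check_tot(pt_tot_rows[c("pt", "count")], pt_totals, "pt", "PT")
  if (nrow(grand_rows) > 0) {
    if (nrow(grand_rows) > 1 || grand_rows$count[1] < grand_total) {
      abort("grand total row inconsistent with pair rows",
            class = "pvsignal_integrity_error")
    }
    grand_total <- grand_rows$count[1]
  }
  # stated totals may exceed within-file pair sums (e.g. an export restricted
  # to one drug against database-wide margins); stated totals win
  if (nrow(drug_tot_rows) > 0) {
    drug_totals <- dplyr::rows_update(drug_totals, drug_tot_rows[c("drug", "count")],
                                      by = "drug", unmatched = "ignore")
    drug_totals <- dplyr::bind_rows(
      drug_totals,
      dplyr::anti_join(drug_tot_rows[c("drug", "count")], drug_totals, by = "drug")
    )
  }
  if (nrow(pt_tot_rows) > 0) {
    pt_totals <- dplyr::rows_update(pt_totals, pt_tot_rows[c("pt", "count")],
                                    by = "pt", unmatched = "ignore")
    pt_totals <- dplyr::bind_rows(
      pt_totals,
      dplyr::anti_join(pt_tot_rows[c("pt", "count")], pt_totals, by = "pt")
    )
  }

  structure(
    list(pairs = pairs, drug_totals = drug_totals, pt_totals = pt_totals,
         grand_total = grand_total, derived_totals = derived),
    class = "aggregate_counts"
  )
}

#' @export
print.aggregate_counts <- function(x, ...) {
  cat("<aggregate_counts> ", nrow(x$pairs), " drug-PT pairs, ",
      nrow(x$drug_totals), " drugs, ", nrow(x$pt_totals), " PTs, grand total ",
      x$grand_total,
      if (x$derived_totals) " (totals derived by summation)" else "", "\n",
      sep = "")
  invisible(x)
}

#' Write a normalized report collection to plain-text tables
#'
#' Persists the deduplicated report collection as three UTF-8 TSV files
#' (`reports.tsv`, `report_drugs.tsv`, `report_pts.tsv`) under `dir`.
#' [read_reports()] round-trips the collection field-for-field.
#'
#' @param reports A `safety_reports` tibble.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_reports <- function(reports, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flat <- reports |>
    dplyr::select(-dplyr::any_of(c("drugs", "pts", "outcomes"))) |>
    dplyr::mutate(
      outcomes = map_chr(reports$outcomes, paste, collapse = "|"),
      therapy_start = as.character(.data$therapy_start),
      event_date = as.character(.data$event_date)
    )
  readr::write_tsv(flat, file.path(dir, "reports.tsv"), progress = FALSE)
  drugs_long <- reports |>
    dplyr::select("case_id", "drugs") |>
    tidyr::unnest("drugs")
  readr::write_tsv(drugs_long, file.path(dir, "report_drugs.tsv"), progress = FALSE)
  pts_long <- reports |>
    dplyr::select("case_id", "pts") |>
    tidyr::unnest_longer("pts", values_to = "pt") |>
    dplyr::filter(!is.na(.data$pt))
  readr::write_tsv(pts_long, file.path(dir, "report_pts.tsv"), progress = FALSE)
  invisible(dir)
}

#' Read a normalized report collection written by [write_reports()]
#'
#' @param dir Directory containing `reports.tsv`, `report_drugs.tsv`,
#'   `report_pts.tsv`.
#' @return A `safety_reports` tibble.
#' @export
read_reports <- function(dir) {
  flat <- readr::read_tsv(file.path(dir, "reports.tsv"), show_col_types = FALSE,
                          progress = FALSE,
                          col_types = readr::cols(
                            case_id = "c", primaryid = "c", version_date = "i",
                            age_years = "d",
                            sex = "c", age_group = "c", reporter = "c",
                            country = "c", continent = "c", outcomes = "c",
                            indication = "c",
                            therapy_start = readr::col_date(),
                            event_date = readr::col_date(),
                            .default = readr::col_guess()
                          ))
  drugs_long <- readr::read_tsv(file.path(dir, "report_drugs.tsv"),
                                show_col_types = FALSE, progress = FALSE,
                                col_types = "ccc")
  pts_long <- readr::read_tsv(file.path(dir, "report_pts.tsv"),
                              show_col_types = FALSE, progress = FALSE,
                              col_types = "cc")
  empty_drugs <- tibble(drug = character(), role = character())
  drugs_by_id <- split(drugs_long[c("drug", "role")], drugs_long$case_id)
  pts_by_id <- lapply(split(pts_long$pt, pts_long$case_id),
                      function(x) sort(unique(x)))
  flat$drugs <- lapply(flat$case_id, function(id) {
    x <- drugs_by_id[[id]]
    if (is.null(x)) empty_drugs else as_tibble(x)
  })
  flat$pts <- lapply(flat$case_id, function(id) pts_by_id[[id]] %||% character())
  flat$outcomes <- lapply(strsplit(dplyr::coalesce(flat$outcomes, ""), "\\|"),
                          function(x) x[nzchar(x)])
  as_safety_reports(flat)
}

#' Read a preferred-term to system-organ-class mapping
#'
#' @param path CSV/TSV with columns `pt` and `soc`; each PT must map to
#'   exactly one primary SOC.
#' @return A tibble with columns `pt`, `soc`.
#' @export
read_soc_map <- function(path) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  m <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE, trim_ws = TRUE)
  if (!all(c("pt", "soc") %in% names(m))) {
    abort("SOC map must have columns pt and soc", class = "pvsignal_format_error")
  }
  m <- dplyr::distinct(m, .data$pt, .data$soc)
  if (anyDuplicated(m$pt)) {
    abort("SOC map assigns more than one primary SOC to a PT",
          class = "pvsignal_integrity_error")
  }
  m[c("pt", "soc")]
}
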