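# Synthetic spontaneous-report databases with known ground truth.
# Every downstream stage (deduplication, contingency tables, the four
# disproportionality statistics, onset-time fits) can be validated against
# the generating parameters without any external data.

#' Run code with a temporary RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# deterministic sub-seed per stage so stages can be regenerated independently
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 1009L + as.integer(h %% 100003L)) %% 2147483647L
}

#' Configuration for the synthetic spontaneous-report generator
#'
#' Defaults describe a mid-sized reporting database: five drugs with equal
#' exposure, fifty preferred terms with background reporting probabilities
#' spread log-uniformly between 0.2% and 8%, no injected associations
#' (all relative reporting ratios 1), demographic margins with the heavy
#' missingness typical of spontaneous reports, and a common onset-time law
#' with a same-day point mass over an early-failure Weibull.
#'
#' @param n_cases Number of cases to generate.
#' @param drugs Tibble with columns `drug`, `prob` (exposure probabilities,
#'   normalized internally).
#' @param pts Tibble with columns `pt`, `prob` (background per-case
#'   reporting probabilities in `[0, 1]`).
#' @param signal_matrix Tibble with columns `drug`, `pt`, `rho`: relative
#'   reporting ratio for the pair (`rho = 1` is the null; omitted pairs are
#'   null).
#' @param demographics Named list of category probability vectors for
#'   `sex`, `age_group`, `reporter`, `country`.
#' @param missingness Named list of per-field missingness rates in `[0, 1)`
#'   (`sex`, `age`, `reporter`, `country`, `dates`).
#' @param onset_laws Tibble with columns `pt`, `scale`, `shape`, `p0`:
#'   per-PT Weibull onset law (days) with a point mass `p0` at day 0. PTs
#'   absent from the table fall back to the `.default` row.
#' @param duplicate_rate,deletion_rate Fractions in `[0, 1)` of cases given
#'   an extra earlier version / placed on the deleted list by
#'   [inject_artifacts()] when run through the full simulation.
#' @param seed Integer master seed; all stage randomness derives from it.
#' @return A `synth_config` list, validated.
#' @export
synth_config <- function(n_cases = 10000,
                         drugs = tibble(
                           drug = sprintf("drug%02d", 1:5),
                           prob = rep(0.2, 5)
                         ),
                         pts = tibble(
                           pt = sprintf("pt%03d", 1:50),
                           prob = exp(seq(log(0.002), log(0.08), length.out = 50))
                         ),
                         signal_matrix = tibble(drug = character(),
                                                pt = character(),
                                                rho = double()),
                         demographics = list(
                           sex = c(male = 0.6, female = 0.4),
                           age_group = c("<18" = 0.01, "18-44" = 0.09,
                                         "45-64" = 0.38, ">=65" = 0.52),
                           reporter = c(physician = 0.62, pharmacist = 0.13,
                                        other_health_professional = 0.19,
                                        consumer = 0.06),
                           country = c(CN = 0.5, US = 0.2, JP = 0.1, DE = 0.1,
                                       AU = 0.05, EG = 0.05)
                         ),
                         missingness = list(sex = 0.3, age = 0.3,
                                            reporter = 0.05, country = 0.1,
                                            dates = 0.5),
                         onset_laws = tibble(pt = ".default", scale = 4.193,
                                             shape = 0.597, p0 = 0.4),
                         duplicate_rate = 0.05,
                         deletion_rate = 0.02,
                         seed = 1L) {
  cfg <- list(
    n_cases = as.integer(n_cases), drugs = as_tibble(drugs),
    pts = as_tibble(pts), signal_matrix = as_tibble(signal_matrix),
    demographics = demographics, missingness = missingness,
    onset_laws = as_tibble(onset_laws),
    duplicate_rate = duplicate_rate, deletion_rate = deletion_rate,
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$n_cases > 0)
  if (any(cfg$drugs$prob < 0) || sum(cfg$drugs$prob) <= 0) {
    abort("drug exposure probabilities must be nonnegative with positive sum",
          class = "pvsignal_config_error")
  }
  if (any(cfg$pts$prob < 0 | cfg$pts$prob > 1)) {
    abort("PT background probabilities must lie in [0, 1]",
          class = "pvsignal_config_error")
  }
  if (all(cfg$pts$prob == 0)) {
    abort("all PT background probabilities are zero: no case can have an event",
          class = "pvsignal_config_error")
  }
  if (nrow(cfg$signal_matrix) > 0 &&
      any(!is.finite(cfg$signal_matrix$rho) | cfg$signal_matrix$rho < 0)) {
    abort("signal_matrix rho values must be finite and nonnegative",
          class = "pvsignal_config_error")
  }
  if (any(cfg$onset_laws$scale <= 0) || any(cfg$onset_laws$shape <= 0) ||
      any(cfg$onset_laws$p0 < 0 | cfg$onset_laws$p0 > 1)) {
    abort("onset laws need scale > 0, shape > 0, p0 in [0, 1]",
          class = "pvsignal_config_error")
  }
  rates <- c(cfg$duplicate_rate, cfg$deletion_rate,
             unlist(cfg$missingness, use.names = FALSE))
  if (any(rates < 0 | rates >= 1)) {
    abort("duplicate/deletion/missingness rates must lie in [0, 1)",
          class = "pvsignal_config_error")
  }
  invisible(cfg)
}

sample_categorical <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE,
                          prob = probs / sum(probs))]
}

#' Generate a synthetic report collection with ground truth
#'
#' Each case draws one suspect drug from the exposure probabilities; each
#' preferred term enters the case independently with probability
#' `background * rho(drug, pt)` clipped at 1, with a redraw guaranteeing at
#' least one PT per case. Onset time is drawn from the index PT's law
#' (day 0 with probability `p0`, else Weibull rounded to whole days) and
#' realized as `event_date - therapy_start`. Demographics and per-field
#' missingness are sampled independently. Reproducible given `config$seed`.
#'
#' @param config A [synth_config()].
#' @return A list with `reports` (a `safety_reports` tibble) and `truth`
#'   (a `synth_truth` list: realized `pair_counts`, the `signal_matrix`
#'   used, and per-case `onsets` with the pre-rounding generating values).
#' @export
generate_reports <- function(config) {
  validate_synth_config(config)
  with_seed(stage_seed(config$seed, "generate"), {
    n <- config$n_cases
    drugs <- config$drugs
    pts <- config$pts
    n_pt <- nrow(pts)

    drug_idx <- sample.int(nrow(drugs), n, replace = TRUE,
                           prob = drugs$prob / sum(drugs$prob))
    drug_of_case <- drugs$drug[drug_idx]

    # per-(drug, pt) inclusion probabilities: background * rho, clipped to 1
    pmat <- matrix(rep(pts$prob, each = nrow(drugs)), nrow = nrow(drugs),
                   dimnames = list(drugs$drug, pts$pt))
    if (nrow(config$signal_matrix) > 0) {
      sm <- config$signal_matrix
      for (k in seq_len(nrow(sm))) {
        if (sm$drug[k] %in% rownames(pmat) && sm$pt[k] %in% colnames(pmat)) {
          pmat[sm$drug[k], sm$pt[k]] <- pmat[sm$drug[k], sm$pt[k]] * sm$rho[k]
        }
      }
    }
    pmat <- pmin(pmat, 1)

    hit_list <- vector("list", n_pt)
    for (j in seq_len(n_pt)) {
      p_vec <- pmat[drug_idx, j]
      hit_list[[j]] <- which(runif(n) < p_vec)
    }
    case_rows <- unlist(hit_list, use.names = FALSE)
    pt_rows <- rep.int(seq_len(n_pt), lengths(hit_list))
    # guarantee at least one PT per case: redraw a single PT proportional to
    # the case's inclusion probabilities
    empty <- setdiff(seq_len(n), unique(case_rows))
    if (length(empty) > 0) {
      for (d in unique(drug_idx[empty])) {
        cases_d <- empty[drug_idx[empty] == d]
        pj <- pmat[d, ]
        if (sum(pj) <= 0) pj <- rep(1, n_pt)
        extra <- sample.int(n_pt, length(cases_d), replace = TRUE,
                            prob = pj / sum(pj))
        case_rows <- c(case_rows, cases_d)
        pt_rows <- c(pt_rows, extra)
      }
    }
    ord <- order(case_rows, pt_rows)
    case_rows <- case_rows[ord]
    pt_rows <- pt_rows[ord]
    pts_by_case <- split(pts$pt[pt_rows], case_rows)
    index_pt <- vapply(pts_by_case, function(x) x[[1]], character(1))

    # onset law per case, keyed on the index PT with a .default fallback
    laws <- config$onset_laws
    law_row <- match(index_pt, laws$pt)
    if (anyNA(law_row)) {
      def <- match(".default", laws$pt)
      if (is.na(def)) {
        abort("onset_laws must cover every PT or provide a '.default' row",
              class = "pvsignal_config_error")
      }
      law_row[is.na(law_row)] <- def
    }
    raw_onset <- rweibull(n, shape = laws$shape[law_row],
                          scale = laws$scale[law_row])
    zero_mass <- runif(n) < laws$p0[law_row]
    raw_onset[zero_mass] <- 0
    onset_days <- round(raw_onset)

    therapy_start <- as.Date("2015-01-01") + sample.int(3652, n, replace = TRUE) - 1L
    event_date <- therapy_start + onset_days
    dates_missing <- runif(n) < config$missingness$dates
    therapy_start[dates_missing] <- NA
    event_date[dates_missing] <- NA

    dg <- config$demographics
    sex <- sample_categorical(n, dg$sex)
    sex[runif(n) < config$missingness$sex] <- "unknown"
    age_group <- sample_categorical(n, dg$age_group)
    age_lo <- c("<18" = 5, "18-44" = 18, "45-64" = 45, ">=65" = 65)
    age_hi <- c("<18" = 17, "18-44" = 44, "45-64" = 64, ">=65" = 90)
    age_years <- round(age_lo[age_group] +
                         runif(n) * (age_hi[age_group] - age_lo[age_group]))
    age_missing <- runif(n) < config$missingness$age
    age_years[age_missing] <- NA
    age_group <- age_group_of(age_years)
    reporter <- sample_categorical(n, dg$reporter)
    reporter[runif(n) < config$missingness$reporter] <- "unknown"
    country <- sample_categorical(n, dg$country)
    country[runif(n) < config$missingness$country] <- "unknown"

    report_date <- pmin(dplyr::coalesce(event_date,
                                        as.Date("2020-06-30")) +
                          sample.int(365, n, replace = TRUE),
                        as.Date("2024-12-31"))

    reports <- tibble(
      case_id = sprintf("C%07d", seq_len(n)),
      primaryid = sprintf("%07d%03d", seq_len(n), 1L),
      version_date = as.integer(format(report_date, "%Y%m%d")),
      event_date = event_date,
      sex = sex,
      age_years = as.numeric(age_years),
      reporter = reporter,
      country = country,
      age_group = age_group,
      continent = country_to_continent(country),
      drugs = {
        # one shared tibble per drug; rows are immutable so sharing is safe
        uniq <- unique(drug_of_case)
        tpl <- lapply(uniq, function(d) tibble(drug = d, role = "primary_suspect"))
        tpl[match(drug_of_case, uniq)]
      },
      pts = unname(lapply(pts_by_case, function(x) sort(unique(x)))),
      therapy_start = therapy_start,
      outcomes = rep(list(character()), n),
      indication = NA_character_
    )
    reports <- as_safety_reports(reports)

    pair_counts <- tibble(drug = drug_of_case[case_rows],
                          pt = pts$pt[pt_rows]) |>
      dplyr::distinct(case = case_rows, drug, pt) |>
      dplyr::count(drug, pt, name = "n") |>
      dplyr::arrange(drug, pt)

    truth <- structure(
      list(
        pair_counts = pair_counts,
        signal_matrix = config$signal_matrix,
        onsets = tibble(case_id = reports$case_id, pt = index_pt,
                        raw_onset = raw_onset, onset_days = onset_days)
      ),
      class = "synth_truth"
    )
    list(reports = reports, truth = truth)
  })
}

#' Inject duplicate versions and deleted cases into a report collection
#'
#' A fraction of cases receives an extra, earlier-dated version (with a
#' smaller report identifier), and a fraction is placed on the deleted-case
#' list. Running [deduplicate_cases()] on the result recovers the
#' pre-injection collection minus the deleted cases exactly.
#'
#' @param reports A `safety_reports` tibble.
#' @param duplicate_rate,deletion_rate Fractions in `[0, 1)`.
#' @param seed Integer seed.
#' @return List with `records` (raw record tibble including the injected
#'   duplicate versions) and `deleted` (character vector of deleted case
#'   identifiers).
#' @export
inject_artifacts <- function(reports, duplicate_rate = 0.05,
                             deletion_rate = 0.02, seed = 1L) {
  if (duplicate_rate < 0 || duplicate_rate >= 1 ||
      deletion_rate < 0 || deletion_rate >= 1) {
    abort("rates must lie in [0, 1)", class = "pvsignal_config_error")
  }
  with_seed(stage_seed(seed, "artifacts"), {
    n <- nrow(reports)
    records <- as_tibble(reports)
    dup_idx <- which(runif(n) < duplicate_rate)
    if (length(dup_idx) > 0) {
      dupes <- records[dup_idx, , drop = FALSE]
      back <- sample.int(300, length(dup_idx), replace = TRUE) + 9L
      old_date <- yyyymmdd_to_date(dupes$version_date) - back
      dupes$version_date <- as.integer(format(old_date, "%Y%m%d"))
      dupes$primaryid <- paste0(substr(dupes$primaryid, 1, 7),
                                sprintf("%03d", 0L))
      records <- dplyr::bind_rows(records, dupes)
    }
    deleted <- sort(sample(records$case_id[seq_len(n)],
                           size = round(deletion_rate * n)))
    records <- records[order(records$case_id, records$version_date), ,
                       drop = FALSE]
    list(records = records, deleted = deleted)
  })
}

#' Write a report collection as FAERS-style quarterly ASCII tables
#'
#' Emits dollar-sign-delimited DEMO/DRUG/REAC/THER/OUTC/INDI files plus a
#' deleted-case list, in the dialect [parse_faers_tables()] reads, so the
#' generator's output can exercise the ingestion path end-to-end.
#'
#' @param records Raw record tibble (e.g. `inject_artifacts()$records`) or a
#'   `safety_reports` tibble.
#' @param dir Output directory (created if absent).
#' @param deleted Character vector of deleted case identifiers.
#' @return Named list of the file paths written, invisibly.
#' @export
write_faers_tables <- function(records, dir, deleted = character()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  records <- as_tibble(records)
  sex_code <- dplyr::case_match(records$sex, "male" ~ "M", "female" ~ "F",
                                .default = NA_character_)
  rep_code <- dplyr::case_match(
    records$reporter,
    "physician" ~ "MD", "pharmacist" ~ "PH",
    "other_health_professional" ~ "HP", "consumer" ~ "CN",
    .default = NA_character_
  )
  demo <- data.frame(
    primaryid = records$primaryid, caseid = records$case_id,
    fda_dt = records$version_date,
    event_dt = date_to_yyyymmdd(records$event_date),
    sex = sex_code,
    age = ifelse(is.na(records$age_years), NA, as.character(records$age_years)),
    age_cod = ifelse(is.na(records$age_years), NA, "YR"),
    occp_cod = rep_code,
    reporter_country = ifelse(records$country == "unknown", NA, records$country),
    check.names = FALSE
  )
  drug <- records |>
    dplyr::select("primaryid", "drugs") |>
    tidyr::unnest("drugs") |>
    dplyr::transmute(primaryid, drugname = drug, role_cod = role_to_code(role))
  reac <- records |>
    dplyr::select("primaryid", "pts") |>
    tidyr::unnest_longer("pts", values_to = "pt")
  ther <- records |>
    dplyr::filter(!is.na(.data$therapy_start)) |>
    dplyr::transmute(primaryid, start_dt = date_to_yyyymmdd(.data$therapy_start))
  outc <- records |>
    dplyr::select("primaryid", "outcomes") |>
    tidyr::unnest_longer("outcomes", values_to = "outcome") |>
    dplyr::filter(!is.na(.data$outcome)) |>
    dplyr::transmute(primaryid, outc_cod = dplyr::case_match(
      .data$outcome,
      "death" ~ "DE", "life_threatening" ~ "LT", "hospitalization" ~ "HO",
      "disability" ~ "DS", .default = "OT"
    ))
  indi <- records |>
    dplyr::filter(!is.na(.data$indication)) |>
    dplyr::transmute(primaryid, indi_pt = .data$indication)

  write_dollar <- function(df, name) {
    path <- file.path(dir, paste0(name, ".txt"))
    utils::write.table(df, path, sep = "$", quote = FALSE, row.names = FALSE,
                       na = "")
    path
  }
  paths <- list(
    demo = write_dollar(demo, "DEMO"),
    drug = write_dollar(drug, "DRUG"),
    reac = write_dollar(reac, "REAC"),
    ther = write_dollar(ther, "THER"),
    outc = write_dollar(outc, "OUTC"),
    indi = write_dollar(indi, "INDI")
  )
  del_path <- file.path(dir, "DELETED.txt")
  writeLines(c("caseid", deleted), del_path)
  paths$deleted <- del_path
  invisible(paths)
}

#' Write the generator's ground truth as JSON
#'
#' @param truth A `synth_truth` object from [generate_reports()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(pair_counts = truth$pair_counts, signal_matrix = truth$signal_matrix),
    path, dataframe = "columns", auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
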