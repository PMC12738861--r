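# Small fixtures built in code: single-report constructor, tiny FAERS-style
# files, and an aggregate-counts CSV writer.

make_report <- function(case_id, pts, drug = "drugx", role = "primary_suspect",
                        sex = "unknown", age_years = NA_real_,
                        reporter = "unknown", country = "unknown",
                        therapy_start = NA, event_date = NA,
                        version_date = 20200101L,
                        primaryid = paste0(case_id, "001"),
                        outcomes = character(), indication = NA_character_) {
  drugs <- if (is.data.frame(drug)) {
    tibble::as_tibble(drug)
  } else {
    tibble::tibble(drug = pvsignal::normalize_drug_name(drug), role = role)
  }
  tibble::tibble(
    case_id = case_id, primaryid = primaryid,
    version_date = as.integer(version_date),
    event_date = as.Date(event_date),
    sex = sex, age_years = age_years, reporter = reporter, country = country,
    age_group = pvsignal::age_group_of(age_years),
    continent = pvsignal::country_to_continent(country),
    drugs = list(drugs), pts = list(sort(unique(pts))),
    therapy_start = as.Date(therapy_start),
    outcomes = list(outcomes), indication = indication
  )
}

make_reports <- function(...) {
  pvsignal::deduplicate_cases(dplyr::bind_rows(...))
}

# a 3-case FAERS-style fixture written as dollar-delimited text
write_tiny_faers <- function(dir, extra_demo_row = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  demo <- c(
    "primaryid$caseid$fda_dt$event_dt$sex$age$age_cod$occp_cod$reporter_country",
    "1000001$100$20190301$20190105$M$64$YR$MD$CN",
    "2000001$200$20190315$$F$71$YR$PH$US",
    "3000001$300$20190320$20190210$$$$$"
  )
  if (!is.null(extra_demo_row)) demo <- c(demo, extra_demo_row)
  writeLines(demo, file.path(dir, "DEMO.txt"))
  writeLines(c(
    "primaryid$drugname$role_cod",
    "1000001$Tirofiban$PS",
    "1000001$aspirin$C",
    "2000001$TIROFIBAN $PS",
    "3000001$heparin$PS",
    "3000001$tirofiban$C"
  ), file.path(dir, "DRUG.txt"))
  writeLines(c(
    "primaryid$pt",
    "1000001$Haemorrhage",
    "1000001$Thrombocytopenia",
    "2000001$Haemorrhage",
    "3000001$Epistaxis"
  ), file.path(dir, "REAC.txt"))
  writeLines(c(
    "primaryid$start_dt",
    "1000001$20190101",
    "2000001$20190201"
  ), file.path(dir, "THER.txt"))
  writeLines(c(
    "primaryid$outc_cod",
    "1000001$HO",
    "1000001$LT"
  ), file.path(dir, "OUTC.txt"))
  invisible(dir)
}

write_agg_csv <- function(path, df, totals = NULL) {
  lines <- c("drug,pt,count",
             sprintf("%s,%s,%d", df$drug, df$pt, df$count))
  if (!is.null(totals)) lines <- c(lines, totals)
  writeLines(lines, path)
  path
}

# independent 2x2 oracles used across tests
oracle_chi2 <- function(a, b, c, d) {
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  suppressWarnings(unname(stats::chisq.test(m, correct = FALSE)$statistic))
}

oracle_fisher_two_sided <- function(a, b, c, d) {
  # full hypergeometric enumeration at fixed margins
  m1 <- a + b; m2 <- c + d; k <- a + c
  lo <- max(0, k - m2); hi <- min(k, m1)
  probs <- stats::dhyper(lo:hi, m1, m2, k)
  p_obs <- stats::dhyper(a, m1, m2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# vectorized bulk constructor for large demographic/onset fixtures
make_bulk_reports <- function(sex_counts = c(unknown = 10), onset_days = NULL,
                              drug = "drugx") {
  n <- if (!is.null(onset_days)) length(onset_days) else sum(sex_counts)
  sex <- if (!is.null(onset_days)) rep("unknown", n)
         else rep(names(sex_counts), sex_counts)
  start <- as.Date("2019-01-01")
  tbl <- tibble::tibble(
    case_id = sprintf("B%07d", seq_len(n)),
    primaryid = sprintf("B%07d001", seq_len(n)),
    version_date = 20200101L,
    event_date = if (is.null(onset_days)) as.Date(rep(NA, n))
                 else start + onset_days,
    sex = sex,
    age_years = rep(NA_real_, n),
    reporter = rep("unknown", n),
    country = rep("unknown", n),
    age_group = rep("unknown", n),
    continent = rep("unknown", n),
    drugs = rep(list(tibble::tibble(drug = drug, role = "primary_suspect")), n),
    pts = rep(list("A"), n),
    therapy_start = if (is.null(onset_days)) as.Date(rep(NA, n))
                    else rep(start, n),
    outcomes = rep(list(character()), n),
    indication = rep(NA_character_, n)
  )
  pvsignal::deduplicate_cases(tbl)
}
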