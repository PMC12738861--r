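test_that("FAERS-style tables parse into typed records with attached PTs", {
  dir <- withr::local_tempdir()
  write_tiny_faers(dir)
  rec <- parse_faers_tables(list(
    demo = file.path(dir, "DEMO.txt"), drug = file.path(dir, "DRUG.txt"),
    reac = file.path(dir, "REAC.txt"), ther = file.path(dir, "THER.txt"),
    outc = file.path(dir, "OUTC.txt")
  ))
  expect_equal(nrow(rec), 3)
  expect_equal(sort(rec$pts[[which(rec$case_id == "100")]]),
               c("Haemorrhage", "Thrombocytopenia"))
  # role code PS maps to primary_suspect, C to concomitant
  d100 <- rec$drugs[[which(rec$case_id == "100")]]
  expect_equal(d100$role[d100$drug == "tirofiban"], "primary_suspect")
  expect_equal(d100$role[d100$drug == "aspirin"], "concomitant")
  # drug names are normalized (case-folded, trimmed)
  d200 <- rec$drugs[[which(rec$case_id == "200")]]
  expect_equal(d200$drug, "tirofiban")
  # typed demographics
  expect_equal(rec$sex[rec$case_id == "100"], "male")
  expect_equal(rec$age_group[rec$case_id == "200"], ">=65")
  expect_equal(rec$continent[rec$case_id == "100"], "Asia")
  expect_equal(rec$therapy_start[rec$case_id == "100"], as.Date("2019-01-01"))
  expect_equal(rec$outcomes[[which(rec$case_id == "100")]],
               c("hospitalization", "life_threatening"))
  expect_equal(rec$sex[rec$case_id == "300"], "unknown")
})

test_that("malformed rows are rejected and counted, not silently dropped", {
  dir <- withr::local_tempdir()
  write_tiny_faers(dir, extra_demo_row = "4000001$$20190401$$M$50$YR$MD$US")
  rec <- parse_faers_tables(list(
    demo = file.path(dir, "DEMO.txt"), drug = file.path(dir, "DRUG.txt"),
    reac = file.path(dir, "REAC.txt")
  ))
  expect_equal(nrow(rec), 3)
  rejects <- attr(rec, "rejects")
  expect_equal(rejects$rejected[rejects$table == "demo"], 1L)
})

test_that("a missing mandatory column raises a format error naming it", {
  dir <- withr::local_tempdir()
  write_tiny_faers(dir)
  writeLines(c("primaryid$drugname", "1000001$tirofiban"),
             file.path(dir, "DRUG.txt"))
  expect_error(
    parse_faers_tables(list(demo = file.path(dir, "DEMO.txt"),
                            drug = file.path(dir, "DRUG.txt"),
                            reac = file.path(dir, "REAC.txt"))),
    "role_cod", class = "pvsignal_format_error"
  )
  expect_error(
    parse_faers_tables(list(demo = file.path(dir, "nope.txt"),
                            drug = file.path(dir, "DRUG.txt"),
                            reac = file.path(dir, "REAC.txt"))),
    class = "pvsignal_io_error"
  )
})

test_that("deduplication keeps the latest version and honors the deleted list", {
  one <- make_report("100", pts = "Haemorrhage")
  expect_equal(nrow(deduplicate_cases(one)), 1)

  two_versions <- dplyr::bind_rows(
    make_report("100", pts = "Haemorrhage", version_date = 20190101,
                primaryid = "1000001"),
    make_report("100", pts = "Thrombocytopenia", version_date = 20190301,
                primaryid = "1000002")
  )
  dd <- deduplicate_cases(two_versions)
  expect_equal(nrow(dd), 1)
  expect_equal(dd$version_date, 20190301L)
  expect_equal(dd$pts[[1]], "Thrombocytopenia")

  # version-date tie broken by the larger report identifier
  tie <- dplyr::bind_rows(
    make_report("100", pts = "A", version_date = 20190101, primaryid = "1000001"),
    make_report("100", pts = "B", version_date = 20190101, primaryid = "1000009")
  )
  expect_equal(deduplicate_cases(tie)$primaryid, "1000009")

  five <- dplyr::bind_rows(lapply(as.character(1:5), function(i) {
    make_report(i, pts = "A")
  }))
  expect_equal(nrow(deduplicate_cases(five, deleted_case_ids = c("2", "4"))), 3)
  expect_equal(nrow(deduplicate_cases(five[0, ])), 0)
})

test_that("deduplication is idempotent and never increases the record count", {
  cfg <- synth_config(n_cases = 300, seed = 7)
  g <- generate_reports(cfg)
  art <- inject_artifacts(g$reports, 0.2, 0.1, seed = 7)
  once <- deduplicate_cases(art$records, art$deleted)
  twice <- deduplicate_cases(once, art$deleted)
  strip <- function(x) {
    attr(x, "cleaning_log") <- NULL
    as.data.frame(x)
  }
  expect_identical(strip(once), strip(twice))
  expect_lte(nrow(once), nrow(art$records))
  # no duplicates/deletions: equality
  clean <- deduplicate_cases(g$reports)
  expect_equal(nrow(clean), nrow(g$reports))
})

test_that("primary-suspect filtering is role- and name-exact", {
  reports <- make_reports(
    make_report("1", pts = "A", drug = "tirofiban", role = "primary_suspect"),
    make_report("2", pts = "A", drug = "tirofiban", role = "concomitant"),
    make_report("3", pts = "B", drug = "Tirofiban ", role = "primary_suspect"),
    make_report("4", pts = "B", drug = "heparin"),
    make_report("5", pts = "B", drug = "aspirin"),
    make_report("6", pts = "A", drug = "aggrastat", role = "primary_suspect")
  )
  kept <- filter_primary_suspect(reports, "TIROFIBAN")
  expect_equal(sort(kept$case_id), c("1", "3"))
  # synonym list extends the match
  kept2 <- filter_primary_suspect(reports, "tirofiban", synonyms = "aggrastat")
  expect_equal(sort(kept2$case_id), c("1", "3", "6"))
  expect_warning(out <- filter_primary_suspect(reports, "no-such-drug"),
                 "not found")
  expect_equal(nrow(out), 0)
  expect_equal(nrow(filter_primary_suspect(reports[0, ], "tirofiban")), 0)
})

test_that("aggregate counts read with derived or stated totals and validate", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(drug = c("x", "x", "y", "y"), pt = c("A", "B", "A", "B"),
                   count = c(1L, 2L, 3L, 4L))
  write_agg_csv(path, df)
  agg <- read_aggregate_counts(path)
  expect_equal(agg$grand_total, 10)
  expect_true(agg$derived_totals)
  expect_equal(agg$pt_totals$count[agg$pt_totals$pt == "A"], 4)

  # stated totals win and are checked; database-wide margins may exceed
  # the in-file pair sums
  write_agg_csv(path, df[df$drug == "x", ],
                totals = c("x,,3", ",A,100", ",B,200", ",,1000"))
  agg2 <- read_aggregate_counts(path)
  expect_false(agg2$derived_totals)
  expect_equal(agg2$grand_total, 1000)
  expect_equal(agg2$pt_totals$count[agg2$pt_totals$pt == "A"], 100)

  write_agg_csv(path, data.frame(drug = "x", pt = "A", count = -1L))
  expect_error(read_aggregate_counts(path), class = "pvsignal_integrity_error")

  # a stated total below the in-file pair sum is an integrity error
  write_agg_csv(path, df, totals = "x,,2")
  expect_error(read_aggregate_counts(path), class = "pvsignal_integrity_error")
})

test_that("demographic summaries give per-category counts and percentages", {
  reports <- make_reports(
    make_report("1", pts = "A", sex = "male", age_years = 70),
    make_report("2", pts = "A", sex = "male", age_years = 50),
    make_report("3", pts = "A", sex = "female", age_years = 30),
    make_report("4", pts = "A")
  )
  tab <- summarize_demographics(reports)
  sex <- tab[tab$field == "sex", ]
  expect_equal(sex$n[sex$category == "male"], 2L)
  expect_equal(sex$percentage[sex$category == "male"], 50)
  expect_equal(sex$percentage[sex$category == "unknown"], 25)
  # percentages within a field sum to 100 within rounding
  sums <- tapply(tab$percentage, tab$field, sum)
  expect_true(all(abs(sums - 100) <= 0.05))
  # all-unknown field
  expect_equal(tab$percentage[tab$field == "reporter" &
                                tab$category == "unknown"], 100)
  expect_error(summarize_demographics(reports[0, ]),
               class = "pvsignal_usage_error")
})

test_that("the normalized export round-trips field-for-field", {
  g <- generate_reports(synth_config(n_cases = 120, seed = 11))
  dir <- withr::local_tempdir()
  write_reports(g$reports, dir)
  back <- read_reports(dir)
  expect_equal(as.data.frame(back), as.data.frame(g$reports))
})

test_that("the FAERS-dialect writer round-trips through the parser", {
  g <- generate_reports(synth_config(n_cases = 150, seed = 3))
  art <- inject_artifacts(g$reports, 0.1, 0.05, seed = 3)
  dir <- withr::local_tempdir()
  write_faers_tables(art$records, dir, deleted = art$deleted)
  rec <- parse_faers_tables(list(
    demo = file.path(dir, "DEMO.txt"), drug = file.path(dir, "DRUG.txt"),
    reac = file.path(dir, "REAC.txt"), ther = file.path(dir, "THER.txt")
  ))
  dd <- deduplicate_cases(rec, read_deleted_cases(file.path(dir, "DELETED.txt")))
  expected <- deduplicate_cases(g$reports,
                                art$deleted)
  expect_equal(nrow(dd), nrow(expected))
  expect_equal(dd$case_id, expected$case_id)
  expect_equal(dd$pts, expected$pts)
  expect_equal(dd$sex, expected$sex)
  expect_equal(dd$therapy_start, expected$therapy_start)
  expect_equal(dd$event_date, expected$event_date)
})
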