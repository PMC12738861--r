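test_that("PT-level cells follow the drug-event pair convention", {
  reports <- make_reports(
    make_report("1", pts = "A", drug = "drugX"),
    make_report("2", pts = c("A", "B"), drug = "drugX"),
    make_report("3", pts = "B", drug = "drugX"),
    make_report("4", pts = "A", drug = "drugY"),
    make_report("5", pts = "B", drug = "drugY"),
    make_report("6", pts = "B", drug = "drugY")
  )
  tabs <- build_pt_tables(reports, "drugX")
  expect_equal(attr(tabs, "N"), 7)
  rowA <- tabs[tabs$event == "A", ]
  expect_equal(unlist(rowA[c("a", "b", "c", "d")], use.names = FALSE),
               c(2L, 2L, 1L, 2L))
  # every table satisfies a+b+c+d = N and shares the drug margin
  expect_true(all(tabs$a + tabs$b + tabs$c + tabs$d == attr(tabs, "N")))
  expect_true(all(tabs$a + tabs$b == attr(tabs, "drug_margin")))
})

test_that("report-level and aggregate-level construction agree", {
  reports <- make_reports(
    make_report("1", pts = "A", drug = "drugX"),
    make_report("2", pts = c("A", "B"), drug = "drugX"),
    make_report("3", pts = "B", drug = "drugX"),
    make_report("4", pts = "A", drug = "drugY"),
    make_report("5", pts = "B", drug = "drugY"),
    make_report("6", pts = "B", drug = "drugY")
  )
  from_reports <- build_pt_tables(reports, "drugX")
  path <- withr::local_tempfile(fileext = ".csv")
  write_agg_csv(path, data.frame(
    drug = c("drugx", "drugx", "drugy", "drugy"),
    pt = c("A", "B", "A", "B"),
    count = c(2L, 2L, 1L, 2L)
  ))
  from_agg <- build_pt_tables(read_aggregate_counts(path), "drugX")
  expect_equal(as.data.frame(from_reports), as.data.frame(from_agg))
})

test_that("degenerate single-report databases build but flag downstream", {
  reports <- make_reports(make_report("1", pts = "A", drug = "drugX"))
  tabs <- build_pt_tables(reports, "drugX")
  expect_equal(unlist(tabs[1, c("a", "b", "c", "d")], use.names = FALSE),
               c(1L, 0L, 0L, 0L))
  # estimators refuse the zero cells rather than erroring
  expect_true(is.na(compute_ror(tabs)$ror))
  expect_true(is.na(compute_prr(tabs)$prr))
})

test_that("SOC-level counting deduplicates within report", {
  soc_map <- tibble::tibble(
    pt = c("A", "B", "C", "D"),
    soc = c("Vascular", "Vascular", "Vascular", "Cardiac")
  )
  reports <- make_reports(
    make_report("1", pts = c("A", "B", "C"), drug = "drugX"),
    make_report("2", pts = c("A", "D"), drug = "drugX"),
    make_report("3", pts = "D", drug = "drugY")
  )
  socs <- build_soc_tables(reports, "drugX", soc_map)
  expect_equal(socs$a[socs$event == "Vascular"], 2L)
  pt_tabs <- build_pt_tables(reports, "drugX")
  expect_lte(sum(socs$a), sum(pt_tabs$a))
  # uncovered PTs go to an 'unmapped' SOC with a warning
  expect_warning(
    socs2 <- build_soc_tables(reports, "drugX", soc_map[1:3, ]),
    "unmapped"
  )
  expect_true("unmapped" %in% socs2$event)
})

test_that("shared SOC vocabulary across two databases intersects correctly", {
  soc_map <- tibble::tibble(pt = sprintf("pt%02d", 1:30),
                            soc = sprintf("SOC%02d", rep(1:10, each = 3)))
  mk <- function(seed, drop_soc) {
    cfg <- synth_config(
      n_cases = 2000, seed = seed,
      pts = tibble::tibble(pt = sprintf("pt%02d", 1:30), prob = 0.05)
    )
    g <- generate_reports(cfg)
    tabs <- build_soc_tables(g$reports, "drug01", soc_map)
    setdiff(tabs$event, drop_soc)
  }
  s1 <- mk(1, "SOC10")
  s2 <- mk(2, "SOC01")
  ov <- intersect_signals(s1, s2)
  expect_equal(ov$n_shared, 8)
})

test_that("stratification partitions reports with unknowns excluded", {
  reports <- make_reports(
    make_report("1", pts = "A", sex = "male"),
    make_report("2", pts = "A", sex = "male"),
    make_report("3", pts = "A", sex = "male"),
    make_report("4", pts = "A", sex = "male"),
    make_report("5", pts = "A", sex = "female"),
    make_report("6", pts = "A", sex = "female"),
    make_report("7", pts = "A", sex = "female"),
    make_report("8", pts = "A"),
    make_report("9", pts = "A"),
    make_report("10", pts = "A")
  )
  s <- stratify(reports, "sex")
  expect_equal(vapply(s, nrow, integer(1)), c(female = 3L, male = 4L))

  # age 65 belongs to the elderly stratum
  ages <- make_reports(
    make_report("1", pts = "A", age_years = 64),
    make_report("2", pts = "A", age_years = 65),
    make_report("3", pts = "A", age_years = 80),
    make_report("4", pts = "A")
  )
  s2 <- stratify(ages, "age65")
  expect_equal(s2[["<65"]]$case_id, "1")
  expect_equal(sort(s2[[">=65"]]$case_id), c("2", "3"))

  # physicians, pharmacists and other HPs form the healthcare stratum
  reps <- make_reports(
    make_report("1", pts = "A", reporter = "physician"),
    make_report("2", pts = "A", reporter = "pharmacist"),
    make_report("3", pts = "A", reporter = "other_health_professional"),
    make_report("4", pts = "A", reporter = "consumer"),
    make_report("5", pts = "A")
  )
  s3 <- stratify(reps, "reporter_type")
  expect_equal(nrow(s3$healthcare), 3)
  expect_equal(nrow(s3$non_healthcare), 1)
  expect_error(stratify(reports, "nope"))
})

test_that("stratum tables sum cell-wise to the known-field table", {
  g <- generate_reports(synth_config(n_cases = 3000, seed = 17))
  known <- g$reports[g$reports$sex %in% c("male", "female"), ]
  full <- build_pt_tables(known, "drug01", include_zero = TRUE)
  strata <- stratify(g$reports, "sex")
  parts <- lapply(strata, build_pt_tables, drug = "drug01", include_zero = TRUE)
  for (ev in full$event) {
    cells <- Reduce(`+`, lapply(parts, function(p) {
      row <- p[p$event == ev, c("a", "b", "c", "d")]
      if (nrow(row) == 0) {
        # PT unobserved in this stratum: it still contributes its margins
        dm <- attr(p, "drug_margin")
        c(a = 0L, b = dm, c = 0L, d = attr(p, "N") - dm)
      } else {
        unlist(row)
      }
    }))
    expect_equal(unname(cells),
                 unname(unlist(full[full$event == ev, c("a", "b", "c", "d")])))
  }
})

test_that("table sets export and re-import losslessly", {
  g <- generate_reports(synth_config(n_cases = 500, seed = 23))
  tabs <- build_pt_tables(g$reports, "drug01")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_table_set(tabs, path)
  back <- read_table_set(path, drug = "drug01")
  expect_equal(as.data.frame(back), as.data.frame(tabs))
  expect_equal(attr(back, "N"), attr(tabs, "N"))
})

test_that("an absent drug yields an empty table set with a warning", {
  g <- generate_reports(synth_config(n_cases = 200, seed = 29))
  expect_warning(tabs <- build_pt_tables(g$reports, "no-such-drug"),
                 "not a primary suspect")
  expect_equal(nrow(tabs), 0)
})
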