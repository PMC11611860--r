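test_that("read_faers_table parses the '$' dialect verbatim", {
  p <- write_dollar_file(withr::local_tempfile(),
                         c("primaryid", "caseid", "fda_dt"),
                         list(c("100", "50", "20210315")))
  tab <- read_faers_table(p, "DEMO")
  expect_equal(nrow(tab), 1L)
  expect_equal(names(tab), c("primaryid", "caseid", "fda_dt"))
  expect_equal(tab$primaryid, "100")
  expect_equal(tab$fda_dt, "20210315")
  expect_equal(attr(tab, "table_kind"), "DEMO")
})

test_that("empty fields, including trailing ones, are preserved as missing", {
  p <- write_dollar_file(withr::local_tempfile(),
                         c("primaryid", "role_cod", "drugname"),
                         list(c("1", "PS", "DISULFIRAM"), c("2", "C", "")))
  tab <- read_faers_table(p, "DRUG")
  expect_equal(tab$drugname, c("DISULFIRAM", ""))
})

test_that("a field-count mismatch is an error naming the line", {
  p <- write_dollar_file(withr::local_tempfile(),
                         c("primaryid", "caseid", "fda_dt"),
                         list(c("1", "2", "3"), c("4", "5")))
  expect_error(read_faers_table(p, "DEMO"), "line 3")
})

test_that("unknown table kinds and missing required columns are rejected", {
  p <- write_dollar_file(withr::local_tempfile(), c("primaryid", "caseid"),
                         list(c("1", "2")))
  expect_error(read_faers_table(p, "BOGUS"))
  expect_error(read_faers_table(p, "DEMO"), "fda_dt")
  expect_error(read_faers_table(withr::local_tempfile(), "DEMO"), "not found")
})

test_that("a written DEMO file round-trips byte-identically through read", {
  cfg <- synthetic_cohort_config(n_reports = 1000, seed = 42)
  reports <- generate_cohort(cfg)
  d <- withr::local_tempdir()
  paths <- write_faers_files(reports, d)
  tab <- read_faers_table(paths[["demo"]], "DEMO")
  reserialized <- file.path(d, "demo2.txt")
  writeLines(c(paste(names(tab), collapse = "$"),
               do.call(paste, c(unname(as.list(tab)), sep = "$"))),
             reserialized)
  expect_identical(readLines(reserialized), readLines(paths[["demo"]]))
})

test_that("deduplication keeps the latest FDA_DT, then the largest PRIMARYID", {
  # a later receipt date wins even against a larger primaryid
  demo <- make_demo(caseid = c("1", "1"), primaryid = c("10", "5"),
                    fda_dt = c("20200101", "20210101"))
  expect_equal(deduplicate_reports(demo)$primaryid, "5")

  # on a date tie the numerically larger primaryid wins
  demo <- make_demo(caseid = c("1", "1"), primaryid = c("10", "12"),
                    fda_dt = c("20200101", "20200101"))
  expect_equal(deduplicate_reports(demo)$primaryid, "12")

  # numeric, not lexicographic: "9" < "10"
  demo <- make_demo(caseid = c("1", "1"), primaryid = c("9", "10"),
                    fda_dt = c("20200101", "20200101"))
  expect_equal(deduplicate_reports(demo)$primaryid, "10")

  # a single row passes through
  demo <- make_demo(caseid = "7", primaryid = "3", fda_dt = "20190101")
  expect_equal(deduplicate_reports(demo), demo, ignore_attr = TRUE)
})

test_that("non-numeric PRIMARYID errors only when a date tie needs it", {
  tie <- make_demo(caseid = c("1", "1"), primaryid = c("A", "B"),
                   fda_dt = c("20200101", "20200101"))
  expect_error(deduplicate_reports(tie), "non-numeric")
  no_tie <- make_demo(caseid = c("1", "1"), primaryid = c("A", "B"),
                      fda_dt = c("20200101", "20210101"))
  expect_equal(deduplicate_reports(no_tie)$primaryid, "B")
})

test_that("deduplication is idempotent, permutation-invariant, one row per case", {
  withr::local_seed(11)
  for (i in 1:5) {
    n <- 60
    demo <- make_demo(
      caseid = as.character(sample(1:20, n, TRUE)),
      primaryid = as.character(sample(1:500, n)),
      fda_dt = as.character(20180000 + sample(101:1231, n, TRUE))
    )
    once <- deduplicate_reports(demo)
    expect_equal(nrow(once), dplyr::n_distinct(demo$caseid))
    expect_equal(deduplicate_reports(once), once, ignore_attr = TRUE)
    shuffled <- demo[sample(n), ]
    expect_equal(deduplicate_reports(shuffled), once, ignore_attr = TRUE)
  }
})

test_that("missing keys are rejected by deduplication", {
  demo <- make_demo(caseid = c("1", ""), primaryid = c("1", "2"),
                    fda_dt = c("20200101", "20200102"))
  expect_error(deduplicate_reports(demo), "caseid")
})

test_that("join_case collapses duplicate PTs and preserves drug roles", {
  demo <- make_demo(caseid = "1", primaryid = "1", fda_dt = "20210315",
                    sex = "M", age = "40", age_cod = "YR", occp_cod = "MD",
                    reporter_country = "US")
  reac <- tibble::tibble(primaryid = c("1", "1"), pt = c("Nausea", "Nausea"))
  drug <- tibble::tibble(primaryid = c("1", "1"), role_cod = c("PS", "C"),
                         drugname = c("Disulfiram", "Ethanol"))
  outc <- tibble::tibble(primaryid = "1", outc_cod = "HO")
  rep1 <- join_case(demo, drug, reac, outc)
  expect_equal(rep1$reactions[[1]], "Nausea")
  expect_equal(rep1$drug_names[[1]], c("DISULFIRAM", "ETHANOL"))
  expect_equal(rep1$drug_roles[[1]], c("PS", "C"))
  expect_equal(rep1$outcomes[[1]], "Hospitalization")
  expect_equal(rep1$gender, "Male")
  expect_equal(rep1$reporter, "Physician")
  expect_equal(rep1$report_year, 2021L)
})

test_that("orphan child rows are counted, not fatal", {
  demo <- make_demo(caseid = "1", primaryid = "1", fda_dt = "20210315")
  reac <- tibble::tibble(primaryid = c("1", "99"), pt = c("Nausea", "Rash"))
  drug <- tibble::tibble(primaryid = "1", role_cod = "PS", drugname = "X")
  outc <- tibble::tibble(primaryid = character(), outc_cod = character())
  rep1 <- join_case(demo, drug, reac, outc)
  expect_equal(nrow(rep1), 1L)
  expect_equal(attr(rep1, "orphans")[["REAC"]], 1L)
  expect_equal(rep1$reactions[[1]], "Nausea")
})

test_that("unknown drug role codes are rejected at parse time", {
  demo <- make_demo(caseid = "1", primaryid = "1", fda_dt = "20210315")
  drug <- tibble::tibble(primaryid = "1", role_cod = "XX", drugname = "X")
  empty_reac <- tibble::tibble(primaryid = character(), pt = character())
  empty_outc <- tibble::tibble(primaryid = character(), outc_cod = character())
  expect_error(join_case(demo, drug, empty_reac, empty_outc), "XX")
})

test_that("ages convert to years by unit, implausible unitless ages drop", {
  demo <- make_demo(
    caseid = as.character(1:6), primaryid = as.character(1:6),
    fda_dt = rep("20200101", 6),
    age = c("24", "730", "520", "4", "40", "130"),
    age_cod = c("MON", "DY", "WK", "DEC", "", "")
  )
  nul <- tibble::tibble(primaryid = character(), role_cod = character(),
                        drugname = character())
  rep1 <- join_case(demo, nul,
                    tibble::tibble(primaryid = character(), pt = character()),
                    tibble::tibble(primaryid = character(), outc_cod = character()))
  expect_equal(rep1$age_years,
               c(2, 730 / 365.25, 520 / 52.18, 40, 40, NA_real_))
  expect_equal(sum(rep1$n_reactions == 0L), 6L)
})

test_that("the PT->SOC map loads, rejects conflicts, warns on unmapped PTs", {
  p <- withr::local_tempfile()
  writeLines(c("pt\tsoc", "Jaundice\tHepatobiliary disorders",
               "Nausea\tGastrointestinal disorders",
               "Nausea\tGastrointestinal disorders"), p)
  map <- load_pt_soc_map(p)
  expect_equal(nrow(map), 2L)  # exact duplicate collapsed
  expect_equal(map$soc[map$pt == "Jaundice"], "Hepatobiliary disorders")
  expect_warning(soc <- pt_to_soc(c("Jaundice", "Vertigo"), map), "UNMAPPED")
  expect_equal(soc, c("Hepatobiliary disorders", "UNMAPPED"))

  conflicted <- withr::local_tempfile()
  writeLines(c("pt\tsoc", "Jaundice\tA", "Jaundice\tB"), conflicted)
  expect_error(load_pt_soc_map(conflicted), "conflicting")

  empty <- withr::local_tempfile()
  writeLines("pt\tsoc", empty)
  expect_error(load_pt_soc_map(empty), "empty")
})
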