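# Fixture builders, all generated in code.

make_table <- function(a, b, c, d, event = "EV", level = "PT") {
  tibble::tibble(event = event, level = level, a = a, b = b, c = c, d = d,
                 N = a + b + c + d)
}

# Write a '$'-delimited file from a header and row vectors.
write_dollar_file <- function(path, header, rows) {
  writeLines(c(paste(header, collapse = "$"),
               vapply(rows, paste, "", collapse = "$")), path)
  path
}

# A minimal raw DEMO tibble.
make_demo <- function(caseid, primaryid, fda_dt, ...) {
  tibble::tibble(caseid = as.character(caseid),
                 primaryid = as.character(primaryid),
                 fda_dt = as.character(fda_dt), ...)
}

# Hand-built case-report tibble (same schema as join_case()).
make_reports <- function(n, drug_names, drug_roles, reactions,
                         gender = "Male", age_years = 40,
                         reporter = "Physician", country = "US",
                         report_year = 2020, outcomes = list(character(0))) {
  tibble::tibble(
    caseid = sprintf("%05d", seq_len(n)),
    primaryid = as.character(seq_len(n) * 10 + 1),
    fda_dt = report_year * 10000L + 101L,
    report_year = rep_len(report_year, n),
    gender = rep_len(gender, n),
    age_years = rep_len(age_years, n),
    reporter = rep_len(reporter, n),
    country = rep_len(country, n),
    outcomes = rep_len(outcomes, n),
    drug_names = rep_len(drug_names, n),
    drug_roles = rep_len(drug_roles, n),
    reactions = rep_len(reactions, n),
    n_reactions = lengths(rep_len(reactions, n))
  )
}

# A 508-report cohort whose marginals equal a published single-drug
# summary table, block by block (blocks are independent columns).
table3_cohort <- function() {
  expand_counts <- function(x) rep(names(x), x)
  gender <- expand_counts(c(Male = 298, Female = 173, Unknown = 37))
  age_groups <- expand_counts(c("<17" = 8, "18~64" = 369, "65~85" = 41,
                                Unknown = 90))
  age_years <- c("<17" = 10, "18~64" = 40, "65~85" = 70)[age_groups]
  reporter <- expand_counts(c(
    Consumer = 112, "Health professional" = 98, Lawyer = 4,
    "Other health professional" = 79, Pharmacist = 37, Physician = 137,
    Unknown = 41
  ))
  country <- expand_counts(c(US = 226, SE = 40, IN = 34, GB = 34, CH = 19,
                             IT = 18, DK = 17, OTHER = 120))
  year <- as.integer(expand_counts(c(
    "2004" = 2, "2005" = 1, "2006" = 4, "2007" = 12, "2008" = 17,
    "2009" = 16, "2010" = 13, "2011" = 13, "2012" = 9, "2013" = 24,
    "2014" = 51, "2015" = 60, "2016" = 44, "2017" = 10, "2018" = 29,
    "2019" = 32, "2020" = 39, "2021" = 79, "2022" = 32, "2023" = 21
  )))
  tibble::tibble(
    caseid = sprintf("%05d", 1:508),
    primaryid = as.character(1:508),
    fda_dt = year * 10000L + 615L,
    report_year = year,
    gender = gender,
    age_years = unname(age_years),
    reporter = reporter,
    country = country,
    outcomes = rep(list(character(0)), 508),
    drug_names = rep(list("DISULFIRAM"), 508),
    drug_roles = rep(list("PS"), 508),
    reactions = rep(list("Headache"), 508),
    n_reactions = 1L
  )
}

get_percent <- function(summary, block, label) {
  summary$percent[summary$block == block & summary$label == label]
}
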