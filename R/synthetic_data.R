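# Seeded generator of FAERS-format fixture data with known ground truth:
# planted drug-event association strengths, duplicate case versions and
# configurable demographic marginals.

#' Default synthetic PT vocabulary with SOC assignments
#'
#' About a hundred MedDRA-style preferred terms across 18 system organ
#' classes — the scale at which a single-drug FAERS cohort typically
#' expresses its adverse events — with Zipf-decaying background
#' frequencies (weight 1/(rank+5), normalised).
#'
#' @return A tibble with columns `pt`, `soc`, `p` (probabilities summing
#'   to 1).
#' @export
default_pt_vocabulary <- function() {
  socs <- list(
    "Nervous system disorders" = c(
      "Headache", "Dizziness", "Polyneuropathy", "Peripheral neuropathy",
      "Seizure", "Generalised tonic-clonic seizure", "Encephalopathy",
      "Toxic encephalopathy", "Somnolence", "Tremor", "Neurotoxicity",
      "Peripheral sensory neuropathy", "Vocal cord paralysis", "Dysgeusia"
    ),
    "Psychiatric disorders" = c(
      "Psychiatric symptom", "Delirium", "Confusional state", "Anxiety",
      "Insomnia", "Psychotic disorder", "Hypomania", "Hallucination",
      "Delusion", "Catatonia", "Mental status changes", "Alcoholism"
    ),
    "Hepatobiliary disorders" = c(
      "Jaundice", "Acute hepatic failure", "Hepatitis acute",
      "Drug-induced liver injury", "Hepatic function abnormal",
      "Ocular icterus", "Hepatic necrosis", "Hepatitis toxic",
      "Hepatic failure", "Liver injury"
    ),
    "Gastrointestinal disorders" = c(
      "Nausea", "Vomiting", "Diarrhoea", "Abdominal pain", "Constipation",
      "Dyspepsia"
    ),
    "General disorders and administration site conditions" = c(
      "Fatigue", "Malaise", "Drug interaction", "Asthenia", "Pyrexia",
      "Chest pain", "Drug ineffective", "Alcohol interaction"
    ),
    "Investigations" = c(
      "Hepatic enzyme increased", "Liver function test increased",
      "Transaminases increased", "Alanine aminotransferase increased",
      "Electrocardiogram st segment depression", "Blood pressure decreased",
      "Blood alcohol increased", "Electroencephalogram abnormal"
    ),
    "Metabolism and nutrition disorders" = c(
      "Alcohol intolerance", "Decreased appetite", "Dehydration"
    ),
    "Cardiac disorders" = c(
      "Tachycardia", "Palpitations", "Myocardial infarction"
    ),
    "Skin and subcutaneous tissue disorders" = c(
      "Rash", "Pruritus", "Hyperhidrosis", "Urticaria", "Erythema"
    ),
    "Injury, poisoning and procedural complications" = c(
      "Off label use", "Toxicity to various agents", "Wrong dose",
      "Overdose", "Product use issue"
    ),
    "Vascular disorders" = c(
      "Flushing", "Hypotension", "Hypertension"
    ),
    "Respiratory, thoracic and mediastinal disorders" = c(
      "Dyspnoea", "Cough", "Respiratory failure"
    ),
    "Immune system disorders" = c(
      "Jarisch-herxheimer reaction", "Hypersensitivity"
    ),
    "Musculoskeletal and connective tissue disorders" = c(
      "Myalgia", "Arthralgia", "Muscular weakness"
    ),
    "Renal and urinary disorders" = c(
      "Acute kidney injury", "Renal impairment"
    ),
    "Eye disorders" = c(
      "Vision blurred", "Optic neuritis"
    ),
    "Blood and lymphatic system disorders" = c(
      "Anaemia", "Methaemoglobinaemia"
    ),
    "Surgical and medical procedures" = c(
      "Liver transplant", "Self-medication"
    )
  )
  pt <- unlist(socs, use.names = FALSE)
  soc <- rep(names(socs), lengths(socs))
  w <- 1 / (seq_along(pt) + 5)
  tibble(pt = pt, soc = soc, p = w / sum(w))
}

DECOY_DRUGS <- c(
  "NALTREXONE", "ACAMPROSATE", "METFORMIN", "LISINOPRIL", "ATORVASTATIN",
  "OMEPRAZOLE", "SERTRALINE", "QUETIAPINE", "GABAPENTIN", "IBUPROFEN",
  "PARACETAMOL", "AMOXICILLIN", "WARFARIN", "PREDNISONE", "DIAZEPAM",
  "ETHANOL"
)

#' Default demographic marginals for the synthetic generator
#'
#' Per-block category probabilities shaped like a real single-drug
#' alcohol-use-disorder pharmacovigilance cohort: male-dominated gender
#' split, mostly working-age adults, physician-led reporting, US-led
#' country mix, a two-decade report-year span, and serious-outcome
#' frequencies dominated by hospitalisation and "other serious".
#'
#' @return A named list of named probability vectors (each block sums
#'   to 1): `gender`, `age_group`, `reporter`, `country`, `report_year`,
#'   `outcomes`.
#' @export
default_demographic_marginals <- function() {
  list(
    gender = c(Female = 173, Male = 298, Unknown = 37) / 508,
    age_group = c("<17" = 8, "18~64" = 369, "65~85" = 41, "Unknown" = 90) / 508,
    reporter = c(
      Consumer = 112, "Health professional" = 98, Lawyer = 4,
      "Other health professional" = 79, Pharmacist = 37, Physician = 137,
      Unknown = 41
    ) / 508,
    country = c(
      US = 226, SE = 40, IN = 34, GB = 34, CH = 19, IT = 18, DK = 17,
      OTHER = 120
    ) / 508,
    report_year = c(
      "2004" = 2, "2005" = 1, "2006" = 4, "2007" = 12, "2008" = 17,
      "2009" = 16, "2010" = 13, "2011" = 13, "2012" = 9, "2013" = 24,
      "2014" = 51, "2015" = 60, "2016" = 44, "2017" = 10, "2018" = 29,
      "2019" = 32, "2020" = 39, "2021" = 79, "2022" = 32, "2023" = 21
    ) / 508,
    outcomes = c(
      Death = 25, Disability = 24, Hospitalization = 241,
      "Life-threatening" = 47, "Other serious" = 255, Missing = 52
    ) / 644
  )
}

#' Configuration of the synthetic report generator
#'
#' Collects and validates every generative-model parameter: cohort scale,
#' the probability a report names the target drug as primary suspect,
#' the background PT frequency vector, planted drug-event association
#' strengths (relative reporting-rate multipliers), the per-report PT
#' multiplicity, the duplicate-version rate, the demographic marginals
#' and the seed.
#'
#' @param n_reports Number of distinct cases to generate (default 10000).
#' @param target_drug Normalised target drug name (default "DISULFIRAM").
#' @param target_drug_fraction Probability a report has the target drug
#'   as primary suspect (default 0.01).
#' @param vocabulary Tibble with columns `pt`, `soc`, `p` (background PT
#'   probabilities summing to 1); default [default_pt_vocabulary()].
#' @param planted_signals Named numeric vector mapping PTs to a relative
#'   reporting-rate multiplier lambda >= 0, applied to the PT's
#'   background probability inside target-PS reports (the PT distribution
#'   then renormalises, so lambda is not itself the true odds ratio — see
#'   the `planted` truth record for the realised values).
#' @param pts_per_report_mean Mean PT count per report; counts are drawn
#'   as 1 + Poisson(mean - 1) and de-duplicated within the report.
#'   Default 2.
#' @param duplicate_rate Fraction of cases later re-emitted as extra
#'   versions by [inject_duplicates()]; in `[0, 1)`.  Default 0.1.
#' @param demographic_marginals List of per-block probability vectors;
#'   default [default_demographic_marginals()].
#' @param seed Integer seed; the generator is fully deterministic given
#'   the config.
#' @return A validated list of class `"synthetic_cohort_config"`.
#' @export
synthetic_cohort_config <- function(n_reports = 10000,
                                    target_drug = "DISULFIRAM",
                                    target_drug_fraction = 0.01,
                                    vocabulary = default_pt_vocabulary(),
                                    planted_signals = c(),
                                    pts_per_report_mean = 2,
                                    duplicate_rate = 0.1,
                                    demographic_marginals = default_demographic_marginals(),
                                    seed = 1) {
  stopifnot(
    n_reports >= 1,
    target_drug_fraction > 0, target_drug_fraction < 1,
    pts_per_report_mean >= 1,
    duplicate_rate >= 0, duplicate_rate < 1
  )
  if (nrow(vocabulary) == 0) abort("empty PT vocabulary")
  if (abs(sum(vocabulary$p) - 1) > 1e-9) {
    abort("vocabulary probabilities must sum to 1")
  }
  if (length(planted_signals) > 0) {
    if (is.null(names(planted_signals)) || any(!nzchar(names(planted_signals)))) {
      abort("planted_signals must be a named vector (PT -> lambda)")
    }
    if (any(planted_signals < 0)) abort("planted lambda must be >= 0")
    missing_pt <- setdiff(names(planted_signals), vocabulary$pt)
    if (length(missing_pt) > 0) {
      abort(paste0("planted PT(s) not in vocabulary: ",
                   paste(missing_pt, collapse = ", ")))
    }
  }
  for (block in names(demographic_marginals)) {
    pr <- demographic_marginals[[block]]
    if (abs(sum(pr) - 1) > 1e-9) {
      abort(paste0("demographic marginal block '", block, "' must sum to 1"))
    }
  }
  structure(
    list(
      n_reports = as.integer(n_reports),
      target_drug = toupper(trimws(target_drug)),
      target_drug_fraction = target_drug_fraction,
      vocabulary = vocabulary,
      planted_signals = planted_signals,
      pts_per_report_mean = pts_per_report_mean,
      duplicate_rate = duplicate_rate,
      demographic_marginals = demographic_marginals,
      seed = as.integer(seed)
    ),
    class = "synthetic_cohort_config"
  )
}

# Probability that a PT with per-draw probability p appears in a report
# whose PT count is 1 + Poisson(m - 1), draws i.i.d. with replacement and
# de-duplicated: P = 1 - (1-p) * exp(-(m-1) * p).
report_presence_prob <- function(p, m) {
  1 - (1 - p) * exp(-(m - 1) * p)
}

sample_block <- function(pr, n) {
  sample(names(pr), n, replace = TRUE, prob = pr)
}

#' Generate a synthetic deduplicated report cohort with known truth
#'
#' Draws `n_reports` case reports: demographics from the configured
#' marginals, a PS drug entry (the target drug for a
#' `target_drug_fraction` share of reports, a decoy otherwise, plus 0-2
#' extra non-PS co-medications; a small share of background reports also
#' carries the target drug in a non-PS role), and a de-duplicated PT list
#' drawn from the background frequencies — with planted PTs drawn at
#' `lambda` times their background rate (renormalised) inside target-PS
#' reports.  Fully deterministic given the config seed.
#'
#' @param cfg A [synthetic_cohort_config()].
#' @return A case-report tibble with the same columns as [join_case()]
#'   output.  Attribute `truth` is a list with `planted` (tibble: `pt`,
#'   `lambda`, per-draw and per-report probabilities under background and
#'   target, and the implied true odds ratio `expected_ror`) and the
#'   `config`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_cohort_config"))
  withr::with_seed(cfg$seed, generate_cohort_impl(cfg))
}

generate_cohort_impl <- function(cfg) {
  n <- cfg$n_reports
  marg <- cfg$demographic_marginals
  vocab <- cfg$vocabulary

  is_target <- runif(n) < cfg$target_drug_fraction
  if (!any(is_target)) {
    # a cohort with zero cases is useless downstream; force one
    is_target[sample.int(n, 1)] <- TRUE
  }

  year <- as.integer(sample_block(marg$report_year, n))
  fda_dt <- year * 10000L + sample(1:12, n, TRUE) * 100L + sample(1:28, n, TRUE)

  gender <- sample_block(marg$gender, n)
  age_group <- sample_block(marg$age_group, n)
  age_years <- rep(NA_real_, n)
  age_years[age_group == "<17"] <- sample(1:17, sum(age_group == "<17"), TRUE)
  age_years[age_group == "18~64"] <- sample(18:64, sum(age_group == "18~64"), TRUE)
  age_years[age_group == "65~85"] <- sample(65:85, sum(age_group == "65~85"), TRUE)
  age_years[age_group == ">85"] <- sample(86:99, sum(age_group == ">85"), TRUE)
  reporter <- sample_block(marg$reporter, n)
  country <- sample_block(marg$country, n)

  # outcomes: one entry per report, a second with probability 0.27
  # ("Missing" as first entry means no outcome rows at all)
  olab <- names(marg$outcomes)
  first <- sample(olab, n, TRUE, prob = marg$outcomes)
  second_on <- runif(n) < 0.27
  second <- sample(olab, n, TRUE, prob = marg$outcomes)
  o_idx <- c(seq_len(n), which(second_on))
  o_val <- c(first, second[second_on])
  keep <- o_val != "Missing"
  # a "Missing" first entry suppresses the whole report's outcomes
  keep[first[o_idx] == "Missing"] <- FALSE
  outcomes <- lapply(
    split(o_val[keep], factor(o_idx[keep], levels = seq_len(n))),
    unique
  )

  # drugs: one PS entry, 0-2 extra co-medications with non-PS roles
  n_extra <- sample(0:2, n, TRUE, prob = c(0.5, 0.3, 0.2))
  ps_name <- ifelse(is_target, cfg$target_drug,
                    sample(DECOY_DRUGS, n, TRUE))
  # some background reports carry the target drug in a non-PS role
  target_nonps <- !is_target & runif(n) < 0.005
  n_drugs <- 1L + n_extra + target_nonps
  d_idx <- rep(seq_len(n), n_drugs)
  d_name <- character(sum(n_drugs))
  d_role <- character(sum(n_drugs))
  pos <- cumsum(n_drugs) - n_drugs + 1L   # first slot per report
  d_name[pos] <- ps_name
  d_role[pos] <- "PS"
  extra_slots <- setdiff(seq_len(sum(n_drugs)), pos)
  nonps_slot <- (cumsum(n_drugs))[target_nonps]   # last slot of those reports
  d_name[nonps_slot] <- cfg$target_drug
  d_role[nonps_slot] <- "C"
  fill <- setdiff(extra_slots, nonps_slot)
  d_name[fill] <- sample(DECOY_DRUGS, length(fill), TRUE)
  d_role[fill] <- sample(c("C", "SS", "I"), length(fill), TRUE,
                         prob = c(0.7, 0.2, 0.1))
  f_idx <- factor(d_idx, levels = seq_len(n))
  drug_names <- split(d_name, f_idx)
  drug_roles <- split(d_role, f_idx)

  # reactions: planted lambdas scale the PT distribution in target reports
  lam <- rep(1, nrow(vocab))
  if (length(cfg$planted_signals) > 0) {
    lam[match(names(cfg$planted_signals), vocab$pt)] <- cfg$planted_signals
  }
  p_bg <- vocab$p
  p_t <- p_bg * lam
  p_t <- p_t / sum(p_t)

  npts <- 1L + rpois(n, cfg$pts_per_report_mean - 1)
  rep_id <- rep(seq_len(n), npts)
  t_long <- rep(is_target, npts)
  pt_idx <- integer(length(rep_id))
  if (any(!t_long)) {
    pt_idx[!t_long] <- sample.int(nrow(vocab), sum(!t_long), TRUE, prob = p_bg)
  }
  if (any(t_long)) {
    pt_idx[t_long] <- sample.int(nrow(vocab), sum(t_long), TRUE, prob = p_t)
  }
  reactions <- lapply(
    split(vocab$pt[pt_idx], factor(rep_id, levels = seq_len(n))),
    unique
  )

  reports <- tibble(
    caseid = sprintf("%08d", seq_len(n)),
    primaryid = as.character(seq_len(n) * 100 + 1),
    fda_dt = fda_dt,
    report_year = year,
    gender = gender,
    age_years = age_years,
    reporter = reporter,
    country = country,
    outcomes = unname(outcomes),
    drug_names = unname(drug_names),
    drug_roles = unname(drug_roles),
    reactions = unname(reactions)
  )
  reports$n_reactions <- lengths(reports$reactions)

  m <- cfg$pts_per_report_mean
  q_bg <- report_presence_prob(p_bg, m)
  q_t <- report_presence_prob(p_t, m)
  planted <- tibble(
    pt = vocab$pt,
    lambda = lam,
    p_background = p_bg,
    p_target = p_t,
    q_background = q_bg,
    q_target = q_t,
    expected_ror = (q_t / (1 - q_t)) / (q_bg / (1 - q_bg))
  )
  attr(reports, "truth") <- list(
    planted = planted[planted$lambda != 1, , drop = FALSE],
    presence = planted,
    config = cfg
  )
  reports
}

#' Re-emit selected cases as duplicate versions
#'
#' Marks a `rate` fraction of cases for duplication and re-emits each 1-3
#' extra times with a strictly later FDA receipt date and a strictly
#' larger PRIMARYID (the content is otherwise identical, with the report
#' year tracking the new date).  The latest version of each group is the
#' expected deduplication survivor, recorded in the truth attribute.
#'
#' @param reports A case-report tibble (e.g. from [generate_cohort()]).
#' @param rate Fraction of cases duplicated, in `[0, 1)`.
#' @param seed Integer seed.
#' @return The expanded tibble (originals first, duplicate versions
#'   appended).  Attribute `dup_truth`: tibble of `caseid`,
#'   `survivor_primaryid`, `n_versions`.  Any `truth` attribute on the
#'   input is carried over.
#' @export
inject_duplicates <- function(reports, rate, seed = 1) {
  stopifnot(rate >= 0, rate < 1)
  withr::with_seed(seed, {
    n <- nrow(reports)
    sel <- which(runif(n) < rate)
    survivor <- reports$primaryid
    n_versions <- rep(1L, n)
    extra <- reports[integer(0), , drop = FALSE]
    if (length(sel) > 0) {
      k <- sample(1:3, length(sel), TRUE)
      n_versions[sel] <- 1L + k
      rows <- rep(sel, k)
      extra <- reports[rows, , drop = FALSE]
      version <- unlist(lapply(k, seq_len), use.names = FALSE)
      offsets <- unlist(lapply(k, function(m) cumsum(sample(1:30, m, TRUE))),
                        use.names = FALSE)
      base_pid <- as.numeric(reports$primaryid[rows])
      extra$primaryid <- as.character(base_pid + version)
      new_date <- ymd_int_to_date(reports$fda_dt[rows]) + offsets
      extra$fda_dt <- date_to_ymd_int(new_date)
      extra$report_year <- extra$fda_dt %/% 10000L
      last <- cumsum(k)
      survivor[sel] <- extra$primaryid[last]
    }
    out <- bind_rows(reports, extra)
    attr(out, "truth") <- attr(reports, "truth")
    attr(out, "dup_truth") <- tibble(
      caseid = reports$caseid,
      survivor_primaryid = survivor,
      n_versions = n_versions
    )
    out
  })
}

#' Write a report collection as FAERS-style ASCII files
#'
#' Serialises case reports into the '$'-delimited DEMO/DRUG/REAC/OUTC
#' quarterly dialect consumed by [read_faers_table()], plus a PT-to-SOC
#' TSV covering every emitted PT and, when present, the generator's truth
#' records as CSVs.
#'
#' @param reports A case-report tibble.
#' @param out_dir Output directory (created if needed).
#' @param map Optional PT-to-SOC tibble; defaults to the vocabulary in the
#'   reports' truth attribute.  Must cover every emitted PT.
#' @return Invisibly, a named character vector of the written file paths
#'   (`demo`, `drug`, `reac`, `outc`, `pt_soc_map`, and truth files when
#'   available).
#' @export
write_faers_files <- function(reports, out_dir, map = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- attr(reports, "truth")
  if (is.null(map)) {
    if (is.null(truth)) {
      abort("write_faers_files(): no PT->SOC map given and no truth attribute")
    }
    map <- truth$config$vocabulary[, c("pt", "soc")]
  }
  emitted_pts <- unique(unlist(reports$reactions, use.names = FALSE))
  uncovered <- setdiff(emitted_pts, map$pt)
  if (length(uncovered) > 0) {
    abort(paste0("PT->SOC map does not cover emitted PT(s): ",
                 paste(uncovered, collapse = ", ")))
  }

  gender_code <- c(Female = "F", Male = "M", Unknown = "UNK")
  occp_code <- setNames(names(OCCP_CODES), OCCP_CODES)
  outc_code <- setNames(names(OUTCOME_CODES), OUTCOME_CODES)

  write_dollar <- function(df, path) {
    lines <- c(
      paste(names(df), collapse = "$"),
      do.call(paste, c(unname(as.list(df)), sep = "$"))
    )
    writeLines(lines, path)
  }

  demo <- tibble(
    primaryid = reports$primaryid,
    caseid = reports$caseid,
    fda_dt = as.character(reports$fda_dt),
    sex = unname(gender_code[reports$gender]),
    age = ifelse(is.na(reports$age_years), "",
                 format(reports$age_years, trim = TRUE)),
    age_cod = ifelse(is.na(reports$age_years), "", "YR"),
    occp_cod = dplyr::coalesce(unname(occp_code[reports$reporter]), ""),
    reporter_country = ifelse(reports$country == "Unknown", "", reports$country),
    occr_country = ifelse(reports$country == "Unknown", "", reports$country)
  )

  n_drugs <- lengths(reports$drug_names)
  drug <- tibble(
    primaryid = rep(reports$primaryid, n_drugs),
    caseid = rep(reports$caseid, n_drugs),
    drug_seq = as.character(unlist(lapply(n_drugs, seq_len), use.names = FALSE)),
    role_cod = unlist(reports$drug_roles, use.names = FALSE),
    drugname = unlist(reports$drug_names, use.names = FALSE)
  )

  n_pts <- lengths(reports$reactions)
  reac <- tibble(
    primaryid = rep(reports$primaryid, n_pts),
    caseid = rep(reports$caseid, n_pts),
    pt = unlist(reports$reactions, use.names = FALSE)
  )

  n_outc <- lengths(reports$outcomes)
  outc <- tibble(
    primaryid = rep(reports$primaryid, n_outc),
    caseid = rep(reports$caseid, n_outc),
    outc_cod = unname(outc_code[unlist(reports$outcomes, use.names = FALSE)])
  )

  paths <- c(
    demo = file.path(out_dir, "demo.txt"),
    drug = file.path(out_dir, "drug.txt"),
    reac = file.path(out_dir, "reac.txt"),
    outc = file.path(out_dir, "outc.txt"),
    pt_soc_map = file.path(out_dir, "pt_soc_map.tsv")
  )
  write_dollar(demo, paths[["demo"]])
  write_dollar(drug, paths[["drug"]])
  write_dollar(reac, paths[["reac"]])
  write_dollar(outc, paths[["outc"]])
  writeLines(c("pt\tsoc", paste(map$pt, map$soc, sep = "\t")),
             paths[["pt_soc_map"]])

  if (!is.null(truth) && nrow(truth$planted) > 0) {
    p <- file.path(out_dir, "truth_planted.csv")
    readr::write_csv(truth$planted, p)
    paths <- c(paths, truth_planted = p)
  }
  dup_truth <- attr(reports, "dup_truth")
  if (!is.null(dup_truth)) {
    p <- file.path(out_dir, "truth_duplicates.csv")
    readr::write_csv(dup_truth, p)
    paths <- c(paths, truth_duplicates = p)
  }
  invisible(paths)
}
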