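# Primary-suspect cohort selection and descriptive summaries.

AGE_GROUP_LEVELS <- c("<17", "18~64", "65~85", ">85", "Unknown")

#' Split reports into target-drug cases and background
#'
#' A deduplicated report is a *case* when at least one of its drug entries
#' has a normalized name in `synonyms` and carries the required role code
#' (by default `"PS"`, primary suspect).  Every other report — including
#' reports that list the target drug only as secondary suspect,
#' interacting or concomitant — stays in the background.
#'
#' @param reports A case-report tibble from [join_case()] or
#'   [generate_cohort()].
#' @param synonyms Character vector of drug-name synonyms (case
#'   insensitive); must be non-empty.
#' @param role Required role code, one of `"PS"`, `"SS"`, `"I"`, `"C"`.
#' @return The input tibble with a logical `is_case` column; attributes
#'   `n_cases` and `n_background`.  Cases and background partition the
#'   input.
#' @export
select_cases <- function(reports, synonyms, role = "PS") {
  if (length(synonyms) == 0 || all(!nzchar(synonyms))) {
    abort("select_cases(): the synonym list is empty")
  }
  role <- match.arg(role, DRUG_ROLE_CODES)
  syn <- toupper(trimws(synonyms))
  is_case <- purrr::map2_lgl(
    reports$drug_names, reports$drug_roles,
    function(nm, rl) any(nm %in% syn & rl == role)
  )
  out <- reports
  out$is_case <- is_case
  attr(out, "n_cases") <- sum(is_case)
  attr(out, "n_background") <- sum(!is_case)
  attr(out, "target_synonyms") <- syn
  attr(out, "required_role") <- role
  out
}

#' Bin age in years into reporting age groups
#'
#' Bins follow the conventional spontaneous-report strata: at most 17,
#' 18 to 64, 65 to 85, over 85, with missing ages as `"Unknown"`.  The
#' bins form a total partition of the age axis: fractional ages below 18
#' fall in `"<17"`.  Negative ages are treated as missing, with a warning.
#'
#' @param age_years Numeric vector of ages in years (NA allowed).
#' @return Factor with levels `r paste(AGE_GROUP_LEVELS, collapse = ", ")`.
#' @export
assign_age_group <- function(age_years) {
  neg <- !is.na(age_years) & age_years < 0
  if (any(neg)) {
    warn(sprintf("%d negative age value(s) treated as Unknown", sum(neg)))
    age_years[neg] <- NA_real_
  }
  lab <- dplyr::case_when(
    is.na(age_years) ~ "Unknown",
    age_years < 18 ~ "<17",
    age_years <= 64 ~ "18~64",
    age_years <= 85 ~ "65~85",
    TRUE ~ ">85"
  )
  factor(lab, levels = AGE_GROUP_LEVELS)
}

count_block <- function(labels, block, denominator) {
  tab <- table(labels)
  tibble(
    block = block,
    label = names(tab),
    count = as.integer(tab),
    percent = percent_of(as.integer(tab), denominator)
  )
}

#' Descriptive summary of a report cohort
#'
#' Tabulates gender, age group, reporter type, country, report year and
#' serious outcomes as (label, count, percent) blocks.  Percentages in the
#' demographic blocks use the cohort size as denominator; the outcome
#' block is counted at the outcome-entry level (one report can carry
#' several outcomes) and uses the total number of outcome entries as its
#' own denominator, with reports carrying no outcome contributing one
#' `"Missing"` entry.  Percents are rounded half away from zero to one
#' decimal, so they recompute exactly from their count and denominator.
#'
#' @param cohort A case-report tibble.  If an `is_case` column is present
#'   (from [select_cases()]) only the cases are summarised.
#' @return A tibble with columns `block`, `label`, `count`, `percent`;
#'   attribute `denominators` (list with `main` and `outcomes`).
#' @export
summarize_demographics <- function(cohort) {
  if ("is_case" %in% names(cohort)) {
    cohort <- cohort[cohort$is_case, , drop = FALSE]
  }
  n <- nrow(cohort)
  if (n == 0) abort("summarize_demographics(): empty cohort")

  gender <- factor(cohort$gender, levels = c("Female", "Male", "Unknown"))
  age_group <- assign_age_group(cohort$age_years)
  reporter <- factor(cohort$reporter)
  country <- factor(cohort$country)
  year <- factor(cohort$report_year)

  outcome_entries <- unlist(lapply(cohort$outcomes, function(x) {
    if (length(x) == 0) "Missing" else x
  }), use.names = FALSE)
  n_out <- length(outcome_entries)

  out <- bind_rows(
    count_block(gender, "gender", n),
    count_block(age_group, "age_group", n),
    count_block(reporter, "reporter", n) |> arrange(desc(.data$count)),
    count_block(country, "country", n) |> arrange(desc(.data$count)),
    count_block(year, "report_year", n),
    count_block(factor(outcome_entries), "outcome", n_out) |>
      arrange(desc(.data$count))
  )
  attr(out, "denominators") <- list(main = n, outcomes = n_out)
  out
}

#' Bar chart of one descriptive-summary block
#'
#' @param summary A tibble from [summarize_demographics()].
#' @param block Which block to draw (default `"gender"`).
#' @return A ggplot object.
#' @export
plot_demographics <- function(summary, block = "gender") {
  dat <- summary[summary$block == block, , drop = FALSE]
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$label, .data$count),
    y = .data$count
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d (%.1f%%)", .data$count, .data$percent)),
                       hjust = -0.05, size = 3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Reports", title = paste("Cohort by", block)) +
    ggplot2::theme_minimal()
}
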