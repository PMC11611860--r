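# Ingestion of FAERS quarterly ASCII tables ('$'-delimited, one header line),
# case-version deduplication, and assembly of joined case reports.

FAERS_TABLE_KINDS <- c("DEMO", "DRUG", "REAC", "OUTC")

# Minimal column set required per table kind (post-2012 FAERS ASCII layout).
REQUIRED_COLUMNS <- list(
  DEMO = c("primaryid", "caseid", "fda_dt"),
  DRUG = c("primaryid", "role_cod", "drugname"),
  REAC = c("primaryid", "pt"),
  OUTC = c("primaryid", "outc_cod")
)

# Split one '$'-delimited line, preserving trailing empty fields.
split_dollar <- function(lines) {
  strsplit(paste0(lines, "$"), "$", fixed = TRUE)
}

#' Read one FAERS-style ASCII table
#'
#' Parses a '$'-delimited FAERS quarterly flat file (DEMO, DRUG, REAC or
#' OUTC).  The first line is the header; every value is kept as an
#' un-coerced string, with empty strings standing for missing values.
#' Column names are lower-cased; extra columns beyond the table kind's
#' required set are preserved.
#'
#' @param path Path to the ASCII file.
#' @param table_kind One of `"DEMO"`, `"DRUG"`, `"REAC"`, `"OUTC"`.
#' @return A tibble of character columns, one row per data line, with
#'   attribute `table_kind`.
#' @seealso [deduplicate_reports()], [join_case()], [write_faers_files()]
#' @export
read_faers_table <- function(path, table_kind = c("DEMO", "DRUG", "REAC", "OUTC")) {
  table_kind <- match.arg(table_kind)
  if (!file.exists(path)) {
    abort(paste0("FAERS table file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L || !nzchar(lines[[1]])) {
    abort(paste0("empty or headerless FAERS file: ", path))
  }
  header <- tolower(split_dollar(lines[[1]])[[1]])
  missing_cols <- setdiff(REQUIRED_COLUMNS[[table_kind]], header)
  if (length(missing_cols) > 0) {
    abort(paste0(
      table_kind, " table ", path, " lacks required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- split_dollar(body)
  n_fields <- lengths(fields)
  bad <- which(n_fields != length(header))
  if (length(bad) > 0) {
    abort(sprintf(
      "malformed %s line %d in %s: expected %d fields, found %d",
      table_kind, bad[[1]] + 1L, path, length(header), n_fields[[bad[[1]]]]
    ))
  }
  mat <- matrix(unlist(fields), ncol = length(header), byrow = TRUE)
  out <- as_tibble(as.data.frame(mat, stringsAsFactors = FALSE),
                   .name_repair = "minimal")
  names(out) <- header
  attr(out, "table_kind") <- table_kind
  out
}

#' Deduplicate FAERS case versions
#'
#' FAERS re-publishes updated versions of a case under the same CASEID.
#' For each CASEID this keeps the version with the latest FDA receipt date
#' (FDA_DT); when several versions share that date, the one with the
#' largest PRIMARYID wins, compared numerically (so "9" < "10").
#'
#' @param demo A DEMO tibble as returned by [read_faers_table()]; must have
#'   non-empty `caseid`, `primaryid` and `fda_dt` on every row.
#' @return A tibble with exactly one row per CASEID, sorted by CASEID, with
#'   attribute `n_removed` (number of discarded versions).
#' @details Deduplication is idempotent and invariant to the input row
#'   order.  A non-numeric PRIMARYID is an error only when a tie on FDA_DT
#'   actually requires the numeric comparison.
#' @export
deduplicate_reports <- function(demo) {
  needed <- c("caseid", "primaryid", "fda_dt")
  if (!all(needed %in% names(demo))) {
    abort("deduplicate_reports() needs columns caseid, primaryid, fda_dt")
  }
  for (col in needed) {
    if (any(!nz(demo[[col]]))) {
      abort(paste0("deduplicate_reports(): empty or missing ", col))
    }
  }
  n_in <- nrow(demo)
  kept <- demo |>
    mutate(.fda = as.numeric(.data$fda_dt)) |>
    group_by(.data$caseid) |>
    filter(.data$.fda == max(.data$.fda)) |>
    ungroup()
  # resolve remaining ties on FDA_DT by numeric PRIMARYID
  ties <- kept |> dplyr::add_count(.data$caseid) |> filter(.data$n > 1L)
  if (nrow(ties) > 0) {
    pid_num <- suppressWarnings(as.numeric(ties$primaryid))
    if (anyNA(pid_num)) {
      abort(paste0(
        "non-numeric PRIMARYID in FDA_DT tie for CASEID ",
        ties$caseid[[which(is.na(pid_num))[1]]]
      ))
    }
  }
  out <- kept |>
    mutate(.pid = dplyr::coalesce(suppressWarnings(as.numeric(.data$primaryid)), -Inf)) |>
    group_by(.data$caseid) |>
    filter(row_number() == which.max(.data$.pid)) |>
    ungroup() |>
    arrange(.data$caseid) |>
    select(-".fda", -".pid")
  attr(out, "table_kind") <- attr(demo, "table_kind")
  attr(out, "n_removed") <- n_in - nrow(out)
  out
}

convert_age_years <- function(age, age_cod) {
  val <- suppressWarnings(as.numeric(age))
  unit <- toupper(trimws(age_cod))
  factor_for <- c(YR = 1, MON = 1 / 12, DY = 1 / 365.25, WK = 1 / 52.18,
                  DEC = 10, HR = 1 / 8766)
  out <- rep(NA_real_, length(val))
  known <- unit %in% names(factor_for)
  out[known] <- val[known] * unname(factor_for[unit[known]])
  # missing unit: accept as years only when physiologically plausible
  no_unit <- !known & !is.na(val)
  out[no_unit & val <= 120] <- val[no_unit & val <= 120]
  out
}

map_gender <- function(sex) {
  dplyr::case_match(toupper(trimws(sex)),
    "F" ~ "Female",
    "M" ~ "Male",
    .default = "Unknown"
  )
}

map_reporter <- function(occp_cod) {
  code <- toupper(trimws(occp_cod))
  out <- unname(OCCP_CODES[code])
  out[is.na(out)] <- "Unknown"
  out
}

#' Join FAERS tables into case reports
#'
#' Aggregates the DRUG, REAC and OUTC rows belonging to each (already
#' deduplicated) DEMO row into one case report per PRIMARYID, normalising
#' demographics on the way: gender codes to Female/Male/Unknown, AGE +
#' AGE_COD to years, OCCP_COD to reporter categories, outcome codes to
#' their labels, and the reporter country (falling back to the occurrence
#' country).  Reaction PTs are de-duplicated within a report; reports with
#' no reactions are kept and counted.  Child rows whose PRIMARYID matches
#' no DEMO row are dropped and counted as orphans, never fatal.
#'
#' @param demo,drug,reac,outc Tibbles from [read_faers_table()]; `demo`
#'   should have passed through [deduplicate_reports()].
#' @return A tibble of case reports with columns `caseid`, `primaryid`,
#'   `fda_dt` (yyyymmdd integer), `report_year`, `gender`, `age_years`,
#'   `reporter`, `country`, and list-columns `outcomes`, `drug_names`,
#'   `drug_roles`, `reactions`, plus `n_reactions`.  Attributes: `orphans`
#'   (named count per child table) and `log` (character lines).
#' @export
join_case <- function(demo, drug, reac, outc) {
  pid <- demo$primaryid
  if (anyDuplicated(pid)) {
    abort("join_case(): demo has duplicated PRIMARYIDs; deduplicate first")
  }

  role <- toupper(trimws(drug$role_cod))
  bad_role <- nz(role) & !(role %in% DRUG_ROLE_CODES)
  if (any(bad_role)) {
    abort(paste0(
      "unknown drug role code(s): ",
      paste(unique(role[bad_role]), collapse = ", ")
    ))
  }

  orphans <- c(DRUG = 0L, REAC = 0L, OUTC = 0L)
  keep_child <- function(child, kind) {
    ok <- child$primaryid %in% pid
    orphans[[kind]] <<- sum(!ok)
    child[ok, , drop = FALSE]
  }
  drug <- keep_child(drug, "DRUG")
  reac <- keep_child(reac, "REAC")
  outc <- keep_child(outc, "OUTC")

  split_on <- function(x, ids) {
    split(x, factor(ids, levels = pid))
  }

  drug_names <- unname(split_on(toupper(trimws(drug$drugname)), drug$primaryid))
  drug_roles <- unname(split_on(toupper(trimws(drug$role_cod)), drug$primaryid))
  reactions <- unname(lapply(split_on(trimws(reac$pt), reac$primaryid), unique))

  outc_lab <- unname(OUTCOME_CODES[toupper(trimws(outc$outc_cod))])
  unknown_outc <- is.na(outc_lab) & nz(outc$outc_cod)
  if (any(unknown_outc)) {
    warn(paste0(
      "dropping ", sum(unknown_outc), " OUTC row(s) with unknown outcome code(s): ",
      paste(unique(toupper(trimws(outc$outc_cod[unknown_outc]))), collapse = ", ")
    ))
  }
  outcomes <- unname(lapply(
    split_on(outc_lab[!unknown_outc], outc$primaryid[!unknown_outc]),
    unique
  ))

  fda_dt <- as.integer(demo$fda_dt)
  country_col <- if ("reporter_country" %in% names(demo)) {
    demo$reporter_country
  } else if ("occr_country" %in% names(demo)) {
    demo$occr_country
  } else {
    rep("", nrow(demo))
  }
  if ("reporter_country" %in% names(demo) && "occr_country" %in% names(demo)) {
    fallback <- !nz(country_col)
    country_col[fallback] <- demo$occr_country[fallback]
  }
  country <- trimws(country_col)
  country[!nz(country)] <- "Unknown"

  sex_col <- if ("sex" %in% names(demo)) demo$sex else demo[["gndr_cod"]] %||%
    rep("", nrow(demo))
  age_col <- demo[["age"]] %||% rep("", nrow(demo))
  age_cod_col <- demo[["age_cod"]] %||% rep("", nrow(demo))
  occp_col <- demo[["occp_cod"]] %||% rep("", nrow(demo))

  reports <- tibble(
    caseid = demo$caseid,
    primaryid = pid,
    fda_dt = fda_dt,
    report_year = fda_dt %/% 10000L,
    gender = map_gender(sex_col),
    age_years = convert_age_years(age_col, age_cod_col),
    reporter = map_reporter(occp_col),
    country = country,
    outcomes = unname(outcomes),
    drug_names = unname(drug_names),
    drug_roles = unname(drug_roles),
    reactions = unname(reactions)
  )
  reports$n_reactions <- lengths(reports$reactions)

  log_lines <- c(
    sprintf("joined %d case reports", nrow(reports)),
    sprintf("orphan child rows dropped: DRUG=%d REAC=%d OUTC=%d",
            orphans[["DRUG"]], orphans[["REAC"]], orphans[["OUTC"]]),
    sprintf("reports with zero reactions: %d", sum(reports$n_reactions == 0L))
  )
  attr(reports, "orphans") <- orphans
  attr(reports, "log") <- log_lines
  reports
}

#' Load a PT-to-SOC mapping table
#'
#' Reads a two-column tab-delimited file mapping each MedDRA preferred
#' term (PT) to its primary system organ class (SOC).  MedDRA assigns one
#' primary SOC per PT, so a PT mapped to two different SOCs is an error;
#' exact duplicate lines are collapsed.
#'
#' @param path Path to the TSV file.
#' @param header Does the first line hold column names? Default `TRUE`.
#' @return A tibble with columns `pt` and `soc`.
#' @export
load_pt_soc_map <- function(path, header = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (header && length(lines) > 0) lines <- lines[-1]
  if (length(lines) == 0) abort(paste0("empty PT->SOC map: ", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    abort(sprintf("PT->SOC map line %d does not have exactly 2 tab-separated fields",
                  which(lengths(parts) != 2L)[1] + as.integer(header)))
  }
  map <- tibble(
    pt = trimws(vapply(parts, `[[`, "", 1L)),
    soc = trimws(vapply(parts, `[[`, "", 2L))
  ) |> dplyr::distinct()
  dup <- map$pt[duplicated(map$pt)]
  if (length(dup) > 0) {
    abort(paste0("PT mapped to conflicting SOCs: ", paste(unique(dup), collapse = ", ")))
  }
  map
}

#' Look up the SOC for each PT
#'
#' @param pts Character vector of PTs.
#' @param map A tibble from [load_pt_soc_map()].
#' @return Character vector of SOCs; unmapped PTs yield `"UNMAPPED"` with a
#'   warning.
#' @export
pt_to_soc <- function(pts, map) {
  soc <- map$soc[match(pts, map$pt)]
  unmapped <- is.na(soc)
  if (any(unmapped)) {
    warn(paste0(
      "PT(s) missing from the PT->SOC map, assigned 'UNMAPPED': ",
      paste(unique(pts[unmapped]), collapse = ", ")
    ))
    soc[unmapped] <- "UNMAPPED"
  }
  soc
}
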