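# End-to-end orchestration: ingest -> deduplicate -> cohort -> contingency
# -> disproportionality -> ranked output tables.

#' Pipeline run configuration
#'
#' @param demo,drug,reac,outc Paths to the four FAERS-style ASCII tables.
#'   Leave `NULL` together with `synthetic` to run on generated data.
#' @param pt_soc_map Path to the PT-to-SOC TSV (`NULL` with synthetic
#'   input: the generator's own map is used).
#' @param synthetic Either `NULL` (read real files) or a
#'   [synthetic_cohort_config()] to generate the input on the fly.
#' @param synonyms Target drug synonyms (default `"DISULFIRAM"`).
#' @param role Required role code for a case (default `"PS"`).
#' @param min_count Minimum PT case count for inclusion (default 3).
#' @param hyper BCPNN priors ([bcpnn_hyperparameters()]).
#' @param correction Chi-squared correction, `"none"` or `"yates"`.
#' @param zero_correction Haldane-Anscombe 0.5 for zero-containing tables.
#' @param top_n How many PT rows to keep in the ranked table (default 50).
#' @param out_dir Directory for the output CSVs and run log.
#' @param seed Seed for the synthetic branch.
#' @return A list of class `"faers_run_config"`.
#' @export
run_config <- function(demo = NULL, drug = NULL, reac = NULL, outc = NULL,
                       pt_soc_map = NULL, synthetic = NULL,
                       synonyms = "DISULFIRAM", role = "PS", min_count = 3,
                       hyper = bcpnn_hyperparameters(),
                       correction = "none", zero_correction = FALSE,
                       top_n = 50, out_dir = "faersignal_out", seed = 1) {
  stopifnot(min_count >= 1, top_n >= 1)
  if (is.null(synthetic) && (is.null(demo) || is.null(drug) || is.null(reac) ||
                             is.null(outc))) {
    abort("run_config(): give all four table paths or a synthetic config")
  }
  structure(
    list(
      demo = demo, drug = drug, reac = reac, outc = outc,
      pt_soc_map = pt_soc_map, synthetic = synthetic,
      synonyms = synonyms, role = role, min_count = min_count,
      hyper = hyper, correction = correction,
      zero_correction = zero_correction, top_n = top_n,
      out_dir = out_dir, seed = as.integer(seed)
    ),
    class = "faers_run_config"
  )
}

#' Read a flat key-value run configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment.  Recognised
#' keys: the four table paths (`demo`, `drug`, `reac`, `outc`),
#' `pt_soc_map`, `synonyms` (comma-separated), `role`, `min_count`,
#' `alpha`, `beta`, `alpha_i`, `beta_j`, `gamma_ij`, `correction`,
#' `zero_correction`, `top_n`, `out_dir`, `seed`, and `synthetic`
#' (`true` to use a default generator config with `n_reports` and
#' `duplicate_rate` optionally overridden).
#'
#' @param path Path to the configuration file.
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
  get <- function(key, default = NULL) {
    if (key %in% keys) vals[[match(key, keys)]] else default
  }
  num <- function(key, default) as.numeric(get(key, default))
  synthetic <- NULL
  if (tolower(get("synthetic", "false")) %in% c("true", "yes", "1")) {
    synthetic <- synthetic_cohort_config(
      n_reports = num("n_reports", 10000),
      target_drug = toupper(get("synonyms", "DISULFIRAM")) |>
        strsplit(",") |> unlist() |> trimws() |> utils::head(1),
      duplicate_rate = num("duplicate_rate", 0.1),
      planted_signals = {
        pt <- get("planted_pt")
        if (is.null(pt)) c() else setNames(num("planted_lambda", 10), pt)
      },
      seed = num("seed", 1)
    )
  }
  run_config(
    demo = get("demo"), drug = get("drug"), reac = get("reac"),
    outc = get("outc"), pt_soc_map = get("pt_soc_map"),
    synthetic = synthetic,
    synonyms = trimws(unlist(strsplit(get("synonyms", "DISULFIRAM"), ","))),
    role = get("role", "PS"),
    min_count = num("min_count", 3),
    hyper = bcpnn_hyperparameters(
      alpha = num("alpha", 2), beta = num("beta", 2),
      alpha_i = num("alpha_i", 1), beta_j = num("beta_j", 1),
      gamma_ij = num("gamma_ij", 1)
    ),
    correction = get("correction", "none"),
    zero_correction = tolower(get("zero_correction", "false")) %in%
      c("true", "yes", "1"),
    top_n = num("top_n", 50),
    out_dir = get("out_dir", "faersignal_out"),
    seed = num("seed", 1)
  )
}

#' Run the full signal-detection pipeline
#'
#' Ingests the quarterly tables (or generates them from a synthetic
#' config, writing the fixture files first so the full file path is
#' exercised), deduplicates case versions, joins the child tables,
#' selects the primary-suspect cohort, and writes four outputs to
#' `cfg$out_dir`:
#'
#' * `descriptive.csv` — the cohort's demographic summary;
#' * `soc_signals.csv` — SOC-level statistics, unfiltered, ordered by
#'   case count descending;
#' * `pt_signals.csv` — PT-level statistics filtered at `min_count` and
#'   ranked by EBGM05 descending (top `top_n` rows);
#' * `run_log.txt` — row counts, duplicates removed, orphan rows, cohort
#'   size, events evaluated.
#'
#' @param cfg A [run_config()] object.
#' @return Invisibly, a list with elements `descriptive`, `soc`, `pt`
#'   (tibbles), `cohort` and `paths`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "faers_run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  if (!is.null(cfg$synthetic)) {
    fixture_dir <- file.path(cfg$out_dir, "fixture")
    reports0 <- generate_cohort(cfg$synthetic)
    reports0 <- inject_duplicates(reports0, cfg$synthetic$duplicate_rate,
                                  seed = cfg$synthetic$seed + 1L)
    paths <- write_faers_files(reports0, fixture_dir)
    cfg$demo <- paths[["demo"]]; cfg$drug <- paths[["drug"]]
    cfg$reac <- paths[["reac"]]; cfg$outc <- paths[["outc"]]
    cfg$pt_soc_map <- paths[["pt_soc_map"]]
    say("synthetic fixture written to %s", fixture_dir)
  }

  demo <- read_faers_table(cfg$demo, "DEMO")
  drug <- read_faers_table(cfg$drug, "DRUG")
  reac <- read_faers_table(cfg$reac, "REAC")
  outc <- read_faers_table(cfg$outc, "OUTC")
  say("read DEMO=%d DRUG=%d REAC=%d OUTC=%d rows",
      nrow(demo), nrow(drug), nrow(reac), nrow(outc))

  demo <- deduplicate_reports(demo)
  say("duplicate case versions removed: %d", attr(demo, "n_removed"))

  reports <- join_case(demo, drug, reac, outc)
  say("%s", paste(attr(reports, "log"), collapse = "\n"))

  if (is.null(cfg$pt_soc_map)) abort("run_pipeline(): no PT->SOC map configured")
  map <- load_pt_soc_map(cfg$pt_soc_map)

  selection <- select_cases(reports, cfg$synonyms, cfg$role)
  n_cases <- attr(selection, "n_cases")
  if (n_cases == 0) {
    abort(paste0("empty cohort: no report has [",
                 paste(cfg$synonyms, collapse = ", "),
                 "] with role ", cfg$role))
  }
  say("cohort: %d cases, %d background reports", n_cases,
      attr(selection, "n_background"))

  descriptive <- summarize_demographics(selection)

  pt_tables <- build_event_tables(selection, "PT") |>
    filter_min_count(min_a = cfg$min_count)
  soc_tables <- build_event_tables(selection, "SOC", map = map)
  say("events evaluated: %d PTs (a >= %d), %d SOCs",
      nrow(pt_tables), cfg$min_count, nrow(soc_tables))

  dispro <- function(tb) {
    disproportionality(tb, hyper = cfg$hyper, correction = cfg$correction,
                       zero_correction = cfg$zero_correction)
  }
  pt_signals <- dispro(pt_tables) |> rank_by_ebgm05(top_n = cfg$top_n)
  soc_signals <- dispro(soc_tables) |> arrange(desc(.data$a), .data$event)

  out_paths <- c(
    descriptive = file.path(cfg$out_dir, "descriptive.csv"),
    soc = file.path(cfg$out_dir, "soc_signals.csv"),
    pt = file.path(cfg$out_dir, "pt_signals.csv"),
    log = file.path(cfg$out_dir, "run_log.txt")
  )
  readr::write_csv(descriptive, out_paths[["descriptive"]])
  readr::write_csv(as_tibble(soc_signals), out_paths[["soc"]])
  readr::write_csv(as_tibble(pt_signals), out_paths[["pt"]])
  writeLines(log_lines, out_paths[["log"]])

  invisible(list(
    descriptive = descriptive,
    soc = soc_signals,
    pt = pt_signals,
    cohort = selection,
    paths = out_paths
  ))
}
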