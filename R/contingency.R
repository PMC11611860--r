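# 2x2 contingency tables per adverse event, at PT or SOC level.
#
# For one event the cells are
#   a  case reports (target drug primary-suspect) with the event
#   b  case reports without the event
#   c  background reports with the event
#   d  background reports without the event
# so a+b is the cohort size, c+d the background size, N = a+b+c+d.

#' Build per-event 2x2 contingency tables
#'
#' Counts deduplicated reports (never reaction rows): at PT level a report
#' contributes at most once to each PT; at SOC level a report contributes
#' at most once to each SOC even when several of its PTs map there.  PTs
#' missing from the map participate at PT level but are excluded from SOC
#' tables (there is no principled SOC for them).  Events observed in no
#' report produce no row.
#'
#' @param selection A tibble from [select_cases()] (must carry `is_case`).
#' @param level `"PT"` or `"SOC"`.
#' @param map A PT-to-SOC tibble from [load_pt_soc_map()]; required when
#'   `level = "SOC"`.
#' @return A tibble with columns `event`, `level`, `a`, `b`, `c`, `d`, `N`,
#'   one row per observed event, sorted by `event`.
#' @export
build_event_tables <- function(selection, level = c("PT", "SOC"), map = NULL) {
  level <- match.arg(level)
  if (!"is_case" %in% names(selection)) {
    abort("build_event_tables() expects the output of select_cases()")
  }
  n_cases <- sum(selection$is_case)
  n_background <- sum(!selection$is_case)

  n_pts <- lengths(selection$reactions)
  long <- tibble(
    event = unlist(selection$reactions, use.names = FALSE),
    is_case = rep(selection$is_case, n_pts)
  )
  if (level == "SOC") {
    if (is.null(map)) abort("SOC-level tables need a PT->SOC map")
    long$event <- pt_to_soc(long$event, map)
    long$report <- rep(seq_len(nrow(selection)), n_pts)
    long <- long |>
      filter(.data$event != "UNMAPPED") |>
      dplyr::distinct(.data$report, .data$event, .keep_all = TRUE)
  }

  counts <- long |>
    group_by(.data$event) |>
    summarise(
      a = sum(.data$is_case),
      c = sum(!.data$is_case),
      .groups = "drop"
    )

  counts |>
    mutate(
      level = level,
      b = n_cases - .data$a,
      d = n_background - .data$c,
      N = n_cases + n_background
    ) |>
    select("event", "level", "a", "b", "c", "d", "N") |>
    arrange(.data$event)
}

#' Apply the minimum case-count inclusion rule
#'
#' Spontaneous-report screens conventionally evaluate only events with at
#' least `min_a` case reports (default 3).  The rule applies at PT level;
#' tables at other levels pass through untouched unless listed in
#' `apply_to`.
#'
#' @param tables A tibble from [build_event_tables()].
#' @param min_a Minimum `a` cell to keep (default 3, must be >= 1).
#' @param apply_to Levels the filter applies to (default `"PT"`).
#' @return The filtered tibble.
#' @export
filter_min_count <- function(tables, min_a = 3, apply_to = "PT") {
  if (min_a < 1) abort("filter_min_count(): min_a must be >= 1")
  tables |> filter(!(.data$level %in% apply_to) | .data$a >= min_a)
}
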