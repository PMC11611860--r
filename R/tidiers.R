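# broom-style accessors and plotting for faers_signals objects.

#' @export
print.faers_signals <- function(x, ...) {
  cat(sprintf("# Disproportionality signals: %d events (%d flagged by all four algorithms)\n",
              nrow(x), sum(x$n_algorithms_flagged == 4, na.rm = TRUE)))
  NextMethod()
}

#' Tidy a disproportionality result
#'
#' One row per event and algorithm, broom-style: the point estimate, the
#' 95% interval bounds and the flag.  For the BCPNN the "estimate" is the
#' posterior expectation E(IC) and only the lower bound (IC025) exists.
#'
#' @param x A `faers_signals` tibble from [disproportionality()].
#' @param ... Unused.
#' @return A tibble with columns `event`, `level`, `a`, `method`,
#'   `estimate`, `conf.low`, `conf.high`, `flagged`.
#' @method tidy faers_signals
#' @export
tidy.faers_signals <- function(x, ...) {
  lvl <- if ("level" %in% names(x)) x$level else NA_character_
  base <- tibble(event = x$event, level = lvl, a = x$a)
  bind_rows(
    base |> mutate(method = "ror", estimate = x$ror,
                   conf.low = x$ror_ci_low, conf.high = x$ror_ci_high,
                   flagged = x$ror_flag),
    base |> mutate(method = "prr", estimate = x$prr,
                   conf.low = x$prr_ci_low, conf.high = x$prr_ci_high,
                   flagged = x$prr_flag),
    base |> mutate(method = "bcpnn", estimate = x$e_ic,
                   conf.low = x$ic025, conf.high = NA_real_,
                   flagged = x$bcpnn_flag),
    base |> mutate(method = "ebgm", estimate = x$ebgm,
                   conf.low = x$ebgm05, conf.high = x$ebgm95,
                   flagged = x$ebgm_flag)
  ) |> arrange(.data$event, .data$method)
}

#' One-line summary of a disproportionality result
#'
#' @param x A `faers_signals` tibble.
#' @param ... Unused.
#' @return A one-row tibble: `n_events`, `n_flagged_any`,
#'   `n_flagged_all4`, `n_cases`, `n_background`.
#' @method glance faers_signals
#' @export
glance.faers_signals <- function(x, ...) {
  tibble(
    n_events = nrow(x),
    n_flagged_any = sum(x$n_algorithms_flagged > 0, na.rm = TRUE),
    n_flagged_all4 = sum(x$n_algorithms_flagged == 4, na.rm = TRUE),
    n_cases = if (nrow(x)) x$a[[1]] + x$b[[1]] else NA_integer_,
    n_background = if (nrow(x)) x$c[[1]] + x$d[[1]] else NA_integer_
  )
}

#' Forest plot of the strongest signals
#'
#' Draws the reporting odds ratio and its 95% interval for the top events
#' ranked by EBGM05, coloured by how many of the four algorithms flag the
#' event.
#'
#' @param object A `faers_signals` tibble from [disproportionality()].
#' @param top_n How many events to show (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot faers_signals
#' @export
autoplot.faers_signals <- function(object, top_n = 20, ...) {
  dat <- rank_by_ebgm05(object, top_n) |>
    filter(!is.na(.data$ror)) |>
    mutate(event = factor(.data$event, levels = rev(.data$event)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$ror, y = .data$event,
                                    colour = factor(.data$n_algorithms_flagged))) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ror_ci_low, xmax = .data$ror_ci_high),
      height = 0.2
    ) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "ROR (95% CI, log scale)", y = NULL,
                  colour = "Algorithms\nflagging") +
    ggplot2::theme_minimal()
}
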