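# Disproportionality statistics on per-event 2x2 tables.
#
# Four classical pharmacovigilance screens, each with its conventional
# flagging rule:
#   ROR   ad/bc,                     flag: a >= 3 and 95% CI lower bound > 1
#   PRR   [a/(a+b)]/[c/(c+d)] + chi2, flag: a >= 3, PRR >= 2, chi2 >= 4
#   BCPNN IC = log2 aN/((a+b)(a+c)) with Bayesian posterior E(IC), V(IC),
#         flag: IC025 = E(IC) - 2*sqrt(V(IC)) > 0
#   EBGM  aN/((a+c)(a+b)) (observed/expected; identical to 2^IC),
#         flag: EBGM05 (lower 95% bound) > 2
#
# All estimators are vectorized over the rows of a contingency tibble.

Z95 <- 1.96

check_cells <- function(tables) {
  need <- c("a", "b", "c", "d")
  if (!all(need %in% names(tables))) {
    abort("expected columns a, b, c, d (see build_event_tables())")
  }
  if (any(tables$a < 0 | tables$b < 0 | tables$c < 0 | tables$d < 0)) {
    abort("negative contingency cell")
  }
  invisible(tables)
}

# Cells as doubles (large-N products overflow integers), optionally with
# the Haldane-Anscombe +0.5 applied to tables containing a zero.
corrected_cells <- function(tables, zero_correction) {
  cells <- lapply(tables[c("a", "b", "c", "d")], as.numeric)
  if (zero_correction) {
    has_zero <- cells$a == 0 | cells$b == 0 | cells$c == 0 | cells$d == 0
    for (nm in names(cells)) cells[[nm]] <- cells[[nm]] + 0.5 * has_zero
  }
  cells
}

#' Reporting odds ratio with 95% confidence interval
#'
#' ROR = ad/bc, with the log-normal interval
#' exp(ln ROR ± 1.96·sqrt(1/a + 1/b + 1/c + 1/d)).  A table with any zero
#' cell has an undefined ROR (reported as `NA`, never flagged) unless
#' `zero_correction = TRUE` adds 0.5 to every cell of such tables.
#' Flagging rule: `a >= 3` and CI lower bound > 1.
#'
#' @param tables A contingency tibble with columns `a`, `b`, `c`, `d`
#'   (from [build_event_tables()] or hand-built).
#' @param zero_correction Apply the Haldane-Anscombe 0.5 continuity
#'   correction to zero-containing tables (default `FALSE`).
#' @return The input tibble with columns `ror`, `ror_ci_low`,
#'   `ror_ci_high`, `ror_flag` appended.
#' @export
ror_signal <- function(tables, zero_correction = FALSE) {
  check_cells(tables)
  k <- corrected_cells(tables, zero_correction)
  defined <- k$a > 0 & k$b > 0 & k$c > 0 & k$d > 0
  ror <- se <- rep(NA_real_, nrow(tables))
  ror[defined] <- (k$a * k$d)[defined] / (k$b * k$c)[defined]
  se[defined] <- sqrt(1 / k$a + 1 / k$b + 1 / k$c + 1 / k$d)[defined]
  lo <- exp(log(ror) - Z95 * se)
  hi <- exp(log(ror) + Z95 * se)
  tables |>
    mutate(
      ror = ror,
      ror_ci_low = lo,
      ror_ci_high = hi,
      ror_flag = !is.na(lo) & .data$a >= 3 & lo > 1
    )
}

#' Proportional reporting ratio with chi-squared companion
#'
#' PRR = \[a/(a+b)\] / \[c/(c+d)\], with the log-normal interval built
#' from SE(ln PRR) = sqrt(1/a − 1/(a+b) + 1/c − 1/(c+d)) and the Pearson
#' chi-squared statistic N(ad−bc)² / ((a+b)(c+d)(a+c)(b+d)), optionally
#' Yates-corrected.  PRR is undefined (`NA`, unflagged) when `c = 0` or a
#' margin is empty.  Flagging rule: `a >= 3`, PRR ≥ 2 and chi² ≥ 4.
#'
#' @inheritParams ror_signal
#' @param correction Chi-squared continuity correction: `"none"` (Pearson,
#'   default) or `"yates"`.
#' @return The input tibble with `prr`, `prr_ci_low`, `prr_ci_high`,
#'   `chi2`, `prr_flag` appended.
#' @export
prr_signal <- function(tables, correction = c("none", "yates"),
                       zero_correction = FALSE) {
  correction <- match.arg(correction)
  check_cells(tables)
  k <- corrected_cells(tables, zero_correction)
  n1 <- k$a + k$b
  n0 <- k$c + k$d
  defined <- k$c > 0 & n1 > 0 & n0 > 0
  prr <- rep(NA_real_, nrow(tables))
  prr[defined] <- ((k$a / n1) / (k$c / n0))[defined]

  se <- rep(NA_real_, nrow(tables))
  se_ok <- defined & k$a > 0
  se[se_ok] <- sqrt(1 / k$a - 1 / n1 + 1 / k$c - 1 / n0)[se_ok]
  lo <- exp(log(prr) - Z95 * se)
  hi <- exp(log(prr) + Z95 * se)

  N <- k$a + k$b + k$c + k$d
  m1 <- k$a + k$c
  m0 <- k$b + k$d
  denom <- n1 * n0 * m1 * m0
  dev <- abs(k$a * k$d - k$b * k$c)
  if (correction == "yates") dev <- pmax(dev - N / 2, 0)
  chi2 <- ifelse(denom > 0, N * dev^2 / denom, NA_real_)

  tables |>
    mutate(
      prr = prr,
      prr_ci_low = lo,
      prr_ci_high = hi,
      chi2 = chi2,
      prr_flag = !is.na(prr) & !is.na(chi2) &
        .data$a >= 3 & prr >= 2 & chi2 >= 4
    )
}

#' BCPNN prior parameters
#'
#' Hyperparameters of the Bayesian confidence propagation neural network:
#' `alpha`, `beta` are the totals and `alpha_i`, `beta_j` the marginal
#' components of the Beta priors on the drug and event margins;
#' `gamma_ij` is the joint-cell component of the Dirichlet prior, whose
#' total `gamma` is derived per table as
#' gamma_ij·(N+alpha)(N+beta)/((a+b+alpha_i)(a+c+beta_j)) so that the
#' posterior information component shrinks toward 0.  The defaults
#' (alpha = beta = 2, alpha_i = beta_j = gamma_ij = 1) are the standard
#' choices of the method.
#'
#' @param alpha,beta,alpha_i,beta_j,gamma_ij Positive reals.
#' @return A list of class `"bcpnn_hyperparameters"`.
#' @export
bcpnn_hyperparameters <- function(alpha = 2, beta = 2, alpha_i = 1,
                                  beta_j = 1, gamma_ij = 1) {
  h <- list(alpha = alpha, beta = beta, alpha_i = alpha_i,
            beta_j = beta_j, gamma_ij = gamma_ij)
  if (any(unlist(h) <= 0)) abort("BCPNN hyperparameters must be positive")
  structure(h, class = "bcpnn_hyperparameters")
}

#' Derived Dirichlet total for the BCPNN posterior
#'
#' @param tables Contingency tibble (columns `a`, `b`, `c`, `d`).
#' @param hyper A [bcpnn_hyperparameters()] object.
#' @return Numeric vector `gamma`, one value per table.
#' @export
bcpnn_gamma <- function(tables, hyper = bcpnn_hyperparameters()) {
  check_cells(tables)
  N <- tables$a + tables$b + tables$c + tables$d
  hyper$gamma_ij * (N + hyper$alpha) * (N + hyper$beta) /
    ((tables$a + tables$b + hyper$alpha_i) * (tables$a + tables$c + hyper$beta_j))
}

#' BCPNN information component with posterior bounds
#'
#' The raw information component is IC = log2(aN / ((a+b)(a+c))).  Its
#' posterior expectation and variance under the Beta/Dirichlet priors are
#'
#'   E(IC) = log2\[(a+γij)(N+α)(N+β) / ((N+γ)(a+b+αi)(a+c+βj))\]
#'
#'   V(IC) = (1/ln2)² · \[ (N−a+γ−γij)/((a+γij)(1+N+γ))
#'                        + (N−(a+b)+α−αi)/((a+b+αi)(1+N+α))
#'                        + (N−(a+c)+β−βj)/((a+c+βj)(1+N+β)) \]
#'
#' with γ from [bcpnn_gamma()].  IC025 = E(IC) − 2·sqrt(V(IC)); the
#' flagging rule is IC025 > 0 (strict).  With positive priors the
#' posterior quantities are defined for every table; `ic_raw` is `-Inf`
#' when `a = 0` and `NA` when a margin is empty.
#'
#' @inheritParams ror_signal
#' @param hyper A [bcpnn_hyperparameters()] object.
#' @return The input tibble with `ic_raw`, `e_ic`, `v_ic`, `ic025`,
#'   `bcpnn_flag` appended.
#' @export
bcpnn_signal <- function(tables, hyper = bcpnn_hyperparameters()) {
  check_cells(tables)
  a <- as.numeric(tables$a); b <- as.numeric(tables$b)
  c <- as.numeric(tables$c); d <- as.numeric(tables$d)
  N <- a + b + c + d
  n1 <- a + b   # drug margin
  m1 <- a + c   # event margin
  margins_ok <- n1 > 0 & m1 > 0 & N > 0

  ic_raw <- rep(NA_real_, length(a))
  ic_raw[margins_ok] <- log2((a * N)[margins_ok] / (n1 * m1)[margins_ok])

  g <- bcpnn_gamma(tables, hyper)
  e_ic <- v_ic <- rep(NA_real_, length(a))
  ok <- margins_ok
  e_ic[ok] <- log2(
    ((a + hyper$gamma_ij) * (N + hyper$alpha) * (N + hyper$beta))[ok] /
      ((N + g) * (n1 + hyper$alpha_i) * (m1 + hyper$beta_j))[ok]
  )
  v_ic[ok] <- (1 / log(2)^2) * (
    ((N - a + g - hyper$gamma_ij) / ((a + hyper$gamma_ij) * (1 + N + g)))[ok] +
      ((N - n1 + hyper$alpha - hyper$alpha_i) /
         ((n1 + hyper$alpha_i) * (1 + N + hyper$alpha)))[ok] +
      ((N - m1 + hyper$beta - hyper$beta_j) /
         ((m1 + hyper$beta_j) * (1 + N + hyper$beta)))[ok]
  )
  ic025 <- e_ic - 2 * sqrt(v_ic)

  tables |>
    mutate(
      ic_raw = ic_raw,
      e_ic = e_ic,
      v_ic = v_ic,
      ic025 = ic025,
      bcpnn_flag = !is.na(ic025) & ic025 > 0
    )
}

#' Empirical Bayes geometric mean (observed/expected ratio)
#'
#' EBGM = aN / ((a+c)(a+b)), the ratio of the observed count to the count
#' expected under independence — algebraically identical to 2^IC.  The
#' 95% interval is exp(ln EBGM ± 1.96·sqrt(1/a + 1/b + 1/c + 1/d)); its
#' lower bound is EBGM05.  Tables with a zero cell are undefined (`NA`,
#' unflagged) unless `zero_correction = TRUE`.  Flagging rule:
#' EBGM05 > 2.
#'
#' @inheritParams ror_signal
#' @return The input tibble with `ebgm`, `ebgm05`, `ebgm95`, `ebgm_flag`
#'   appended.
#' @export
ebgm_signal <- function(tables, zero_correction = FALSE) {
  check_cells(tables)
  k <- corrected_cells(tables, zero_correction)
  N <- k$a + k$b + k$c + k$d
  defined <- k$a > 0 & k$b > 0 & k$c > 0 & k$d > 0
  ebgm <- se <- rep(NA_real_, nrow(tables))
  ebgm[defined] <- (k$a * N)[defined] / ((k$a + k$c) * (k$a + k$b))[defined]
  se[defined] <- sqrt(1 / k$a + 1 / k$b + 1 / k$c + 1 / k$d)[defined]
  lo <- exp(log(ebgm) - Z95 * se)
  hi <- exp(log(ebgm) + Z95 * se)
  tables |>
    mutate(
      ebgm = ebgm,
      ebgm05 = lo,
      ebgm95 = hi,
      ebgm_flag = !is.na(lo) & lo > 2
    )
}

#' Re-evaluate the four flagging rules
#'
#' Recomputes every algorithm's flag from the statistic columns already
#' present, plus `n_algorithms_flagged` (0-4).  All thresholds are
#' overridable; the defaults are the conventional screening rules.  An
#' undefined statistic never flags.
#'
#' @param results A tibble carrying `a` and the statistic columns produced
#'   by the four `*_signal()` functions.
#' @param min_a Minimum case count for ROR/PRR (default 3).
#' @param ror_ci,prr_min,chi2_min,ic025_min,ebgm05_min Rule cutoffs
#'   (defaults 1, 2, 4, 0, 2).
#' @return `results` with the four `*_flag` columns and
#'   `n_algorithms_flagged` recomputed.
#' @export
evaluate_thresholds <- function(results, min_a = 3, ror_ci = 1, prr_min = 2,
                                chi2_min = 4, ic025_min = 0, ebgm05_min = 2) {
  safe <- function(x) !is.na(x) & x
  results |>
    mutate(
      ror_flag = safe(.data$a >= min_a & .data$ror_ci_low > ror_ci),
      prr_flag = safe(.data$a >= min_a & .data$prr >= prr_min & .data$chi2 >= chi2_min),
      bcpnn_flag = safe(.data$ic025 > ic025_min),
      ebgm_flag = safe(.data$ebgm05 > ebgm05_min),
      n_algorithms_flagged = .data$ror_flag + .data$prr_flag +
        .data$bcpnn_flag + .data$ebgm_flag
    )
}

#' All four disproportionality statistics at once
#'
#' Runs [ror_signal()], [prr_signal()], [bcpnn_signal()] and
#' [ebgm_signal()] on a contingency tibble and applies
#' [evaluate_thresholds()].  The result carries class `"faers_signals"`
#' and supports [tidy()], [glance()] and [autoplot()].
#'
#' @inheritParams prr_signal
#' @param hyper A [bcpnn_hyperparameters()] object.
#' @return A `faers_signals` tibble: the input columns plus every
#'   statistic, interval bound, per-algorithm flag and
#'   `n_algorithms_flagged`.
#' @export
disproportionality <- function(tables, hyper = bcpnn_hyperparameters(),
                               correction = c("none", "yates"),
                               zero_correction = FALSE) {
  correction <- match.arg(correction)
  out <- tables |>
    ror_signal(zero_correction = zero_correction) |>
    prr_signal(correction = correction, zero_correction = zero_correction) |>
    bcpnn_signal(hyper = hyper) |>
    ebgm_signal(zero_correction = zero_correction) |>
    evaluate_thresholds()
  class(out) <- c("faers_signals", class(out))
  attr(out, "hyper") <- hyper
  attr(out, "correction") <- correction
  attr(out, "zero_correction") <- zero_correction
  out
}

#' Rank signal results by EBGM05
#'
#' Orders events by descending EBGM05 — the most stringent of the four
#' lower bounds — with undefined values last; ties break by descending
#' case count `a`, then event label.
#'
#' @param results A tibble with `ebgm05`, `a` and `event` columns.
#' @param top_n Keep at most this many rows (default all).
#' @return The reordered (and possibly truncated) tibble.
#' @export
rank_by_ebgm05 <- function(results, top_n = Inf) {
  out <- results |>
    arrange(desc(.data$ebgm05), desc(.data$a), .data$event)
  if (is.finite(top_n)) out <- out |> slice_head(n = as.integer(top_n))
  out
}
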