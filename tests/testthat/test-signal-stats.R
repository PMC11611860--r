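test_that("point estimates and intervals match hand-derived values", {
  r <- disproportionality(make_table(10, 90, 100, 9800))
  o <- oracle_stats(10, 90, 100, 9800)
  expect_equal(r$ror, 10.89, tolerance = 0.001)
  expect_equal(r$ror_ci_low, 5.50, tolerance = 0.001)
  expect_equal(r$prr, 9.90, tolerance = 0.001)
  expect_equal(r$ebgm, 9.09, tolerance = 0.001)
  expect_equal(r$ror, o$ror)
  expect_equal(r$chi2, o$chi2)
  expect_equal(r$e_ic, o$e_ic)
  expect_equal(r$v_ic, o$v_ic)
  # shrinkage pulls the posterior expectation below the raw IC
  expect_lt(r$e_ic, r$ic_raw)
})

test_that("balanced tables are null under every statistic", {
  for (k in c(1, 5, 50)) {
    r <- disproportionality(make_table(k, k, k, k))
    expect_equal(r$ror, 1)
    expect_equal(r$prr, 1)
    expect_equal(r$chi2, 0)
    expect_equal(r$ic_raw, 0)
    expect_equal(r$ebgm, 1)
    expect_equal(r$n_algorithms_flagged, 0L)
  }
})

test_that("degenerate cells give explicit undefined results, never flags", {
  r <- disproportionality(make_table(5, 0, 10, 100))
  expect_true(is.na(r$ror))
  expect_false(r$ror_flag)
  expect_true(is.na(r$ebgm))
  expect_false(r$ebgm_flag)

  r0 <- disproportionality(make_table(5, 5, 0, 100))
  expect_true(is.na(r0$prr))
  expect_false(r0$prr_flag)

  ra <- disproportionality(make_table(0, 10, 10, 100))
  expect_equal(ra$n_algorithms_flagged, 0L)
  expect_equal(ra$prr, 0)
  expect_equal(ra$ic_raw, -Inf)
})

test_that("the Haldane correction makes zero-cell tables estimable on request", {
  r <- ror_signal(make_table(5, 0, 10, 100), zero_correction = TRUE)
  o <- oracle_stats(5.5, 0.5, 10.5, 100.5)
  expect_equal(r$ror, o$ror)
  # tables without zeros are untouched by the switch
  r2 <- ror_signal(make_table(5, 5, 10, 100), zero_correction = TRUE)
  expect_equal(r2$ror, oracle_stats(5, 5, 10, 100)$ror)
})

test_that("EBGM equals 2^IC on random positive tables", {
  withr::local_seed(99)
  a <- sample(1:500, 1000, TRUE); b <- sample(1:500, 1000, TRUE)
  c <- sample(1:500, 1000, TRUE); d <- sample(1:5000, 1000, TRUE)
  tb <- make_table(a, b, c, d, event = sprintf("e%04d", 1:1000))
  r <- disproportionality(tb)
  expect_equal(r$ebgm, 2^r$ic_raw, tolerance = 1e-12)
})

test_that("flag boundaries follow the screening rules exactly", {
  base <- disproportionality(make_table(10, 90, 100, 9800))
  # a below the minimum count unflags ROR and PRR even with strong CIs
  small <- disproportionality(make_table(2, 8, 10, 9800))
  expect_gt(small$ror_ci_low, 1)
  expect_false(small$ror_flag)
  expect_false(small$prr_flag)

  # rule boundaries: >= for PRR and chi2, strict for the three lower bounds
  probe <- base |>
    dplyr::mutate(prr = 2, chi2 = 4, ror_ci_low = 1, ic025 = 0, ebgm05 = 2) |>
    evaluate_thresholds()
  expect_true(probe$prr_flag)
  expect_false(probe$ror_flag)
  expect_false(probe$bcpnn_flag)
  expect_false(probe$ebgm_flag)
  probe2 <- base |>
    dplyr::mutate(ror_ci_low = 1 + 1e-9, ic025 = 1e-9, ebgm05 = 2 + 1e-9) |>
    evaluate_thresholds()
  expect_true(probe2$ror_flag)
  expect_true(probe2$bcpnn_flag)
  expect_true(probe2$ebgm_flag)
  expect_equal(probe2$n_algorithms_flagged, 4L)
})

test_that("custom thresholds are honoured", {
  r <- disproportionality(make_table(10, 90, 100, 9800))
  strict <- evaluate_thresholds(r, ebgm05_min = 1e6)
  expect_false(strict$ebgm_flag)
})

test_that("all four point estimates are nondecreasing in a", {
  ests <- sapply(1:30, function(a) {
    r <- disproportionality(make_table(a, 90, 100, 9800))
    c(r$ror, r$prr, r$e_ic, r$ebgm)
  })
  for (i in 1:4) expect_true(all(diff(ests[i, ]) > -1e-12))
})

test_that("the posterior IC converges to the raw IC as counts grow", {
  gap <- sapply(c(1, 10, 100, 1000), function(k) {
    r <- bcpnn_signal(make_table(4 * k, 16 * k, 36 * k, 144 * k))
    abs(r$e_ic - r$ic_raw)
  })
  expect_true(all(diff(gap) < 0))
  expect_lt(gap[4], 0.01)
})

test_that("ROR approximates PRR in the rare-event limit", {
  # events rare within cohort (a << b) and background (c << d); the ratio
  # of the two statistics is (1 + a/b)/(1 + c/d), so it collapses to 1 here
  tb <- make_table(c(5, 20, 80), c(495, 1980, 7920), c(1000, 4000, 16000),
                   c(98500, 394000, 1576000), event = c("r1", "r2", "r3"))
  r <- prr_signal(ror_signal(tb))
  expect_true(all(abs(r$ror - r$prr) / r$prr < 0.05))
})

test_that("the 95% ROR interval has near-nominal coverage", {
  withr::local_seed(2024)
  n_rep <- 10000
  n1 <- 300; n0 <- 20000
  p1 <- 0.25; p0 <- 0.1
  true_or <- (p1 / (1 - p1)) / (p0 / (1 - p0))
  a <- stats::rbinom(n_rep, n1, p1)
  c <- stats::rbinom(n_rep, n0, p0)
  tb <- make_table(a, n1 - a, c, n0 - c, event = sprintf("s%05d", 1:n_rep))
  r <- ror_signal(tb)
  covered <- r$ror_ci_low <= true_or & r$ror_ci_high >= true_or
  expect_equal(mean(covered, na.rm = TRUE), 0.95, tolerance = 0.02 / 0.95)
})

test_that("EBGM05 ranking is total: lower bound, case count, label", {
  tb <- make_table(c(5, 9, 4, 3), c(10, 10, 10, 10), c(10, 10, 10, 10),
                   c(975, 975, 975, 975), event = c("w", "x", "y", "z"))
  r <- disproportionality(tb) |>
    dplyr::mutate(ebgm05 = c(5, 7, 7, NA))
  rk <- rank_by_ebgm05(r)
  # ties on the bound break by larger a; undefined values sort last
  expect_equal(rk$event, c("x", "y", "w", "z"))
  expect_equal(rank_by_ebgm05(r, top_n = 2)$event, c("x", "y"))
  expect_equal(nrow(rank_by_ebgm05(r, top_n = 100)), 4L)
})

test_that("the derived Dirichlet total recomputes from the printed pieces", {
  tb <- make_table(7, 13, 29, 451)
  h <- bcpnn_hyperparameters()
  g <- bcpnn_gamma(tb, h)
  N <- 7 + 13 + 29 + 451
  expect_equal(g, h$gamma_ij * (N + h$alpha) * (N + h$beta) /
                 ((7 + 13 + h$alpha_i) * (7 + 29 + h$beta_j)))
  expect_error(bcpnn_hyperparameters(alpha = -1), "positive")
})

test_that("tidy and glance expose the broom view of a result", {
  r <- disproportionality(make_table(c(10, 3), c(90, 97), c(100, 50),
                                     c(9800, 9850), event = c("e1", "e2")))
  td <- tidy(r)
  expect_equal(nrow(td), 8L)
  expect_setequal(unique(td$method), c("ror", "prr", "bcpnn", "ebgm"))
  expect_equal(td$estimate[td$event == "e1" & td$method == "ror"], r$ror[1])
  gl <- glance(r)
  expect_equal(gl$n_events, 2L)
  expect_s3_class(autoplot(r), "ggplot")
})
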