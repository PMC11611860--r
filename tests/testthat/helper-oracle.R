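# Independent scalar reference implementation of the four statistics.
# Deliberately written as step-by-step scalar arithmetic on the log scale,
# separate from the package's vectorized code path.

oracle_stats <- function(a, b, c, d,
                         alpha = 2, beta = 2, alpha_i = 1, beta_j = 1,
                         gamma_ij = 1) {
  N <- a + b + c + d
  out <- list()

  # ROR = ad/bc, CI on the log scale
  if (a > 0 && b > 0 && c > 0 && d > 0) {
    log_ror <- log(a) + log(d) - log(b) - log(c)
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    out$ror <- exp(log_ror)
    out$ror_lo <- exp(log_ror - 1.96 * se)
    out$ror_hi <- exp(log_ror + 1.96 * se)
  } else {
    out$ror <- out$ror_lo <- out$ror_hi <- NA_real_
  }

  # PRR and Pearson chi-squared
  if (c > 0 && (a + b) > 0 && (c + d) > 0) {
    log_prr <- log(a / (a + b)) - log(c / (c + d))
    out$prr <- exp(log_prr)
    if (a > 0) {
      se_p <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
      out$prr_lo <- exp(log_prr - 1.96 * se_p)
      out$prr_hi <- exp(log_prr + 1.96 * se_p)
    } else {
      out$prr_lo <- out$prr_hi <- NA_real_
    }
  } else {
    out$prr <- out$prr_lo <- out$prr_hi <- NA_real_
  }
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  out$chi2 <- if (denom > 0) N * (a * d - b * c)^2 / denom else NA_real_

  # BCPNN posterior
  if ((a + b) > 0 && (a + c) > 0) {
    out$ic_raw <- log2(a * N / ((a + b) * (a + c)))
    gam <- gamma_ij * (N + alpha) * (N + beta) /
      ((a + b + alpha_i) * (a + c + beta_j))
    out$gamma <- gam
    out$e_ic <- log2(
      (a + gamma_ij) * (N + alpha) * (N + beta) /
        ((N + gam) * (a + b + alpha_i) * (a + c + beta_j))
    )
    t1 <- (N - a + gam - gamma_ij) / ((a + gamma_ij) * (1 + N + gam))
    t2 <- (N - (a + b) + alpha - alpha_i) / ((a + b + alpha_i) * (1 + N + alpha))
    t3 <- (N - (a + c) + beta - beta_j) / ((a + c + beta_j) * (1 + N + beta))
    out$v_ic <- (t1 + t2 + t3) / log(2)^2
    out$ic025 <- out$e_ic - 2 * sqrt(out$v_ic)
  } else {
    out$ic_raw <- out$e_ic <- out$v_ic <- out$ic025 <- NA_real_
  }

  # EBGM = observed / expected
  if (a > 0 && b > 0 && c > 0 && d > 0) {
    log_ebgm <- log(a) + log(N) - log(a + c) - log(a + b)
    se_e <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    out$ebgm <- exp(log_ebgm)
    out$ebgm05 <- exp(log_ebgm - 1.96 * se_e)
    out$ebgm95 <- exp(log_ebgm + 1.96 * se_e)
  } else {
    out$ebgm <- out$ebgm05 <- out$ebgm95 <- NA_real_
  }
  out
}
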