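# Shared fixtures: a small simulated cohort reused across test files, and
# hand-built toy log tables for the filtration tests.

small_cohort <- local({
  cfg <- generator_config(n_participants = 6, n_days = 4, seed = 101)
  simulate_cohort(cfg)
})

small_records <- local({
  rec <- align_records(filter_daytime(small_cohort$hr),
                       filter_daytime(small_cohort$sound))
  rec
})

# Toy log tables with known counts: 10 HR logs, 3 of them at night.
toy_hr_logs <- local({
  ts <- as.POSIXct("2019-06-03 00:00:00", tz = "UTC") +
    c(2 * 3600, 4 * 3600, 5 * 3600 + 3599,          # night
      6 * 3600, 8 * 3600, 10 * 3600, 12 * 3600,     # day
      15 * 3600, 19 * 3600, 23 * 3600 + 3599)       # day
  tibble::tibble(participant_id = "P1", timestamp = ts, hr = 70 + seq_len(10))
})

# Dense multivariate-normal log-likelihood evaluated from an explicit
# covariance matrix; the independent oracle for the structured computation.
dense_mvn_loglik <- function(y, X, beta, V) {
  r <- y - as.numeric(X %*% beta)
  ch <- chol(V)
  w <- backsolve(ch, r, transpose = TRUE)
  -0.5 * (length(y) * log(2 * pi) + 2 * sum(log(diag(ch))) + sum(w^2))
}

# Explicit marginal covariance of the mixed model on a design: dense
# Z G Z' + sigma2 * AR1 blocks, built directly from first principles.
dense_model_cov <- function(design, varcomp, sigma2, phi) {
  n <- design$n
  lamv <- varcomp[design$vgroup]
  V <- matrix(0, n, n)
  # random effects are independent across participants: block-diagonal
  for (pid in unique(design$participant)) {
    idx <- which(design$participant == pid)
    Zi <- design$Z[idx, , drop = FALSE]
    V[idx, idx] <- Zi %*% (diag(lamv, ncol(Zi)) %*% t(Zi))
  }
  for (b in unique(design$block)) {
    idx <- which(design$block == b)
    m <- length(idx)
    V[idx, idx] <- V[idx, idx] +
      sigma2 * phi^abs(outer(seq_len(m), seq_len(m), "-"))
  }
  V
}
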