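# Mixed-model machinery: design encoding, likelihood oracles (dense
# multivariate normal, OLS collapse, independent library fits), diagnostics
# (LRT, GVIF), effect sizes and contrasts.

make_records <- function(n_participants = 4, per_day = 12, n_days = 3,
                         seed = 1, sd_p = 2, phi = 0.4, sd_e = 3,
                         beta = c(spl = 1.5, sml = 0.7, snr = -1),
                         classes = FALSE) {
  set.seed(seed)
  out <- list()
  for (p in seq_len(n_participants)) {
    bp <- rnorm(1, 0, sd_p)
    for (d in seq_len(n_days)) {
      t0 <- as.POSIXct("2019-06-03 08:00:00", tz = "UTC") + (d - 1) * 86400
      e <- numeric(per_day)
      e[1] <- rnorm(1, 0, sd_e)
      for (i in 2:per_day)
        e[i] <- phi * e[i - 1] + rnorm(1, 0, sd_e * sqrt(1 - phi^2))
      x <- matrix(rnorm(per_day * 3), per_day, 3,
                  dimnames = list(NULL, c("spl", "sml", "snr")))
      cls <- sample(SOUNDSCAPES, per_day, replace = TRUE)
      hr <- 75 + x %*% beta + bp + e
      out[[length(out) + 1]] <- tibble::tibble(
        participant_id = sprintf("P%02d", p),
        timestamp = t0 + (seq_len(per_day) - 1) * 420,
        hr = as.numeric(hr),
        spl = x[, 1] * 6 + 60, sml = x[, 2] * 5 + 15, snr = x[, 3] * 4 + 6,
        soundscape = cls,
        weekday = as.integer(format(t0, "%u")),
        hour = as.integer(format(t0 + (seq_len(per_day) - 1) * 420, "%H")))
    }
  }
  dplyr::bind_rows(out)
}

test_that("design encoding standardizes, dummy-codes and collapses classes", {
  rec <- make_records(seed = 3)
  d <- build_design(rec, model_spec("acoustic"))
  expect_equal(mean(d$X[, "spl"]), 0, tolerance = 1e-10)
  expect_equal(sd(d$X[, "spl"]), 1, tolerance = 1e-10)
  ds <- build_design(rec, model_spec("soundscape"))
  expect_equal(colnames(ds$X), c("(Intercept)", "Speech", "SpeechInNoise",
                                 "Noise"))
  # Quiet rows have all dummies zero (reference level)
  qrow <- which(ds$records$soundscape == "Quiet")[1]
  expect_equal(unname(ds$X[qrow, -1]), c(0, 0, 0))
  di <- build_design(rec, model_spec("interaction"))
  expect_true(all(c("Speech", "Noisy", "Speech:spl", "Noisy:snr") %in%
                    colnames(di$X)))
  # constant predictor is rejected
  rec_const <- rec; rec_const$sml <- 15
  expect_error(build_design(rec_const, model_spec("acoustic")), "constant")
})

test_that("structured AR(1) log-likelihood equals the dense MVN oracle", {
  rec <- make_records(n_participants = 3, per_day = 10, n_days = 3, seed = 5)
  d <- build_design(rec, model_spec("acoustic"))
  fit <- fit_lme_ar1(d)
  V <- dense_model_cov(d, fit$varcomp, fit$sigma2, fit$phi)
  ll_dense <- dense_mvn_loglik(d$y, d$X, fit$beta, V)
  expect_equal(fit$loglik, ll_dense, tolerance = 1e-8)
  # also at a non-optimal parameter point
  lam <- setNames(rep(0.3, length(fit$lambda)), names(fit$lambda))
  pl <- soundhr:::profiled_ll(d, soundhr:::design_cache(d), lam, 0.25, "ML")
  V2 <- dense_model_cov(d, lam * pl$sigma2, pl$sigma2, 0.25)
  ll2 <- dense_mvn_loglik(d$y, d$X, pl$beta, V2)
  expect_equal(pl$ll, ll2, tolerance = 1e-8)
})

test_that("the mixed model collapses to OLS when variances and phi are zero", {
  rec <- make_records(sd_p = 0, phi = 0, seed = 11)
  d <- build_design(rec, model_spec("acoustic"))
  # evaluated at the zero-variance, zero-phi limit the GLS profile is OLS
  lam0 <- setNames(rep(1e-12, 6),
                   c("participant", "slope_spl", "slope_sml", "slope_snr",
                     "weekday", "hour"))
  pl <- soundhr:::profiled_ll(d, soundhr:::design_cache(d), lam0, 0, "ML")
  ols <- lm(d$y ~ d$X[, -1])
  expect_equal(unname(pl$beta), unname(coef(ols)), tolerance = 1e-6)
  s2 <- sum(resid(ols)^2) / d$n
  expect_equal(pl$ll, -0.5 * d$n * (log(2 * pi * s2) + 1), tolerance = 1e-6)
  # the free fit on data generated without random structure lands close
  fit <- fit_lme_ar1(d)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 0.05)
  expect_lt(abs(fit$phi), 0.1)
})

test_that("a reduced structure matches nlme and lme4 maximum likelihoods", {
  skip_if_not_installed("nlme")
  skip_if_not_installed("lme4")
  # one AR(1) block per participant: comparable to corAR1 | participant
  rec <- make_records(n_participants = 6, per_day = 25, n_days = 1, seed = 7)
  d <- build_design(rec, model_spec("acoustic", random_slopes = FALSE,
                                    random_weekday = FALSE,
                                    random_hour = FALSE))
  fit <- fit_lme_ar1(d)
  df <- data.frame(y = d$y, d$X[, -1], g = d$participant)
  nl <- nlme::lme(y ~ spl + sml + snr, random = ~ 1 | g, data = df,
                  correlation = nlme::corAR1(form = ~ 1 | g), method = "ML")
  expect_equal(fit$loglik, as.numeric(stats::logLik(nl)), tolerance = 1e-5)
  expect_equal(unname(fit$beta), unname(nlme::fixef(nl)), tolerance = 1e-4)
  expect_equal(fit$phi,
               as.numeric(coef(nl$modelStruct$corStruct, unconstrained = FALSE)),
               tolerance = 1e-3)
  # without AR(1): equals lme4 ML deviance
  d2 <- build_design(rec, model_spec("acoustic", random_slopes = FALSE,
                                     random_weekday = FALSE,
                                     random_hour = FALSE, ar1 = FALSE))
  fit2 <- fit_lme_ar1(d2)
  lm4 <- lme4::lmer(y ~ spl + sml + snr + (1 | g), data = df, REML = FALSE)
  expect_equal(fit2$loglik, as.numeric(stats::logLik(lm4)), tolerance = 1e-5)
})

test_that("REML matches nlme's restricted likelihood", {
  skip_if_not_installed("nlme")
  rec <- make_records(n_participants = 5, per_day = 20, n_days = 1, seed = 13)
  d <- build_design(rec, model_spec("acoustic", random_slopes = FALSE,
                                    random_weekday = FALSE,
                                    random_hour = FALSE))
  fit <- fit_lme_ar1(d, method = "REML")
  df <- data.frame(y = d$y, d$X[, -1], g = d$participant)
  nl <- nlme::lme(y ~ spl + sml + snr, random = ~ 1 | g, data = df,
                  correlation = nlme::corAR1(form = ~ 1 | g), method = "REML")
  expect_equal(fit$loglik, as.numeric(stats::logLik(nl)), tolerance = 1e-4)
})

test_that("likelihood-ratio test arithmetic and parameter counting", {
  rec <- make_records(seed = 17)
  full <- fit_lme_ar1(build_design(rec, model_spec("acoustic")))
  null <- fit_lme_ar1(build_design(rec, model_spec("intercept",
                                                   random_slopes = FALSE)))
  lrt <- likelihood_ratio_test(full, null)
  expect_equal(lrt$chi2, 2 * (full$loglik - null$loglik))
  # 3 fixed slopes + 3 random-slope variances
  expect_equal(lrt$df, 6)
  # identical models: chi2 = 0, p = 1
  lrt0 <- likelihood_ratio_test(full, full)
  expect_equal(lrt0$chi2, 0)
  expect_equal(lrt0$p, 1)
  # REML fits are rejected
  fr <- fit_lme_ar1(build_design(rec, model_spec("acoustic")), method = "REML")
  expect_error(likelihood_ratio_test(fr, null), "ML")
  # soundscape model vs intercept-only: 3 fixed offsets
  fs <- fit_lme_ar1(build_design(rec, model_spec("soundscape")))
  expect_equal(likelihood_ratio_test(fs, null)$df, 3)
})

test_that("GVIF matches closed forms and the car implementation", {
  # orthogonal predictors: GVIF 1
  X <- cbind(a = rep(c(-1, 1), 10), b = rep(c(-1, -1, 1, 1), 5))
  expect_equal(unname(gvif(X)), c(1, 1))
  # correlation 0.9: VIF = 1 / (1 - 0.81)
  set.seed(2)
  n <- 5000
  x1 <- rnorm(n)
  x2 <- 0.9 * x1 + sqrt(1 - 0.81) * rnorm(n)
  g <- gvif(cbind(x1 = x1, x2 = x2))
  r <- cor(x1, x2)
  expect_equal(unname(g[1]), 1 / (1 - r^2), tolerance = 1e-10)
  # three predictors: explicit determinant arithmetic
  x3 <- rnorm(n)
  X3 <- cbind(x1 = x1, x2 = x2, x3 = x3)
  R <- cor(X3)
  manual <- sapply(1:3, function(i)
    det(R[i, i, drop = FALSE]) * det(R[-i, -i]) / det(R))
  expect_equal(unname(gvif(X3)), manual)
  # scaling invariance
  X3s <- X3; X3s[, 1] <- X3s[, 1] * 100
  expect_equal(gvif(X3s), gvif(X3))
  skip_if_not_installed("car")
  df <- data.frame(y = rnorm(n), X3)
  vifs <- car::vif(lm(y ~ x1 + x2 + x3, data = df))
  expect_equal(unname(gvif(X3)), unname(vifs), tolerance = 1e-10)
  # perfectly collinear columns are rejected
  expect_error(gvif(cbind(a = x1, b = x1)), "singular")
})

test_that("partial R2 is 0 for identical models and approaches 1 without noise", {
  rec <- make_records(seed = 19)
  full <- fit_lme_ar1(build_design(rec, model_spec("acoustic")))
  expect_equal(partial_r2(full, full)$RP2, 0)
  # noiseless fixed-effect data: fixed effects explain everything
  rec2 <- make_records(sd_p = 0, phi = 0, sd_e = 1e-4, seed = 23)
  f2 <- fit_lme_ar1(build_design(rec2, model_spec("acoustic")))
  # the null shares the nested intercept structure but has no slopes
  n2b <- fit_lme_ar1(build_design(rec2, model_spec("intercept")))
  es <- partial_r2(f2, n2b)
  expect_gt(es$RP2, 0.99)
  expect_gt(es$RF2, 0.99)
  # mismatched nested structure is rejected
  no_hour <- fit_lme_ar1(build_design(rec2, model_spec("intercept",
                                                       random_hour = FALSE)))
  expect_error(partial_r2(f2, no_hour), "random structure")
})

test_that("percent change back-transforms log-scale coefficients", {
  expect_equal(percent_change(0), 0)
  expect_equal(percent_change(log(2)), 100)
  expect_equal(percent_change(0.0015388), 0.154, tolerance = 1e-3)
})

test_that("interaction contrasts equal stratified OLS slope differences", {
  # no random effects, no AR(1): the contrast must equal the difference of
  # per-class OLS slopes on the standardized variable
  set.seed(31)
  n <- 900
  cls <- sample(c("Quiet", "Speech", "Noise"), n, replace = TRUE)
  spl <- rnorm(n, 60, 6); sml <- rnorm(n, 15, 5); snr <- rnorm(n, 6, 4)
  slope <- c(Quiet = 2, Speech = 2.2, Noise = 1.1)
  zs <- (spl - mean(spl)) / sd(spl)
  hr <- 75 + slope[cls] * zs + rnorm(n, 0, 2)
  rec <- tibble::tibble(
    participant_id = rep(c("A", "B", "C"), length.out = n),
    timestamp = as.POSIXct("2019-06-03 08:00:00", tz = "UTC") +
      ave(seq_len(n), rep(c("A", "B", "C"), length.out = n),
          FUN = seq_along) * 420,
    hr = hr, spl = spl, sml = sml, snr = snr, soundscape = cls,
    weekday = 1L, hour = 10L)
  d <- build_design(rec, model_spec("interaction", random_slopes = FALSE,
                                    random_weekday = FALSE,
                                    random_hour = FALSE, ar1 = FALSE))
  # freeze variances near zero: plain OLS on the interaction design
  fit <- fit_lme_ar1(d)
  ctr <- interaction_contrasts(fit)
  # stratified OLS oracle: with every predictor interacting with class and
  # class intercepts present, the interaction design is equivalent to
  # separate per-class multiple regressions on the pooled-standardized
  # predictors, so each contrast is an exact difference of those slopes
  zf <- function(v) (v - mean(v)) / sd(v)
  zd <- data.frame(hr = rec$hr, spl = zf(rec$spl), sml = zf(rec$sml),
                   snr = zf(rec$snr), cls = rec$soundscape)
  ols_slope <- function(cl) {
    sel <- if (cl == "Noisy") zd$cls == "Noise" else zd$cls == cl
    coef(lm(hr ~ spl + sml + snr, data = zd[sel, ]))["spl"]
  }
  want_speech <- ols_slope("Speech") - ols_slope("Quiet")
  want_noisy <- ols_slope("Noisy") - ols_slope("Quiet")
  got <- ctr[ctr$predictor == "spl", ]
  expect_equal(got$estimate[got$class == "Speech"], unname(want_speech),
               tolerance = 1e-3)
  expect_equal(got$estimate[got$class == "Noisy"], unname(want_noisy),
               tolerance = 1e-3)
  expect_error(interaction_contrasts(
    fit_lme_ar1(build_design(rec, model_spec("acoustic", ar1 = FALSE)))),
    "interaction")
})
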