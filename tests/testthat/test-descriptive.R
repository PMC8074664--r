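# Descriptive computations: CDFs, hourly summaries, marginal-mean decile
# regressions, repeated-measures ANOVA, and the Leq aggregation property.

test_that("Leq dominates the arithmetic dB mean (Jensen)", {
  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(50, 60, 8)
    expect_gte(leq(x), mean(x))
  }
  expect_equal(leq(rep(55, 10)), 55)
})

test_that("class CDF curves collapse to zero-width CIs for identical participants", {
  base <- tibble::tibble(
    participant_id = "A",
    soundscape = rep(c("Quiet", "Speech"), each = 200),
    spl = c(seq(40, 60, length.out = 200), seq(55, 75, length.out = 200)))
  logs <- dplyr::bind_rows(base,
                           dplyr::mutate(base, participant_id = "B"),
                           dplyr::mutate(base, participant_id = "C"))
  cd <- class_cdfs(logs, "spl", n_boot = 50)
  expect_true(all(cd$upper - cd$lower == 0))
  expect_equal(sort(unique(cd$soundscape)), c("Quiet", "Speech"))
  # single-participant class is omitted with a warning
  solo <- dplyr::bind_rows(logs,
                           tibble::tibble(participant_id = "A",
                                          soundscape = "Noise",
                                          spl = rnorm(30, 65)))
  expect_warning(class_cdfs(solo, "spl", n_boot = 10), "fewer than 2")
})

test_that("synthetic speech dominates noise in SNR at all percentiles", {
  cd <- class_cdfs(small_cohort$sound, "snr", n_boot = 30)
  sp <- cd[cd$soundscape == "Speech", ]
  no <- cd[cd$soundscape == "Noise", ]
  expect_true(all(sp$median > no$median))
})

test_that("hourly occupancy rows sum to 100 and track the configuration", {
  hs <- hourly_summaries(small_cohort$sound)
  occ <- as.matrix(hs$occupancy[, SOUNDSCAPES])
  expect_equal(unname(rowSums(occ)), rep(100, nrow(occ)), tolerance = 1e-9)
  # all-Quiet input: 100% Quiet in every hour
  sl <- small_cohort$sound
  sl$soundscape <- "Quiet"
  occ_q <- hourly_summaries(sl)$occupancy
  expect_true(all(occ_q$Quiet == 100))
  # generated occupancy follows the configured diurnal profile: Quiet share
  # in the early morning exceeds the midday share
  cfgocc <- generator_config()$diurnal_occupancy
  q7 <- occ[hs$occupancy$hour == 7, "Quiet"] / 100
  q12 <- occ[hs$occupancy$hour == 12, "Quiet"] / 100
  expect_gt(q7, q12)
  expect_lt(abs(q7 - cfgocc["7", "Quiet"]), 0.12)
  expect_lt(abs(q12 - cfgocc["12", "Quiet"]), 0.12)
})

test_that("marginal means recover exact linear structure and match OLS closed forms", {
  set.seed(9)
  n <- 600
  rec <- tibble::tibble(
    participant_id = rep(c("A", "B", "C"), each = n / 3),
    spl = rnorm(n, 60, 6))
  # HR an exact linear function of the variable (per participant affine)
  rec$hr <- 70 + 2 * rec$spl + rep(c(0, 5, -4), each = n / 3)
  # bin means are exactly linear in the binned variable; the tiny gap from
  # r2 = 1 comes from mid-quantile centers standing in for bin means
  mm <- marginal_means(rec, "spl")
  expect_gt(mm$r2, 0.995)
  expect_gt(mm$F, 1000)
  expect_equal(mm$df, c(1, 8))
  # closed-form simple regression on the 10 bin means
  bx <- mm$bins$center; by <- mm$bins$mean_hr
  slope_cf <- sum((bx - mean(bx)) * (by - mean(by))) / sum((bx - mean(bx))^2)
  expect_equal(mm$slope, slope_cf, tolerance = 1e-10)
  # invariance to per-participant affine rescaling of raw HR
  rec2 <- rec
  rec2$hr <- ifelse(rec2$participant_id == "B", 10 + 3 * rec2$hr, rec2$hr)
  mm2 <- marginal_means(rec2, "spl")
  expect_equal(mm2$bins$mean_hr, mm$bins$mean_hr, tolerance = 1e-10)
  # independent HR: slope near zero, F small
  rec3 <- rec; rec3$hr <- rnorm(n, 75, 5)
  mm3 <- marginal_means(rec3, "spl")
  expect_lt(abs(mm3$slope), 0.5)
  expect_lt(mm3$F, 25)
})

test_that("marginal means stratify on the 60 dB SPL rule", {
  rec <- small_records
  lo <- marginal_means(rec, "snr", spl_stratum = "low")
  hi <- marginal_means(rec, "snr", spl_stratum = "high")
  expect_equal(lo$threshold, 60)
  expect_equal(nrow(lo$bins), 10)
  expect_equal(nrow(hi$bins), 10)
})

test_that("repeated-measures ANOVA matches the hand-computed decomposition", {
  # 5 participants x 4 classes, textbook two-way decomposition by hand
  Y <- matrix(c(70, 72, 75, 74,
                68, 71, 73, 75,
                72, 73, 74, 78,
                69, 70, 74, 73,
                71, 74, 76, 77), 5, 4, byrow = TRUE)
  rec <- tibble::tibble(
    participant_id = rep(paste0("P", 1:5), each = 4),
    soundscape = rep(SOUNDSCAPES, 5),
    hr = as.numeric(t(Y)))
  res <- rm_anova_soundscape(rec, correction = "none")
  grand <- mean(Y)
  ss_class <- 5 * sum((colMeans(Y) - grand)^2)
  resid <- sweep(sweep(Y, 1, rowMeans(Y)), 2, colMeans(Y)) + grand
  F_hand <- (ss_class / 3) / (sum(resid^2) / 12)
  expect_equal(res$F, F_hand, tolerance = 1e-10)
  expect_equal(res$df1, 3)
  expect_equal(res$df2, 12)
  # Bonferroni adjustment multiplies raw p by the number of pairs
  expect_equal(res$pairwise$p_bonferroni,
               pmin(res$pairwise$p_raw * 6, 1))
  expect_true(all(res$pairwise$p_bonferroni >= res$pairwise$p_raw))
})

test_that("ANOVA degenerates correctly: equal means and two-level sphericity", {
  rec <- tibble::tibble(
    participant_id = rep(paste0("P", 1:4), each = 4),
    soundscape = rep(SOUNDSCAPES, 4),
    hr = rep(c(70, 72, 71, 69), each = 4)) # identical across classes
  res <- rm_anova_soundscape(rec)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  # with two classes there is a single contrast: epsilon is exactly 1 and
  # the Greenhouse-Geisser dfs are integer
  rec2 <- tibble::tibble(
    participant_id = rep(paste0("P", 1:5), each = 2),
    soundscape = rep(c("Quiet", "Speech"), 5),
    hr = c(70, 72, 71, 74, 69, 73, 72, 74, 70, 75))
  res2 <- rm_anova_soundscape(rec2)
  expect_equal(res2$epsilon, 1)
  expect_equal(res2$df1, 1)
  expect_equal(res2$df2, 4)
  expect_error(rm_anova_soundscape(rec2[1:4, ]), "at least 3")
})

test_that("soundscape ANOVA on synthetic class-offset data finds the effect", {
  cfg <- generator_config(n_participants = 10, n_days = 4,
                          scenario = "soundscape", seed = 55)
  co <- simulate_cohort(cfg)
  rec <- align_records(filter_daytime(co$hr), filter_daytime(co$sound))
  res <- rm_anova_soundscape(rec)
  expect_lt(res$p, 0.01)
  # Noise cells sit above Quiet cells on average (offset +2.61 bpm)
  expect_gt(res$cell_means[["Noise"]], res$cell_means[["Quiet"]])
})
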