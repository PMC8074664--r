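# Parameter-recovery runs: simulate a cohort under a scenario's generative
# defaults, run the preprocessing/alignment path, fit the matching model,
# and report the estimates the study's tables print. Used by the acceptance
# machinery and reusable for calibration studies.

#' Simulate-and-refit parameter recovery for one scenario and seed
#'
#' Simulates a cohort with [simulate_cohort()] under the scenario's default
#' effect sizes, applies the daytime filter and 5-min window alignment,
#' fits the matching mixed model, and returns the quantities of interest:
#' \describe{
#'   \item{acoustic}{bpm-per-1-s.d. coefficients for SPL, SML, SNR.}
#'   \item{soundscape}{bpm offsets vs Quiet for the three classes.}
#'   \item{movement}{bpm per m/s slope from a participant-intercept model
#'     on GPS-bearing records (window-averaged haversine speeds).}
#'   \item{log_acoustic}{percent change in HR per dB of SPL, SML, SNR from
#'     the log-response refit with dB-scale predictors.}
#'   \item{interaction}{slope offsets vs Quiet for each class and
#'     predictor (classes collapsed to Quiet/Speech/Noisy).}
#' }
#'
#' @param scenario Generator scenario name.
#' @param seed Integer seed for the cohort.
#' @param n_participants,n_days Cohort size (defaults 56 x 14, about 450
#'   aligned records per participant).
#' @return List with `estimates` (named numeric), `se` (matching standard
#'   errors), `fit` (the model fit) and `n_records`.
#' @export
recover_scenario <- function(scenario, seed, n_participants = 56,
                             n_days = 14) {
  cfg <- generator_config(n_participants = n_participants, n_days = n_days,
                          scenario = scenario, seed = seed)
  co <- simulate_cohort(cfg)
  rec <- align_records(filter_daytime(co$hr), filter_daytime(co$sound))
  if (scenario == "movement") {
    rec <- movement_speed(rec, filter_daytime(co$gps))
    rec <- rec[!is.na(rec$movement), , drop = FALSE]
    fit <- fit_lme_ar1(build_design(rec, model_spec(
      "movement", random_slopes = FALSE,
      random_weekday = FALSE, random_hour = FALSE)))
    est <- c(movement = unname(fit$beta[["movement"]]))
    se <- c(movement = unname(fit$se[["movement"]]))
  } else if (scenario == "acoustic") {
    fit <- fit_lme_ar1(build_design(rec, model_spec("acoustic")))
    est <- fit$beta[c("spl", "sml", "snr")]
    se <- fit$se[c("spl", "sml", "snr")]
  } else if (scenario == "soundscape") {
    fit <- fit_lme_ar1(build_design(rec, model_spec("soundscape")))
    est <- fit$beta[c("Speech", "SpeechInNoise", "Noise")]
    se <- fit$se[c("Speech", "SpeechInNoise", "Noise")]
  } else if (scenario == "log_acoustic") {
    fit <- fit_lme_ar1(build_design(rec, model_spec(
      "acoustic", response = "log_hr", predictor_scaling = "raw_db")))
    est <- percent_change(fit$beta[c("spl", "sml", "snr")])
    # delta method: d/db (exp(b)-1)*100 = 100 exp(b), with b near 0
    se <- 100 * exp(fit$beta[c("spl", "sml", "snr")]) *
      fit$se[c("spl", "sml", "snr")]
  } else if (scenario == "interaction") {
    fit <- fit_lme_ar1(build_design(rec, model_spec("interaction")))
    ctr <- interaction_contrasts(fit)
    nm <- paste0(ctr$class, ":", ctr$predictor)
    est <- stats::setNames(ctr$estimate, nm)
    se <- stats::setNames(ctr$se, nm)
  } else stop("unknown scenario: ", scenario, call. = FALSE)
  list(estimates = est, se = se, fit = fit, n_records = nrow(rec))
}

#' Average recovery over several seeds
#'
#' Runs [recover_scenario()] for each seed and averages the estimates, with
#' the Monte-Carlo standard error of the mean computed from the fits' own
#' standard errors.
#'
#' @inheritParams recover_scenario
#' @param seeds Integer vector of seeds (three or more recommended).
#' @return List `mean` (named estimates), `se_mean`, `per_seed` (matrix),
#'   `n_records` (per seed).
#' @export
recover_average <- function(scenario, seeds, n_participants = 56,
                            n_days = 14) {
  runs <- lapply(seeds, function(s)
    recover_scenario(scenario, s, n_participants, n_days))
  per_seed <- do.call(rbind, lapply(runs, `[[`, "estimates"))
  ses <- do.call(rbind, lapply(runs, `[[`, "se"))
  list(mean = colMeans(per_seed),
       se_mean = sqrt(colMeans(ses^2)) / sqrt(length(seeds)),
       per_seed = per_seed,
       n_records = vapply(runs, `[[`, numeric(1), "n_records"))
}
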