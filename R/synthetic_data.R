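# Synthetic cohort generator. Emits hearing-aid style sound logs (60 s
# cadence, 06:00-24:00 with a small night-time fraction), wearable-style
# 5-min mean heart-rate logs at jittered ~7.6 min cadence during wear
# sessions, and optional GPS tracks, together with a complete ground-truth
# record of every sampled random effect and linear predictor.
#
# Heart rate is generated directly from the multilevel linear model the
# analysis fits (population mean + fixed effects + nested random effects +
# AR(1) residuals); no cardiophysiological simulation is attempted.

# -- default calibration tables ----------------------------------------------

# Class-conditional acoustic parameters (window/record level, dB). Means and
# SDs follow the published medians/SDs for the four soundscapes; the Speech
# and Speech-in-Noise gaps are filled with values consistent with the class
# geometry (Speech highest SNR/SML, Speech-in-Noise highest SPL, Quiet
# lowest SPL).
default_class_acoustics <- function() {
  list(
    means = rbind(
      Quiet         = c(spl = 48.8, sml = 15.3, snr = 4.9),
      Speech        = c(spl = 62.0, sml = 21.8, snr = 12.5),
      SpeechInNoise = c(spl = 72.5, sml = 16.0, snr = 6.5),
      Noise         = c(spl = 66.0, sml = 11.6, snr = 3.8)
    ),
    sds = rbind(
      Quiet         = c(spl = 5.25, sml = 5.84, snr = 3.86),
      Speech        = c(spl = 6.00, sml = 6.45, snr = 5.14),
      SpeechInNoise = c(spl = 3.87, sml = 5.00, snr = 3.00),
      Noise         = c(spl = 7.34, sml = 4.69, snr = 2.50)
    ),
    # shared within-class correlation of (spl, sml, snr)
    corr = matrix(c(1, 0.3, -0.2,
                    0.3, 1, 0.4,
                    -0.2, 0.4, 1), 3, 3,
                  dimnames = list(c("spl", "sml", "snr"),
                                  c("spl", "sml", "snr")))
  )
}

# Per-hour soundscape occupancy probabilities (rows = hour 0..23). Shaped so
# that Quiet dominates early morning and late evening, Speech peaks in the
# early evening, and noisy classes peak around midday; record-level shares
# land near 35/32/18/15 percent.
default_diurnal_occupancy <- function() {
  p <- rbind(
    c(.85, .05, .05, .05), c(.85, .05, .05, .05), c(.85, .05, .05, .05),
    c(.85, .05, .05, .05), c(.85, .05, .05, .05), c(.85, .05, .05, .05),
    c(.60, .20, .10, .10), c(.55, .22, .12, .11), c(.50, .25, .13, .12),
    c(.45, .28, .14, .13), c(.38, .30, .17, .15), c(.33, .32, .20, .15),
    c(.28, .33, .22, .17), c(.32, .32, .20, .16), c(.34, .31, .19, .16),
    c(.32, .33, .19, .16), c(.28, .38, .19, .15), c(.26, .40, .19, .15),
    c(.25, .40, .20, .15), c(.28, .38, .19, .15), c(.35, .36, .15, .14),
    c(.42, .34, .13, .11), c(.55, .27, .10, .08), c(.65, .22, .07, .06)
  )
  p <- p / rowSums(p)
  dimnames(p) <- list(0:23, SOUNDSCAPES)
  p
}

default_mobility_params <- function() {
  list(stationary_sigma = 0.085, # Rayleigh scale of GPS-jitter speeds (m/s)
       p_start_move = 0.06, p_stop_move = 0.14, # two-state bout chain, per min
       speed_meanlog = log(1.3), speed_sdlog = 0.4, # walking-speed lognormal
       fast_fraction = 0.01, # minutes at vehicle speed (> 10 m/s)
       start_lat = 55.9, start_lon = 12.5)
}

#' Configuration of the synthetic cohort generator
#'
#' Defaults encode the study conditions the pipeline is meant to recover:
#' a 56-participant, 14-day cohort with roughly 450 aligned records per
#' participant; population heart rate 75.60 (6.89) bpm; acoustic fixed
#' effects +1.47 / +0.72 / -1.03 bpm per 1 s.d. of SPL / SML / SNR;
#' soundscape offsets +1.07 / +2.23 / +2.61 bpm vs Quiet; movement effect
#' 0.39 bpm per m/s; interaction slope offsets vs Quiet (classes collapsed
#' to Quiet/Speech/Noisy) SPL +0.16 / -0.60, SML -0.74 / -1.08,
#' SNR 0 / +0.79; log-scale effects 0.154 / 0.112 / -0.169 percent per dB.
#'
#' The `scenario` selects which effect family drives the generated heart
#' rate, so that fitting the matching model is a well-posed parameter
#' recovery: `"acoustic"` (continuous slopes on standardized window
#' acoustics), `"soundscape"` (class offsets), `"interaction"` (class
#' offsets plus class-specific slopes, Speech-in-Noise and Noise collapsed
#' to Noisy), `"log_acoustic"` (log-bpm response, dB-scale slopes), or
#' `"movement"` (GPS movement slope).
#'
#' @param n_participants,n_days Cohort dimensions.
#' @param scenario Response-generating model; see Details.
#' @param sound_log_period Sound log cadence (s).
#' @param hr_log_period_mean,hr_log_period_sd Mean/SD (s) of the jittered
#'   heart-rate logging interval (defaults 456/168, i.e. 7.6 and 2.8 min).
#' @param population_hr_mean,population_hr_sd Population heart rate (bpm).
#' @param fixed_effects Named bpm-per-1-s.d. slopes for `spl`, `sml`, `snr`.
#' @param soundscape_effects Named bpm offsets vs Quiet for `Speech`,
#'   `SpeechInNoise`, `Noise`.
#' @param interaction_effects List with `class_offsets` (Speech, Noisy) and
#'   `slope_offsets`, a 2x3 matrix (rows Speech, Noisy; cols spl, sml, snr).
#' @param log_effects Natural-log-scale slopes per dB for the log-HR
#'   scenario.
#' @param movement_effect bpm per m/s.
#' @param random_sd Named SDs (bpm): `participant`, `slope` (per-predictor
#'   random slopes), `weekday`, `hour`.
#' @param ar1_phi Lag-1 residual autocorrelation within participant-day.
#' @param residual_sd Marginal SD (bpm) of the stationary AR(1) residual.
#' @param class_acoustic_params List with `means`, `sds` (4x3 matrices,
#'   rows Quiet/Speech/SpeechInNoise/Noise) and a 3x3 `corr`.
#' @param diurnal_occupancy 24x4 per-hour class probability matrix.
#' @param dwell_redraw Per-minute probability that the soundscape Markov
#'   chain redraws its class from the hourly distribution (controls dwell
#'   times; stationary occupancy is unaffected).
#' @param sessions_per_day,session_hours_mean Wearable wear-session model:
#'   number of sessions per day and mean session duration (h).
#' @param night_fraction Target share of sound logs emitted between 00:00
#'   and 06:00 (exercises the daytime filter).
#' @param with_gps Generate GPS tracks (default TRUE only for the movement
#'   scenario).
#' @param mobility_params GPS bout/speed parameters; see
#'   `default_mobility_params`.
#' @param start_date Date of day 1 (local time; timestamps carry no zone).
#' @param seed Integer master seed; all randomness derives from it.
#' @return A classed config list.
#' @export
generator_config <- function(n_participants = 56,
                             n_days = 14,
                             scenario = c("acoustic", "soundscape",
                                          "interaction", "log_acoustic",
                                          "movement"),
                             sound_log_period = 60,
                             hr_log_period_mean = 456,
                             hr_log_period_sd = 168,
                             population_hr_mean = 75.60,
                             population_hr_sd = 6.89,
                             fixed_effects = c(spl = 1.47, sml = 0.72,
                                               snr = -1.03),
                             soundscape_effects = c(Speech = 1.07,
                                                    SpeechInNoise = 2.23,
                                                    Noise = 2.61),
                             interaction_effects = list(
                               class_offsets = c(Speech = 1.07, Noisy = 2.40),
                               slope_offsets = rbind(
                                 Speech = c(spl = 0.16, sml = -0.74, snr = 0.00),
                                 Noisy = c(spl = -0.60, sml = -1.08, snr = 0.79))),
                             log_effects = c(spl = log1p(0.154 / 100),
                                             sml = log1p(0.112 / 100),
                                             snr = log1p(-0.169 / 100)),
                             movement_effect = 0.39,
                             random_sd = c(participant = 4.0, slope = 0.5,
                                           weekday = 1.0, hour = 1.5),
                             ar1_phi = 0.5,
                             residual_sd = 4.5,
                             class_acoustic_params = default_class_acoustics(),
                             diurnal_occupancy = default_diurnal_occupancy(),
                             dwell_redraw = 0.2,
                             sessions_per_day = 3,
                             session_hours_mean = 1.4,
                             night_fraction = 0.05,
                             with_gps = NULL,
                             mobility_params = default_mobility_params(),
                             start_date = as.Date("2019-06-03"),
                             seed = 1L) {
  scenario <- match.arg(scenario)
  if (is.null(with_gps)) with_gps <- scenario == "movement"
  cfg <- list(n_participants = n_participants, n_days = n_days,
              scenario = scenario, sound_log_period = sound_log_period,
              hr_log_period_mean = hr_log_period_mean,
              hr_log_period_sd = hr_log_period_sd,
              population_hr_mean = population_hr_mean,
              population_hr_sd = population_hr_sd,
              fixed_effects = fixed_effects,
              soundscape_effects = soundscape_effects,
              interaction_effects = interaction_effects,
              log_effects = log_effects,
              movement_effect = movement_effect,
              random_sd = random_sd, ar1_phi = ar1_phi,
              residual_sd = residual_sd,
              class_acoustic_params = class_acoustic_params,
              diurnal_occupancy = diurnal_occupancy,
              dwell_redraw = dwell_redraw,
              sessions_per_day = sessions_per_day,
              session_hours_mean = session_hours_mean,
              night_fraction = night_fraction,
              with_gps = with_gps, mobility_params = mobility_params,
              start_date = start_date, seed = as.integer(seed))
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  if (cfg$n_participants < 1) stop_field("n_participants", "must be >= 1")
  if (cfg$n_days < 1) stop_field("n_days", "must be >= 1")
  if (cfg$sound_log_period <= 0) stop_field("sound_log_period", "must be > 0")
  if (cfg$hr_log_period_mean <= 0) stop_field("hr_log_period_mean", "must be > 0")
  if (cfg$hr_log_period_sd < 0) stop_field("hr_log_period_sd", "must be >= 0")
  if (any(cfg$random_sd < 0)) stop_field("random_sd", "SDs must be >= 0")
  if (cfg$residual_sd < 0) stop_field("residual_sd", "must be >= 0")
  if (abs(cfg$ar1_phi) >= 1) stop_field("ar1_phi", "must satisfy |phi| < 1")
  occ <- cfg$diurnal_occupancy
  if (!is.matrix(occ) || nrow(occ) != 24 || ncol(occ) != 4)
    stop_field("diurnal_occupancy", "must be a 24 x 4 matrix")
  if (any(occ < 0) || any(abs(rowSums(occ) - 1) > 1e-9))
    stop_field("diurnal_occupancy", "rows must be probabilities summing to 1")
  if (cfg$dwell_redraw <= 0 || cfg$dwell_redraw > 1)
    stop_field("dwell_redraw", "must be in (0, 1]")
  if (cfg$night_fraction < 0 || cfg$night_fraction >= 1)
    stop_field("night_fraction", "must be in [0, 1)")
  invisible(cfg)
}

#' Sample a per-minute soundscape sequence with hourly occupancy
#'
#' First-order Markov chain: each minute, with probability `dwell_redraw`
#' the class is redrawn from the current hour's occupancy distribution,
#' otherwise the previous class persists. The stationary per-hour occupancy
#' equals the supplied probabilities; `dwell_redraw` only controls dwell
#' times (mean dwell approximately `1 / (dwell_redraw * (1 - p_class))`).
#'
#' @param hour_probabilities 24 x 4 matrix of per-hour class probabilities
#'   (rows hours 0-23, columns Quiet/Speech/SpeechInNoise/Noise).
#' @param hours Integer vector, the hour-of-day (0-23) of each minute in
#'   the sequence.
#' @param dwell_redraw Per-minute redraw probability in (0, 1].
#' @param seed Integer seed (optional; when `NULL` the current RNG state is
#'   used).
#' @param new_block Logical vector marking minutes that start an
#'   independent block (e.g. a new participant-day); defaults to the first
#'   minute only. Block starts always redraw.
#' @return Character vector of classes, one per minute.
#' @export
sample_soundscape_sequence <- function(hour_probabilities, hours,
                                       dwell_redraw = 0.2, seed = NULL,
                                       new_block = NULL) {
  if (any(hour_probabilities < 0) ||
      any(abs(rowSums(hour_probabilities) - 1) > 1e-9))
    stop("hour probabilities must be non-negative and sum to 1 per hour",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- length(hours)
  if (is.null(new_block)) new_block <- c(TRUE, rep(FALSE, n - 1))
  cum <- t(apply(hour_probabilities, 1, cumsum))
  u <- stats::runif(n)
  # inverse-CDF draw of the candidate class for every minute
  row <- hours + 1L
  cand <- 1L + (u > cum[cbind(row, 1L)]) + (u > cum[cbind(row, 2L)]) +
    (u > cum[cbind(row, 3L)])
  redraw <- stats::runif(n) < dwell_redraw
  redraw[new_block] <- TRUE
  # index of the most recent redraw carries the class forward
  src <- cummax(ifelse(redraw, seq_len(n), 0L))
  SOUNDSCAPES[cand[src]]
}

#' Synthesize a level-envelope time series for a soundscape class
#'
#' Produces a broadband level series in dB emulating what the acoustic
#' estimator chain would see: Quiet is a low noise floor; Noise a high
#' unmodulated floor; Speech a syllabic-rate (default 2--4 Hz) duty-cycled
#' burst modulation between a floor and a peak level; Speech-in-Noise the
#' energy sum of a burst-modulated speech component and a high noise floor
#' (which compresses the visible modulation). No audio waveform is
#' synthesized.
#'
#' @param class One of `"Quiet"`, `"Speech"`, `"SpeechInNoise"`, `"Noise"`.
#' @param duration_s Duration in seconds (> 0).
#' @param sample_rate Samples per second (default 100; must resolve the
#'   30 ms tracker release, so >= 20).
#' @param params Optional per-class parameter list with fields `floor_db`,
#'   `peak_db`, `depth_db` (burst-to-gap level drop), `mod_rate_range`
#'   (syllabic rate, Hz), `duty` (burst duty cycle), `noise_sd`; defaults
#'   are calibrated so the estimator chain reproduces the class geometry.
#' @param seed Optional integer seed.
#' @return Numeric vector of instantaneous level (dB).
#' @export
synthesize_level_envelope <- function(class, duration_s, sample_rate = 100,
                                      params = NULL, seed = NULL) {
  if (!class %in% SOUNDSCAPES) stop("unknown class: ", class, call. = FALSE)
  if (duration_s <= 0) stop_field("duration_s", "must be > 0")
  if (sample_rate < 20) stop_field("sample_rate", "must be >= 20 Hz")
  if (!is.null(seed)) set.seed(seed)
  defaults <- list(
    Quiet = list(floor_db = 48.8, peak_db = NULL, depth_db = 0,
                 mod_rate_range = c(2, 8), duty = 0.55, noise_sd = 1.0),
    Speech = list(floor_db = 48, peak_db = 72, depth_db = 24,
                  mod_rate_range = c(2, 4), duty = 0.55, noise_sd = 0.5),
    SpeechInNoise = list(floor_db = 60, peak_db = 77, depth_db = 30,
                         mod_rate_range = c(2, 4), duty = 0.65, noise_sd = 0.8),
    Noise = list(floor_db = 66, peak_db = NULL, depth_db = 0,
                 mod_rate_range = c(2, 8), duty = 0.55, noise_sd = 1.5)
  )
  p <- utils::modifyList(defaults[[class]], params %||% list())
  n <- ceiling(duration_s * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  noise <- stats::rnorm(n, 0, p$noise_sd)
  if (p$depth_db == 0 || is.null(p$peak_db)) {
    return(p$floor_db + noise)
  }
  f <- stats::runif(1, p$mod_rate_range[1], p$mod_rate_range[2])
  phase <- stats::runif(1, 0, 1)
  # syllabic bursts: on at the peak level for `duty` of each cycle
  m <- as.numeric(((t * f + phase) %% 1) < p$duty)
  speech_db <- p$peak_db - p$depth_db * (1 - m)
  if (class == "SpeechInNoise") {
    # energy sum of the modulated component and the noise floor
    lev <- 10 * log10(10^(p$floor_db / 10) + 10^(speech_db / 10))
  } else {
    lev <- pmax(speech_db, p$floor_db)
  }
  lev + noise
}

#' Generate a GPS track with stationary and moving bouts
#'
#' 60-s positions from a two-state (stationary/moving) bout process.
#' Stationary minutes move at Rayleigh-distributed GPS-jitter speeds;
#' moving minutes at lognormal walking speeds; a configurable fraction of
#' minutes moves at vehicle speed (> 10 m/s) so the downstream speed filter
#' has work to do. Displacement direction follows a random-walk heading.
#'
#' @param time_s Fix times in seconds (typically 60 s apart).
#' @param mobility_params See `default_mobility_params`.
#' @param seed Optional integer seed.
#' @return Tibble with `time_s`, `latitude`, `longitude` and the true
#'   per-step `speed` (m/s; speed of the step ending at each fix, NA for
#'   the first).
#' @export
generate_gps_track <- function(time_s, mobility_params = default_mobility_params(),
                               seed = NULL) {
  mp <- utils::modifyList(default_mobility_params(), mobility_params %||% list())
  if (mp$stationary_sigma < 0) stop_field("stationary_sigma", "must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- length(time_s)
  dt <- diff(time_s)
  # two-state bout chain over steps
  moving <- logical(max(n - 1, 0))
  if (n > 1) {
    state <- stats::runif(1) < mp$p_start_move / (mp$p_start_move + mp$p_stop_move)
    u <- stats::runif(n - 1)
    for (i in seq_len(n - 1)) {
      state <- if (state) u[i] > mp$p_stop_move else u[i] < mp$p_start_move
      moving[i] <- state
    }
  }
  speed <- numeric(n - 1)
  n_mov <- sum(moving)
  # Rayleigh jitter for stationary minutes, lognormal walking speed otherwise
  speed[!moving] <- mp$stationary_sigma * sqrt(-2 * log(stats::runif(n - 1 - n_mov)))
  speed[moving] <- stats::rlnorm(n_mov, mp$speed_meanlog, mp$speed_sdlog)
  fast <- stats::runif(n - 1) < mp$fast_fraction
  speed[fast] <- stats::runif(sum(fast), 11, 25)
  heading <- cumsum(stats::rnorm(n - 1, 0, 0.6)) + stats::runif(1, 0, 2 * pi)
  dist <- speed * dt
  m_per_deg <- pi * 6371000 / 180
  lat <- mp$start_lat + cumsum(c(0, dist * cos(heading) / m_per_deg))
  lon <- mp$start_lon + cumsum(c(0, dist * sin(heading) /
                                   (m_per_deg * cos(mp$start_lat * pi / 180))))
  tibble::tibble(time_s = time_s, latitude = lat, longitude = lon,
                 speed = c(NA_real_, speed))
}

# -- cohort simulation -------------------------------------------------------

# Correlated class-conditional draws of (spl, sml, snr) for a vector of
# classes; one row per minute.
draw_class_acoustics <- function(classes, cap) {
  n <- length(classes)
  z <- matrix(stats::rnorm(3 * n), n, 3)
  L <- chol(cap$corr) # upper triangular; z %*% L has correlation corr
  zc <- z %*% L
  idx <- match(classes, SOUNDSCAPES)
  out <- cap$means[idx, , drop = FALSE] + zc * cap$sds[idx, , drop = FALSE]
  dimnames(out) <- NULL
  out
}

# Stationary AR(1) series with marginal SD sigma: first draw at the
# stationary distribution, then x[i] = phi x[i-1] + innovation.
ar1_series <- function(n, phi, sigma) {
  if (n == 0) return(numeric(0))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sigma)
  if (n > 1) {
    innov <- stats::rnorm(n - 1, 0, sigma * sqrt(1 - phi^2))
    for (i in 2:n) x[i] <- phi * x[i - 1] + innov[i - 1]
  }
  x
}

#' Simulate a synthetic cohort of sound, heart-rate and GPS logs
#'
#' Generates, per participant-day: a per-minute soundscape sequence with
#' hourly occupancy, class-conditional correlated (SPL, SML, SNR) draws at
#' the sound-log cadence covering 06:00-24:00 (plus a small night-time
#' fraction), wear sessions during which heart-rate logs are emitted at a
#' jittered cadence, and (optionally) GPS fixes. Heart rate is the
#' scenario's linear predictor on window-averaged acoustics plus sampled
#' participant / participant-weekday / participant-hour random effects and
#' a stationary AR(1) residual within each participant-day. Deterministic
#' given the config seed; participant streams are split by stable hashing
#' so results do not depend on iteration order.
#'
#' @param config A [generator_config()].
#' @return List with tibbles `sound` (`participant_id`, `timestamp`, `spl`,
#'   `sml`, `snr`, `soundscape`), `hr` (`participant_id`, `timestamp`,
#'   `hr`), `gps` (or `NULL`), and `truth`: per-record ground truth
#'   (sampled random effects, realized linear predictor, window acoustics,
#'   standardization constants) plus the generating config.
#' @export
simulate_cohort <- function(config = generator_config()) {
  validate_generator_config(config)
  cfg <- config
  day_minutes <- (6 * 60):(24 * 60 - 1) # minute-of-day indices, daytime
  night_minutes <- 0:(6 * 60 - 1)
  # emission probability for night minutes so they form ~night_fraction of logs
  p_night <- if (cfg$night_fraction > 0) {
    cfg$night_fraction * length(day_minutes) /
      ((1 - cfg$night_fraction) * length(night_minutes))
  } else 0

  sound_list <- vector("list", cfg$n_participants)
  hr_list <- vector("list", cfg$n_participants)
  gps_list <- vector("list", cfg$n_participants)
  truth_list <- vector("list", cfg$n_participants)

  for (p in seq_len(cfg$n_participants)) {
    set.seed(substream_seed(cfg$seed, paste0("participant", p)))
    pid <- sprintf("P%03d", p)

    # participant-level random effects
    re_participant <- stats::rnorm(1, 0, cfg$random_sd[["participant"]])
    re_slopes <- stats::rnorm(3, 0, cfg$random_sd[["slope"]])
    names(re_slopes) <- c("spl", "sml", "snr")
    re_weekday <- stats::rnorm(7, 0, cfg$random_sd[["weekday"]])
    re_hour <- stats::rnorm(24, 0, cfg$random_sd[["hour"]])
    # class-wise random slope offsets reuse the continuous ones only for
    # continuous scenarios; soundscape scenario carries intercepts only

    # ---- sound logs over all days ----
    keep_night <- stats::runif(cfg$n_days * length(night_minutes)) < p_night
    per_day <- lapply(seq_len(cfg$n_days), function(d) {
      nm <- night_minutes[keep_night[((d - 1) * length(night_minutes) + 1):
                                       (d * length(night_minutes))]]
      mins <- c(nm, day_minutes)
      tibble::tibble(day = d, minute = mins)
    })
    sm <- dplyr::bind_rows(per_day)
    sm$hour <- sm$minute %/% 60
    sm$new_block <- c(TRUE, diff(sm$day) != 0 | diff(sm$minute) != 1)
    cls <- sample_soundscape_sequence(cfg$diurnal_occupancy, sm$hour,
                                      dwell_redraw = cfg$dwell_redraw,
                                      new_block = sm$new_block)
    ac <- draw_class_acoustics(cls, cfg$class_acoustic_params)
    sm$time_s <- (sm$day - 1) * 86400 + sm$minute * 60
    sound <- tibble::tibble(participant_id = pid, time_s = sm$time_s,
                            spl = ac[, 1], sml = ac[, 2], snr = ac[, 3],
                            soundscape = cls)
    sound_list[[p]] <- sound

    # ---- wear sessions and HR log times ----
    hr_times <- list()
    for (d in seq_len(cfg$n_days)) {
      n_sess <- cfg$sessions_per_day
      dur_h <- stats::rgamma(n_sess, shape = 6,
                             rate = 6 / cfg$session_hours_mean)
      start_h <- sort(stats::runif(n_sess, 5.5, 23))
      for (s in seq_len(n_sess)) {
        t0 <- (d - 1) * 86400 + start_h[s] * 3600
        t1 <- min(t0 + dur_h[s] * 3600, (d - 1) * 86400 + 86399)
        gaps <- pmax(stats::rnorm(200, cfg$hr_log_period_mean,
                                  cfg$hr_log_period_sd), 120)
        tt <- t0 + cumsum(gaps)
        hr_times[[length(hr_times) + 1]] <- tt[tt <= t1]
      }
    }
    hr_t <- sort(unique(round(unlist(hr_times))))
    if (!length(hr_t)) next

    # ---- window acoustics for each HR log (same rule as the aligner) ----
    win <- window_stats(sound$time_s, as.matrix(sound[, c("spl", "sml", "snr")]),
                        sound$soundscape, hr_t, window = 300)

    # ---- GPS and movement ----
    movement <- rep(0, length(hr_t))
    if (cfg$with_gps) {
      gps_day <- lapply(seq_len(cfg$n_days), function(d) {
        ts <- (d - 1) * 86400 + day_minutes * 60
        g <- generate_gps_track(ts, cfg$mobility_params)
        g$participant_id <- pid
        g
      })
      gps <- dplyr::bind_rows(gps_day)
      mv <- window_mean(gps$time_s[-1][!is.na(gps$speed[-1])] ,
                        gps$speed[-1][!is.na(gps$speed[-1])], hr_t, 300)
      movement <- ifelse(is.na(mv), 0, mv)
      gps_list[[p]] <- gps
    }

    # ---- linear predictor by scenario ----
    day_of <- floor(hr_t / 86400) + 1
    wd <- as.integer(format(cfg$start_date + (day_of - 1), "%u")) # 1..7
    hod <- (hr_t %% 86400) %/% 3600
    re_wd <- re_weekday[wd]
    re_hr <- re_hour[hod + 1]

    truth <- tibble::tibble(participant_id = pid, time_s = hr_t,
                            day = day_of, weekday = wd, hour = hod,
                            n_window_logs = win$n,
                            spl = win$means[, 1], sml = win$means[, 2],
                            snr = win$means[, 3], soundscape = win$modal,
                            movement = movement,
                            re_participant = re_participant,
                            re_weekday = re_wd, re_hour = re_hr)
    truth$re_slope_spl <- re_slopes[["spl"]]
    truth$re_slope_sml <- re_slopes[["sml"]]
    truth$re_slope_snr <- re_slopes[["snr"]]
    truth_list[[p]] <- truth
    hr_list[[p]] <- tibble::tibble(participant_id = pid, time_s = hr_t)
  }

  sound <- dplyr::bind_rows(sound_list)
  hr <- dplyr::bind_rows(hr_list)
  truth <- dplyr::bind_rows(truth_list)
  gps <- if (cfg$with_gps) dplyr::bind_rows(gps_list) else NULL

  # ---- pooled standardization of window acoustics (cohort-level) ----
  ok <- truth$n_window_logs > 0
  scaling <- list(
    mean = c(spl = mean(truth$spl[ok]), sml = mean(truth$sml[ok]),
             snr = mean(truth$snr[ok])),
    sd = c(spl = stats::sd(truth$spl[ok]), sml = stats::sd(truth$sml[ok]),
           snr = stats::sd(truth$snr[ok]))
  )
  z <- sapply(c("spl", "sml", "snr"), function(v) {
    out <- (truth[[v]] - scaling$mean[[v]]) / scaling$sd[[v]]
    ifelse(ok, out, 0) # no sound logs in window: predictor at pooled mean
  })

  lp <- rep(cfg$population_hr_mean, nrow(truth))
  sc <- cfg$scenario
  # records with no sound log in the window (never aligned downstream)
  # carry the reference class and mean-level predictors
  cls_gen <- ifelse(is.na(truth$soundscape), "Quiet", truth$soundscape)
  if (sc == "acoustic") {
    for (v in c("spl", "sml", "snr"))
      lp <- lp + (cfg$fixed_effects[[v]] + truth[[paste0("re_slope_", v)]]) *
        z[, v]
  } else if (sc == "soundscape") {
    off <- c(Quiet = 0, cfg$soundscape_effects)
    lp <- lp + unname(off[cls_gen])
  } else if (sc == "interaction") {
    cls3 <- ifelse(cls_gen == "Quiet", "Quiet",
                   ifelse(cls_gen == "Speech", "Speech", "Noisy"))
    off <- c(Quiet = 0, cfg$interaction_effects$class_offsets)
    lp <- lp + off[cls3]
    so <- rbind(Quiet = c(spl = 0, sml = 0, snr = 0),
                cfg$interaction_effects$slope_offsets)
    for (v in c("spl", "sml", "snr"))
      lp <- lp + (cfg$fixed_effects[[v]] + so[cls3, v] +
                    truth[[paste0("re_slope_", v)]]) * z[, v]
    truth$soundscape3 <- cls3
  } else if (sc == "movement") {
    lp <- lp + cfg$movement_effect * truth$movement
  } else if (sc == "log_acoustic") {
    lp <- rep(log(cfg$population_hr_mean), nrow(truth))
    for (v in c("spl", "sml", "snr"))
      lp <- lp + cfg$log_effects[[v]] *
        ifelse(ok, truth[[v]] - scaling$mean[[v]], 0)
  }

  # random effects + AR(1) residual (log scale for log_acoustic)
  scale_div <- if (sc == "log_acoustic") cfg$population_hr_mean else 1
  lp <- lp + (truth$re_participant + truth$re_weekday + truth$re_hour) /
    scale_div

  resid <- numeric(nrow(truth))
  key <- paste(truth$participant_id, truth$day)
  for (k in unique(key)) {
    idx <- which(key == k)
    set.seed(substream_seed(cfg$seed, paste0("resid", k)))
    resid[idx] <- ar1_series(length(idx), cfg$ar1_phi,
                             cfg$residual_sd / scale_div)
  }
  truth$linpred <- lp
  truth$resid <- resid
  hr_val <- lp + resid
  if (sc == "log_acoustic") hr_val <- exp(hr_val)
  hr$hr <- hr_val

  # timestamps
  t0 <- as.POSIXct(paste(cfg$start_date, "00:00:00"), tz = "UTC")
  sound$timestamp <- t0 + sound$time_s
  hr$timestamp <- t0 + hr$time_s
  if (!is.null(gps)) gps$timestamp <- t0 + gps$time_s
  truth$timestamp <- t0 + truth$time_s

  list(sound = sound[, c("participant_id", "timestamp", "spl", "sml", "snr",
                         "soundscape")],
       hr = hr[, c("participant_id", "timestamp", "hr")],
       gps = if (!is.null(gps))
         gps[, c("participant_id", "timestamp", "latitude", "longitude")],
       truth = list(records = truth, scaling = scaling, config = cfg))
}

# Windowed statistics of sound logs for HR times: arithmetic means of the
# value columns and modal class over the half-open window (t - window, t].
# Shared between the generator and the aligner so both apply one rule.
window_stats <- function(stimes, svals, sclass, htimes, window = 300) {
  o <- order(stimes)
  stimes <- stimes[o]; svals <- svals[o, , drop = FALSE]; sclass <- sclass[o]
  lo <- findInterval(htimes - window, stimes) # counts <= t - window
  hi <- findInterval(htimes, stimes)         # counts <= t
  n <- hi - lo
  cs <- apply(svals, 2, function(v) cumsum(c(0, v)))
  means <- (cs[hi + 1, , drop = FALSE] - cs[lo + 1, , drop = FALSE]) / n
  cls_ind <- sapply(SOUNDSCAPES, function(cc) cumsum(c(0, sclass == cc)))
  counts <- cls_ind[hi + 1, , drop = FALSE] - cls_ind[lo + 1, , drop = FALSE]
  modal <- rep(NA_character_, length(htimes))
  nz <- n > 0
  if (any(nz))
    modal[nz] <- SOUNDSCAPES[max.col(counts[nz, , drop = FALSE],
                                     ties.method = "last")]
  list(means = means, n = n, modal = modal)
}

# Windowed mean of a single value series (used for movement speeds).
window_mean <- function(times, values, htimes, window = 300) {
  o <- order(times)
  times <- times[o]; values <- values[o]
  lo <- findInterval(htimes - window, times)
  hi <- findInterval(htimes, times)
  n <- hi - lo
  cs <- cumsum(c(0, values))
  out <- (cs[hi + 1] - cs[lo + 1]) / n
  out[n == 0] <- NA_real_
  out
}
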