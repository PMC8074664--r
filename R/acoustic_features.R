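# Envelope-domain acoustic estimators: one-pole SPL smoother, asymmetric
# top/bottom (peak/valley) trackers, SML/SNR derivation, threshold soundscape
# classifier, and 60-s aggregation into sound logs. All operations act on
# broadband level series in dB; there is no spectral analysis.

#' Tracker time constants for the top/bottom envelope followers
#'
#' The bottom tracker is a valley detector: it drops quickly (fast release,
#' 30 ms default) when the level falls below its state and recovers slowly
#' (slow attack, default 3 s within the plausible 1--5 s range). The top
#' tracker mirrors this (fast 30 ms attack upward, slow 3 s fall).
#'
#' @param spl_tau Time constant (s) of the one-pole SPL smoother. Default 0.063.
#' @param bottom_rise_tau,bottom_fall_tau Bottom-tracker rise/fall constants (s).
#' @param top_rise_tau,top_fall_tau Top-tracker rise/fall constants (s).
#' @return A classed list of time constants.
#' @export
tracker_config <- function(spl_tau = 0.063,
                           bottom_rise_tau = 3.0, bottom_fall_tau = 0.030,
                           top_rise_tau = 0.030, top_fall_tau = 3.0) {
  taus <- c(spl_tau = spl_tau, bottom_rise_tau = bottom_rise_tau,
            bottom_fall_tau = bottom_fall_tau, top_rise_tau = top_rise_tau,
            top_fall_tau = top_fall_tau)
  for (nm in names(taus)) {
    if (!is.finite(taus[[nm]]) || taus[[nm]] <= 0) stop_field(nm, "must be > 0")
  }
  if (bottom_fall_tau >= bottom_rise_tau)
    stop_field("bottom_fall_tau", "bottom tracker must fall faster than it rises")
  if (top_rise_tau >= top_fall_tau)
    stop_field("top_rise_tau", "top tracker must rise faster than it falls")
  structure(as.list(taus), class = "tracker_config")
}

#' Soundscape classifier thresholds
#'
#' Documented stand-in decision rules for the in-device proprietary
#' classifier: a frame is Quiet below an SPL ceiling; otherwise Speech when
#' both SNR and SML are high; otherwise Speech-in-Noise at intermediate
#' SNR/SML; otherwise Noise.
#'
#' @param quiet_spl_max SPL (dB) below which a frame is Quiet. Default 52.
#' @param speech_snr_min,speech_sml_min SNR/SML floors (dB) for Speech.
#' @param sin_snr_min,sin_sml_min SNR/SML floors (dB) for Speech-in-Noise.
#' @return A classed list of thresholds.
#' @export
classifier_thresholds <- function(quiet_spl_max = 52,
                                  speech_snr_min = 8, speech_sml_min = 15,
                                  sin_snr_min = 4, sin_sml_min = 10) {
  if (sin_snr_min >= speech_snr_min)
    stop_field("sin_snr_min", "must be below speech_snr_min")
  if (sin_sml_min >= speech_sml_min)
    stop_field("sin_sml_min", "must be below speech_sml_min")
  structure(list(quiet_spl_max = quiet_spl_max,
                 speech_snr_min = speech_snr_min, speech_sml_min = speech_sml_min,
                 sin_snr_min = sin_snr_min, sin_sml_min = sin_sml_min),
            class = "classifier_thresholds")
}

# One-pole recursion y[n] = y[n-1] + alpha * (x[n] - y[n-1]) with possibly
# regime-dependent alpha, initialized at x[1]. Implemented as a plain loop:
# the asymmetric trackers are order-dependent and cannot be expressed as a
# linear filter.
one_pole_asym <- function(x, alpha_up, alpha_down) {
  n <- length(x)
  y <- numeric(n)
  y[1] <- x[1]
  for (i in 2:n) {
    a <- if (x[i] >= y[i - 1]) alpha_up else alpha_down
    y[i] <- y[i - 1] + a * (x[i] - y[i - 1])
  }
  y
}

#' Smooth an instantaneous level series into SPL
#'
#' Low-pass one-pole (infinite impulse response) smoother
#' `y[n] = y[n-1] + alpha * (x[n] - y[n-1])` with
#' `alpha = 1 - exp(-dt / tau)`, initialized at the first sample.
#'
#' @param level_db Numeric vector, instantaneous level in dB.
#' @param sample_rate Samples per second (> 0).
#' @param spl_tau Time constant in seconds (default 63 ms).
#' @return Numeric vector of smoothed SPL, same length as input.
#' @export
estimate_spl <- function(level_db, sample_rate, spl_tau = 0.063) {
  if (!length(level_db)) stop("empty level series", call. = FALSE)
  if (!is.finite(sample_rate) || sample_rate <= 0)
    stop_field("sample_rate", "must be > 0")
  if (any(!is.finite(level_db))) stop_field("level_db", "must be finite")
  alpha <- 1 - exp(-1 / (sample_rate * spl_tau))
  # linear symmetric recursion: stats::filter with init = x[1] gives
  # y[1] = (1-a) x[1] + a x[1] = x[1], i.e. initialization at the first sample
  as.numeric(stats::filter(alpha * level_db, 1 - alpha, method = "recursive",
                           init = level_db[1]))
}

#' Track envelope extrema with asymmetric attack/release followers
#'
#' Runs a top (peak) and a bottom (valley) follower over a smoothed SPL
#' series. Both are one-pole recursions whose coefficient depends on the
#' direction of change: the bottom tracker falls with `bottom_fall_tau`
#' (fast) and rises with `bottom_rise_tau` (slow); the top tracker rises
#' with `top_rise_tau` (fast) and falls with `top_fall_tau` (slow). Both are
#' initialized at the first SPL sample, so pointwise `top >= bottom`.
#'
#' @param spl_db Smoothed SPL series (dB).
#' @param sample_rate Samples per second.
#' @param config A [tracker_config()].
#' @return A list with numeric vectors `top` and `bottom`.
#' @export
track_extrema <- function(spl_db, sample_rate, config = tracker_config()) {
  stopifnot(inherits(config, "tracker_config"))
  if (length(spl_db) < 1) stop("empty SPL series", call. = FALSE)
  a <- function(tau) 1 - exp(-1 / (sample_rate * tau))
  bottom <- one_pole_asym(spl_db, alpha_up = a(config$bottom_rise_tau),
                          alpha_down = a(config$bottom_fall_tau))
  top <- one_pole_asym(spl_db, alpha_up = a(config$top_rise_tau),
                       alpha_down = a(config$top_fall_tau))
  list(top = top, bottom = bottom)
}

#' Derive SML and SNR from SPL and tracker series
#'
#' SML (sound modulation level) is the top minus the bottom tracker, a
#' measure of envelope modulation depth, non-negative by construction. SNR
#' is the immediate SPL minus the bottom (noise-floor) tracker, signed so
#' that signal above the floor is positive.
#'
#' @param spl_db,top_db,bottom_db Aligned numeric series (dB).
#' @return A list with numeric vectors `sml` and `snr`.
#' @export
derive_sml_snr <- function(spl_db, top_db, bottom_db) {
  n <- length(spl_db)
  if (length(top_db) != n || length(bottom_db) != n)
    stop("spl, top and bottom series must have equal length", call. = FALSE)
  list(sml = top_db - bottom_db, snr = spl_db - bottom_db)
}

#' Classify a frame into a soundscape
#'
#' Decision list: Quiet if `spl < quiet_spl_max`; else Speech if
#' `snr >= speech_snr_min` and `sml >= speech_sml_min`; else Speech-in-Noise
#' if `snr >= sin_snr_min` and `sml >= sin_sml_min`; else Noise.
#' Vectorized and total on finite inputs.
#'
#' @param spl,sml,snr Numeric vectors (recycled to common length) in dB.
#' @param thresholds A [classifier_thresholds()].
#' @return Character vector of classes
#'   (`"Quiet"`, `"Speech"`, `"SpeechInNoise"`, `"Noise"`).
#' @export
classify_soundscape <- function(spl, sml, snr,
                                thresholds = classifier_thresholds()) {
  stopifnot(inherits(thresholds, "classifier_thresholds"))
  n <- max(length(spl), length(sml), length(snr))
  spl <- rep_len(spl, n); sml <- rep_len(sml, n); snr <- rep_len(snr, n)
  if (any(!is.finite(c(spl, sml, snr)))) stop("non-finite inputs", call. = FALSE)
  out <- rep("Noise", n)
  out[snr >= thresholds$sin_snr_min & sml >= thresholds$sin_sml_min] <- "SpeechInNoise"
  out[snr >= thresholds$speech_snr_min & sml >= thresholds$speech_sml_min] <- "Speech"
  out[spl < thresholds$quiet_spl_max] <- "Quiet"
  out
}

#' Aggregate per-sample acoustic frames into periodic sound logs
#'
#' One record per full period: arithmetic mean of SPL/SML/SNR over the
#' period and the modal soundscape class (ties broken toward the more
#' complex class, in the order Quiet < Speech < SpeechInNoise < Noise).
#' Periods containing no frames produce no record.
#'
#' @param time_s Sample times in seconds (monotone non-decreasing).
#' @param spl,sml,snr Aligned numeric series (dB).
#' @param soundscape Character vector of per-sample classes.
#' @param period Logging period in seconds (default 60).
#' @return A tibble with `time_s` (period start), `spl`, `sml`, `snr`,
#'   `soundscape`, `n_frames`.
#' @export
log_sound <- function(time_s, spl, sml, snr, soundscape, period = 60) {
  n <- length(time_s)
  stopifnot(length(spl) == n, length(sml) == n, length(snr) == n,
            length(soundscape) == n)
  # each frame covers one sample interval; n frames span n * dt seconds
  dt <- if (n > 1) stats::median(diff(sort(time_s))) else 0
  if (diff(range(time_s)) + dt < period)
    stop("frames must span at least one logging period", call. = FALSE)
  bin <- floor(time_s / period)
  cls <- soundscape_factor(soundscape)
  agg <- function(v) as.numeric(tapply(v, bin, mean))
  counts <- table(bin, cls) # rows ordered by bin
  # ties.method = "last" with columns in complexity order resolves ties
  # toward the more complex class
  modal <- SOUNDSCAPES[max.col(as.matrix(counts), ties.method = "last")]
  tibble::tibble(
    time_s = as.numeric(names(table(bin))) * period,
    spl = agg(spl), sml = agg(sml), snr = agg(snr),
    soundscape = modal,
    n_frames = as.integer(table(bin))
  )
}

#' Full estimator chain from an instantaneous level series to sound logs
#'
#' Convenience wrapper: smooth to SPL, run the trackers, derive SML/SNR,
#' classify each sample, and aggregate to periodic logs.
#'
#' @param level_db Instantaneous level in dB.
#' @param sample_rate Samples per second.
#' @param config A [tracker_config()].
#' @param thresholds A [classifier_thresholds()].
#' @param period Logging period (s).
#' @return As [log_sound()].
#' @export
acoustic_pipeline <- function(level_db, sample_rate,
                              config = tracker_config(),
                              thresholds = classifier_thresholds(),
                              period = 60) {
  spl <- estimate_spl(level_db, sample_rate, config$spl_tau)
  tr <- track_extrema(spl, sample_rate, config)
  ds <- derive_sml_snr(spl, tr$top, tr$bottom)
  cls <- classify_soundscape(spl, ds$sml, ds$snr, thresholds)
  time_s <- (seq_along(level_db) - 1) / sample_rate
  log_sound(time_s, spl, ds$sml, ds$snr, cls, period = period)
}
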