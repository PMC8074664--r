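# Preprocessing and filtration of log tables: daytime filter, HR-sound
# window alignment, pooled percentile and minimum-record filters, effective
# sampling frequency, and GPS movement estimation. The pipeline order is
# fixed: daytime filter -> alignment -> percentile filter -> participant
# filter. Every stage is pure and accounts for what it drops.

#' Preprocessing configuration
#'
#' @param day_start,day_end Valid clock hours; records in
#'   `[day_start, day_end)` are kept (defaults 6 and 24).
#' @param window Alignment window in seconds (default 300); for each HR log
#'   at time t, sound logs in the half-open window `(t - window, t]` are
#'   averaged.
#' @param min_window_logs Minimum sound logs required in a window for a
#'   record to be emitted (default 3 of the 5 expected at 60 s cadence,
#'   i.e. at least 60 percent window coverage).
#' @param hr_lower_percentile,hr_upper_percentile Pooled heart-rate
#'   percentile bounds (defaults 5 and 95); records strictly outside are
#'   removed.
#' @param min_records_per_participant Participants with fewer aligned
#'   records are dropped entirely (default 50).
#' @param max_speed Movement exclusion threshold in m/s applied to the
#'   window-averaged movement (default 10, cycling speed).
#' @param earth_radius Sphere radius for the haversine distance (m).
#' @return A classed config list.
#' @export
preprocess_config <- function(day_start = 6, day_end = 24, window = 300,
                              min_window_logs = 3,
                              hr_lower_percentile = 5,
                              hr_upper_percentile = 95,
                              min_records_per_participant = 50,
                              max_speed = 10, earth_radius = 6371000) {
  if (window <= 0) stop_field("window", "must be > 0")
  if (!(hr_lower_percentile >= 0 && hr_lower_percentile < hr_upper_percentile &&
        hr_upper_percentile <= 100))
    stop_field("hr_percentiles", "need 0 <= lower < upper <= 100")
  structure(list(day_start = day_start, day_end = day_end, window = window,
                 min_window_logs = min_window_logs,
                 hr_lower_percentile = hr_lower_percentile,
                 hr_upper_percentile = hr_upper_percentile,
                 min_records_per_participant = min_records_per_participant,
                 max_speed = max_speed, earth_radius = earth_radius),
            class = "preprocess_config")
}

parse_timestamps <- function(ts) {
  if (inherits(ts, "POSIXct")) return(ts)
  out <- as.POSIXct(strptime(ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  alt <- is.na(out)
  if (any(alt))
    out[alt] <- as.POSIXct(strptime(ts[alt], "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  bad <- which(is.na(out))
  if (length(bad))
    stop("unparseable timestamp at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  out
}

ts_seconds_of_day <- function(ts) {
  as.numeric(ts) %% 86400
}

#' Keep only daytime log records
#'
#' Retains records whose local clock time falls in
#' `[day_start:00, day_end:00)`; with the defaults a log at 05:59:59 is
#' dropped and one at exactly 06:00:00 is kept. Order is preserved.
#'
#' @param logs Tibble with a `timestamp` column (POSIXct or ISO-8601 text).
#' @param config A [preprocess_config()].
#' @return The filtered tibble.
#' @export
filter_daytime <- function(logs, config = preprocess_config()) {
  if (!nrow(logs)) return(logs)
  ts <- parse_timestamps(logs$timestamp)
  sod <- ts_seconds_of_day(ts)
  keep <- sod >= config$day_start * 3600 & sod < config$day_end * 3600
  logs[keep, , drop = FALSE]
}

#' Align heart-rate logs with window-averaged sound logs
#'
#' For each HR log at time t, gathers that participant's sound logs in the
#' half-open window `(t - window, t]`. When at least `min_window_logs` are
#' present, emits a data record with the arithmetic dB mean of SPL/SML/SNR
#' and the modal soundscape class (ties toward the more complex class);
#' otherwise the HR log is skipped and counted.
#'
#' @param hr_logs Tibble `participant_id`, `timestamp`, `hr`.
#' @param sound_logs Tibble `participant_id`, `timestamp`, `spl`, `sml`,
#'   `snr`, `soundscape`.
#' @param config A [preprocess_config()].
#' @return Tibble of data records (`participant_id`, `timestamp`, `hr`,
#'   `spl`, `sml`, `snr`, `soundscape`, `weekday`, `hour`,
#'   `n_window_logs`) with attribute `n_skipped` (HR logs without enough
#'   window coverage).
#' @export
align_records <- function(hr_logs, sound_logs, config = preprocess_config()) {
  hr_ts <- parse_timestamps(hr_logs$timestamp)
  sd_ts <- parse_timestamps(sound_logs$timestamp)
  out <- vector("list", length(unique(hr_logs$participant_id)))
  skipped <- 0L
  for (i in seq_along(pids <- unique(hr_logs$participant_id))) {
    pid <- pids[i]
    hsel <- hr_logs$participant_id == pid
    ssel <- sound_logs$participant_id == pid
    ht <- as.numeric(hr_ts[hsel])
    st <- as.numeric(sd_ts[ssel])
    ws <- window_stats(st, as.matrix(sound_logs[ssel, c("spl", "sml", "snr")]),
                       sound_logs$soundscape[ssel], ht, window = config$window)
    ok <- ws$n >= config$min_window_logs
    skipped <- skipped + sum(!ok)
    if (!any(ok)) next
    ts_ok <- hr_ts[hsel][ok]
    out[[i]] <- tibble::tibble(
      participant_id = pid,
      timestamp = ts_ok,
      hr = hr_logs$hr[hsel][ok],
      spl = as.numeric(ws$means[ok, 1]), sml = as.numeric(ws$means[ok, 2]),
      snr = as.numeric(ws$means[ok, 3]),
      soundscape = ws$modal[ok],
      weekday = as.integer(format(ts_ok, "%u")),
      hour = as.integer(format(ts_ok, "%H")),
      n_window_logs = ws$n[ok]
    )
  }
  res <- dplyr::bind_rows(out)
  attr(res, "n_skipped") <- skipped
  res
}

#' Exclude records with extreme pooled heart rates
#'
#' Computes the lower/upper percentiles (linear-interpolation quantiles) of
#' heart rate pooled over all participants and removes records strictly
#' below the lower or strictly above the upper percentile.
#'
#' @param records Data records with an `hr` column.
#' @param config A [preprocess_config()].
#' @return Filtered records; attributes `hr_bounds` and `n_removed`.
#' @export
filter_hr_percentiles <- function(records, config = preprocess_config()) {
  if (!nrow(records)) stop("no records to filter", call. = FALSE)
  if (nrow(records) < 20)
    warning("fewer than 20 records; percentile bounds are degenerate")
  bounds <- quantile_li(records$hr, c(config$hr_lower_percentile,
                                      config$hr_upper_percentile) / 100)
  keep <- records$hr >= bounds[1] & records$hr <= bounds[2]
  out <- records[keep, , drop = FALSE]
  attr(out, "hr_bounds") <- bounds
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Drop participants with too few records
#'
#' Removes all records of participants contributing fewer than
#' `min_records_per_participant` aligned records (boundary kept: exactly 50
#' records survives with the default).
#'
#' @param records Data records with `participant_id`.
#' @param config A [preprocess_config()].
#' @return Filtered records; attribute `n_participants_dropped`.
#' @export
filter_min_records <- function(records, config = preprocess_config()) {
  counts <- table(records$participant_id)
  keep_ids <- names(counts)[counts >= config$min_records_per_participant]
  out <- records[records$participant_id %in% keep_ids, , drop = FALSE]
  attr(out, "n_participants_dropped") <- sum(counts < config$min_records_per_participant)
  out
}

#' Effective sampling frequency of data records
#'
#' Average number of data records per participant-day-hour, summarized as
#' per-hour means and SDs across participant-days plus a grand mean:
#' the representativeness of sampling across the day.
#'
#' @param records Data records with `participant_id`, `timestamp`, `hour`.
#' @return List with `per_hour` (tibble `hour`, `mean`, `sd`) and `grand`
#'   (list `mean`, `sd`, computed over all participant-day-hour cells with
#'   at least one record).
#' @export
effective_sampling_frequency <- function(records) {
  ts <- parse_timestamps(records$timestamp)
  date <- format(ts, "%Y-%m-%d")
  hour <- if ("hour" %in% names(records)) records$hour
          else as.integer(format(ts, "%H"))
  cell <- paste(records$participant_id, date, hour)
  counts <- as.data.frame(table(cell), stringsAsFactors = FALSE)
  hr_of_cell <- as.integer(sub(".* ", "", counts$cell))
  per_hour <- tibble::tibble(
    hour = sort(unique(hr_of_cell)),
    mean = as.numeric(tapply(counts$Freq, hr_of_cell, mean)),
    sd = as.numeric(tapply(counts$Freq, hr_of_cell, stats::sd))
  )
  list(per_hour = per_hour,
       grand = list(mean = mean(counts$Freq), sd = stats::sd(counts$Freq)))
}

#' Haversine great-circle distance
#'
#' `d = 2 r arcsin( sqrt( sin^2((lat2-lat1)/2) +
#' cos(lat1) cos(lat2) sin^2((lon2-lon1)/2) ) )` with coordinates in
#' degrees. Symmetric, non-negative, bounded by `pi * r`.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in degrees (vectorized).
#' @param r Sphere radius in metres (default 6 371 000).
#' @return Distance(s) in metres.
#' @export
haversine_distance <- function(lat1, lon1, lat2, lon2, r = 6371000) {
  if (any(abs(c(lat1, lat2)) > 90)) stop_field("latitude", "|lat| <= 90")
  if (any(abs(c(lon1, lon2)) > 180)) stop_field("longitude", "|lon| <= 180")
  to_rad <- pi / 180
  p1 <- lat1 * to_rad; p2 <- lat2 * to_rad
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(p1) * cos(p2) * sin(dlon)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Window-averaged movement speed per data record
#'
#' Per-step speed is the haversine distance between consecutive GPS fixes
#' divided by their time difference (steps with non-positive time
#' difference are skipped and counted). Each record's movement is the mean
#' of step speeds ending in the half-open window `(t - window, t]`; records
#' whose *averaged* movement exceeds `max_speed` are excluded (a single
#' fast step does not by itself exclude a record). Decile labels (1-10)
#' are assigned from the pooled retained movement values.
#'
#' @param records Aligned data records (`participant_id`, `timestamp`).
#' @param gps_logs Tibble `participant_id`, `timestamp`, `latitude`,
#'   `longitude`.
#' @param config A [preprocess_config()].
#' @return Records with `movement` and `movement_decile` columns; rows
#'   without any GPS step in the window get `NA` movement and are kept;
#'   attribute `n_excluded_speed` counts rows removed by the speed filter,
#'   `n_skipped_steps` counts non-positive-interval GPS steps.
#' @export
movement_speed <- function(records, gps_logs, config = preprocess_config()) {
  g_ts <- parse_timestamps(gps_logs$timestamp)
  r_ts <- parse_timestamps(records$timestamp)
  movement <- rep(NA_real_, nrow(records))
  skipped_steps <- 0L
  for (pid in unique(records$participant_id)) {
    gsel <- which(gps_logs$participant_id == pid)
    rsel <- which(records$participant_id == pid)
    if (length(gsel) < 2) next
    o <- gsel[order(g_ts[gsel])]
    tt <- as.numeric(g_ts[o])
    dt <- diff(tt)
    d <- haversine_distance(gps_logs$latitude[o][-length(o)],
                            gps_logs$longitude[o][-length(o)],
                            gps_logs$latitude[o][-1],
                            gps_logs$longitude[o][-1],
                            r = config$earth_radius)
    okstep <- dt > 0
    skipped_steps <- skipped_steps + sum(!okstep)
    sp <- d[okstep] / dt[okstep]
    st <- tt[-1][okstep] # step assigned to its end time
    movement[rsel] <- window_mean(st, sp, as.numeric(r_ts[rsel]),
                                  config$window)
  }
  keep <- is.na(movement) | movement <= config$max_speed
  out <- records[keep, , drop = FALSE]
  out$movement <- movement[keep]
  mv <- out$movement[!is.na(out$movement)]
  out$movement_decile <- NA_integer_
  if (length(mv) >= 10) {
    out$movement_decile[!is.na(out$movement)] <- decile_bin(mv)
  }
  attr(out, "n_excluded_speed") <- sum(!keep)
  attr(out, "n_skipped_steps") <- skipped_steps
  out
}

#' Run the full preprocessing pipeline with a filtration report
#'
#' Fixed stage order: daytime filter (HR and sound logs) -> window
#' alignment -> pooled HR percentile filter -> minimum-records participant
#' filter -> (optional) movement estimation and speed filter. Counts in
#' equal counts out plus counts dropped at every stage.
#'
#' @param hr_logs,sound_logs,gps_logs Input log tibbles (`gps_logs`
#'   optional).
#' @param config A [preprocess_config()].
#' @return List `records` (final data records) and `report` (per-stage
#'   counts).
#' @export
preprocess_pipeline <- function(hr_logs, sound_logs, gps_logs = NULL,
                                config = preprocess_config()) {
  report <- list()
  hr_day <- filter_daytime(hr_logs, config)
  sound_day <- filter_daytime(sound_logs, config)
  report$daytime <- list(hr_in = nrow(hr_logs), hr_out = nrow(hr_day),
                         sound_in = nrow(sound_logs),
                         sound_out = nrow(sound_day))
  rec <- align_records(hr_day, sound_day, config)
  report$alignment <- list(hr_in = nrow(hr_day), records = nrow(rec),
                           skipped = attr(rec, "n_skipped"))
  rec2 <- filter_hr_percentiles(rec, config)
  report$hr_percentile <- list(records_in = nrow(rec),
                               records_out = nrow(rec2),
                               removed = attr(rec2, "n_removed"),
                               bounds = as.numeric(attr(rec2, "hr_bounds")))
  rec3 <- filter_min_records(rec2, config)
  report$min_records <- list(
    records_in = nrow(rec2), records_out = nrow(rec3),
    participants_dropped = attr(rec3, "n_participants_dropped"),
    participants_kept = length(unique(rec3$participant_id)))
  if (!is.null(gps_logs)) {
    rec4 <- movement_speed(rec3, filter_daytime(gps_logs, config), config)
    report$movement <- list(records_in = nrow(rec3),
                            records_out = nrow(rec4),
                            excluded_speed = attr(rec4, "n_excluded_speed"))
    rec3 <- rec4
  }
  list(records = rec3, report = report)
}
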