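# Filtration and alignment rules on hand-built toy fixtures, plus the
# haversine and movement arithmetic.

ts0 <- function(s) as.POSIXct("2019-06-03 00:00:00", tz = "UTC") + s

test_that("daytime filter keeps [06:00, 24:00) with the stated boundaries", {
  # 05:59:59 dropped, 06:00:00 kept
  logs <- tibble::tibble(
    participant_id = "P1",
    timestamp = ts0(c(6 * 3600 - 1, 6 * 3600, 23 * 3600 + 3599)),
    hr = c(70, 71, 72))
  out <- filter_daytime(logs)
  expect_equal(out$hr, c(71, 72))
  # empty input passes through
  expect_equal(nrow(filter_daytime(logs[0, ])), 0)
  # toy set of 10 logs with 3 at night -> 7 kept
  expect_equal(nrow(filter_daytime(toy_hr_logs)), 7)
  # unparseable timestamps are rejected with a row index
  bad <- tibble::tibble(participant_id = "P1",
                        timestamp = c("2019-06-03T10:00:00", "not a time"),
                        hr = c(70, 71))
  expect_error(filter_daytime(bad), "row")
})

test_that("alignment averages the half-open 5-min window and applies the log minimum", {
  t <- 10 * 3600 # HR log at 10:00:00
  sound <- tibble::tibble(
    participant_id = "P1",
    timestamp = ts0(t - c(300, 240, 180, 120, 60, 0)),
    spl = c(99, 50, 51, 52, 53, 54), # 99 sits exactly at t-300: excluded
    sml = c(99, 10, 11, 12, 13, 14),
    snr = c(99, 1, 2, 3, 4, 5),
    soundscape = c("Noise", "Quiet", "Quiet", "Speech", "Speech", "Speech"))
  hr <- tibble::tibble(participant_id = "P1", timestamp = ts0(t), hr = 70)
  rec <- align_records(hr, sound)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$spl, 52)       # mean of 50..54; the t-300 log is excluded
  expect_equal(rec$n_window_logs, 5L)
  expect_equal(rec$soundscape, "Speech")
  # plain majority wins when there is no tie
  sound2 <- sound[-1, ]
  sound2$soundscape <- c("Quiet", "Quiet", "Noise", "Noise", "Quiet")
  rec2 <- align_records(hr, sound2)
  expect_equal(rec2$soundscape, "Quiet")
  # only 2 logs in the window with min_window_logs = 3 -> skipped
  rec3 <- align_records(hr, sound[5:6, ])
  expect_equal(nrow(rec3), 0)
  expect_equal(attr(rec3, "n_skipped"), 1L)
})

test_that("modal class of a window counts correctly", {
  t <- 12 * 3600
  sound <- tibble::tibble(
    participant_id = "P1", timestamp = ts0(t - c(240, 180, 120, 60)),
    spl = 60, sml = 10, snr = 5,
    soundscape = c("Quiet", "Quiet", "Speech", "Speech"))
  hr <- tibble::tibble(participant_id = "P1", timestamp = ts0(t), hr = 70)
  rec <- align_records(hr, sound)
  expect_equal(rec$soundscape, "Speech") # 2-2 tie -> more complex
  sound$soundscape <- c("Quiet", "Quiet", "Quiet", "Noise")
  expect_equal(align_records(hr, sound)$soundscape, "Quiet")
})

test_that("pooled percentile filter removes the strict tails", {
  # 100 distinct values -> 90 survive under linear-interpolation quantiles
  rec <- tibble::tibble(participant_id = "P1", hr = sample(1:100))
  out <- filter_hr_percentiles(rec)
  expect_equal(nrow(out), 90)
  expect_equal(sort(out$hr), 6:95)
  # identical values: nothing removed
  same <- tibble::tibble(participant_id = "P1", hr = rep(70, 50))
  expect_equal(nrow(filter_hr_percentiles(same)), 50)
  expect_error(filter_hr_percentiles(same[0, ]), "no records")
  expect_warning(filter_hr_percentiles(same[1:5, ]), "fewer than 20")
})

test_that("participant minimum-record filter keeps the boundary", {
  rec <- tibble::tibble(
    participant_id = rep(c("A", "B", "C"), c(60, 50, 10)),
    hr = 70)
  out <- filter_min_records(rec)
  expect_equal(nrow(out), 110)
  expect_equal(sort(unique(out$participant_id)), c("A", "B"))
  expect_equal(attr(out, "n_participants_dropped"), 1L)
  # 49 records -> dropped entirely
  rec49 <- tibble::tibble(participant_id = "Z", hr = rep(70, 49))
  expect_equal(nrow(filter_min_records(rec49)), 0)
})

test_that("effective sampling frequency counts records per participant-day-hour", {
  # one record per hour for 2 participants x 2 days x hours 6..23
  grid <- expand.grid(p = c("A", "B"), d = 0:1, h = 6:23)
  rec <- tibble::tibble(
    participant_id = grid$p,
    timestamp = ts0(grid$d * 86400 + grid$h * 3600),
    hour = grid$h)
  esf <- effective_sampling_frequency(rec)
  expect_equal(esf$grand$mean, 1)
  expect_equal(esf$grand$sd, 0)
  # doubling hour 19 makes it the peak
  rec2 <- dplyr::bind_rows(rec, rec[rec$hour == 19, ])
  esf2 <- effective_sampling_frequency(rec2)
  expect_equal(esf2$per_hour$hour[which.max(esf2$per_hour$mean)], 19)
})

test_that("haversine distance matches its closed forms", {
  expect_equal(haversine_distance(12, 55, 12, 55), 0)
  r <- 6371000
  expect_equal(haversine_distance(0, 0, 0, 180), pi * r)
  expect_equal(haversine_distance(0, 0, 90, 0), pi * r / 2)
  # symmetry
  expect_equal(haversine_distance(10, 20, 30, 40),
               haversine_distance(30, 40, 10, 20))
  expect_error(haversine_distance(95, 0, 0, 0), "latitude")
})

test_that("movement speed averages the window and filters on the average", {
  # steps of 120 m per 60 s -> 2.0 m/s
  m_per_deg <- pi * 6371000 / 180
  lat <- 55 + (0:10) * 120 / m_per_deg
  gps <- tibble::tibble(participant_id = "P1",
                        timestamp = ts0(10 * 3600 + (0:10) * 60),
                        latitude = lat, longitude = 12)
  rec <- tibble::tibble(participant_id = "P1",
                        timestamp = ts0(10 * 3600 + 600), hr = 70)
  out <- movement_speed(rec, gps)
  expect_equal(out$movement, 2, tolerance = 1e-6)
  # stationary track -> movement 0 and the lowest decile given pooled labels
  gps0 <- gps; gps0$latitude <- 55
  expect_equal(movement_speed(rec, gps0)$movement, 0)
  # a single 11 m/s step inside an otherwise slow window does not by itself
  # exclude the record: the window mean decides
  lat2 <- 55 + cumsum(c(0, rep(6, 6), 660, rep(6, 3))) / m_per_deg
  gps2 <- gps; gps2$latitude <- lat2
  out2 <- movement_speed(rec, gps2)
  expect_equal(nrow(out2), 1) # kept: the 11 m/s step is averaged down
  expect_equal(out2$movement, mean(c(0.1, 11, 0.1, 0.1, 0.1)),
               tolerance = 1e-6)
  # but a window-mean above 10 m/s is excluded
  lat3 <- 55 + cumsum(c(0, rep(660, 10))) / m_per_deg
  gps3 <- gps; gps3$latitude <- lat3
  out3 <- movement_speed(rec, gps3)
  expect_equal(nrow(out3), 0)
  expect_equal(attr(out3, "n_excluded_speed"), 1L)
})

test_that("the pipeline conserves counts stage by stage", {
  pp <- preprocess_pipeline(small_cohort$hr, small_cohort$sound,
                            config = preprocess_config(
                              min_records_per_participant = 10))
  rep <- pp$report
  expect_equal(rep$alignment$hr_in,
               rep$alignment$records + rep$alignment$skipped)
  expect_equal(rep$hr_percentile$records_in,
               rep$hr_percentile$records_out + rep$hr_percentile$removed)
  expect_equal(rep$min_records$records_in - rep$min_records$records_out >= 0,
               TRUE)
  expect_equal(nrow(pp$records), rep$min_records$records_out)
  # filters are pure: rerunning gives identical output
  pp2 <- preprocess_pipeline(small_cohort$hr, small_cohort$sound,
                             config = preprocess_config(
                               min_records_per_participant = 10))
  expect_identical(pp$records, pp2$records)
})
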