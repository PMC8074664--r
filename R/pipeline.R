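# Orchestration and IO: CSV log schemas, YAML/JSON pipeline configuration,
# schema validation, and the end-to-end run (simulate/ingest -> preprocess
# -> fit -> describe) with a reproducible manifest.

LOG_SCHEMAS <- list(
  sound = list(columns = c("participant_id", "timestamp", "spl", "sml",
                           "snr", "soundscape"),
               numeric = c("spl", "sml", "snr")),
  hr = list(columns = c("participant_id", "timestamp", "hr"),
            numeric = "hr", positive = "hr"),
  gps = list(columns = c("participant_id", "timestamp", "latitude",
                         "longitude"),
             numeric = c("latitude", "longitude"))
)

fmt_ts <- function(ts) format(ts, "%Y-%m-%dT%H:%M:%S")

#' Write cohort log tables as CSV (ISO-8601 timestamps)
#'
#' @param cohort A [simulate_cohort()] result (or a list with compatible
#'   `sound` / `hr` / `gps` tibbles and optional `truth`).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (nm in c("sound", "hr", "gps")) {
    tb <- cohort[[nm]]
    if (is.null(tb)) next
    tb$timestamp <- fmt_ts(tb$timestamp)
    path <- file.path(dir, paste0(nm, "_logs.csv"))
    utils::write.csv(tb, path, row.names = FALSE)
    paths <- c(paths, path)
  }
  if (!is.null(cohort$truth)) {
    tr <- cohort$truth
    tr$records$timestamp <- fmt_ts(tr$records$timestamp)
    tr$config$start_date <- as.character(tr$config$start_date)
    path <- file.path(dir, "truth.json")
    jsonlite::write_json(list(records = tr$records, scaling = tr$scaling,
                              config = unclass(tr$config)),
                         path, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a log CSV
#'
#' @param path CSV file path.
#' @param kind `"sound"`, `"hr"` or `"gps"`.
#' @return Tibble with parsed POSIXct timestamps.
#' @export
read_logs <- function(path, kind = c("sound", "hr", "gps")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(LOG_SCHEMAS[[kind]]$columns, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df$timestamp <- parse_timestamps(df$timestamp)
  tibble::as_tibble(df)
}

#' Validate a log file against its schema
#'
#' Checks column presence, numeric types, timestamp parseability and
#' per-participant monotonicity, and value ranges (positive heart rate,
#' latitude/longitude bounds).
#'
#' @param path CSV file path.
#' @param kind `"sound"`, `"hr"` or `"gps"`.
#' @return List `ok` (logical), `errors`, `warnings` (character vectors
#'   with row-level diagnostics).
#' @export
validate_logs <- function(path, kind = c("sound", "hr", "gps")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  errors <- character(); warnings <- character()
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  schema <- LOG_SCHEMAS[[kind]]
  missing_cols <- setdiff(schema$columns, names(df))
  if (length(missing_cols)) {
    errors <- c(errors, paste("missing column(s):",
                              paste(missing_cols, collapse = ", ")))
    return(list(ok = FALSE, errors = errors, warnings = warnings))
  }
  ts <- suppressWarnings(as.POSIXct(df$timestamp, tz = "UTC",
                                    tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                                   "%Y-%m-%d %H:%M:%S")))
  bad <- which(is.na(ts))
  if (length(bad))
    errors <- c(errors, paste("unparseable timestamp at row(s):",
                              paste(utils::head(bad, 5), collapse = ", ")))
  for (cn in schema$numeric) {
    nn <- which(!is.finite(suppressWarnings(as.numeric(df[[cn]]))))
    if (length(nn))
      errors <- c(errors, paste0("non-numeric '", cn, "' at row(s): ",
                                 paste(utils::head(nn, 5), collapse = ", ")))
  }
  for (cn in schema$positive %||% character()) {
    neg <- which(suppressWarnings(as.numeric(df[[cn]])) <= 0)
    if (length(neg))
      errors <- c(errors, paste0("non-positive '", cn, "' at row(s): ",
                                 paste(utils::head(neg, 5), collapse = ", ")))
  }
  if (kind == "gps" && !length(errors)) {
    out_lat <- which(abs(df$latitude) > 90)
    out_lon <- which(abs(df$longitude) > 180)
    if (length(out_lat))
      errors <- c(errors, paste("latitude out of range at row(s):",
                                paste(utils::head(out_lat, 5), collapse = ", ")))
    if (length(out_lon))
      errors <- c(errors, paste("longitude out of range at row(s):",
                                paste(utils::head(out_lon, 5), collapse = ", ")))
  }
  if (!length(errors)) {
    for (pid in unique(df$participant_id)) {
      tt <- ts[df$participant_id == pid]
      if (is.unsorted(tt))
        warnings <- c(warnings,
                      paste0("timestamps not monotone for participant ", pid))
    }
  }
  if (kind == "sound" && !length(errors)) {
    bad_cls <- which(!df$soundscape %in% SOUNDSCAPES)
    if (length(bad_cls))
      errors <- c(errors, paste("unknown soundscape at row(s):",
                                paste(utils::head(bad_cls, 5), collapse = ", ")))
  }
  list(ok = !length(errors), errors = errors, warnings = warnings)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file may override any [generator_config()] or [preprocess_config()]
#' field under top-level keys `generator` and `preprocess`, select `models`
#' to fit, and set `seed` and `output_dir`.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return List with `generator`, `preprocess`, `models`, `seed`,
#'   `output_dir`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  seed <- raw$seed %||% 1L
  gen_args <- raw$generator %||% list()
  if (is.null(gen_args$seed)) gen_args$seed <- substream_seed(seed, "simulate")
  list(generator = do.call(generator_config, gen_args),
       preprocess = do.call(preprocess_config, raw$preprocess %||% list()),
       models = raw$models %||% c("acoustic", "soundscape"),
       seed = seed,
       output_dir = raw$output_dir %||% "results")
}

#' Run the full pipeline and write a manifest
#'
#' Simulates a cohort (or ingests CSV logs), preprocesses with the full
#' filtration chain, fits the requested mixed models, computes the
#' descriptive summaries, writes every artifact under `output_dir`, and
#' returns a manifest of stages, record counts, seeds and a config hash.
#'
#' @param config A list as returned by [read_pipeline_config()], or a path
#'   to a YAML/JSON config file.
#' @param logs Optional list with `sound`, `hr` (and `gps`) tibbles to use
#'   instead of simulating.
#' @return The manifest (list), invisibly written as JSON too.
#' @export
run_pipeline <- function(config, logs = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed,
                   config_hash = substream_seed(
                     0, paste(deparse(config$generator), collapse = "")),
                   stages = list())
  if (is.null(logs)) {
    cohort <- simulate_cohort(config$generator)
    write_cohort(cohort, file.path(config$output_dir, "logs"))
    logs <- cohort
    manifest$stages$simulate <- list(
      sound_logs = nrow(cohort$sound), hr_logs = nrow(cohort$hr),
      gps_logs = if (is.null(cohort$gps)) 0 else nrow(cohort$gps))
  }
  pp <- preprocess_pipeline(logs$hr, logs$sound, logs$gps, config$preprocess)
  rec_path <- file.path(config$output_dir, "data_records.csv")
  rec_out <- pp$records
  rec_out$timestamp <- fmt_ts(rec_out$timestamp)
  utils::write.csv(rec_out, rec_path, row.names = FALSE)
  jsonlite::write_json(pp$report,
                       file.path(config$output_dir, "filtration_report.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$stages$preprocess <- list(records = nrow(pp$records),
                                     report = pp$report)

  fits <- list()
  for (m in config$models) {
    sp <- model_spec(model = m)
    fit <- fit_lme_ar1(build_design(pp$records, sp))
    fits[[m]] <- list(
      beta = as.list(fit$beta),
      ci = apply(fit$ci, 1, as.list),
      varcomp = as.list(fit$varcomp), phi = fit$phi,
      loglik = fit$loglik, n_obs = fit$n_obs)
  }
  jsonlite::write_json(fits, file.path(config$output_dir, "model_fits.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$stages$fit <- list(models = config$models)

  hs <- hourly_summaries(logs$sound)
  utils::write.csv(hs$occupancy,
                   file.path(config$output_dir, "hourly_occupancy.csv"),
                   row.names = FALSE)
  utils::write.csv(hs$quartiles,
                   file.path(config$output_dir, "hourly_quartiles.csv"),
                   row.names = FALSE)
  manifest$stages$describe <- list(hours = nrow(hs$occupancy))

  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}
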