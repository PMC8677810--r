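# CSV readers/writers for the package's external interfaces, a trajectory
# exporter and a run manifest.  All files are plain UTF-8 CSV with period
# decimal separators; numeric round trips hold to better than 1e-9.

read_typed_csv <- function(path, required, optional = character(0),
                           what = "file") {
  if (!file.exists(path)) stop(what, " not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss) > 0) {
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) {
    warning(what, " contains a header but no records", call. = FALSE)
    return(df)
  }
  for (col in intersect(c(required, optional), names(df))) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed) & !is.na(v) & v != "")
      if (length(bad) > 0) {
        stop(what, ": non-numeric value '", v[bad[1]], "' in column '", col,
             "', row ", bad[1], call. = FALSE)
      }
      df[[col]] <- parsed
    }
  }
  df
}

#' Read or write an hourly sensor log
#'
#' Schema: `timestamp_h,do_in_mg_l,do_out_mg_l,flow_m3_h,biomass_kg`,
#' with the optional biofilter-outlet channel `do_bf_out_mg_l` (written
#' by [generate_sensor_log()]).  Malformed cells are reported with row
#' and column, not skipped.
#'
#' @param path CSV path.
#' @return For the reader, a `sensor_log` data frame; the writer returns
#'   `path` invisibly.
#' @export
read_sensor_log <- function(path) {
  df <- read_typed_csv(path,
                       required = c("timestamp_h", "do_in_mg_l", "do_out_mg_l",
                                    "flow_m3_h", "biomass_kg"),
                       optional = "do_bf_out_mg_l",
                       what = "sensor log")
  class(df) <- c("sensor_log", "data.frame")
  df
}

#' @rdname read_sensor_log
#' @param log a `sensor_log` data frame.
#' @export
write_sensor_log <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a weighing log
#'
#' Schema: `day,weight_g` (one row per weighing, day 0 allowed).
#'
#' @param path CSV path.
#' @return For the reader, a `weighing_log` data frame; the writer
#'   returns `path` invisibly.
#' @export
read_weighing_log <- function(path) {
  df <- read_typed_csv(path, required = c("day", "weight_g"),
                       what = "weighing log")
  class(df) <- c("weighing_log", "data.frame")
  df
}

#' @rdname read_weighing_log
#' @param log a `weighing_log` data frame.
#' @export
write_weighing_log <- function(log, path) {
  utils::write.csv(as.data.frame(log), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a daily environment schedule from CSV
#'
#' Schema: `day,temperature_c,do_mg_l,nh3_mg_l,photoperiod_h`.
#'
#' @param path CSV path.
#' @return Data frame usable as the `env` argument of [run_simulation()].
#' @export
read_schedule <- function(path) {
  read_typed_csv(path, required = c("day", "temperature_c", "do_mg_l",
                                    "nh3_mg_l", "photoperiod_h"),
                 what = "environment schedule")
}

#' Write a simulation trajectory to a directory
#'
#' Emits `growth.csv` (daily growth records, weights to 2 decimals),
#' `oxygen_hourly.csv` (hourly budget and DO trace, fluxes to 4 decimals)
#' and `summary.json`.
#'
#' @param trajectory a `ras_trajectory`.
#' @param dir output directory (created if missing).
#' @return Character vector of the files written, invisibly.
#' @export
write_trajectory <- function(trajectory, dir) {
  stopifnot(inherits(trajectory, "ras_trajectory"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)

  d <- trajectory$daily
  g <- data.frame(
    day = d$day,
    weight_g = sprintf("%.2f", d$weight_g),
    fgr_g_day = sprintf("%.4f", d$fgr_g_day),
    feeding_ratio_pct = sprintf("%.4f", d$feeding_ratio_pct),
    feed_kg_day = sprintf("%.4f", d$feed_kg_day),
    tau = sprintf("%.4f", d$tau), kappa = sprintf("%.4f", d$kappa),
    delta = sprintf("%.4f", d$delta), phi = sprintf("%.4f", d$phi)
  )
  f <- file.path(dir, "growth.csv")
  utils::write.csv(g, f, row.names = FALSE, quote = FALSE)
  files <- c(files, f)

  if (!is.null(trajectory$hourly)) {
    h <- trajectory$hourly
    o <- data.frame(
      time_h = h$time_h, day = h$day,
      do_fr = sprintf("%.4f", h$do_fr), do_n = sprintf("%.4f", h$do_n),
      do_b = sprintf("%.4f", h$do_b), do_pf = sprintf("%.4f", h$do_pf),
      do_sup = sprintf("%.4f", h$do_sup),
      do_conc = sprintf("%.4f", h$do_conc)
    )
    f <- file.path(dir, "oxygen_hourly.csv")
    utils::write.csv(o, f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }

  s <- summarize_trajectory(trajectory)
  f <- file.path(dir, "summary.json")
  jsonlite::write_json(
    list(preset = s$preset, days = s$days,
         weight = as.list(s$weight), oxygen = s$oxygen),
    f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, f)
  invisible(files)
}

#' Write a run manifest
#'
#' Records the command, parameter hash, preset, seed, package version,
#' collected warnings and output file list alongside a run's outputs, so
#' a run can be audited and reproduced.
#'
#' @param dir output directory.
#' @param command the subcommand or function that produced the outputs.
#' @param params the `ras_params` bundle used.
#' @param seed integer seed, or NULL for deterministic runs.
#' @param outputs character vector of files written.
#' @param warnings character vector of warnings emitted during the run.
#' @return Path of `manifest.json`, invisibly.
#' @export
write_manifest <- function(dir, command, params, seed = NULL,
                           outputs = character(0), warnings = character(0)) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  missing_out <- outputs[!file.exists(outputs)]
  if (length(missing_out) > 0) {
    stop("manifest lists output file(s) that do not exist: ",
         paste(missing_out, collapse = ", "), call. = FALSE)
  }
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(command = command,
         param_hash = param_hash(params),
         preset = attr(params, "preset") %||% "custom",
         seed = seed,
         package = "rasoxy",
         version = as.character(utils::packageVersion("rasoxy")),
         warnings = warnings,
         outputs = basename(outputs),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}
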