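#' Pair model and measured series by nearest time
#'
#' For each measured record, finds the nearest model time; pairs within
#' the tolerance are kept, the rest are dropped with their count recorded
#' in the `n_dropped` attribute.  Errors when the time ranges do not
#' overlap at all.
#'
#' @param model_time,model_value model series (equal length).
#' @param meas_time,meas_value measured series (equal length).
#' @param tolerance maximum |model - measured| time distance for a pair
#'   (same unit as the time vectors; use 0.5 h for hourly oxygen, 1 day
#'   for weighings).
#' @return Data frame with columns `time` (measured time), `predicted`,
#'   `measured`; attribute `n_dropped`.
#' @export
align_series <- function(model_time, model_value, meas_time, meas_value,
                         tolerance = 0.5) {
  stopifnot(length(model_time) == length(model_value),
            length(meas_time) == length(meas_value))
  if (min(meas_time) > max(model_time) || max(meas_time) < min(model_time)) {
    stop("model and measured series have no overlapping time coverage",
         call. = FALSE)
  }
  idx <- vapply(meas_time, function(t) which.min(abs(model_time - t)),
                integer(1))
  dist <- abs(model_time[idx] - meas_time)
  keep <- dist <= tolerance
  out <- data.frame(time = meas_time[keep],
                    predicted = model_value[idx[keep]],
                    measured = meas_value[keep])
  attr(out, "n_dropped") <- sum(!keep)
  if (nrow(out) == 0) {
    stop("no measured records within the pairing tolerance", call. = FALSE)
  }
  out
}

#' Parity regression of predicted on measured values
#'
#' Ordinary least squares of the predicted series on the measured series
#' (the predicted quantity is the response, matching the convention
#' \eqn{pred = slope \cdot meas + intercept} used when reporting model
#' validations), with the coefficient of determination of that fit and
#' the mean absolute relative error
#' \eqn{mean(|pred - meas| / |meas|) \cdot 100} percent.
#'
#' @param predicted,measured numeric series of equal length (>= 2); the
#'   measured series must not be constant.
#' @return An object of class `parity_fit`: list with `slope`,
#'   `intercept`, `slope_se`, `r_squared`, `mare_pct`, `n`, `pred_range`,
#'   `meas_range`.
#' @examples
#' f <- linear_parity_fit(1:10, 1:10)
#' c(f$slope, f$intercept, f$r_squared)  # 1 0 1
#' @export
linear_parity_fit <- function(predicted, measured) {
  stopifnot(length(predicted) == length(measured))
  if (length(measured) < 2) {
    stop("parity fit needs at least 2 pairs", call. = FALSE)
  }
  if (diff(range(measured)) == 0) {
    stop("measured series is constant; parity fit is degenerate", call. = FALSE)
  }
  fit <- stats::lm(predicted ~ measured)
  # summary.lm warns on exact fits; a perfect parity is a designed case
  # here (noise-free round trips), not a numerical accident
  sm <- suppressWarnings(summary(fit))
  mare <- mean(abs(predicted - measured) /
                 ifelse(measured == 0, NA, abs(measured)), na.rm = TRUE) * 100
  out <- list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    slope_se = unname(sm$coefficients[2, 2]),
    r_squared = sm$r.squared,
    mare_pct = mare,
    n = length(measured),
    pred_range = range(predicted),
    meas_range = range(measured)
  )
  class(out) <- "parity_fit"
  out
}

#' @export
print.parity_fit <- function(x, ...) {
  cat(sprintf("<parity_fit> pred = %.4f meas %+.4f  R2 = %.4f  MARE = %.3f%%  n = %d\n",
              x$slope, x$intercept, x$r_squared, x$mare_pct, x$n))
  invisible(x)
}

# Daily means of an hourly sensor log column; day d covers hours
# 24(d-1)+1 .. 24d (timestamps are end-of-hour indices as in the
# trajectory's time_h).
daily_mean_by <- function(timestamp_h, value) {
  day <- ceiling(timestamp_h / 24)
  agg <- tapply(value, day, mean)
  data.frame(day = as.integer(names(agg)), value = as.numeric(agg))
}

#' Validate a model trajectory against sensor and weighing logs
#'
#' Mirrors the model-vs-measurement comparison reported for the farm
#' system: a parity fit ([linear_parity_fit()]) per compared quantity
#' plus the min/max of each series.  Compared quantities:
#' \describe{
#'   \item{respiration}{mass-specific oxygen consumption, mg O2 kg-1 h-1;
#'     measured via [oxygen_consumption_from_sensors()] on the tank
#'     inlet/outlet pair, predicted from the budget's `do_fr` and
#'     stocking density.}
#'   \item{biofilter}{volumetric consumption across the biofilter passage
#'     (which includes nitrification in the filter bed), g O2 m-3 h-1;
#'     requires the `do_bf_out_mg_l` column, otherwise skipped with a
#'     note.}
#'   \item{total}{respiration converted to volumetric via the preset
#'     stocking density plus the biofilter passage, against the model's
#'     `do_fr + do_n + do_b`.}
#'   \item{fish_weight}{weighing-log individual weights against the model
#'     daily weights.}
#' }
#' Oxygen series are compared as daily means by default (`hourly = TRUE`
#' compares raw hourly values).
#'
#' @param trajectory a `ras_trajectory` with an hourly table.
#' @param sensor_log data frame as from [read_sensor_log()] /
#'   [generate_sensor_log()].
#' @param weighing_log data frame with columns `day`, `weight_g`, or NULL.
#' @param hourly compare hourly instead of daily-averaged oxygen series.
#' @return An object of class `ras_validation_report`: list with one
#'   `parity_fit` per quantity (`respiration`, `biofilter`, `total`,
#'   `fish_weight`) and a `notes` character vector (dropped pairs,
#'   truncated weighing coverage, skipped quantities).
#' @export
validation_report <- function(trajectory, sensor_log, weighing_log = NULL,
                              hourly = FALSE) {
  stopifnot(inherits(trajectory, "ras_trajectory"))
  h <- trajectory$hourly
  if (is.null(h)) stop("trajectory has no hourly table", call. = FALSE)
  need <- c("timestamp_h", "do_in_mg_l", "do_out_mg_l", "flow_m3_h",
            "biomass_kg")
  miss <- setdiff(need, names(sensor_log))
  if (length(miss) > 0) {
    stop("sensor log is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  notes <- character(0)
  V <- trajectory$meta$params$tank$volume

  # measured mass-specific respiration
  oc_meas <- suppressWarnings(oxygen_consumption_from_sensors(
    sensor_log$do_in_mg_l, sensor_log$do_out_mg_l,
    sensor_log$flow_m3_h, sensor_log$biomass_kg))
  pred_oc <- h$do_fr * 1000 / h$sd_kg_m3

  pair_oxy <- function(pred, meas_t, meas_v) {
    if (hourly) {
      align_series(h$time_h, pred, meas_t, meas_v, tolerance = 0.5)
    } else {
      pd <- daily_mean_by(h$time_h, pred)
      md <- daily_mean_by(meas_t, meas_v)
      align_series(pd$day, pd$value, md$day, md$value, tolerance = 0.5)
    }
  }

  pr <- pair_oxy(pred_oc, sensor_log$timestamp_h, oc_meas)
  report <- list(respiration = linear_parity_fit(pr$predicted, pr$measured))
  if (attr(pr, "n_dropped") > 0) {
    notes <- c(notes, paste0(attr(pr, "n_dropped"),
                             " unpaired respiration records dropped"))
  }

  if ("do_bf_out_mg_l" %in% names(sensor_log)) {
    bf_meas <- (sensor_log$do_out_mg_l - sensor_log$do_bf_out_mg_l) *
      sensor_log$flow_m3_h / V
    pb <- pair_oxy(h$do_n + h$do_b, sensor_log$timestamp_h, bf_meas)
    report$biofilter <- linear_parity_fit(pb$predicted, pb$measured)

    # total: measured respiration scaled to volumetric + biofilter passage
    sd_day <- h$sd_kg_m3[match(ceiling(sensor_log$timestamp_h / 24), h$day)]
    tot_meas <- oc_meas * sd_day / 1000 + bf_meas
    pt <- pair_oxy(h$do_fr + h$do_n + h$do_b, sensor_log$timestamp_h, tot_meas)
    report$total <- linear_parity_fit(pt$predicted, pt$measured)
  } else {
    notes <- c(notes,
               "sensor log has no do_bf_out_mg_l column; biofilter and total fits skipped")
  }

  if (!is.null(weighing_log)) {
    if (!all(c("day", "weight_g") %in% names(weighing_log))) {
      stop("weighing log must have columns day, weight_g", call. = FALSE)
    }
    d <- trajectory$daily
    pw <- align_series(d$day, d$weight_g, weighing_log$day,
                       weighing_log$weight_g, tolerance = 1)
    report$fish_weight <- linear_parity_fit(pw$predicted, pw$measured)
    if (max(weighing_log$day) < max(d$day)) {
      notes <- c(notes, paste0("weighing log covers only ",
                               max(weighing_log$day), " of ", max(d$day),
                               " simulated days (truncated coverage)"))
    }
  }

  report$notes <- notes
  class(report) <- "ras_validation_report"
  report
}

#' @export
print.ras_validation_report <- function(x, ...) {
  cat("<ras_validation_report>\n")
  for (nm in setdiff(names(x), "notes")) {
    cat(sprintf("  %-12s", nm))
    print(x[[nm]])
  }
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}
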