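#' Apply a named preset to a parameter bundle
#'
#' Two presets ship:
#' \describe{
#'   \item{`reproduction`}{fixed stocking density 100 kg m-3, pipe-flow
#'     volume basis 1 m3, temperature-factor low side using the printed
#'     upper half-width.  Under these settings the published volumetric
#'     oxygen figures (46.06 at 28 C and 3 g, supplemental demand pairs,
#'     the 12.01 series minimum) are reproduced.}
#'   \item{`physical`}{dynamic stocking density N W / V and pipe-flow
#'     volume basis equal to the tank volume; the physically consistent
#'     configuration for actual design use.}
#' }
#'
#' @param params a `ras_params` bundle.
#' @param preset `"reproduction"` or `"physical"`.
#' @return The modified, re-validated bundle.
#' @export
apply_preset <- function(params, preset = c("reproduction", "physical")) {
  preset <- match.arg(preset)
  if (preset == "reproduction") {
    params$tank$sd_mode <- "fixed"
    params$tank$sd_fixed <- 100
    params$aeration$volume_basis <- 1
    params$growth$tau_low_denominator <- "t_max"
  } else {
    params$tank$sd_mode <- "dynamic"
    params$aeration$volume_basis <- params$tank$volume
    params$growth$tau_low_denominator <- "t_min"
  }
  out <- validate_params(unclass(params))
  attr(out, "preset") <- preset
  out
}

#' Run the coupled growth and oxygen-budget simulation
#'
#' Couples the daily bioenergetic growth model with the hourly oxygen
#' budget over a grow-out horizon.  Each day the individual weight is
#' advanced by the growth rate; each hour of that day the four budget
#' terms are evaluated at the start-of-day weight (no intra-day
#' interpolation) and the dissolved-oxygen trace is advanced by
#' [do_step()].  Deterministic given its inputs.
#'
#' @param params a `ras_params` bundle (pass a calibrated bundle, e.g. from
#'   [calibrated_growth_params()], for realistic growth).
#' @param days horizon, days (>= 1).
#' @param env environment schedule from [environment_schedule()].
#' @param preset optional preset name applied to `params` first (see
#'   [apply_preset()]); `NULL` leaves the bundle as supplied.
#' @param hourly emit the hourly budget/DO table (default TRUE).
#' @param do_mode sign convention for the DO trace, see [do_step()].
#' @param initial_do starting DO for the trace, g m-3; defaults to the
#'   schedule's day-1 ambient DO.
#' @param f_feed optional override of the relative feeding level.
#' @return An object of class `ras_trajectory`: list with
#'   \describe{
#'     \item{daily}{growth records as from [integrate_growth()], plus
#'       `biomass_kg`;}
#'     \item{hourly}{one row per simulated hour: `time_h`, `day`, the four
#'       budget terms, `do_sup`, `sd_kg_m3`, `biomass_kg`, `do_conc`;}
#'     \item{meta}{preset name, parameter hash, horizon, environment.}
#'   }
#' @examples
#' p <- apply_preset(default_parameters(), "reproduction")
#' tr <- run_simulation(p, days = 2, f_feed = 0)
#' head(tr$hourly)
#' @export
run_simulation <- function(params = default_parameters(), days = 150,
                           env = environment_schedule(days),
                           preset = NULL, hourly = TRUE,
                           do_mode = c("physical", "as_printed"),
                           initial_do = NULL, f_feed = NULL) {
  do_mode <- match.arg(do_mode)
  days <- as.integer(days)
  if (days < 1) stop("horizon must be at least 1 day", call. = FALSE)
  if (!is.null(preset)) params <- apply_preset(params, preset)
  validate_params(unclass(params))

  daily <- integrate_growth(params$tank$w0, days, env, params, f_feed)
  daily$biomass_kg <- daily$weight_g * params$tank$n_fish / 1000
  n_days_run <- nrow(daily) - 1  # simulated days (may be < days if truncated)

  hourly_df <- NULL
  if (hourly && n_days_run > 0) {
    day_idx <- rep(seq_len(n_days_run), each = 24)
    W_day <- daily$weight_g[day_idx]           # start-of-day weight
    T_day <- env$temperature_c[day_idx]
    budget <- oxygen_budget(T_day, W_day, params, warn = FALSE)
    # warn once per run if the respiration fit range was left
    vr <- params$respiration
    if (any(W_day < vr$valid_weight_range[1] | W_day > vr$valid_weight_range[2]) ||
        any(T_day < vr$valid_temp_range[1] | T_day > vr$valid_temp_range[2])) {
      warning("respiration polynomial evaluated outside its fitted range ",
              "during this run", call. = FALSE)
    }
    do0 <- if (is.null(initial_do)) env$do_mg_l[1] else initial_do
    do_conc <- numeric(length(day_idx))
    prev <- do0
    for (h in seq_along(day_idx)) {
      prev <- do_step(prev, budget[h, ], dt = 1, mode = do_mode)
      do_conc[h] <- prev
    }
    hourly_df <- data.frame(
      time_h = seq_along(day_idx), day = day_idx,
      do_fr = budget$do_fr, do_n = budget$do_n, do_b = budget$do_b,
      do_pf = budget$do_pf, do_sup = budget$do_sup,
      sd_kg_m3 = budget$sd_kg_m3, biomass_kg = budget$biomass_kg,
      do_conc = do_conc
    )
  }

  out <- list(
    daily = daily,
    hourly = hourly_df,
    meta = list(
      preset = attr(params, "preset") %||% "custom",
      param_hash = param_hash(params),
      days = n_days_run,
      truncated = isTRUE(attr(daily, "truncated")),
      do_mode = do_mode,
      params = params,
      env = env[seq_len(min(nrow(env), max(n_days_run, 1))), ]
    )
  )
  class(out) <- "ras_trajectory"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ras_trajectory <- function(x, ...) {
  cat("<ras_trajectory> ", x$meta$days, "days, preset", x$meta$preset,
      if (x$meta$truncated) "(truncated)" else "", "\n")
  cat("  weight:", round(x$daily$weight_g[1], 2), "->",
      round(x$daily$weight_g[nrow(x$daily)], 2), "g\n")
  if (!is.null(x$hourly)) {
    cat("  do_fr :", round(min(x$hourly$do_fr), 2), "-",
        round(max(x$hourly$do_fr), 2), "g O2 m-3 h-1\n")
  }
  invisible(x)
}

#' Summarize a simulation trajectory
#'
#' Tabulates the start/end values and extremes of each oxygen budget
#' component, the total consumption (respiration + nitrification +
#' biofilter), the supplemental demand, and the weight endpoints.
#'
#' @param trajectory a `ras_trajectory` from [run_simulation()] with an
#'   hourly table.
#' @return An object of class `ras_summary`: list with `weight` (start,
#'   end) and a data frame `oxygen` with one row per quantity (`do_fr`,
#'   `do_n`, `do_b`, `total`, `do_sup`) and columns `start`, `end`,
#'   `min`, `max`.
#' @export
summarize_trajectory <- function(trajectory) {
  stopifnot(inherits(trajectory, "ras_trajectory"))
  h <- trajectory$hourly
  if (is.null(h) || nrow(h) == 0) {
    stop("trajectory has no hourly records to summarize", call. = FALSE)
  }
  total <- h$do_fr + h$do_n + h$do_b
  series <- list(do_fr = h$do_fr, do_n = h$do_n, do_b = h$do_b,
                 total = total, do_sup = h$do_sup)
  oxy <- do.call(rbind, lapply(names(series), function(nm) {
    v <- series[[nm]]
    data.frame(quantity = nm, start = v[1], end = v[length(v)],
               min = min(v), max = max(v))
  }))
  d <- trajectory$daily
  out <- list(
    weight = c(start = d$weight_g[1], end = d$weight_g[nrow(d)]),
    oxygen = oxy,
    preset = trajectory$meta$preset,
    days = trajectory$meta$days
  )
  class(out) <- "ras_summary"
  out
}

#' @export
print.ras_summary <- function(x, ...) {
  cat("<ras_summary> ", x$days, "days, preset", x$preset, "\n")
  cat("  weight:", round(x$weight["start"], 2), "->",
      round(x$weight["end"], 2), "g\n")
  print(cbind(quantity = x$oxygen$quantity,
              round(x$oxygen[, -1], 4)), row.names = FALSE)
  invisible(x)
}

#' Run the simulation across a set of water temperatures
#'
#' Re-runs [run_simulation()] with the same bundle and a constant-
#' temperature schedule at each requested temperature, returning one
#' summary per temperature (ordering preserved).
#'
#' @inheritParams run_simulation
#' @param temps water temperatures, C (non-empty).
#' @param env_template optional schedule supplying DO/NH3/photoperiod
#'   series; its temperature column is overwritten per sweep point.
#' @return A list of `ras_summary` objects, named by temperature, with
#'   attribute `final_weights` (named numeric vector).
#' @export
temperature_sweep <- function(params = default_parameters(), temps,
                              days = 150, env_template = NULL,
                              preset = NULL, f_feed = NULL,
                              do_mode = "physical") {
  if (length(temps) == 0) stop("temps must be non-empty", call. = FALSE)
  if (is.null(env_template)) env_template <- environment_schedule(days)
  res <- lapply(temps, function(Tc) {
    env <- env_template
    env$temperature_c <- Tc
    tr <- run_simulation(params, days = days, env = env, preset = preset,
                         do_mode = do_mode, f_feed = f_feed)
    s <- summarize_trajectory(tr)
    s$temperature <- Tc
    s
  })
  names(res) <- as.character(temps)
  attr(res, "final_weights") <- vapply(res, function(s) unname(s$weight["end"]),
                                       numeric(1))
  res
}
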