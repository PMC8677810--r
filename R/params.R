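#' Parameter bundle for the oxygen budget and growth model
#'
#' Builds the full set of model constants and run settings with the
#' literature defaults.  Every component can be overridden, either here or
#' through a configuration file read by [load_config()].  The bundle is
#' validated on construction: an invariant violation (for example a critical
#' dissolved-oxygen level below the minimum level) is rejected with an error
#' naming the offending field.
#'
#' Components:
#' \describe{
#'   \item{respiration}{coefficients of the mass-specific oxygen consumption
#'     polynomial in temperature and weight (mg O2 kg-1 fish h-1), with the
#'     weight/temperature range the regression was fitted on (20--200 g,
#'     24--32 C).  The model is routinely evaluated outside that range
#'     (down to 3 g fingerlings); this warns rather than fails.}
#'   \item{nitrification}{stoichiometric oxygen demand of nitrification
#'     (4.57 g O2 per g total ammonia nitrogen), the temperature coefficient
#'     \eqn{K_{NR} = k_{base} \theta^{T - T_{ref}}}, and the fraction of feed
#'     excreted as TAN (0.03).}
#'   \item{biofilter}{unfiltered five-day biochemical oxygen demand excretion
#'     rate (2160 mg O2 kg-1 fish day-1) and the factor 2.3 by which the
#'     biofilter's oxygen demand exceeds it.}
#'   \item{aeration}{pump cycle length (h), pumping frequency (h-1),
#'     aeration efficiency (fraction) and oxygen transfer rate (g O2 h-1),
#'     plus the volume basis used when converting the transfer rate to a
#'     volumetric addition (see [apply_preset()]).}
#'   \item{growth}{bioenergetic constants: anabolism coefficient 0.2919,
#'     food consumption coefficient h, weight exponents m (anabolism) and n
#'     (catabolism), fasting catabolism coefficient K_min at T_min with
#'     temperature sensitivity s, the cardinal temperatures, the dissolved
#'     oxygen and unionized ammonia thresholds, the relative feeding level
#'     f_feed, and two documented knobs: `k_scale` (rescales K_min during
#'     calibration) and `tau_low_denominator` (which half-width the
#'     below-optimum temperature factor uses).  The tabulated constant
#'     C = 0.236 is stored but referenced by no equation.}
#'   \item{feeding}{coefficients of the log-normal feeding-ratio curve
#'     (percent body mass per day as a function of weight) and the stepwise
#'     reference schedule used in `table2` mode.}
#'   \item{tank}{water volume (m3), number of fish, initial individual
#'     weight (g), recirculation flow rate (m3 h-1), and the stocking
#'     density mode: `dynamic` (N W / V) or `fixed` (a constant SD,
#'     default 100 kg m-3, the value under which the published volumetric
#'     respiration figures are reproduced).}
#' }
#'
#' @param respiration,nitrification,biofilter,aeration,growth,feeding,tank
#'   named lists overriding individual fields of the corresponding component.
#' @return A validated list of class `ras_params`.
#' @seealso [load_config()], [apply_preset()], [calibrated_growth_params()]
#' @examples
#' p <- default_parameters()
#' p$biofilter$bod5_excretion
#' p2 <- default_parameters(tank = list(volume = 100))
#' @export
default_parameters <- function(respiration = list(), nitrification = list(),
                               biofilter = list(), aeration = list(),
                               growth = list(), feeding = list(),
                               tank = list()) {
  bundle <- list(
    respiration = list(
      c0 = 2014.45, c1 = 2.75, c2 = -165.2, c3 = 0.007, c4 = 3.93, c5 = -0.21,
      valid_weight_range = c(20, 200),
      valid_temp_range = c(24, 32)
    ),
    nitrification = list(
      o2_per_tan = 4.57, k_base = 0.1, theta = 1.08, t_ref = 20,
      tan_fraction = 0.03
    ),
    biofilter = list(
      bod5_excretion = 2160, demand_factor = 2.3
    ),
    aeration = list(
      pump_cycle_h = 1, pump_frequency_per_h = 1, efficiency = 0.5,
      otr = 36.8, volume_basis = 1
    ),
    growth = list(
      anabolism_const = 0.2919, h_food = 0.81, m_exp = 0.67, n_exp = 0.81,
      k_min = 0.25, s_const = 0.015,
      t_min = 15, t_max = 40, t_opt = 28,
      do_crit = 5, do_min = 3, nh3_max = 0.6, nh3_crit = 0.025,
      f_feed = NA_real_, k_scale = 1,
      tau_low_denominator = "t_min",
      c_const = 0.236
    ),
    feeding = list(
      fr_amp = 17.02, fr_shift = 1.14, fr_width = 19.52,
      schedule_mode = "equation",
      table2_schedule = tilapia_feeding_table()
    ),
    tank = list(
      volume = 150, n_fish = 20000, w0 = 3, flow_rate = 30,
      sd_mode = "dynamic", sd_fixed = 100
    )
  )
  user <- list(respiration = respiration, nitrification = nitrification,
               biofilter = biofilter, aeration = aeration, growth = growth,
               feeding = feeding, tank = tank)
  for (comp in names(user)) {
    bundle[[comp]] <- merge_fields(bundle[[comp]], user[[comp]], comp)
  }
  validate_params(bundle)
}

merge_fields <- function(base, override, comp) {
  if (length(override) == 0) return(base)
  if (is.null(names(override)) || any(names(override) == "")) {
    stop("overrides for '", comp, "' must be a named list", call. = FALSE)
  }
  unknown <- setdiff(names(override), names(base))
  if (length(unknown) > 0) {
    stop("unknown field(s) in '", comp, "': ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  base[names(override)] <- override
  base
}

#' Reference feeding schedule for Nile tilapia in tanks
#'
#' The stepwise recommended feeding rates and expected growth rates at 28 C
#' for tilapia from 0.02 g fry to 450 g, as tabulated in the hatchery
#' literature.  Ranged feeding rates are kept as raw bounds with a midpoint
#' used for lookups; growth rates are absent (NA) for the fry stages.
#'
#' @return A data frame with columns `w_lo_g`, `w_hi_g`, `growth_g_day`,
#'   `feed_pct_lo`, `feed_pct_hi`, `feed_pct` (midpoint), `period_day`.
#' @export
tilapia_feeding_table <- function() {
  tab <- data.frame(
    w_lo_g = c(0.02, 0.5, 5, 20, 50, 100, 250),
    w_hi_g = c(0.5, 5, 20, 50, 100, 250, 450),
    growth_g_day = c(NA, NA, 0.5, 1.0, 1.5, 2.5, 3.0),
    feed_pct_lo = c(15, 10, 7, 4, 3.5, 1.5, 1.0),
    feed_pct_hi = c(20, 15, 10, 7, 4, 3.5, 1.5),
    period_day = c(30, 30, 30, 30, 30, 50, 70)
  )
  tab$feed_pct <- (tab$feed_pct_lo + tab$feed_pct_hi) / 2
  tab
}

#' Reference growth-rate schedule used for feeding-level calibration
#'
#' The rows of [tilapia_feeding_table()] that carry a numeric expected
#' growth rate (5 g upward), in the shape consumed by
#' [calibrate_relative_feeding()].
#'
#' @return Data frame with columns `w_lo_g`, `w_hi_g`, `growth_g_day`.
#' @export
growth_reference_schedule <- function() {
  tab <- tilapia_feeding_table()
  tab <- tab[!is.na(tab$growth_g_day), c("w_lo_g", "w_hi_g", "growth_g_day")]
  rownames(tab) <- NULL
  tab
}

# Invariant checks; every failure names the offending field(s).
check_that <- function(ok, field, msg) {
  if (!isTRUE(ok)) stop("invalid parameters: ", field, " ", msg, call. = FALSE)
}

#' Validate a parameter bundle
#'
#' Checks every documented invariant (positivity, threshold orderings,
#' interval coverage).  Called by [default_parameters()] and
#' [load_config()]; exported so externally assembled bundles can be checked.
#'
#' @param p a parameter bundle as returned by [default_parameters()].
#' @return `p`, invisibly classed `ras_params`, or an error naming the field.
#' @export
validate_params <- function(p) {
  num_fields <- list(
    c("respiration", "c0"), c("respiration", "c1"), c("respiration", "c2"),
    c("respiration", "c3"), c("respiration", "c4"), c("respiration", "c5"),
    c("nitrification", "o2_per_tan"), c("nitrification", "k_base"),
    c("nitrification", "theta"), c("nitrification", "t_ref"),
    c("nitrification", "tan_fraction"),
    c("biofilter", "bod5_excretion"), c("biofilter", "demand_factor"),
    c("aeration", "pump_cycle_h"), c("aeration", "pump_frequency_per_h"),
    c("aeration", "efficiency"), c("aeration", "otr"),
    c("aeration", "volume_basis"),
    c("growth", "anabolism_const"), c("growth", "h_food"),
    c("growth", "m_exp"), c("growth", "n_exp"), c("growth", "k_min"),
    c("growth", "s_const"), c("growth", "t_min"), c("growth", "t_max"),
    c("growth", "t_opt"), c("growth", "do_crit"), c("growth", "do_min"),
    c("growth", "nh3_max"), c("growth", "nh3_crit"), c("growth", "k_scale"),
    c("feeding", "fr_amp"), c("feeding", "fr_shift"), c("feeding", "fr_width"),
    c("tank", "volume"), c("tank", "n_fish"), c("tank", "w0"),
    c("tank", "flow_rate"), c("tank", "sd_fixed")
  )
  for (f in num_fields) {
    v <- p[[f[1]]][[f[2]]]
    field <- paste(f, collapse = ".")
    check_that(is.numeric(v) && length(v) == 1, field, "must be a single number")
    check_that(is.finite(v), field, "must be finite")
  }

  r <- p$respiration
  check_that(length(c(r$c0, r$c1, r$c2, r$c3, r$c4, r$c5)) == 6,
             "respiration.c0..c5", "must have exactly 6 coefficients")
  check_that(diff(r$valid_weight_range) > 0, "respiration.valid_weight_range",
             "must be a non-empty interval")
  check_that(diff(r$valid_temp_range) > 0, "respiration.valid_temp_range",
             "must be a non-empty interval")

  ni <- p$nitrification
  for (f in c("o2_per_tan", "k_base", "theta", "tan_fraction")) {
    check_that(ni[[f]] > 0, paste0("nitrification.", f), "must be positive")
  }
  check_that(ni$theta > 1, "nitrification.theta", "must exceed 1")

  b <- p$biofilter
  check_that(b$bod5_excretion > 0, "biofilter.bod5_excretion", "must be positive")
  check_that(b$demand_factor > 0, "biofilter.demand_factor", "must be positive")

  a <- p$aeration
  check_that(a$efficiency >= 0 && a$efficiency <= 1, "aeration.efficiency",
             "must lie in [0, 1]")
  for (f in c("pump_cycle_h", "pump_frequency_per_h", "otr", "volume_basis")) {
    check_that(a[[f]] > 0, paste0("aeration.", f), "must be positive")
  }

  g <- p$growth
  check_that(g$t_min < g$t_opt && g$t_opt < g$t_max,
             "growth.t_min/t_opt/t_max", "must satisfy t_min < t_opt < t_max")
  check_that(g$do_min < g$do_crit, "growth.do_crit/do_min",
             "must satisfy do_min < do_crit")
  check_that(g$nh3_crit < g$nh3_max, "growth.nh3_crit/nh3_max",
             "must satisfy nh3_crit < nh3_max")
  check_that(g$k_min > 0, "growth.k_min", "must be positive")
  check_that(g$k_scale > 0, "growth.k_scale", "must be positive")
  if (!is.na(g$f_feed)) {
    check_that(g$f_feed >= 0 && g$f_feed <= 1, "growth.f_feed",
               "must lie in [0, 1]")
  }
  check_that(g$tau_low_denominator %in% c("t_min", "t_max"),
             "growth.tau_low_denominator", "must be 't_min' or 't_max'")

  fe <- p$feeding
  check_that(fe$fr_amp > 0, "feeding.fr_amp", "must be positive")
  check_that(fe$fr_width > 0, "feeding.fr_width", "must be positive")
  check_that(fe$schedule_mode %in% c("equation", "table2"),
             "feeding.schedule_mode", "must be 'equation' or 'table2'")
  tab <- fe$table2_schedule
  check_that(is.data.frame(tab) && nrow(tab) > 0, "feeding.table2_schedule",
             "must be a non-empty data frame")
  o <- order(tab$w_lo_g)
  check_that(all(tab$w_hi_g[o][-nrow(tab)] <= tab$w_lo_g[o][-1] + 1e-9),
             "feeding.table2_schedule", "intervals must not overlap")
  check_that(min(tab$w_lo_g) <= 0.02 && max(tab$w_hi_g) >= 450,
             "feeding.table2_schedule", "must cover 0.02-450 g")

  tk <- p$tank
  for (f in c("volume", "n_fish", "w0", "sd_fixed")) {
    check_that(tk[[f]] > 0, paste0("tank.", f), "must be positive")
  }
  check_that(tk$flow_rate >= 0, "tank.flow_rate", "must be non-negative")
  check_that(tk$sd_mode %in% c("dynamic", "fixed"), "tank.sd_mode",
             "must be 'dynamic' or 'fixed'")

  class(p) <- "ras_params"
  invisible(p)
}

#' @export
print.ras_params <- function(x, ...) {
  cat("<ras_params>\n")
  cat("  tank:     V =", x$tank$volume, "m3,", x$tank$n_fish, "fish, w0 =",
      x$tank$w0, "g, SD mode", x$tank$sd_mode, "\n")
  cat("  aeration: OTR", x$aeration$otr, "g O2/h, efficiency",
      x$aeration$efficiency, ", volume basis", x$aeration$volume_basis, "m3\n")
  cat("  growth:   f_feed =", x$growth$f_feed, ", k_scale =",
      x$growth$k_scale, ", T(opt) =", x$growth$t_opt, "C\n")
  cat("  hash:    ", param_hash(x), "\n")
  invisible(x)
}

#' Load a parameter bundle from a configuration file or list
#'
#' Reads a JSON or YAML configuration whose top-level keys are the bundle
#' component names (`respiration`, `nitrification`, `biofilter`, `aeration`,
#' `growth`, `feeding`, `tank`) with fields named as in
#' [default_parameters()].  Unspecified fields keep their defaults;
#' invariant violations are rejected with the field name.
#'
#' @param source path to a `.json`/`.yaml`/`.yml` file, or a named list.
#' @return A validated `ras_params` bundle.
#' @examples
#' p <- load_config(list(tank = list(volume = 150, n_fish = 20000, w0 = 3)))
#' stocking_density(p, W = 3)   # 0.4 kg m-3
#' @export
load_config <- function(source) {
  if (is.character(source)) {
    if (!file.exists(source)) stop("config file not found: ", source, call. = FALSE)
    ext <- tolower(tools::file_ext(source))
    cfg <- switch(ext,
      "json" = jsonlite::fromJSON(source, simplifyVector = TRUE),
      "yaml" = ,
      "yml"  = yaml::read_yaml(source),
      stop("unsupported config format: .", ext, " (use JSON or YAML)",
           call. = FALSE)
    )
  } else if (is.list(source)) {
    cfg <- source
  } else {
    stop("config source must be a file path or a named list", call. = FALSE)
  }
  known <- c("respiration", "nitrification", "biofilter", "aeration",
             "growth", "feeding", "tank")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (comp in names(cfg)) {
    for (f in names(cfg[[comp]])) {
      v <- cfg[[comp]][[f]]
      if (!f %in% c("schedule_mode", "tau_low_denominator", "sd_mode",
                    "table2_schedule", "valid_weight_range",
                    "valid_temp_range") && !is.numeric(v)) {
        stop("non-numeric value for ", comp, ".", f, call. = FALSE)
      }
    }
  }
  if (!is.null(cfg$feeding$table2_schedule)) {
    tab <- as.data.frame(cfg$feeding$table2_schedule)
    canon <- names(tilapia_feeding_table())
    if (all(canon %in% names(tab))) tab <- tab[, canon]
    cfg$feeding$table2_schedule <- tab
  }
  do.call(default_parameters, cfg)
}

#' Serialize a parameter bundle to JSON or YAML
#'
#' Inverse of [load_config()]: `load_config(save_config(p, path))`
#' reproduces `p` field for field.
#'
#' @param p a `ras_params` bundle.
#' @param path output path; the extension selects the format.
#' @return `path`, invisibly.
#' @export
save_config <- function(p, path) {
  x <- unclass(p)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path)
  } else {
    stop("unsupported config format: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' Stocking density implied by a parameter bundle
#'
#' In `dynamic` mode the density is the live biomass per unit volume,
#' N W / (1000 V) kg m-3; in `fixed` mode it is the configured constant.
#'
#' @param p a `ras_params` bundle.
#' @param W individual fish weight, g (vectorized).
#' @return stocking density, kg m-3.
#' @export
stocking_density <- function(p, W) {
  if (p$tank$sd_mode == "fixed") {
    rep(p$tank$sd_fixed, length(W))
  } else {
    p$tank$n_fish * W / 1000 / p$tank$volume
  }
}

#' Daily environment schedule for a simulation run
#'
#' Per-day water temperature, ambient dissolved oxygen (used by the growth
#' limitation factor, not fed back from the oxygen balance), unionized
#' ammonia, and photoperiod.  Scalars are recycled over the horizon.
#'
#' @param days horizon length in days (>= 1).
#' @param temperature water temperature, C.
#' @param do dissolved oxygen, mg L-1.
#' @param nh3 unionized ammonia, mg L-1.
#' @param photoperiod_h daylight hours per day, in [0, 24].
#' @return Data frame with columns `day` (1..days), `temperature_c`,
#'   `do_mg_l`, `nh3_mg_l`, `photoperiod_h`.
#' @export
environment_schedule <- function(days, temperature = 28, do = 6.5,
                                 nh3 = 0.01, photoperiod_h = 12) {
  days <- as.integer(days)
  if (days < 1) stop("days must be >= 1", call. = FALSE)
  rec <- function(x, nm) {
    if (length(x) == 1) x <- rep(x, days)
    if (length(x) != days) {
      stop("series '", nm, "' must have length 1 or ", days, call. = FALSE)
    }
    x
  }
  photoperiod_h <- rec(photoperiod_h, "photoperiod_h")
  if (any(photoperiod_h < 0 | photoperiod_h > 24)) {
    stop("photoperiod_h must lie in [0, 24]", call. = FALSE)
  }
  data.frame(
    day = seq_len(days),
    temperature_c = rec(temperature, "temperature"),
    do_mg_l = rec(do, "do"),
    nh3_mg_l = rec(nh3, "nh3"),
    photoperiod_h = photoperiod_h
  )
}

# FNV-1a 32-bit hash of the serialized bundle; provenance stamp for
# manifests and trajectory metadata (no cryptographic intent).
param_hash <- function(p) {
  s <- jsonlite::toJSON(unclass(p), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    # 32-bit modular multiply by the FNV prime 16777619 = 2^24 + 403,
    # kept exact in doubles: h * 2^24 mod 2^32 = (h mod 2^8) * 2^24
    h <- (h * 403 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
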