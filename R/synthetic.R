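#' Noise specification for synthetic logs
#'
#' @param do_sigma additive Gaussian noise on each DO channel, mg L-1
#'   (>= 0).  0.12 mg L-1 corresponds to the 1.5 percent tolerance class
#'   of a typical handheld DO meter at an 8 mg L-1 supply.
#' @param weight_cv multiplicative lognormal coefficient of variation for
#'   weighings (>= 0).
#' @param seed integer RNG seed; a fixed seed makes generation
#'   reproducible bit-for-bit.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(do_sigma = 0, weight_cv = 0, seed = 1L) {
  if (do_sigma < 0 || weight_cv < 0) {
    stop("noise sigmas must be non-negative", call. = FALSE)
  }
  structure(list(do_sigma = do_sigma, weight_cv = weight_cv,
                 seed = as.integer(seed)), class = "noise_spec")
}

#' Generate a measured-style hourly sensor log from a model trajectory
#'
#' Emulates the farm instrumentation: for every simulated hour an inlet
#' DO is chosen (constant baseline, default 8 mg L-1) and the tank outlet
#' DO is set so that the inlet/outlet consumption formula
#' ([oxygen_consumption_from_sensors()]) recovers the model's
#' mass-specific respiration exactly; a biofilter outlet channel is set
#' likewise so the biofilter passage recovers the model's nitrification +
#' biofilter demand.  Gaussian noise of sd `do_sigma` is then added to
#' each DO channel independently.  Outlet DO is derived from consumption,
#' not from simulated tank dynamics: the construction makes the
#' validation round trip exact by design.
#'
#' Flow: `"constant"` holds the tank's configured flow rate; `"ramp"`
#' scales flow up with demand so the tank DO drop stays near
#' `target_drop` (the farm practice of adjusting flow with growth).  If a
#' requested drop cannot be realized with non-negative outlet DO the
#' generator errors, reporting the first limiting hour.
#'
#' @param trajectory a `ras_trajectory` with an hourly table.
#' @param noise a [noise_spec()].
#' @param inlet_do inlet DO baseline, mg L-1 (default 8).
#' @param flow_mode `"constant"` or `"ramp"`.
#' @param target_drop tank DO drop targeted in ramp mode, mg L-1.
#' @return Data frame of class `sensor_log` with columns `timestamp_h`,
#'   `do_in_mg_l`, `do_out_mg_l`, `do_bf_out_mg_l`, `flow_m3_h`,
#'   `biomass_kg`.
#' @export
generate_sensor_log <- function(trajectory, noise = noise_spec(),
                                inlet_do = 8,
                                flow_mode = c("constant", "ramp"),
                                target_drop = 2) {
  stopifnot(inherits(trajectory, "ras_trajectory"))
  flow_mode <- match.arg(flow_mode)
  h <- trajectory$hourly
  if (is.null(h)) stop("trajectory has no hourly table", call. = FALSE)
  tank <- trajectory$meta$params$tank
  if (tank$flow_rate <= 0) stop("tank flow_rate must be positive", call. = FALSE)

  oc <- h$do_fr * 1000 / h$sd_kg_m3          # mg O2 kg-1 h-1, model respiration
  bf_load <- (h$do_n + h$do_b) * tank$volume  # g O2 h-1 across the biofilter
  Q <- if (flow_mode == "constant") {
    rep(tank$flow_rate, nrow(h))
  } else {
    pmax(tank$flow_rate, oc * h$biomass_kg / (1000 * target_drop))
  }
  drop_tank <- oc * h$biomass_kg / (1000 * Q)  # mg L-1
  drop_bf <- bf_load / Q                       # mg L-1
  do_out <- inlet_do - drop_tank
  do_bf_out <- do_out - drop_bf
  if (any(do_bf_out < 0)) {
    hr <- h$time_h[which(do_bf_out < 0)[1]]
    stop("flow too small to realize the demanded DO difference with ",
         "non-negative outlet DO (first limiting hour: ", hr, ")",
         call. = FALSE)
  }
  set.seed(noise$seed)
  n <- nrow(h)
  log <- data.frame(
    timestamp_h = h$time_h,
    do_in_mg_l = inlet_do + stats::rnorm(n, 0, noise$do_sigma),
    do_out_mg_l = do_out + stats::rnorm(n, 0, noise$do_sigma),
    do_bf_out_mg_l = do_bf_out + stats::rnorm(n, 0, noise$do_sigma),
    flow_m3_h = Q,
    biomass_kg = h$biomass_kg
  )
  class(log) <- c("sensor_log", "data.frame")
  log
}

#' Generate a periodic weighing log from a model trajectory
#'
#' Samples the model's daily individual weight every `interval_days`
#' (day 0 always included) and applies multiplicative lognormal noise
#' with the requested coefficient of variation, mean-corrected so the
#' noise is unbiased (E[noisy/true] = 1).
#'
#' @param trajectory a `ras_trajectory`.
#' @param interval_days weighing interval, days (>= 1; the farm protocol
#'   weighed every ten days).
#' @param noise a [noise_spec()]; only `weight_cv` and `seed` are used.
#' @return Data frame of class `weighing_log` with columns `day`,
#'   `weight_g`.
#' @export
generate_weighing_log <- function(trajectory, interval_days = 10,
                                  noise = noise_spec()) {
  stopifnot(inherits(trajectory, "ras_trajectory"))
  interval_days <- as.integer(interval_days)
  if (interval_days < 1) stop("interval_days must be >= 1", call. = FALSE)
  d <- trajectory$daily
  days <- seq(0, max(d$day), by = interval_days)
  w <- d$weight_g[match(days, d$day)]
  if (noise$weight_cv > 0) {
    set.seed(noise$seed)
    sdlog <- sqrt(log(1 + noise$weight_cv^2))
    w <- w * stats::rlnorm(length(w), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  log <- data.frame(day = days, weight_g = w)
  class(log) <- c("weighing_log", "data.frame")
  log
}
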