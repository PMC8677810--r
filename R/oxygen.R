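#' Mass-specific oxygen consumption by fish respiration
#'
#' Second-order polynomial in water temperature and individual weight,
#' fitted for tilapia in the 20--200 g, 24--32 C range:
#' \deqn{FR = c_0 + c_1 W + c_2 T + c_3 W^2 + c_4 T^2 + c_5 W T}
#' with default coefficients 2014.45, 2.75, -165.2, 0.007, 3.93, -0.21.
#' Outside the fitted range (fingerlings at 3 g, harvest fish above 200 g)
#' the polynomial is still evaluated, with a warning, because grow-out
#' trajectories start and end there.
#'
#' @param T water temperature, C (vectorized).
#' @param W individual fish weight, g (vectorized).
#' @param params a `ras_params` bundle (only `$respiration` is used).
#' @param warn warn when inputs leave the fitted range (default TRUE).
#' @return oxygen consumption, mg O2 kg-1 fish h-1.
#' @examples
#' respiration_rate(28, 3)      # 460.64
#' respiration_rate(28, 226.25) # 120.13
#' @export
respiration_rate <- function(T, W, params = default_parameters(), warn = TRUE) {
  if (!all(is.finite(T)) || !all(is.finite(W))) {
    stop("temperature and weight must be finite", call. = FALSE)
  }
  r <- params$respiration
  if (warn) {
    if (any(W < r$valid_weight_range[1] | W > r$valid_weight_range[2])) {
      warning("weight outside the fitted range [",
              r$valid_weight_range[1], ", ", r$valid_weight_range[2],
              "] g; extrapolating the respiration polynomial", call. = FALSE)
    }
    if (any(T < r$valid_temp_range[1] | T > r$valid_temp_range[2])) {
      warning("temperature outside the fitted range [",
              r$valid_temp_range[1], ", ", r$valid_temp_range[2],
              "] C; extrapolating the respiration polynomial", call. = FALSE)
    }
  }
  r$c0 + r$c1 * W + r$c2 * T + r$c3 * W^2 + r$c4 * T^2 + r$c5 * W * T
}

#' Volumetric oxygen consumption by fish respiration
#'
#' Converts the mass-specific rate to a per-volume rate via the stocking
#' density: \eqn{DO_{FR} = FR \times SD / 1000}.
#'
#' @inheritParams respiration_rate
#' @param SD stocking density, kg m-3 (>= 0).
#' @return g O2 m-3 h-1.
#' @examples
#' do_fish_respiration(28, 3, 100)  # 46.06
#' do_fish_respiration(32, 3, 100)  # 74.05
#' @export
do_fish_respiration <- function(T, W, SD, params = default_parameters(),
                                warn = TRUE) {
  if (any(SD < 0)) stop("stocking density must be non-negative", call. = FALSE)
  respiration_rate(T, W, params, warn = warn) * SD / 1000
}

#' Weight minimizing the respiration polynomial at fixed temperature
#'
#' The polynomial is an upward parabola in weight (positive quadratic
#' coefficient), so at each temperature the mass-specific rate has a
#' minimum at the vertex \eqn{W^* = -(c_1 + c_5 T) / (2 c_3)}.  At 28 C
#' this is about 223.6 g, which is why the predicted respiration series
#' bottoms out near the end of a grow-out to 226 g.
#'
#' @inheritParams respiration_rate
#' @return vertex weight, g (can be <= 0 at low temperatures).
#' @examples
#' respiration_minimum_weight(28)  # 223.57
#' @export
respiration_minimum_weight <- function(T, params = default_parameters()) {
  r <- params$respiration
  if (r$c3 <= 0) stop("quadratic weight coefficient must be positive", call. = FALSE)
  -(r$c1 + r$c5 * T) / (2 * r$c3)
}

#' Temperature coefficient of nitrification
#'
#' Arrhenius-style correction \eqn{K_{NR} = k_{base} \theta^{T - T_{ref}}}
#' (defaults 0.1 and 1.08 about 20 C); demand roughly doubles every 9 C.
#'
#' @inheritParams respiration_rate
#' @return dimensionless coefficient.
#' @examples
#' nitrification_coefficient(20)  # 0.1
#' nitrification_coefficient(28)  # 0.18509
#' @export
nitrification_coefficient <- function(T, params = default_parameters()) {
  if (!all(is.finite(T))) stop("temperature must be finite", call. = FALSE)
  n <- params$nitrification
  n$k_base * n$theta^(T - n$t_ref)
}

#' Total ammonia nitrogen production rate
#'
#' A fixed fraction (default 3 percent) of the daily feed mass is excreted
#' as TAN; converting percent body mass per day and grams to an hourly
#' stock-level rate gives
#' \eqn{Nr = tan\_fraction \cdot F_r \cdot W \cdot N_F / (24 \cdot 1000)}.
#'
#' @param Fr feeding ratio, percent of body mass per day.
#' @param W individual fish weight, g.
#' @param n_fish number of fish.
#' @inheritParams respiration_rate
#' @return g TAN h-1.
#' @export
nitrification_rate <- function(Fr, W, n_fish, params = default_parameters()) {
  if (any(Fr < 0) || any(W < 0) || any(n_fish < 0)) {
    stop("feeding ratio, weight and fish count must be non-negative",
         call. = FALSE)
  }
  params$nitrification$tan_fraction * Fr * W * n_fish / (24 * 1000)
}

#' Volumetric oxygen consumption by nitrification
#'
#' Oxidizing 1 g of TAN consumes 4.57 g O2; the volumetric demand is
#' \eqn{DO_N = 4.57 \cdot K_{NR}(T) \cdot Nr / V}.
#'
#' @inheritParams nitrification_rate
#' @param V water volume, m3 (> 0).
#' @return g O2 m-3 h-1.
#' @export
do_nitrification <- function(T, Fr, W, n_fish, V, params = default_parameters()) {
  if (any(V <= 0)) stop("water volume must be positive", call. = FALSE)
  params$nitrification$o2_per_tan * nitrification_coefficient(T, params) *
    nitrification_rate(Fr, W, n_fish, params) / V
}

#' Volumetric oxygen consumption by the biofilter
#'
#' The biofilter's demand is taken as 2.3 times the fish stock's unfiltered
#' BOD5 excretion (2160 mg O2 kg-1 fish day-1), spread over the water
#' volume and 24 h:
#' \eqn{DO_B = 2.3 \cdot BOD_5 \cdot W_n / (V \cdot 24 \cdot 1000)}.
#'
#' @param biomass total fish biomass, kg.
#' @param V water volume, m3 (> 0).
#' @inheritParams respiration_rate
#' @return g O2 m-3 h-1.
#' @examples
#' do_biofilter(1000, 150)  # 1.38
#' @export
do_biofilter <- function(biomass, V, params = default_parameters()) {
  if (any(biomass < 0)) stop("biomass must be non-negative", call. = FALSE)
  if (any(V <= 0)) stop("water volume must be positive", call. = FALSE)
  b <- params$biofilter
  b$demand_factor * b$bod5_excretion * biomass / (V * 24 * 1000)
}

#' Volumetric oxygen addition through pipe-flow aeration
#'
#' Agitation as water is pumped through the system adds
#' \eqn{DO_{PF} = PC \cdot f \cdot E \cdot OTR / V} where PC is the pump
#' cycle length, f the pumping frequency, E the efficiency and OTR the
#' oxygen transfer rate.  The volume basis V is a preset choice: the
#' published supplemental-demand figures use V = 1 m3 (per-cubic-metre
#' transfer, DO_PF = 18.4); the physically scaled variant divides by the
#' tank volume.
#'
#' @inheritParams respiration_rate
#' @return g O2 m-3 h-1.
#' @examples
#' do_pipe_flow(default_parameters())  # 18.4 (volume basis 1)
#' @export
do_pipe_flow <- function(params = default_parameters()) {
  a <- params$aeration
  if (a$volume_basis <= 0) stop("aeration volume basis must be positive", call. = FALSE)
  a$pump_cycle_h * a$pump_frequency_per_h * a$efficiency * a$otr / a$volume_basis
}

#' Supplemental oxygen demand
#'
#' Balance of the budget: the oxygen generator must supply whatever the
#' three consumption terms exceed the pipe-flow addition by,
#' \eqn{DO_{sup} = DO_{FR} + DO_B + DO_N - DO_{PF}}.  A negative value
#' (aeration alone exceeds demand) is reported as-is with an
#' `"aeration_surplus"` attribute rather than clamped.
#'
#' @param do_fr,do_n,do_b consumption terms, g O2 m-3 h-1 (>= 0).
#' @param do_pf pipe-flow addition, g O2 m-3 h-1 (>= 0).
#' @return g O2 m-3 h-1, with attribute `aeration_surplus` (logical).
#' @examples
#' supplemental_demand(74.55, 0, 0, 18.4)  # 56.15
#' @export
supplemental_demand <- function(do_fr, do_n, do_b, do_pf) {
  if (any(c(do_fr, do_n, do_b, do_pf) < 0)) {
    stop("budget components must be non-negative", call. = FALSE)
  }
  out <- do_fr + do_n + do_b - do_pf
  attr(out, "aeration_surplus") <- out < 0
  out
}

#' Hourly oxygen budget at a tank state
#'
#' Assembles all four flux terms and the supplemental demand for a given
#' temperature and weight under a parameter bundle (stocking density and
#' feeding ratio are derived from the bundle).
#'
#' @inheritParams respiration_rate
#' @return A one-row data frame (vectorized over T/W) with columns
#'   `do_fr`, `do_n`, `do_b`, `do_pf`, `do_sup`, `sd_kg_m3`, `biomass_kg`.
#' @export
oxygen_budget <- function(T, W, params = default_parameters(), warn = TRUE) {
  SD <- stocking_density(params, W)
  biomass <- params$tank$n_fish * W / 1000
  Fr <- feeding_ratio(W, params)
  do_fr <- do_fish_respiration(T, W, SD, params, warn = warn)
  do_n <- do_nitrification(T, Fr, W, params$tank$n_fish, params$tank$volume,
                           params)
  do_b <- do_biofilter(biomass, params$tank$volume, params)
  do_pf <- do_pipe_flow(params)
  data.frame(
    do_fr = do_fr, do_n = do_n, do_b = do_b, do_pf = do_pf,
    do_sup = as.numeric(supplemental_demand(do_fr, do_n, do_b, do_pf)),
    sd_kg_m3 = SD, biomass_kg = biomass
  )
}

#' Advance the dissolved-oxygen concentration by one time step
#'
#' Explicit Euler update \eqn{DO_t = DO_{t-1} + (dDO/dt) \, dt} in one of
#' two sign conventions:
#' \describe{
#'   \item{`as_printed`}{the rate is DO_FR + DO_B + DO_N - DO_PF, i.e. the
#'     unmet-demand rate; DO rises with consumption.  Kept verbatim because
#'     the source model states it this way.}
#'   \item{`physical`}{the rate is DO_PF + supplied - (DO_FR + DO_B + DO_N);
#'     `supplied` defaults to the budget's DO_sup (a generator meeting
#'     demand exactly, hence a flat trace).}
#' }
#' The result is floored at 0 with a warning; the model has no feedback
#' preventing negative concentrations.
#'
#' @param do_prev concentration at the previous step, g m-3 (>= 0).
#' @param budget a row as produced by [oxygen_budget()] (list or data frame
#'   with `do_fr`, `do_n`, `do_b`, `do_pf`, `do_sup`).
#' @param dt time step, h (> 0).
#' @param mode `"as_printed"` or `"physical"`.
#' @param supplied generator supply rate for physical mode, g m-3 h-1;
#'   defaults to `budget$do_sup` (clamped below at 0: the generator cannot
#'   remove oxygen).
#' @return concentration at the next step, g m-3.
#' @export
do_step <- function(do_prev, budget, dt = 1,
                    mode = c("physical", "as_printed"), supplied = NULL) {
  mode <- match.arg(mode)
  if (any(dt <= 0)) stop("dt must be positive", call. = FALSE)
  if (any(do_prev < 0)) stop("do_prev must be non-negative", call. = FALSE)
  cons <- budget$do_fr + budget$do_b + budget$do_n
  rate <- if (mode == "as_printed") {
    cons - budget$do_pf
  } else {
    if (is.null(supplied)) supplied <- pmax(budget$do_sup, 0)
    budget$do_pf + supplied - cons
  }
  out <- do_prev + rate * dt
  if (any(out < 0)) {
    warning("dissolved oxygen fell below 0; floored at 0", call. = FALSE)
    out <- pmax(out, 0)
  }
  out
}

#' Oxygen consumption from inlet/outlet sensor readings
#'
#' The measured mass-specific consumption across a tank passage:
#' \eqn{OC = (DO_{in} - DO_{out}) \cdot Q / W_n \cdot 1000} in
#' mg O2 kg-1 fish h-1, with Q the flow (m3 h-1) and W_n the biomass (kg).
#' A negative difference (outlet richer than inlet, i.e. in-tank aeration)
#' is returned as-is with a warning.
#'
#' @param do_in,do_out dissolved oxygen at tank inlet/outlet, mg L-1.
#' @param Q flow rate, m3 h-1 (>= 0).
#' @param biomass fish biomass in the tank, kg (> 0).
#' @return mg O2 kg-1 fish h-1.
#' @examples
#' oxygen_consumption_from_sensors(8, 6, 30, 600)  # 100
#' @export
oxygen_consumption_from_sensors <- function(do_in, do_out, Q, biomass) {
  if (any(biomass <= 0)) stop("biomass must be positive", call. = FALSE)
  if (any(Q < 0)) stop("flow rate must be non-negative", call. = FALSE)
  out <- (do_in - do_out) * Q / biomass * 1000
  if (any(out < 0)) {
    warning("negative consumption: outlet DO exceeds inlet DO", call. = FALSE)
  }
  out
}
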