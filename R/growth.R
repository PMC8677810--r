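#' Temperature limitation factor for food intake
#'
#' Bell-shaped factor in [0, 1], maximal (exactly 1) at the optimum
#' temperature:
#' \deqn{\tau = \exp\{-4.6 [(T_{opt} - T)/(T_{opt} - D_{low})]^4\}, T < T_{opt}}
#' \deqn{\tau = \exp\{-4.6 [(T - T_{opt})/(T_{max} - T_{opt})]^4\}, T \ge T_{opt}}
#' The below-optimum half-width \eqn{D_{low}} is selectable through
#' `growth$tau_low_denominator`: `"t_min"` (the symmetric cardinal form,
#' default) or `"t_max"` (the variant used by the reproduction preset, in
#' which both sides share the upper half-width since the ratio enters at an
#' even power).
#'
#' @param T water temperature, C (vectorized).
#' @param params a `ras_params` bundle.
#' @return dimensionless fraction in [0, 1].
#' @examples
#' temperature_factor(28)  # 1
#' temperature_factor(32)  # 0.9448
#' @export
temperature_factor <- function(T, params = default_parameters()) {
  g <- params$growth
  d_low <- if (g$tau_low_denominator == "t_min") {
    g$t_opt - g$t_min
  } else {
    g$t_max - g$t_opt   # |T_opt - T_max|; sign is lost at the 4th power
  }
  ifelse(T < g$t_opt,
         exp(-4.6 * ((g$t_opt - T) / d_low)^4),
         exp(-4.6 * ((T - g$t_opt) / (g$t_max - g$t_opt))^4))
}

#' Catabolism coefficient
#'
#' Fasting catabolism grows exponentially with temperature above the
#' feeding minimum: \eqn{K = k_{scale} K_{min} e^{s (T - T_{min})}}.
#' Below \eqn{T_{min}} the coefficient is held at \eqn{K_{min}} with a
#' warning (the model is not intended there).  `k_scale` is 1 for the
#' literature value and is refit by [calibrate_relative_feeding()].
#'
#' @inheritParams temperature_factor
#' @return g^(1-n) day-1.
#' @examples
#' catabolism_coefficient(15)  # 0.25
#' catabolism_coefficient(28)  # 0.30383
#' @export
catabolism_coefficient <- function(T, params = default_parameters()) {
  g <- params$growth
  if (any(T < g$t_min)) {
    warning("temperature below t_min; catabolism coefficient held at K_min",
            call. = FALSE)
  }
  g$k_scale * g$k_min * exp(g$s_const * (pmax(T, g$t_min) - g$t_min))
}

#' Dissolved-oxygen limitation factor for food intake
#'
#' Three stages: no effect above the critical level, linear decline
#' between the minimum and critical levels, feeding stops below the
#' minimum.  Both boundary points take the value of the permissive side
#' (continuity).
#'
#' @param DO dissolved oxygen, mg L-1 (>= 0, vectorized).
#' @inheritParams temperature_factor
#' @return dimensionless fraction in [0, 1].
#' @export
do_factor <- function(DO, params = default_parameters()) {
  if (any(DO < 0)) stop("DO must be non-negative", call. = FALSE)
  g <- params$growth
  out <- (DO - g$do_min) / (g$do_crit - g$do_min)
  pmin(pmax(out, 0), 1)
}

#' Unionized-ammonia limitation factor for food intake
#'
#' Mirror image of [do_factor()]: no effect below the critical
#' concentration, linear decline up to the maximum tolerated
#' concentration, feeding stops above it.
#'
#' @param NH3 unionized ammonia, mg L-1 (>= 0, vectorized).
#' @inheritParams temperature_factor
#' @return dimensionless fraction in [0, 1].
#' @export
ammonia_factor <- function(NH3, params = default_parameters()) {
  if (any(NH3 < 0)) stop("NH3 must be non-negative", call. = FALSE)
  g <- params$growth
  out <- (g$nh3_max - NH3) / (g$nh3_max - g$nh3_crit)
  pmin(pmax(out, 0), 1)
}

#' Photoperiod factor
#'
#' Daylight hours over the 12 h reference of a 12:12 light-dark cycle;
#' tilapia feed in daylight, so food consumption scales with it.  Exceeds
#' 1 for photoperiods above 12 h.
#'
#' @param photoperiod_h daylight hours, in [0, 24].
#' @return dimensionless, photoperiod / 12.
#' @export
photoperiod_factor <- function(photoperiod_h) {
  if (any(photoperiod_h < 0 | photoperiod_h > 24)) {
    stop("photoperiod_h must lie in [0, 24]", call. = FALSE)
  }
  photoperiod_h / 12
}

#' Feeding ratio as a function of fish weight
#'
#' Log-normal-shaped curve in weight,
#' \eqn{F_r = 17.02 \exp[-(\ln W + 1.14)^2 / 19.52]} percent of body mass
#' per day, peaking at about 0.32 g fry and declining toward harvest size.
#' In `table2` schedule mode a stepwise lookup in the reference feeding
#' table (interval midpoints) replaces the curve.
#'
#' @param W individual fish weight, g (> 0, vectorized).
#' @inheritParams temperature_factor
#' @return percent of body mass per day.
#' @examples
#' feeding_ratio(3)       # 13.17
#' feeding_ratio(226.25)  # 1.87
#' @export
feeding_ratio <- function(W, params = default_parameters()) {
  if (any(W <= 0)) stop("weight must be positive", call. = FALSE)
  fe <- params$feeding
  if (fe$schedule_mode == "table2") {
    tab <- fe$table2_schedule
    idx <- findInterval(W, c(tab$w_lo_g, Inf), rightmost.closed = FALSE)
    idx[idx < 1] <- 1
    idx[idx > nrow(tab)] <- nrow(tab)
    return(tab$feed_pct[idx])
  }
  fe$fr_amp * exp(-(log(W) + fe$fr_shift)^2 / fe$fr_width)
}

#' Daily bioenergetic growth rate
#'
#' Anabolism scaled by the four limitation factors minus catabolism:
#' \deqn{FGR = a \,\tau \kappa \delta \varphi \, h f W^m - K(T) W^n}
#' with a = 0.2919, h the food consumption coefficient, f the relative
#' feeding level, m and n the anabolism/catabolism weight exponents and
#' K(T) from [catabolism_coefficient()].  The rate may be negative
#' (weight loss) and is reported unclamped.  Note that with the literature
#' constants at face value the rate is negative for all weights above
#' about 0.2 g even at f = 1; see [calibrate_relative_feeding()].
#'
#' @param W individual fish weight, g (> 0).
#' @param T water temperature, C.
#' @param DO dissolved oxygen, mg L-1.
#' @param NH3 unionized ammonia, mg L-1.
#' @param photoperiod_h daylight hours.
#' @inheritParams temperature_factor
#' @param f_feed optional override of `params$growth$f_feed`.
#' @return g day-1, with the factors as attribute `factors`
#'   (tau, kappa, delta, phi, K).
#' @export
daily_growth_rate <- function(W, T, DO, NH3, photoperiod_h = 12,
                              params = default_parameters(), f_feed = NULL) {
  if (any(W <= 0)) stop("weight must be positive", call. = FALSE)
  g <- params$growth
  f <- if (is.null(f_feed)) g$f_feed else f_feed
  if (any(is.na(f))) {
    stop("relative feeding level f_feed is unset; set growth$f_feed or pass f_feed",
         call. = FALSE)
  }
  if (any(f < 0 | f > 1)) stop("f_feed must lie in [0, 1]", call. = FALSE)
  tau <- temperature_factor(T, params)
  kappa <- photoperiod_factor(photoperiod_h)
  delta <- do_factor(DO, params)
  phi <- ammonia_factor(NH3, params)
  K <- catabolism_coefficient(T, params)
  fgr <- g$anabolism_const * tau * kappa * delta * phi * g$h_food * f * W^g$m_exp -
    K * W^g$n_exp
  attr(fgr, "factors") <- data.frame(tau = tau, kappa = kappa, delta = delta,
                                     phi = phi, K = K)
  fgr
}

#' Daily feed mass for the stock
#'
#' \eqn{feed = F_r \cdot W_n \cdot N_F / 100000} kg day-1 (the 100,000
#' combines the percent in the feeding ratio with the g-to-kg conversion).
#'
#' @param Fr feeding ratio, percent of body mass per day.
#' @param W individual fish weight, g.
#' @param n_fish number of fish.
#' @return kg day-1.
#' @examples
#' daily_feed_mass(2.5, 100, 20000)  # 50
#' @export
daily_feed_mass <- function(Fr, W, n_fish) {
  if (any(c(Fr, W, n_fish) < 0)) {
    stop("feed inputs must be non-negative", call. = FALSE)
  }
  Fr * W * n_fish / 100000
}

#' Integrate individual growth over a horizon
#'
#' Daily explicit Euler accumulation \eqn{W_n = W_{n-1} + FGR_n} starting
#' from `W0`, with the limitation factors taken from the per-day
#' environment schedule.  Returns one record per day boundary (day 0 is
#' the stocking state), each carrying the growth rate, feeding ratio and
#' feed mass computed at that day's start weight.  If weight would fall
#' below 0.1 g the integration stops early and the result is flagged
#' (`attr(x, "truncated")`).
#'
#' @param W0 initial individual weight, g (> 0).
#' @param days horizon, days (>= 0).
#' @param env environment schedule from [environment_schedule()] covering
#'   `days` rows.
#' @inheritParams temperature_factor
#' @param f_feed optional override of `params$growth$f_feed`.
#' @return Data frame with columns `day` (0..days), `weight_g`,
#'   `fgr_g_day`, `feeding_ratio_pct`, `feed_kg_day`, `tau`, `kappa`,
#'   `delta`, `phi`; attribute `truncated` (logical).
#' @export
integrate_growth <- function(W0, days, env = environment_schedule(max(days, 1)),
                             params = default_parameters(), f_feed = NULL) {
  if (W0 <= 0) stop("W0 must be positive", call. = FALSE)
  days <- as.integer(days)
  if (days < 0) stop("days must be >= 0", call. = FALSE)
  if (days > 0 && nrow(env) < days) {
    stop("environment schedule does not cover the horizon (", nrow(env),
         " < ", days, " days)", call. = FALSE)
  }
  n_rec <- days + 1
  rec <- data.frame(day = 0:days, weight_g = NA_real_, fgr_g_day = NA_real_,
                    feeding_ratio_pct = NA_real_, feed_kg_day = NA_real_,
                    tau = NA_real_, kappa = NA_real_, delta = NA_real_,
                    phi = NA_real_)
  W <- W0
  truncated <- FALSE
  for (i in seq_len(n_rec)) {
    # env row for day i (record i-1 covers simulated day i); the final
    # record reuses the last day's conditions for its instantaneous fields
    e <- env[min(max(i, 1), nrow(env)), ]
    fgr <- daily_growth_rate(W, e$temperature_c, e$do_mg_l, e$nh3_mg_l,
                             e$photoperiod_h, params, f_feed)
    fac <- attr(fgr, "factors")
    Fr <- feeding_ratio(W, params)
    rec[i, -1] <- c(W, as.numeric(fgr), Fr,
                    daily_feed_mass(Fr, W, params$tank$n_fish),
                    fac$tau, fac$kappa, fac$delta, fac$phi)
    if (i <= days) {
      W <- W + as.numeric(fgr)
      if (W < 0.1) {
        truncated <- TRUE
        rec <- rec[seq_len(i), ]
        break
      }
    }
  }
  attr(rec, "truncated") <- truncated
  rec
}

# Exact mean of W^p over [lo, hi]: integral of the power divided by the
# interval length.
interval_mean_power <- function(lo, hi, p) {
  (hi^(p + 1) - lo^(p + 1)) / ((p + 1) * (hi - lo))
}

#' Calibrate the relative feeding level against a reference schedule
#'
#' Sweeps the relative feeding level f over the grid 0, 0.01, ..., 1.0 and
#' scores each value by the sum of squared deviations between the model's
#' mean growth rate over each reference weight interval and the reference
#' rate (interval means of \eqn{W^m} and \eqn{W^n} are taken in closed
#' form).  Calibration conditions are the optimum: reference temperature
#' (default 28 C, where tau = 1), DO above critical, ammonia below
#' critical, 12 h photoperiod.
#'
#' With the literature constants at face value no f on the grid achieves
#' positive growth, so `refine = TRUE` additionally profiles out the
#' catabolism rescale `k_scale` for each f (the objective is quadratic in
#' it, so the inner minimizer is closed-form, constrained positive).  The
#' shipped calibrated preset ([calibrated_growth_params()]) uses this
#' joint fit and records both values.
#'
#' @param reference data frame with columns `w_lo_g`, `w_hi_g`,
#'   `growth_g_day` (default [growth_reference_schedule()], the 28 C
#'   tank schedule).
#' @inheritParams temperature_factor
#' @param temperature calibration temperature, C (default 28).
#' @param refine also fit `k_scale` (joint fit); default FALSE.
#' @param f_grid grid of relative feeding levels (default 101 points).
#' @param c_over_a_max optional upper bound on the ratio of the fitted
#'   catabolism coefficient to the anabolism coefficient, used by
#'   [calibrated_growth_params()] to anchor the temperature optimum;
#'   `Inf` (default) leaves the joint fit unconstrained.
#' @return An object of class `ras_calibration`: list with `f_star`,
#'   `k_scale`, `objective`, and `grid` (data frame of f, k_scale,
#'   objective over the sweep).
#' @export
calibrate_relative_feeding <- function(reference = growth_reference_schedule(),
                                       params = default_parameters(),
                                       temperature = 28, refine = FALSE,
                                       f_grid = seq(0, 1, by = 0.01),
                                       c_over_a_max = Inf) {
  if (!is.data.frame(reference) || nrow(reference) == 0) {
    stop("reference schedule must be a non-empty data frame", call. = FALSE)
  }
  need <- c("w_lo_g", "w_hi_g", "growth_g_day")
  if (!all(need %in% names(reference))) {
    stop("reference schedule must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  g <- params$growth
  tau <- temperature_factor(temperature, params)
  K_T <- g$k_min * exp(g$s_const * (temperature - g$t_min))  # before k_scale
  A <- interval_mean_power(reference$w_lo_g, reference$w_hi_g, g$m_exp)
  B <- interval_mean_power(reference$w_lo_g, reference$w_hi_g, g$n_exp)
  target <- reference$growth_g_day
  # anabolism slope per unit f at the calibration conditions
  a1 <- g$anabolism_const * tau * 1 * 1 * 1 * g$h_food

  eval_f <- function(f) {
    a <- a1 * f
    if (refine) {
      # minimize sum((a A - c B - target)^2) over c = k_scale * K_T > 0,
      # optionally capped at c <= c_over_a_max * a
      c_hat <- sum(B * (a * A - target)) / sum(B^2)
      c_hat <- min(max(c_hat, 1e-9), c_over_a_max * a)
      c_hat <- max(c_hat, 1e-9)
      ks <- c_hat / K_T
    } else {
      ks <- g$k_scale
      c_hat <- ks * K_T
    }
    resid <- a * A - c_hat * B - target
    c(objective = sum(resid^2), k_scale = ks)
  }
  sweep <- t(vapply(f_grid, eval_f, c(objective = 0, k_scale = 0)))
  grid <- data.frame(f = f_grid, k_scale = sweep[, "k_scale"],
                     objective = sweep[, "objective"])
  best <- which.min(grid$objective)
  out <- list(f_star = grid$f[best], k_scale = grid$k_scale[best],
              objective = grid$objective[best], grid = grid,
              temperature = temperature, refined = refine)
  class(out) <- "ras_calibration"
  out
}

#' @export
print.ras_calibration <- function(x, ...) {
  cat("<ras_calibration>  f* =", format(x$f_star),
      " k_scale =", format(round(x$k_scale, 5)),
      " objective =", format(signif(x$objective, 5)),
      if (x$refined) " (joint fit)" else " (f only)", "\n")
  invisible(x)
}

#' Parameter bundle with the calibrated growth preset
#'
#' Runs the joint (f, k_scale) calibration against the reference feeding
#' schedule and returns the bundle with `growth$f_feed` and
#' `growth$k_scale` set to the fitted values.  Deterministic and cheap
#' (closed-form inner fit over a 101-point grid).
#'
#' The reconstruction has two anchors, both study conditions of the
#' source experiment: the reference growth-rate schedule, and the
#' reported growth optimum at the feeding-optimum temperature (28 C gave
#' the highest 150-day weight among 24--32 C).  The unconstrained joint
#' fit honours only the first and places the growth optimum at 26 C,
#' because near the optimum the quartic temperature factor is almost
#' flat while catabolism falls exponentially with temperature.  With
#' `anchor_optimum = TRUE` (default) the fit is therefore constrained so
#' that the growth rate at the optimum temperature dominates the rate at
#' every other studied temperature pointwise up to the marketable weight
#' (`w_max`), which pins the 150-day weight maximum to the optimum
#' temperature; `anchor_optimum = FALSE` returns the unconstrained fit.
#'
#' @inheritParams temperature_factor
#' @param anchor_optimum constrain the fit to reproduce the reported
#'   temperature optimum (default TRUE).
#' @param temps studied water temperatures defining the ordering
#'   constraint, C.
#' @param w_max weight up to which pointwise dominance is enforced, g
#'   (marketable weight).
#' @return A validated `ras_params` bundle with attribute `calibration`.
#' @export
calibrated_growth_params <- function(params = default_parameters(),
                                     anchor_optimum = TRUE,
                                     temps = c(24, 26, 28, 30, 32),
                                     w_max = 250) {
  g <- params$growth
  gamma <- Inf
  if (anchor_optimum) {
    # FGR(T_opt) - FGR(T) = a W^m (1 - tau(T)) - c W^n (1 - e^{s(T - T_opt)})
    # >= 0 for all W <= w_max  iff  c/a <= (1 - tau(T)) / (1 - e^{s dT}) *
    # w_max^{m-n} for every studied T below T_opt (above it both terms help).
    for (Tc in setdiff(temps, g$t_opt)) {
      den <- 1 - exp(g$s_const * (Tc - g$t_opt))
      if (den <= 0) next
      num <- 1 - temperature_factor(Tc, params)
      gamma <- min(gamma, num / den * w_max^(g$m_exp - g$n_exp))
    }
  }
  cal <- calibrate_relative_feeding(params = params, refine = TRUE,
                                    c_over_a_max = gamma)
  params$growth$f_feed <- cal$f_star
  params$growth$k_scale <- cal$k_scale
  out <- validate_params(unclass(params))
  attr(out, "calibration") <- cal
  out
}
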