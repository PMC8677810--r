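test_that("presets set density mode, aeration basis and tau variant", {
  pr <- repro_params()
  expect_equal(pr$tank$sd_mode, "fixed")
  expect_equal(pr$tank$sd_fixed, 100)
  expect_equal(pr$aeration$volume_basis, 1)
  expect_equal(do_pipe_flow(pr), 18.4)
  ph <- physical_params()
  expect_equal(ph$tank$sd_mode, "dynamic")
  expect_equal(ph$aeration$volume_basis, ph$tank$volume)
})

test_that("a one-day reproduction run holds the published start budget", {
  tr <- suppressWarnings(
    run_simulation(repro_params(), days = 1, f_feed = 0))
  expect_equal(nrow(tr$hourly), 24)
  expect_true(all(abs(tr$hourly$do_fr - 46.0643) < 1e-4))
  expect_true(all(tr$hourly$do_pf == 18.4))
  # biomass at stocking: 20000 x 3 g = 60 kg
  expect_equal(tr$hourly$biomass_kg[1], 60)
})

test_that("identical configurations give identical trajectories", {
  p <- calibrated_growth_params(repro_params())
  t1 <- suppressWarnings(run_simulation(p, days = 5))
  t2 <- suppressWarnings(run_simulation(p, days = 5))
  expect_identical(t1$daily, t2$daily)
  expect_identical(t1$hourly, t2$hourly)
  expect_identical(t1$meta$param_hash, t2$meta$param_hash)
})

test_that("budget terms stay non-negative and the balance closes row-wise", {
  tr <- calibrated_run()
  h <- tr$hourly
  expect_true(all(h$do_fr >= 0 & h$do_n >= 0 & h$do_b >= 0 & h$do_pf >= 0))
  closure <- h$do_sup + h$do_pf - (h$do_fr + h$do_n + h$do_b)
  expect_true(all(abs(closure) < 1e-9))
  expect_equal(nrow(h), 24 * tr$meta$days)
})

test_that("dynamic-density respiration per unit biomass is the specific rate", {
  p <- calibrated_growth_params(physical_params())
  tr <- suppressWarnings(run_simulation(p, days = 10))
  h <- tr$hourly
  env_T <- tr$meta$env$temperature_c[h$day]
  W_day <- tr$daily$weight_g[h$day]
  expect_equal(h$do_fr * p$tank$volume / h$biomass_kg,
               respiration_rate(env_T, W_day, p, warn = FALSE) / 1000,
               tolerance = 1e-12)
})

test_that("hourly demand accumulates 24 x the daily rate under constant conditions", {
  tr <- suppressWarnings(run_simulation(repro_params(), days = 1, f_feed = 0))
  h <- tr$hourly
  expect_equal(sum(h$do_fr + h$do_n + h$do_b), 24 * (h$do_fr[1] + h$do_n[1] + h$do_b[1]),
               tolerance = 1e-9)
})

test_that("summaries agree with the first and last trajectory rows", {
  tr <- calibrated_run()
  s <- summarize_trajectory(tr)
  h <- tr$hourly
  expect_equal(s$oxygen$start[s$oxygen$quantity == "do_fr"], h$do_fr[1])
  expect_equal(s$oxygen$end[s$oxygen$quantity == "do_sup"],
               h$do_sup[nrow(h)])
  expect_equal(unname(s$weight["end"]), tr$daily$weight_g[nrow(tr$daily)])
  # totals minus aeration equal the supplemental demand row-wise
  tot <- s$oxygen[s$oxygen$quantity == "total", ]
  sup <- s$oxygen[s$oxygen$quantity == "do_sup", ]
  expect_equal(tot$start - h$do_pf[1], sup$start, tolerance = 1e-9)
})

test_that("temperature sweep reproduces the fixed-weight respiration series", {
  # hold weight at 3 g (f = 0 disables anabolism but catabolism would
  # shrink the fish; a 1-day sweep keeps the start weight throughout)
  sw <- suppressWarnings(
    temperature_sweep(repro_params(), c(24, 26, 28, 30, 32), days = 1,
                      f_feed = 0))
  start_fr <- vapply(sw, function(s)
    s$oxygen$start[s$oxygen$quantity == "do_fr"], 0)
  expect_equal(unname(start_fr), c(30.6523, 36.7923, 46.0643, 58.4863, 74.0523),
               tolerance = 1e-4)
  # single temperature equals run + summarize composition
  one <- suppressWarnings(
    temperature_sweep(repro_params(), 28, days = 1, f_feed = 0))
  expect_equal(length(one), 1)
  expect_equal(one[["28"]]$oxygen,
               summarize_trajectory(suppressWarnings(run_simulation(
                 repro_params(), days = 1, f_feed = 0)))$oxygen)
})

test_that("150-day growth is maximized at the optimum temperature", {
  pc <- calibrated_growth_params(repro_params())
  sw <- suppressWarnings(
    temperature_sweep(pc, c(24, 26, 28, 30, 32), days = 150))
  fw <- attr(sw, "final_weights")
  expect_equal(names(fw)[which.max(fw)], "28")
  # and the coldest/warmest extremes grow worst, as reported
  expect_true(all(fw[c("24", "32")] < fw[c("26", "30")]))
})

test_that("long reproduction runs bottom out at the respiration vertex", {
  pc <- calibrated_growth_params(repro_params())
  tr <- suppressWarnings(run_simulation(pc, days = 150))
  h <- tr$hourly
  # do_fr decreases with weight up to the vertex, so its minimum over the
  # run occurs at the largest start-of-day weight reached (if below the
  # vertex) and never undercuts the vertex value
  W_used <- tr$daily$weight_g[h$day]
  W_at_min <- W_used[which.min(h$do_fr)]
  vertex <- respiration_minimum_weight(28)
  expect_equal(W_at_min, min(max(W_used), vertex), tolerance = 1e-6)
  expect_true(all(h$do_fr >= do_fish_respiration(28, vertex, 100, warn = FALSE) - 1e-9))
})
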