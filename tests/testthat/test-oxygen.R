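# Frozen expected values were derived term-by-term by hand from the
# respiration polynomial and the nitrification/biofilter arithmetic
# before implementation.

test_that("respiration polynomial matches hand-evaluated values", {
  expect_equal(respiration_rate(28, 3, warn = FALSE), 460.643, tolerance = 1e-6)
  expect_equal(respiration_rate(24, 3, warn = FALSE), 306.523, tolerance = 1e-6)
  expect_equal(respiration_rate(28, 226.25, warn = FALSE), 120.13094,
               tolerance = 1e-6)
  expect_warning(respiration_rate(28, 3), "weight outside")
  expect_warning(respiration_rate(20, 50), "temperature outside")
  expect_error(respiration_rate(NA, 3), "finite")
})

test_that("volumetric respiration scales with stocking density", {
  expect_equal(do_fish_respiration(28, 3, 100, warn = FALSE), 46.0643,
               tolerance = 1e-4)
  expect_equal(do_fish_respiration(32, 3, 100, warn = FALSE), 74.0523,
               tolerance = 1e-4)
  expect_equal(do_fish_respiration(28, 3, 0, warn = FALSE), 0)
  # linear in SD
  expect_equal(do_fish_respiration(28, 50, 200, warn = FALSE),
               2 * do_fish_respiration(28, 50, 100, warn = FALSE))
  expect_error(do_fish_respiration(28, 3, -1, warn = FALSE), "non-negative")
})

test_that("weight of minimum respiration equals the quadratic vertex", {
  expect_equal(respiration_minimum_weight(28), 223.5714, tolerance = 1e-4)
  expect_equal(respiration_minimum_weight(24), 163.5714, tolerance = 1e-4)
  expect_equal(respiration_minimum_weight(2.75 / 0.21), 0, tolerance = 1e-9)
  # oracle: dense grid scan over W agrees with the vertex to grid resolution
  for (Tc in c(24, 28, 32)) {
    W <- seq(1, 300, by = 0.01)
    fr <- respiration_rate(Tc, W, warn = FALSE)
    expect_equal(W[which.min(fr)], respiration_minimum_weight(Tc),
                 tolerance = 0.011)
  }
})

test_that("nitrification coefficient follows the 1.08 temperature law", {
  expect_equal(nitrification_coefficient(20), 0.1)
  expect_equal(nitrification_coefficient(28), 0.1850930, tolerance = 1e-6)
  expect_equal(nitrification_coefficient(24), 0.1360489, tolerance = 1e-6)
  # strictly increasing in T, and demand doubles about every 9 C
  Ts <- seq(10, 35, length.out = 200)
  expect_true(all(diff(nitrification_coefficient(Ts)) > 0))
  expect_equal(nitrification_coefficient(24 + 9.006) /
                 nitrification_coefficient(24), 2, tolerance = 1e-3)
})

test_that("nitrification rate and demand follow the TAN chain", {
  expect_equal(nitrification_rate(13.167, 3, 20000), 0.98753, tolerance = 1e-4)
  expect_equal(nitrification_rate(2.5, 100, 20000), 6.25)
  expect_equal(nitrification_rate(5, 0, 20000), 0)
  expect_equal(do_nitrification(24, 13.167, 3, 20000, 150), 0.0040933,
               tolerance = 1e-4)
  expect_equal(do_nitrification(24, 0, 3, 20000, 150), 0)
  # only K_NR depends on temperature
  expect_equal(do_nitrification(20, 10, 50, 20000, 150) /
                 do_nitrification(28, 10, 50, 20000, 150),
               1.08^-8, tolerance = 1e-9)
  expect_error(do_nitrification(24, 10, 50, 20000, 0), "volume")
})

test_that("biofilter demand is 2.3 x BOD5 over volume and day", {
  expect_equal(do_biofilter(1000, 150), 1.38)
  expect_equal(do_biofilter(60, 150), 0.0828)
  expect_equal(do_biofilter(0, 150), 0)
  expect_error(do_biofilter(-1, 150), "non-negative")
})

test_that("pipe-flow aeration follows PC f E OTR / V", {
  expect_equal(do_pipe_flow(default_parameters(aeration = list(volume_basis = 1))),
               18.4)
  expect_equal(do_pipe_flow(default_parameters(aeration = list(volume_basis = 150))),
               18.4 / 150, tolerance = 1e-9)
  expect_equal(do_pipe_flow(default_parameters(aeration = list(efficiency = 0))), 0)
})

test_that("supplemental demand closes the oxygen balance", {
  expect_equal(as.numeric(supplemental_demand(74.55, 0, 0, 18.4)), 56.15)
  expect_equal(as.numeric(supplemental_demand(46.49, 0, 0, 18.4)), 28.09)
  expect_equal(as.numeric(supplemental_demand(0, 0, 0, 0)), 0)
  s <- supplemental_demand(1, 0.1, 0.2, 18.4)
  expect_true(attr(s, "aeration_surplus"))
  # closure property on random budgets
  set.seed(7)
  for (i in 1:50) {
    x <- runif(4, 0, 80)
    s <- as.numeric(supplemental_demand(x[1], x[2], x[3], x[4]))
    expect_equal(s + x[4] - (x[1] + x[2] + x[3]), 0, tolerance = 1e-9)
  }
})

test_that("DO stepping telescopes and floors at zero", {
  b <- list(do_fr = 10, do_n = 1, do_b = 2, do_pf = 13, do_sup = 0)
  # zero net rate leaves the concentration unchanged
  expect_equal(do_step(6, b, mode = "as_printed"), 6)
  # as_printed over n constant steps telescopes to DO0 + n dt rate
  b2 <- list(do_fr = 3, do_n = 0.5, do_b = 0.5, do_pf = 1, do_sup = 3)
  x <- 2
  for (i in 1:10) x <- do_step(x, b2, dt = 0.5, mode = "as_printed")
  expect_equal(x, 2 + 10 * 0.5 * (3 + 0.5 + 0.5 - 1), tolerance = 1e-12)
  # physical mode with supply equal to demand is stationary
  b3 <- list(do_fr = 46.49, do_n = 0, do_b = 0, do_pf = 18.4, do_sup = 28.09)
  expect_equal(do_step(6, b3, mode = "physical"), 6)
  # floor with warning
  b4 <- list(do_fr = 1.5, do_n = 0, do_b = 0, do_pf = 0.5, do_sup = 0)
  expect_warning(out <- do_step(0.5, b4, mode = "physical", supplied = 0),
                 "floored")
  expect_equal(out, 0)
  expect_error(do_step(1, b4, dt = 0), "dt")
})

test_that("sensor consumption formula matches the inlet/outlet arithmetic", {
  expect_equal(oxygen_consumption_from_sensors(8, 6, 30, 600), 100)
  expect_equal(oxygen_consumption_from_sensors(7, 7, 30, 600), 0)
  expect_warning(oc <- oxygen_consumption_from_sensors(6, 8, 30, 600),
                 "negative consumption")
  expect_equal(oc, -100)
  expect_error(oxygen_consumption_from_sensors(8, 6, 30, 0), "biomass")
})
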