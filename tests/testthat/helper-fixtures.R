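# Shared fixtures: parameter bundles and a short calibrated run used by
# several test files.  Everything is generated in code; no stored data.

repro_params <- function() {
  apply_preset(default_parameters(), "reproduction")
}

physical_params <- function() {
  apply_preset(default_parameters(), "physical")
}

# Small calibrated run for round-trip tests: 40 days keeps suites fast
# while giving the parity fits non-degenerate variation.
calibrated_run <- local({
  cache <- NULL
  function(days = 40) {
    if (is.null(cache) || cache$meta$days != days) {
      p <- calibrated_growth_params(repro_params())
      cache <<- suppressWarnings(run_simulation(p, days = days))
    }
    cache
  }
})
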