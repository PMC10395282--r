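# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# small desk route + telemetry + one recording (default SNR)
small_sim <- function() memo("small_sim", {
  route <- simulate_route(3000, 5, seed = 101)
  tel <- simulate_telemetry(route, seed = 101)
  sim <- simulate_recording(route, tel, subject = subject_config(),
                            seed = 102)
  sim$route <- route
  sim$telemetry <- tel
  sim
})

# noiseless, oscillation-free variant for exact recovery checks
clean_sim <- function() memo("clean_sim", {
  route <- simulate_route(3000, 5, seed = 103)
  tel <- simulate_telemetry(route, seed = 103)
  cfg <- subject_config(snr = Inf, alpha_amp = 0, theta_amp = 0,
                        amp_jitter_sd = 0)
  sim <- simulate_recording(route, tel, subject = cfg, seed = 104)
  sim$route <- route
  sim$telemetry <- tel
  sim$cfg <- cfg
  sim
})
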