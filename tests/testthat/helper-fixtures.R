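# shared fixtures, built once per test run and memoised
.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# full-size synthetic season and its mixed-model fit (the expensive pair)
shared_obs <- function() memo("obs", generate_observations(simulation_config(seed = 42)))
shared_fit <- function() memo("fit", fit_landing_glmm(shared_obs()))

# compact season for tests that refit (cheaper glmer calls)
small_obs <- function(seed = 99, n = 1500)
  memo(paste0("small", seed, "_", n),
       generate_observations(simulation_config(n_attempts = n, seed = seed)))

guillemot_ln <- list(ledge = "long_narrow", species = "guillemot", height = "h3")
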