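# Shared fixtures: benchmarks and trained models are expensive, so they
# are built once per test session and cached.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# compact planted-lead task (2.56 s at 100 Hz) for module-level tests
small_bench <- function() memo("small_bench",
  planted_lead_benchmark(n_train = 160, n_test = 80, input_length = 256,
                         fs = 100, seed = 0))

small_model <- function() memo("small_model", {
  bm <- small_bench()
  cfg <- ecgnet_config(n_leads = 12, input_length = 256, seed = 0)
  ecgnet(bm$x_train, bm$y_train, cfg, epochs = 10, seed = 0)
})

# full-scale planted benchmark (2.56 s at 400 Hz, n = 500/200)
full_bench <- function() memo("full_bench",
  planted_lead_benchmark(n_train = 500, n_test = 200, input_length = 1024,
                         fs = 400, seed = 0))

full_model <- function() memo("full_model", {
  bm <- full_bench()
  cfg <- ecgnet_config(n_leads = 12, input_length = 1024, seed = 0)
  ecgnet(bm$x_train, bm$y_train, cfg, epochs = 20, seed = 0)
})

# tiny 2-lead configuration for gradient/oracle work
toy_config <- function(...) {
  ecgnet_config(n_leads = 2, input_length = 16, enc_channels = 2,
                enc_kernel = 5, trunk_blocks = 2, trunk_channels = 3,
                trunk_kernel = 3, pool = 2, seed = 3, ...)
}

toy_model <- function(...) cardiolens:::build_ecgnet(toy_config(...))

random_input <- function(n, L, T, seed = 1) {
  set.seed(seed)
  array(stats::rnorm(n * L * T), c(n, L, T))
}
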