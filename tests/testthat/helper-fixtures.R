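# Small fixtures shared across the test files. Everything is built in
# code; simulations use short horizons so the default suite stays fast.

tiny_reversal <- function(horizon = 60, uncertainty = "low", ...) {
  make_environment("reversal", horizon = horizon, uncertainty = uncertainty,
                   ...)
}

tiny_cfg <- function(m = 40, generations = 60, ...) {
  evo_config(m = m, generations = generations, ...)
}

# deterministic social-info history: one record per step built from
# explicit actions/rewards
info_hist_from <- function(..., k = 2) {
  steps <- list(...)
  lapply(steps, function(s) social_info(s$actions, s$rewards, k))
}
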