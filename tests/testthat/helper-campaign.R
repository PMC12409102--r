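# Small campaign configurations for cheap structural tests; analysis-grade
# tests use the full defaults.
small_config <- function(seed = 1L, seasons = c("wet", "dry"), ...) {
  synthetic_config(seed = seed, seasons = seasons, n_trees_per_stratum = 6L,
                   leaves_per_branch = 3L, ...)
}

# A clean yield table built through the exact forward model (no noise, no
# corruption): states drawn on a grid so that all yields are positive.
clean_yield_table <- function(n = 100) {
  ql <- seq(0.05, 0.95, length.out = n)
  npqt <- seq(0.1, 6, length.out = n)
  cbind(forward_fluorescence(ql, npqt), ql_true = ql, npqt_true = npqt)
}
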