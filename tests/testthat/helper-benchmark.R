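# The full simulation benchmark is reused by several acceptance-style
# tests; compute each grid once per test run.
.bench_cache <- new.env(parent = emptyenv())

benchmark_grid <- function(T) {
  key <- paste0("T", T)
  if (is.null(.bench_cache[[key]])) {
    sim <- simulate_pairs(T = T, delays = -2:2,
                          noise_sds = c(0.1, 0.2, 0.3),
                          n_pairs_per_cell = 1000, frac_null = 0.5,
                          seed = 20170 + T)
    .bench_cache[[key]] <- evaluate_methods(sim)
  }
  .bench_cache[[key]]
}

# aggregate sensitivity over true pairs with nonzero delay, and
# specificity over all null pairs, per method
benchmark_rates <- function(bench) {
  calls <- bench$calls
  by_method <- split(calls, calls$method)
  list(
    sens_nonzero = vapply(by_method, function(d)
      mean(d$called[d$is_associated & !is.na(d$true_delay) &
                      d$true_delay != 0]), numeric(1)),
    sens_all = vapply(by_method, function(d)
      mean(d$called[d$is_associated]), numeric(1)),
    specificity = vapply(by_method, function(d)
      mean(!d$called[!d$is_associated]), numeric(1)))
}
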