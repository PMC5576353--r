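# Shared benchmark computations for the acceptance-style tests.  The
# reconstruction conditions are expensive, so they are computed once per
# test run and memoised in this environment.

.bench_cache <- new.env(parent = emptyenv())

bench_targets <- function() {
  if (is.null(.bench_cache$targets)) {
    .bench_cache$targets <- make_benchmark(101)
  }
  .bench_cache$targets
}

bench_control <- function() engine_control(n_hops = 6)

# canonical study conditions over the benchmark, all at base_seed 50
bench_conditions <- function() list(
  fullmap_ss = experiment_condition(min_sep = 1, use_ss = TRUE,
                                    n_models = 20),
  c_sep6 = experiment_condition(min_sep = 6, n_models = 20),
  ss_sep6 = experiment_condition(min_sep = 6, use_ss = TRUE,
                                 n_models = 20),
  nc_sep6 = experiment_condition(min_sep = 6, use_noncontacts = TRUE,
                                 n_models = 20),
  c_sep12 = experiment_condition(min_sep = 12, n_models = 5),
  c_sep24 = experiment_condition(min_sep = 24, n_models = 5)
)

bench_rows <- function(name) {
  if (is.null(.bench_cache[[name]])) {
    cond <- bench_conditions()[[name]]
    .bench_cache[[name]] <- run_condition(bench_targets(), cond,
                                          base_seed = 50,
                                          control = bench_control())
  }
  .bench_cache[[name]]
}
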