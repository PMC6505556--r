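# Memoised scenario runs shared across test files. Full-scale runs (31
# elements, 10 flapping periods at dt = 1e-5 s) take a few seconds each,
# so each is computed once per test session.

.run_cache <- new.env(parent = emptyenv())

cached_run <- function(name, n_elements = 31, rotation_rate = NULL,
                       short = FALSE) {
  key <- paste(name, n_elements, rotation_rate %||% "default",
               if (short) "short" else "full", sep = "|")
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  kin <- if (short) {
    kinematics_spec(total_periods = 7, analysis_periods = 3, dt = 2e-5)
  } else NULL
  run <- run_scenario(name, n_elements = n_elements, kin = kin,
                      rotation_rate = rotation_rate)
  .run_cache[[key]] <- run
  run
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cached_spike_summary <- function(alpha = c(0, pi / 8, pi / 4, 3 * pi / 8, pi / 2)) {
  key <- paste("spikes", paste(signif(alpha, 6), collapse = ","), sep = "|")
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  out <- encode_runs(cached_run("cs_flap"), cached_run("cs_rot"),
                     neural_filter(), alpha = alpha)
  .run_cache[[key]] <- out
  out
}
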