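# Shared fixtures: parameter sets and small synthetic inputs built in code.

# Experiment-A control means (literature-calibrated reference)
exp_a_params <- function() reference_params("A")

# IPSC-shaped benchmark parameters (identifiable rates)
bench_params <- function() reference_params("benchmark")

# a quick noiseless single-event trace from given params
noiseless_event <- function(params = bench_params(), pre = 20, post = 300) {
  make_event_trace(params, acq = acquisition_spec(noise_sd = 0),
                   pre_event_ms = pre, post_event_ms = post, filter = FALSE)
}

# small fit configuration for fast tests
quick_config <- function(..., n_starts = 6, max_iterations = 600, seed = 1) {
  fit_config(n_starts = n_starts, max_iterations = max_iterations,
             seed = seed, ...)
}

# synthetic fit-table rows drawn straight from a reference distribution
# (stands in for fitted parameters when testing the statistics layer)
synthetic_fit_table <- function(n, condition = "control", seed = 1,
                                days = 3, reference =
                                  control_reference("benchmark")) {
  tbl <- sample_params(reference, n = n, seed = seed)
  tbl$condition <- condition
  tbl$cell <- paste0(condition, "_c", rep_len(1:5, n))
  tbl$day <- paste0("day", sort(rep_len(seq_len(days), n)))
  tbl$accepted <- TRUE
  tbl
}
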