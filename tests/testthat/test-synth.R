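# Synthetic-data generator: parameter draws, event traces, Poisson trains,
# pseudo-Voigt amplitude sampling, multi-condition datasets.

test_that("zero-SD references reproduce the means exactly", {
  ref <- control_reference("A")
  ref$sd <- 0
  draws <- sample_params(ref, n = 5, seed = 1)
  for (r in 1:5)
    expect_equal(unlist(draws[r, fittable_params()]),
                 stats::setNames(ref$mean, ref$parameter),
                 tolerance = 1e-15)
})

test_that("around-reference draws centre on the truncated-normal means", {
  ref <- control_reference("A")
  n <- 10000
  draws <- sample_params(ref, n = n, seed = 2)
  # resampling into [0, inf) realizes a zero-truncated normal whose mean is
  # m + s * dnorm(m/s) / pnorm(m/s); the published SDs are large relative
  # to the means, so the truncation shift is part of the oracle
  for (pm in setdiff(fittable_params(), c("tau_r", "phi"))) {
    x <- draws[[pm]]
    m <- ref$mean[ref$parameter == pm]
    s <- ref$sd[ref$parameter == pm]
    m_trunc <- m + s * stats::dnorm(m / s) / stats::pnorm(m / s)
    sd_trunc <- s * sqrt(1 + (m / s) * stats::dnorm(m / s) /
                           stats::pnorm(m / s) -
                           (stats::dnorm(m / s) / stats::pnorm(m / s))^2)
    expect_lt(abs(mean(x) - m_trunc), 4 * sd_trunc / sqrt(n))
    expect_true(all(x >= 0))
  }
  expect_true(all(draws$phi > 0 & draws$phi < 2))
  expect_true(all(draws$tau_r < draws$tau_d))
  expect_true(all(draws$tau_r > 0))
})

test_that("log-uniform draws span at least four decades per parameter", {
  ref <- control_reference("A")
  draws <- sample_params(ref, n = 10000, mode = "log-uniform-range",
                         seed = 3)
  for (pm in setdiff(fittable_params(), c("phi", "tau_r"))) {
    span <- log10(max(draws[[pm]])) - log10(min(draws[[pm]]))
    expect_gte(span, 4)
  }
  expect_true(all(draws$tau_r < draws$tau_d))
  expect_true(all(draws$phi < 2))
})

test_that("noiseless unfiltered traces equal the model current sample-for-sample", {
  p <- bench_params()
  tr <- noiseless_event(p, pre = 10, post = 200)
  post <- tr$t >= 10
  expect_identical(tr$i[!post], rep(0, sum(!post)))
  expect_equal(tr$i[post], analytic_current(p, tr$t[post] - 10),
               tolerance = 1e-12)
  expect_equal(attr(tr, "onset_ms"), 10)
})

test_that("baseline noise has the requested standard deviation", {
  acq <- acquisition_spec(noise_sd = 2, filter_cutoff = NA)
  tr <- make_event_trace(bench_params(), acq = acq, pre_event_ms = 1000,
                         post_event_ms = 50, seed = 4, filter = FALSE)
  base <- tr$i[tr$t < 1000]
  expect_gt(length(base), 9000)
  expect_lt(abs(stats::sd(base) - 2) / 2, 0.15)
})

test_that("trace generation is bit-for-bit reproducible under a seed", {
  a <- make_event_trace(bench_params(), seed = 11)
  b <- make_event_trace(bench_params(), seed = 11)
  expect_identical(a$i, b$i)
  c <- make_event_trace(bench_params(), seed = 12)
  expect_false(identical(a$i, c$i))
})

test_that("low-pass filtering reduces the noise bandwidth", {
  p <- bench_params()
  raw <- make_event_trace(p, acq = acquisition_spec(noise_sd = 3,
                                                    filter_cutoff = NA),
                          seed = 5, filter = FALSE)
  flt <- make_event_trace(p, acq = acquisition_spec(noise_sd = 3,
                                                    filter_cutoff = 2000),
                          seed = 5, filter = TRUE)
  sd_raw <- stats::sd(raw$i[raw$t < 20])
  sd_flt <- stats::sd(flt$i[flt$t < 20])
  expect_lt(sd_flt, sd_raw)
})

test_that("Poisson event trains have the expected event count and flags", {
  tr <- make_event_train(freq_hz = 1.5, duration_s = 200, seed = 6,
                         acq = acquisition_spec(noise_sd = 1))
  n <- nrow(tr$events)
  expect_lt(abs(n - 300), 3 * sqrt(300))
  # overlap bookkeeping: onsets closer than 20 ms are flagged
  gaps <- diff(tr$events$onset_ms)
  close_prev <- c(Inf, gaps) < 20
  close_next <- c(gaps, Inf) < 20
  expect_identical(tr$events$overlapping, close_prev | close_next)
})

test_that("a vanishing event rate yields an empty event list", {
  tr <- make_event_train(freq_hz = 1e-9, duration_s = 5, seed = 7,
                         acq = acquisition_spec(noise_sd = 1))
  expect_identical(nrow(tr$events), 0L)
  expect_gt(nrow(tr$trace), 0)
})

test_that("event amplitudes in a train hit the sampled peaks", {
  tr <- make_event_train(freq_hz = 0.5, duration_s = 30,
                         amplitude_sampler = function(n) rep(40, n),
                         acq = acquisition_spec(noise_sd = 0), seed = 8,
                         min_separation_ms = 400)
  for (on in tr$events$onset_ms) {
    seg <- tr$trace$i[tr$trace$t >= on & tr$trace$t <= on + 100]
    expect_equal(max(abs(seg)), 40, tolerance = 0.02)
  }
})

test_that("pseudo-Voigt sampling has the right centre and mode", {
  # pure Gaussian branch, centre far from zero: mean within 3 SE of x0
  pv <- list(a = 1, b = 5, c = 0, x0 = 100)
  x <- sample_peak_amplitudes(pv, 50000, seed = 9)
  expect_lt(abs(mean(x) - 100), 3 * 5 / sqrt(50000))
  # published NLS parameter set: empirical mode within +/- 2 pA of x0
  x2 <- sample_peak_amplitudes(pv_reference("A", "nls"), 50000, seed = 10)
  d <- stats::density(x2, from = 0, to = 200, n = 2048)
  mode_est <- d$x[which.max(d$y)]
  expect_lt(abs(mode_est - 42.5906), 2)
  expect_true(all(x2 > 0))
})

test_that("single pseudo-Voigt draws are reproducible", {
  pv <- pv_reference("B", "control")
  expect_identical(sample_peak_amplitudes(pv, 1, seed = 3),
                   sample_peak_amplitudes(pv, 1, seed = 3))
  expect_error(sample_peak_amplitudes(list(a = 1, b = -1, c = 0, x0 = 10),
                                      5), "invalid")
})

test_that("matched condition specs give matched ground-truth distributions", {
  ds <- make_condition_dataset(
    condition_spec("control"), condition_spec("blocked"),
    n_events_per_condition = 500, seed = 12, traces = FALSE)
  ev <- ds$events
  for (pm in fittable_params()) {
    ks <- suppressWarnings(stats::ks.test(
      ev[[pm]][ev$condition == "control"],
      ev[[pm]][ev$condition == "blocked"]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("GEPH scaling propagates quadratically to ground-truth peaks", {
  ref <- control_reference("benchmark")
  ref$sd <- 0 # all-else-equal, noiseless comparison
  ds <- make_condition_dataset(
    condition_spec("control"),
    condition_spec("blocked", geph_scale = 0.43),
    n_events_per_condition = 3, reference = ref, seed = 13,
    traces = FALSE)
  m <- tapply(ds$events$true_peak_pa, ds$events$condition, mean)
  expect_equal(unname(m["blocked"] / m["control"]), 0.43^2,
               tolerance = 1e-6)
})

test_that("a manifest plus seed regenerates the dataset exactly", {
  ds <- make_condition_dataset(
    condition_spec("control", n_cells = 2, n_days = 2),
    condition_spec("nls", geph_scale = 0.7, n_cells = 2, n_days = 2),
    n_events_per_condition = 4, seed = 14, traces = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  write_manifest(ds, path)
  ds2 <- regenerate_dataset(read_manifest(path))
  expect_equal(dplyr::select(ds2$events, -"trace"),
               dplyr::select(ds$events, -"trace"), tolerance = 1e-12)
  expect_identical(ds2$events$trace[[1]]$i, ds$events$trace[[1]]$i)
})
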