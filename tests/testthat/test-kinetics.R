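# Kinetic model: conductance, steady states, closed form vs ODE, scaling.

test_that("conductance is zero at onset and peaks at the analytic time", {
  p <- syn_params(w = 1, tau_r = 1, tau_d = 4, beta = 1, alpha_f = 1,
                  alpha_b = 0.1, phi = 1, GEPH = 1, h = 1, h1 = 1)
  expect_identical(conductance(0, p), 0)
  # t* = tau_r tau_d/(tau_d - tau_r) log(tau_d/tau_r) = (4/3) log 4
  t_star <- conductance_peak_time(p)
  expect_equal(t_star, 4 / 3 * log(4), tolerance = 1e-12)
  # dense grid search confirms the analytic argmax
  grid <- seq(0, 20, by = 1e-3)
  expect_equal(grid[which.max(conductance(grid, p))], t_star,
               tolerance = 1e-3)
  expect_true(all(conductance(grid, p) >= 0))
})

test_that("conductance peak for calibrated control parameters matches a brute-force maximum", {
  p <- exp_a_params() # w = 8.7916e-4, tau_d = 55.93, tau_r = 0.794
  peak_formula <- conductance(conductance_peak_time(p), p)
  grid <- seq(0, 300, by = 0.01)
  peak_grid <- max(conductance(grid, p))
  expect_equal(peak_formula, peak_grid, tolerance = 1e-4)
})

test_that("degenerate time constants are rejected", {
  expect_error(syn_params(w = 1, tau_r = 4, tau_d = 4, beta = 1,
                          alpha_f = 1, alpha_b = 0.1, phi = 1, GEPH = 1,
                          h = 1, h1 = 1), "tau_r")
  expect_error(update_params(bench_params(), tau_r = 50), "tau_r")
})

test_that("NLG2 steady state solves the Michaelis-Menten balance", {
  expect_equal(nlg2_steady_state(2, 1), 1)
  expect_equal(nlg2_steady_state(5, 2 - 1e-12), 0, tolerance = 1e-10)
  expect_equal(nlg2_steady_state(2.2645, 0.3477),
               2.2645 * (2 - 0.3477) / (2 * 0.3477), tolerance = 1e-12)
  expect_equal(nlg2_steady_state(2.2645, 0.3477), 5.381, tolerance = 1e-3)
  expect_error(nlg2_steady_state(1, 2.5), "phi")
  expect_error(nlg2_steady_state(1, 0), "phi")
})

test_that("receptor steady state is h GEPH / h1", {
  expect_equal(ry_steady_state(0.3, 0.3, 1.7), 1.7)
  expect_equal(ry_steady_state(0.5, 2, 0), 0)
  expect_equal(ry_steady_state(0.0193, 0.1279, 2.2645), 0.3417,
               tolerance = 1e-3)
  expect_error(ry_steady_state(1, 0, 1), "h1")
})

test_that("relaxing the subcellular ODEs reaches the analytic steady states", {
  p <- exp_a_params()
  nlg2_ss <- nlg2_steady_state(p$GEPH, p$phi)
  ry_ss <- ry_steady_state(p$h, p$h1, p$GEPH)
  # negligible drive; start both pools away from equilibrium and integrate
  # for 20 time constants of the slower pool
  p0 <- update_params(p, w = 1e-12)
  t_end <- 20 / min(p$phi, p$h1)
  sim <- simulate_ode(p0, seq(0, t_end, length.out = 200),
                      init = c(N = 0, NLG2 = 2 * nlg2_ss, Ry = 0.2 * ry_ss))
  expect_equal(sim$NLG2[nrow(sim)], nlg2_ss, tolerance = 1e-3)
  expect_equal(sim$Ry[nrow(sim)], ry_ss, tolerance = 1e-3)
  expect_true(all(sim$N >= 0 & sim$NLG2 >= 0 & sim$Ry >= 0))
})

test_that("instantaneous current follows c1 N Ry (v - erev)", {
  p <- bench_params()
  expect_equal(syn_current(0, 3, p), 0)
  expect_equal(syn_current(2, 0.5, update_params(p, v = 0, erev = 0)), 0)
  p1 <- update_params(p, v = -70, erev = 0, c1 = 1)
  expect_equal(syn_current(2, 0.5, p1), -70)
})

test_that("I_FACT matches its expanded form and is quadratic in GEPH", {
  p <- exp_a_params()
  expanded <- p$c1 * ry_steady_state(p$h, p$h1, 1) *
    nlg2_steady_state(p$GEPH, p$phi) * p$GEPH * p$beta * p$alpha_f * p$w
  expect_equal(i_fact(p), expanded, tolerance = 1e-14)
  expect_gt(i_fact(p), 0)
  expect_equal(i_fact(update_params(p, GEPH = 2 * p$GEPH)) / i_fact(p), 4,
               tolerance = 1e-12)
  expect_equal(i_fact(update_params(p, phi = 2 - 1e-12)), 0,
               tolerance = 1e-10)
})

test_that("closed-form current matches the integrated ODE with no extra scale", {
  tg <- seq(0, 300, by = 0.1)
  for (p in list(exp_a_params(), bench_params())) {
    sim <- simulate_ode(p, tg)
    ia <- analytic_current(p, tg)
    expect_lt(max(abs(sim$current - ia)) / max(abs(ia)), 1e-3)
    expect_gt(stats::cor(sim$current, ia), 0.9999)
  }
  # the three exponentials cancel at t = 0 (to floating-point rounding)
  expect_equal(analytic_current(bench_params(), 0), 0, tolerance = 1e-10)
})

test_that("closed form agrees with the ODE for random valid parameter sets", {
  draws <- sample_params(control_reference("benchmark"), n = 12, seed = 31)
  tg <- seq(0, 300, by = 0.5)
  for (r in seq_len(nrow(draws))) {
    p <- params_from_row(draws[r, ])
    sim <- simulate_ode(p, tg)
    ia <- analytic_current(p, tg)
    expect_lt(max(abs(sim$current - ia)) / max(abs(ia)), 1e-3)
  }
})

test_that("with negligible drive an equilibrated synapse stays silent", {
  p <- update_params(bench_params(), w = 1e-12)
  sim <- simulate_ode(p, seq(0, 100, by = 0.5))
  expect_lt(max(abs(sim$current)), 1e-8)
  expect_equal(sim$NLG2, rep(sim$NLG2[1], nrow(sim)), tolerance = 1e-6)
  expect_equal(sim$Ry, rep(sim$Ry[1], nrow(sim)), tolerance = 1e-6)
})

test_that("peak current scales linearly in w, beta, alpha_f, h, c1 and quadratically in GEPH", {
  p <- bench_params()
  tg <- seq(0, 300, by = 0.2)
  peak_of <- function(pp) max(abs(simulate_ode(pp, tg)$current))
  base <- peak_of(p)
  for (nm in c("w", "beta", "alpha_f", "h", "c1")) {
    pp <- do.call(update_params, c(list(p), stats::setNames(
      list(unclass(p)[[nm]] * 2), nm)))
    expect_equal(peak_of(pp) / base, 2, tolerance = 1e-6)
  }
  p_geph <- update_params(p, GEPH = 2 * p$GEPH)
  expect_equal(peak_of(p_geph) / base, 4, tolerance = 1e-6)
})

test_that("halving w halves the analytic current everywhere", {
  p <- bench_params()
  tg <- seq(0, 200, by = 1)
  expect_equal(analytic_current(update_params(p, w = p$w / 2), tg),
               analytic_current(p, tg) / 2, tolerance = 1e-12)
})

test_that("current is inward (non-positive) below the reversal potential", {
  p <- bench_params() # v = -70, erev = 0
  tg <- seq(0, 300, by = 0.5)
  expect_true(all(analytic_current(p, tg) <= 0))
  expect_true(all(simulate_ode(p, tg)$current <= 1e-12))
})

test_that("peak current decreases strictly with the NLG2 turnover rate phi", {
  p <- bench_params()
  phis <- seq(0.2, 1.8, by = 0.2)
  peaks <- vapply(phis, function(ph)
    peak_current(update_params(p, phi = ph))$peak, numeric(1))
  expect_true(all(diff(peaks) < 0))
})

test_that("parameter sets serialize to flat JSON and back", {
  p <- exp_a_params()
  json <- params_to_json(p)
  q <- params_from_json(json)
  expect_equal(unclass(q), unclass(p), tolerance = 1e-15)
  keys <- names(jsonlite::fromJSON(json))
  expect_setequal(keys, c(fittable_params(), "c1", "erev", "v"))
})

test_that("invalid parameters are rejected at construction", {
  base <- as.list(unclass(bench_params()))
  bad <- list(list(w = -1), list(phi = 2), list(phi = 0), list(h1 = -0.1),
              list(beta = -5))
  for (b in bad) {
    args <- utils::modifyList(base, b)
    expect_error(do.call(syn_params, args))
  }
})
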