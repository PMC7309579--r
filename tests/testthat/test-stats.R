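# Pseudo-Voigt fitting, parameter summaries, day-wise control screening,
# rank-based comparison and effect classification.

test_that("the pseudo-Voigt profile has the right landmark values", {
  pv <- list(a = 2, b = 5, c = 1, x0 = 50)
  expect_equal(pseudo_voigt(50, pv), 2)
  # pure Lorentzian: half height at one width from centre
  expect_equal(pseudo_voigt(55, pv), 1)
  expect_equal(pseudo_voigt(45, pv), 1)
  # pure Gaussian: a * exp(-1/2) at one width
  pvg <- list(a = 2, b = 5, c = 0, x0 = 50)
  expect_equal(pseudo_voigt(55, pvg), 2 * exp(-0.5))
  # mixed case: c + (1 - c) sums to one at the centre
  pvm <- list(a = 3, b = 2, c = 0.3, x0 = 10)
  expect_equal(pseudo_voigt(10, pvm), 3)
})

test_that("the profile has finite positive mass for valid parameters", {
  for (pv in split(pv_reference(), seq_len(nrow(pv_reference())))) {
    mass <- stats::integrate(function(x) pseudo_voigt(x, as.list(pv)),
                             -Inf, Inf)$value
    expect_gt(mass, 0)
    expect_true(is.finite(mass))
  }
})

test_that("sampling and refitting a pseudo-Voigt recovers centre and width", {
  pv <- pv_reference("A", "nls") # a=0.2258 b=16.538 c=0.3102 x0=42.5906
  x <- sample_peak_amplitudes(pv, 50000, seed = 15)
  fit <- fit_pseudo_voigt(x)
  expect_equal(fit$params$x0, 42.5906, tolerance = 0.05)
  expect_equal(fit$params$b, 16.538, tolerance = 0.15)
  expect_gt(fit$params$r, 0.98)
})

test_that("a pure Gaussian sample fits with a small Lorentzian fraction", {
  set.seed(16)
  x <- stats::rnorm(50000, 60, 8)
  fit <- fit_pseudo_voigt(x)
  expect_lt(fit$params$c, 0.3)
  expect_equal(fit$params$x0, 60, tolerance = 0.02)
})

test_that("degenerate or tiny samples are rejected, never silently fitted", {
  expect_error(fit_pseudo_voigt(rep(42, 1000)), "degenerate")
  expect_error(fit_pseudo_voigt(stats::rnorm(20, 50, 5)), "insufficient")
})

test_that("parameter summaries follow the condition-table layout", {
  tbl <- synthetic_fit_table(1, seed = 17)
  s1 <- summarize_params(tbl)
  expect_identical(nrow(s1), 10L)
  expect_equal(s1$mean[s1$parameter == "tau_d"], tbl$tau_d)
  expect_true(all(s1$sd == 0 | is.na(s1$sd)))
  # two identical rows: zero SD throughout
  tbl2 <- dplyr::bind_rows(tbl, tbl)
  s2 <- summarize_params(tbl2)
  expect_true(all(s2$sd == 0))
  # fixed parameters are reported without an SD
  s3 <- summarize_params(tbl2, fixed_params = "GEPH")
  expect_true(is.na(s3$sd[s3$parameter == "GEPH"]))
  expect_error(summarize_params(tbl[0, ]), "empty")
})

test_that("summaries of many draws recover the generating centre", {
  tbl <- synthetic_fit_table(400, seed = 18)
  s <- summarize_params(tbl)
  ref <- control_reference("benchmark")
  m_ref <- ref$mean[ref$parameter == "tau_d"]
  expect_equal(s$mean[s$parameter == "tau_d"], m_ref, tolerance = 0.05)
})

test_that("identical day groups show zero control variability", {
  tbl <- synthetic_fit_table(30, seed = 19, days = 1)
  tbl2 <- dplyr::bind_rows(tbl, tbl)
  tbl2$day <- rep(c("day1", "day2"), each = 30)
  cv <- control_variability(tbl2)
  expect_true(all(cv$max_abs_diff_pct == 0))
  expect_error(control_variability(tbl), "day")
})

test_that("a constructed median shift is reported at its known size", {
  tbl <- synthetic_fit_table(400, seed = 20, days = 2)
  shift <- tbl$day == "day2"
  tbl$tau_r[shift] <- tbl$tau_r[shift] *
    (1.692 * stats::median(tbl$tau_r[!shift]) /
       stats::median(tbl$tau_r[shift]))
  cv <- control_variability(tbl)
  expect_equal(cv$max_abs_diff_pct[cv$parameter == "tau_r"], 69.2,
               tolerance = 0.01)
})

test_that("the maximum pairwise difference is taken over all day pairs", {
  tbl <- synthetic_fit_table(30, seed = 21, days = 1)
  t3 <- dplyr::bind_rows(tbl, tbl, tbl)
  t3$day <- rep(c("day1", "day2", "day3"), each = 30)
  f <- t3$day == "day2"
  t3$w[f] <- t3$w[f] * 1.2 # +20% vs day1
  g <- t3$day == "day3"
  t3$w[g] <- t3$w[g] * 1.1 # +10% vs day1, -8.3% vs day2
  cv <- control_variability(t3)
  expect_equal(cv$max_abs_diff_pct[cv$parameter == "w"], 20,
               tolerance = 1e-6)
})

test_that("mean-if-normal centring uses the mean only under normality", {
  set.seed(26)
  a <- stats::rnorm(80, 10, 1)
  b <- stats::rnorm(80, 12, 1)
  stopifnot(stats::shapiro.test(a)$p.value > 0.05,
            stats::shapiro.test(b)$p.value > 0.05)
  tbl <- tibble::tibble(w = c(a, b), day = rep(c("d1", "d2"), each = 80))
  cv_med <- control_variability(tbl, params = "w", center = "median")
  cv_mean <- control_variability(tbl, params = "w",
                                 center = "mean-if-normal")
  expect_equal(cv_mean$max_abs_diff_pct,
               abs(100 * (mean(b) - mean(a)) / mean(a)), tolerance = 1e-9)
  expect_equal(cv_med$max_abs_diff_pct,
               abs(100 * (stats::median(b) - stats::median(a)) /
                     stats::median(a)), tolerance = 1e-9)
})

test_that("identical groups compare as indistinguishable", {
  tbl <- synthetic_fit_table(50, seed = 23)
  t2 <- dplyr::bind_rows(tbl, tbl)
  t2$condition <- rep(c("control", "blocked"), each = 50)
  cmp <- compare_conditions(t2)
  expect_true(all(cmp$p_value > 0.99))
  expect_true(all(cmp$relative_change == 0))
})

test_that("a large shift is detected with overwhelming significance", {
  tbl <- synthetic_fit_table(50, seed = 24)
  t2 <- dplyr::bind_rows(tbl, tbl)
  t2$condition <- rep(c("control", "blocked"), each = 50)
  blk <- t2$condition == "blocked"
  t2$beta[blk] <- t2$beta[blk] + 3 * stats::sd(t2$beta)
  cmp <- compare_conditions(t2, params = "beta", control = "control")
  expect_lt(cmp$p_value, 0.001)
  expect_identical(cmp$direction, 1)
  expect_error(compare_conditions(t2[1:55, ], params = "beta"),
               "insufficient")
})

test_that("three-group comparisons produce all control pairs", {
  tbl <- synthetic_fit_table(30, seed = 25)
  t3 <- dplyr::bind_rows(tbl, tbl, tbl)
  t3$condition <- rep(c("control", "cyto", "nls"), each = 30)
  cmp <- compare_conditions(t3, params = c("w", "beta"),
                            control = "control")
  expect_identical(nrow(cmp), 6L) # 2 params x 3 pairs
  expect_true(all(cmp$group1[cmp$group2 != "control"] %in%
                    c("control", "cyto", "nls")))
})

test_that("effect labels follow the four-way rule", {
  cmp <- tibble::tibble(
    parameter = c("w", "beta", "tau_d", "phi"),
    group1 = "control", group2 = "blocked", kw_p = 0.01,
    z = c(1, -3, 3, 0.5),
    p_value = c(0.2, 0.01, 0.01, 0.5),
    direction = c(1, 1, 1, -1),
    relative_change = c(30, 50, 5, -2))
  cv <- tibble::tibble(parameter = c("w", "beta", "tau_d", "phi"),
                       max_abs_diff_pct = c(20, 20, 20, 20))
  eff <- classify_effects(cmp, cv)
  expect_identical(eff$label,
                   c("no-difference", "significant-increase",
                     "within-control-range", "no-difference"))
  # permuting the parameter order permutes the labels identically
  perm <- c(3, 1, 4, 2)
  eff_p <- classify_effects(cmp[perm, ], cv)
  expect_identical(eff_p$label, eff$label[perm])
  expect_identical(eff_p$parameter, eff$parameter[perm])
})

test_that("a significant decrease beyond the control range is cyan-labelled", {
  cmp <- tibble::tibble(parameter = "h", group1 = "control",
                        group2 = "blocked", kw_p = 0.001, z = -4,
                        p_value = 0.001, direction = -1,
                        relative_change = -45)
  cv <- tibble::tibble(parameter = "h", max_abs_diff_pct = 15)
  expect_identical(classify_effects(cmp, cv)$label,
                   "significant-decrease")
})
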