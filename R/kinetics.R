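#' Synaptic conductance waveform
#'
#' Double-exponential conductance transient
#' `g(t) = w * (exp(-t/tau_d) - exp(-t/tau_r))`, zero at `t = 0`,
#' non-negative for `t >= 0` when `tau_r < tau_d`.
#'
#' @param t time since event onset (ms), scalar or vector, `t >= 0`.
#' @param params a [syn_params()] object.
#' @return Conductance values, same length as `t`.
#' @export
#' @examples
#' p <- reference_params("A")
#' conductance(c(0, 1, 10), p)
conductance <- function(t, params) {
  stopifnot(is_syn_params(params), all(t >= 0))
  params$w * (exp(-t / params$tau_d) - exp(-t / params$tau_r))
}

#' Time of the conductance peak
#'
#' Analytic argmax of the double-exponential waveform:
#' `t* = tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r)`.
#'
#' @inheritParams conductance
#' @return Peak time (ms).
#' @export
conductance_peak_time <- function(params) {
  stopifnot(is_syn_params(params))
  with(params, tau_r * tau_d / (tau_d - tau_r) * log(tau_d / tau_r))
}

#' Steady state of the NLG2 (neuroligin-2/neurexin) cluster level
#'
#' Non-trivial root of
#' `dNLG2/dt = GEPH / (1 + GEPH/(2 NLG2)) - phi * NLG2`,
#' namely `NLG2* = GEPH (2 - phi) / (2 phi)`.
#'
#' @param GEPH gephyrin cluster level, `GEPH >= 0`.
#' @param phi NLG2/NRXN turnover rate (1/ms), in (0, 2).
#' @return Steady-state NLG2 level.
#' @export
#' @examples
#' nlg2_steady_state(2, 1)  # 1
nlg2_steady_state <- function(GEPH, phi) {
  if (any(phi <= 0) || any(phi >= 2))
    stop("phi must lie strictly inside (0, 2)", call. = FALSE)
  if (any(GEPH < 0)) stop("GEPH must be >= 0", call. = FALSE)
  GEPH * (2 - phi) / (2 * phi)
}

#' Steady state of the postsynaptic receptor pool
#'
#' Root of `dRy/dt = h * GEPH - h1 * Ry`, namely `Ry* = h GEPH / h1`.
#'
#' @param h receptor scaffolding rate (1/ms).
#' @param h1 receptor removal rate (1/ms), `h1 > 0`.
#' @param GEPH gephyrin cluster level.
#' @return Steady-state receptor level.
#' @export
ry_steady_state <- function(h, h1, GEPH) {
  if (any(h1 <= 0)) stop("h1 must be > 0", call. = FALSE)
  h * GEPH / h1
}

#' Instantaneous synaptic current
#'
#' `I = c1 * N * Ry * (v - erev)`. With `v < erev` the current is inward
#' (negative); reported peak amplitudes are absolute values.
#'
#' @param N neurotransmitter level(s).
#' @param Ry receptor level(s).
#' @param params a [syn_params()] object supplying `c1`, `v`, `erev`.
#' @return Current (pA scale set by `c1`/`w`).
#' @export
syn_current <- function(N, Ry, params) {
  stopifnot(is_syn_params(params))
  params$c1 * N * Ry * (params$v - params$erev)
}

#' Closed-form amplitude factor of the modelled current
#'
#' `I_FACT = c1 * (h/h1) * ((2 - phi) * GEPH^2 / (2 phi)) * beta * alpha_f
#' * w`; the stationary amplitude scale of the synaptic current, quadratic
#' in `GEPH` and linear in each of `w`, `beta`, `alpha_f`, `h`, `c1`.
#'
#' @param params a [syn_params()] object.
#' @return The (strictly positive) amplitude factor.
#' @export
i_fact <- function(params) {
  stopifnot(is_syn_params(params))
  if (params$h1 <= 0) stop("h1 must be > 0", call. = FALSE)
  with(params,
       c1 * (h / h1) * ((2 - phi) * GEPH^2 / (2 * phi)) * beta * alpha_f * w)
}

# Exact bracket of the closed-form current: solution of
#   dN/dt = beta*alpha_f*g(t)*NLG2ss - alpha_b*N,  N(0) = 0
# divided by (beta*alpha_f*w*NLG2ss).  Numerator coefficients carry the
# tau_d/tau_r factors required for the three exponentials to cancel at t=0.
.current_bracket <- function(t, tau_r, tau_d, alpha_b) {
  d1 <- 1 - alpha_b * tau_d
  d2 <- 1 - alpha_b * tau_r
  ((tau_d - tau_r) * exp(-alpha_b * t) -
     tau_d * d2 * exp(-t / tau_d) +
     tau_r * d1 * exp(-t / tau_r)) / (d1 * d2)
}

#' Closed-form synaptic current
#'
#' Evaluates the analytic solution of the kinetic model for an event
#' arriving on an equilibrated synapse (`N(0) = 0`, NLG2 and Ry at their
#' steady states):
#' `I(t) = I_FACT * B(t) * (v - erev)` with
#' `B(t) = [(tau_d - tau_r) e^{-alpha_b t} - tau_d (1 - alpha_b tau_r)
#' e^{-t/tau_d} + tau_r (1 - alpha_b tau_d) e^{-t/tau_r}] /
#' [(1 - alpha_b tau_d)(1 - alpha_b tau_r)]`.
#'
#' This is the exact solution of the linear neurotransmitter equation under
#' double-exponential drive; it matches [simulate_ode()] to integration
#' tolerance with no extra scale factor (see the methods vignette). When
#' `alpha_b` is within `tol` of `1/tau_d` or `1/tau_r` the denominator is
#' singular and the function falls back to numerical integration.
#'
#' @param params a [syn_params()] object.
#' @param t time(s) since onset (ms), `t >= 0`.
#' @param tol relative tolerance for detecting a singular denominator.
#' @return Current values at `t` (negative for `v < erev`).
#' @export
#' @examples
#' p <- reference_params("benchmark")
#' analytic_current(p, c(0, 5, 50))
analytic_current <- function(params, t, tol = 1e-8) {
  stopifnot(is_syn_params(params), all(t >= 0))
  ab <- params$alpha_b
  if (abs(1 - ab * params$tau_d) < tol || abs(1 - ab * params$tau_r) < tol) {
    sim <- simulate_ode(params, t_grid = sort(unique(c(0, t))))
    return(stats::approx(sim$t, sim$current, xout = t)$y)
  }
  i_fact(params) * .current_bracket(t, params$tau_r, params$tau_d, ab) *
    (params$v - params$erev)
}

#' Peak amplitude of the modelled current
#'
#' Absolute peak of [analytic_current()] located by optimization on
#' `[0, t_max]` (refined golden-section search after a coarse grid scan).
#'
#' @param params a [syn_params()] object.
#' @param t_max end of the search window (ms).
#' @return A list with `peak` (pA, absolute value) and `t_peak` (ms).
#' @export
peak_current <- function(params, t_max = 300) {
  grid <- seq(0, t_max, length.out = 2001)
  y <- abs(analytic_current(params, grid))
  i0 <- which.max(y)
  lo <- grid[max(1L, i0 - 1L)]
  hi <- grid[min(length(grid), i0 + 1L)]
  opt <- stats::optimize(function(tt) abs(analytic_current(params, tt)),
                         lower = lo, upper = hi, maximum = TRUE,
                         tol = 1e-8)
  list(peak = opt$objective, t_peak = opt$maximum)
}

#' Numerically integrate the kinetic model
#'
#' Integrates the three-variable subcellular system
#' `dN/dt = beta alpha_f g(t) NLG2 - alpha_b N`,
#' `dNLG2/dt = GEPH / (1 + GEPH/(2 NLG2)) - phi NLG2`,
#' `dRy/dt = h GEPH - h1 Ry`
#' with `lsoda` (relative tolerance 1e-8, absolute 1e-10) and returns the
#' state trajectories together with the current
#' `c1 N Ry (v - erev)`. NLG2 is floored at 1e-12 inside the derivative
#' (its equation is singular at 0).
#'
#' @param params a [syn_params()] object.
#' @param t_grid increasing, uniform time grid (ms) starting at the event
#'   onset.
#' @param init named numeric vector `c(N=, NLG2=, Ry=)`; defaults to the
#'   equilibrated synapse `N = 0`, NLG2 and Ry at steady state. `NLG2` must
#'   be positive.
#' @param rtol,atol integrator tolerances.
#' @return A tibble with columns `t`, `N`, `NLG2`, `Ry`, `current`.
#' @export
simulate_ode <- function(params, t_grid,
                         init = c(N = 0,
                                  NLG2 = nlg2_steady_state(params$GEPH,
                                                           params$phi),
                                  Ry = ry_steady_state(params$h, params$h1,
                                                       params$GEPH)),
                         rtol = 1e-8, atol = 1e-10) {
  stopifnot(is_syn_params(params))
  if (length(t_grid) < 2L || any(diff(t_grid) <= 0))
    stop("t_grid must be increasing with at least two points", call. = FALSE)
  if (any(init < 0)) stop("initial state must be non-negative", call. = FALSE)
  if (init[["NLG2"]] <= 0)
    stop("NLG2 initial value must be positive (equation singular at 0)",
         call. = FALSE)

  deriv <- function(t, y, p) {
    nlg2 <- max(y[["NLG2"]], 1e-12)
    g <- p$w * (exp(-t / p$tau_d) - exp(-t / p$tau_r))
    list(c(
      N = p$beta * p$alpha_f * g * nlg2 - p$alpha_b * y[["N"]],
      NLG2 = p$GEPH / (1 + p$GEPH / (2 * nlg2)) - p$phi * nlg2,
      Ry = p$h * p$GEPH - p$h1 * y[["Ry"]]
    ))
  }
  t0 <- t_grid
  offset <- 0
  if (t0[1] > 0) { # lsoda integrates from the first grid point
    t0 <- c(0, t0)
    offset <- 1L
  }
  out <- deSolve::lsoda(y = init[c("N", "NLG2", "Ry")], times = t0,
                        func = deriv, parms = unclass(params),
                        rtol = rtol, atol = atol)
  if (anyNA(out) || nrow(out) < length(t0)) {
    t_fail <- if (nrow(out) > 0) out[nrow(out), "time"] else t0[1]
    stop(sprintf("integration failure near t = %.4g ms", t_fail),
         call. = FALSE)
  }
  out <- tibble::as_tibble(as.data.frame(out))[(1 + offset):(length(t0)), ]
  names(out)[1] <- "t"
  out$current <- syn_current(out$N, out$Ry, params)
  out
}
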