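# Multi-start derivative-free fitting of the kinetic model to individual
# events, RMSE acceptance, and frequency-proportional GEPH fixing.

#' Root mean squared error between two traces
#'
#' @param model_trace,data_trace numeric vectors on the same grid.
#' @return `sqrt(mean((model - data)^2))`; every sample weighted equally.
#' @export
rmse <- function(model_trace, data_trace) {
  if (length(model_trace) != length(data_trace))
    stop("traces must have equal length", call. = FALSE)
  sqrt(mean((model_trace - data_trace)^2))
}

#' Fit acceptance rule
#'
#' A fit is accepted when its RMSE is strictly lower than
#' `rmse_accept_fraction` of the event's peak current.
#'
#' @param fit_rmse RMSE of the fit (pA).
#' @param peak event peak amplitude (pA), must be positive.
#' @param rmse_accept_fraction acceptance threshold as a fraction of peak.
#' @return Logical flag.
#' @export
accept_fit <- function(fit_rmse, peak, rmse_accept_fraction = 0.10) {
  if (peak <= 0) stop("peak must be positive", call. = FALSE)
  is.finite(fit_rmse) && fit_rmse < rmse_accept_fraction * peak
}

#' Frequency-proportional GEPH fixing
#'
#' The gephyrin level of a blocked condition is fixed to the control mean
#' scaled by the ratio of spontaneous-event frequencies, frequency being
#' taken as proportional to the number of gephyrin molecules.
#'
#' @param geph_control_mean mean fitted GEPH under control conditions.
#' @param freq_control_hz,freq_blocked_hz mean event frequencies (Hz).
#' @return The fixed GEPH value for the blocked condition.
#' @export
#' @examples
#' geph_from_frequency(2.2645, 1.5, 1.1) # 1.66063
geph_from_frequency <- function(geph_control_mean, freq_control_hz,
                                freq_blocked_hz) {
  if (geph_control_mean <= 0 || freq_control_hz <= 0 || freq_blocked_hz <= 0)
    stop("all inputs must be positive", call. = FALSE)
  geph_control_mean * freq_blocked_hz / freq_control_hz
}

#' Bookkeeping percentages
#'
#' `acceptance_rate()` is the percentage of events passing a screen;
#' `frequency_reduction()` the percentage reduction of an event frequency
#' relative to control.
#'
#' @param n_accepted,n_total event counts.
#' @return Percentage (0-100).
#' @export
#' @examples
#' acceptance_rate(3926, 4392) # 89.39
acceptance_rate <- function(n_accepted, n_total) {
  if (any(n_total <= 0)) stop("n_total must be positive", call. = FALSE)
  100 * n_accepted / n_total
}

#' @rdname acceptance_rate
#' @param freq_control_hz,freq_blocked_hz mean event frequencies (Hz).
#' @export
frequency_reduction <- function(freq_control_hz, freq_blocked_hz) {
  if (freq_control_hz <= 0) stop("control frequency must be positive",
                                 call. = FALSE)
  100 * (freq_control_hz - freq_blocked_hz) / freq_control_hz
}

#' Fitting configuration
#'
#' @param n_starts number of random multi-start initializations.
#' @param max_iterations iteration cap per local minimization.
#' @param decades half-width of the log10 search range around the reference
#'   means (2.5 decades gives the 5-orders-of-magnitude initialization
#'   span).
#' @param reference tibble (`parameter`, `mean`, `sd`) whose means centre
#'   the log-space bounds; see [control_reference()].
#' @param fixed_params named numeric vector of parameters held fixed (e.g.
#'   `c(GEPH = 1.2035)`).
#' @param rmse_accept_fraction acceptance threshold as a fraction of the
#'   event peak (strictly-lower-than rule).
#' @param seed RNG seed controlling the random starts.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_starts = 100, max_iterations = 3000, decades = 2.5,
                       reference = control_reference("benchmark"),
                       fixed_params = NULL, rmse_accept_fraction = 0.10,
                       seed = 1) {
  if (n_starts < 1) stop("n_starts must be >= 1", call. = FALSE)
  if (rmse_accept_fraction <= 0 || rmse_accept_fraction >= 1)
    stop("rmse_accept_fraction must lie in (0, 1)", call. = FALSE)
  centre <- stats::setNames(reference$mean, reference$parameter)
  if (any(centre <= 0)) stop("bounds must be positive", call. = FALSE)
  lower <- log10(centre) - decades
  upper <- log10(centre) + decades
  upper["phi"] <- min(upper["phi"], log10(2 - 1e-9))
  structure(list(n_starts = n_starts, max_iterations = max_iterations,
                 decades = decades, log_lower = lower, log_upper = upper,
                 fixed_params = fixed_params,
                 rmse_accept_fraction = rmse_accept_fraction,
                 v = attr(reference, "v") %||% -70, seed = seed),
            class = "fit_config")
}

# repair an (unclamped) log10 parameter vector into the valid region:
# clip to bounds, enforce phi < 2 and tau_r < tau_d by swap-and-nudge
.repair_lp <- function(lp, cfg) {
  lp <- pmin(pmax(lp, cfg$log_lower[names(lp)]), cfg$log_upper[names(lp)])
  if ("tau_r" %in% names(lp) || "tau_d" %in% names(lp)) {
    tr <- lp["tau_r"]; td <- lp["tau_d"]
    if (!is.na(tr) && !is.na(td) && tr >= td) {
      mid <- (tr + td) / 2
      lp["tau_r"] <- mid - 0.05
      lp["tau_d"] <- mid + 0.05
    }
  }
  lp
}

# The closed-form current is a sum of three exponentials with rates
# {alpha_b, 1/tau_d, 1/tau_r} and Vandermonde-style coefficients, and is
# exactly invariant (up to a constant absorbed by w) under ANY relabelling
# of the three rates: e.g. for a <-> b (a = alpha_b, b = 1/tau_d,
# r = 1/tau_r) the bracket maps to itself times (r-a)/(r (r-b)). All
# equivalent labellings fit identically; we return the one log-closest to
# the search centre, verified equivalent by its recomputed RMSE.
.canonicalize_rates <- function(params, cfg, shape_at, y, profile_w) {
  if (!profile_w) return(params) # w fixed: cannot absorb the relabel scale
  rates <- c(params$alpha_b, 1 / params$tau_d, 1 / params$tau_r)
  if (!all(is.finite(rates)) || any(rates <= 0)) return(params)
  centre <- (cfg$log_lower + cfg$log_upper) / 2
  dist_to_centre <- function(p)
    (log10(p$tau_d) - centre["tau_d"])^2 +
    (log10(p$tau_r) - centre["tau_r"])^2 +
    (log10(p$alpha_b) - centre["alpha_b"])^2
  refit_w <- function(p) {
    s <- shape_at(update_params(p, w = 1))
    ss <- sum(s^2)
    if (ss == 0) return(NULL)
    w_hat <- sum(s * y) / ss
    if (!is.finite(w_hat) || w_hat <= 0) return(NULL)
    update_params(p, w = w_hat)
  }
  base_rmse <- sqrt(mean((shape_at(params) - y)^2))
  best <- params
  best_d <- dist_to_centre(params)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  for (pm in perms[-1]) {
    rr <- rates[pm] # (alpha_b, 1/tau_d, 1/tau_r) relabelled
    td <- 1 / rr[2]; tr_ <- 1 / rr[3]
    if (tr_ >= td) next
    cand <- try(update_params(params, alpha_b = rr[1], tau_d = td,
                              tau_r = tr_), silent = TRUE)
    if (inherits(cand, "try-error")) next
    cand <- refit_w(cand)
    if (is.null(cand)) next
    r_cand <- sqrt(mean((shape_at(cand) - y)^2))
    if (r_cand > base_rmse + 1e-9 * (1 + base_rmse)) next # not equivalent
    d <- dist_to_centre(cand)
    if (d < best_d) { best <- cand; best_d <- d }
  }
  best
}

#' Fit the kinetic model to one event
#'
#' Minimizes the RMSE between the closed-form model current and the
#' baseline-subtracted event data by multi-start Nelder-Mead in log10
#' parameter space. Starts are drawn log-uniformly within the configured
#' bounds; `tau_r < tau_d` and `phi < 2` are maintained by clip/swap
#' repair. The overall scale `w` is profiled out by linear least squares at
#' every cost evaluation (the model current is exactly linear in `w`), so
#' the search effectively explores the shape parameters. Fixed parameters
#' are never moved.
#'
#' @param trace a trace tibble (columns `t` ms, `i` pA, `sampling_rate`).
#' @param config a [fit_config()].
#' @param window optional window (see [segment_event()]); by default the
#'   whole trace is used with the onset taken from the trace's `onset_ms`
#'   attribute (or 0).
#' @param onset_ms event onset within the trace (ms); overrides the
#'   attribute.
#' @return An object of class `ipsc_fit`: list with `params` (best-fit
#'   [syn_params()]), `rmse`, `peak_pa`, `rmse_over_peak`, `accepted`,
#'   `start_index`, `iterations`, `converged`, and `starts` (per-start
#'   tibble of parameters and RMSE).
#' @export
fit_event <- function(trace, config = fit_config(), window = NULL,
                      onset_ms = NULL) {
  if (is.null(onset_ms))
    onset_ms <- attr(trace, "onset_ms") %||% 0
  if (!is.null(window)) {
    trace <- trace[window$fit_start:(window$fit_end - 1L), ]
    onset_ms <- trace$t[window$onset_idx - window$fit_start + 1L]
  }
  fs <- trace$sampling_rate[1]
  pre <- trace$i[trace$t < onset_ms]
  baseline <- if (length(pre) > 0) mean(pre) else 0
  y <- trace$i - baseline
  tt <- trace$t - onset_ms
  post <- tt >= 0
  peak <- max(abs(y[post]))
  if (!is.finite(peak) || peak <= 0 || stats::sd(y) == 0)
    stop("degenerate event: no signal to fit", call. = FALSE)

  fixed <- config$fixed_params
  free_names <- setdiff(fittable_params(), c(names(fixed), "w"))
  profile_w <- !("w" %in% names(fixed))
  w_bounds <- 10^c(config$log_lower["w"], config$log_upper["w"])

  # model on the window grid: zero before onset, closed form after;
  # evaluated at w = 1, the optimal w is the linear least-squares scale
  shape_at <- function(p1) {
    s <- numeric(length(tt))
    s[post] <- analytic_current(p1, tt[post])
    s
  }
  cost <- function(lp_free) {
    lp <- .repair_lp(stats::setNames(lp_free, free_names), config)
    # w slot: evaluate shape at w = 1 then profile the optimal scale
    p1 <- try({
      vals <- 10^lp
      wv <- if (profile_w) 1 else unname(fixed["w"])
      all_p <- c(as.list(vals), as.list(fixed[setdiff(names(fixed), "w")]))
      all_p$w <- wv
      do.call(syn_params, c(all_p[fittable_params()],
                            list(c1 = 1, erev = 0, v = config$v)))
    }, silent = TRUE)
    if (inherits(p1, "try-error")) return(1e6 * peak)
    s <- shape_at(p1)
    if (profile_w) {
      ss <- sum(s^2)
      if (ss == 0) return(1e6 * peak)
      w_hat <- min(max(sum(s * y) / ss, w_bounds[1]), w_bounds[2])
      s <- s * w_hat
    }
    r <- sqrt(mean((s - y)^2))
    if (!is.finite(r)) 1e6 * peak else r
  }

  starts <- with_seed(config$seed, {
    lapply(seq_len(config$n_starts), function(k)
      .repair_lp(stats::setNames(
        stats::runif(length(free_names),
                     config$log_lower[free_names],
                     config$log_upper[free_names]),
        free_names), config))
  })

  run_start <- function(k) {
    opt <- stats::optim(unname(starts[[k]]), cost, method = "Nelder-Mead",
                        control = list(maxit = config$max_iterations,
                                       reltol = 1e-10))
    lp <- .repair_lp(stats::setNames(opt$par, free_names), config)
    # reconstruct fitted w
    vals <- 10^lp
    wv <- if (profile_w) 1 else unname(fixed["w"])
    all_p <- c(as.list(vals), as.list(fixed[setdiff(names(fixed), "w")]))
    all_p$w <- wv
    p1 <- do.call(syn_params, c(all_p[fittable_params()],
                                list(c1 = 1, erev = 0, v = config$v)))
    if (profile_w) {
      s <- shape_at(p1)
      ss <- sum(s^2)
      w_hat <- if (ss > 0)
        min(max(sum(s * y) / ss, w_bounds[1]), w_bounds[2])
      else w_bounds[1]
      p1 <- update_params(p1, w = w_hat)
    }
    p1 <- .canonicalize_rates(p1, config, shape_at, y, profile_w)
    r_final <- sqrt(mean((shape_at(p1) - y)^2))
    list(params = p1, rmse = r_final, iterations = opt$counts[["function"]],
         converged = opt$convergence == 0, start_index = k)
  }
  results <- lapply(seq_len(config$n_starts), run_start)
  rmses <- vapply(results, `[[`, numeric(1), "rmse")
  if (all(!is.finite(rmses) | rmses >= 1e6 * peak))
    stop("all starts failed: no finite RMSE", call. = FALSE)
  best_i <- which.min(replace(rmses, !is.finite(rmses), Inf)) # lowest index wins ties
  best <- results[[best_i]]

  starts_tbl <- dplyr::bind_rows(lapply(results, function(r) {
    out <- tibble::as_tibble(unclass(r$params)[fittable_params()])
    out$rmse <- r$rmse
    out$start_index <- r$start_index
    out$converged <- r$converged
    out
  }))
  structure(list(params = best$params, rmse = best$rmse, peak_pa = peak,
                 rmse_over_peak = best$rmse / peak,
                 accepted = accept_fit(best$rmse, peak,
                                       config$rmse_accept_fraction),
                 start_index = best$start_index,
                 iterations = best$iterations, converged = best$converged,
                 onset_ms = onset_ms, baseline_pa = baseline,
                 data = tibble::tibble(t = trace$t, i = y),
                 starts = starts_tbl),
            class = "ipsc_fit")
}

#' @export
print.ipsc_fit <- function(x, ...) {
  cat(sprintf(
    "<ipsc_fit> peak %.1f pA | RMSE %.3f pA (%.2f%% of peak) | %s | start %d\n",
    x$peak_pa, x$rmse, 100 * x$rmse_over_peak,
    if (x$accepted) "accepted" else "rejected", x$start_index))
  print(x$params)
  invisible(x)
}

#' Fit every event of a labelled dataset
#'
#' Applies the per-condition amplitude-consistency screen, fixes GEPH per
#' condition where requested, fits every surviving event and returns a tidy
#' fit table (one row per event) with per-condition screening/acceptance
#' counts attached as the `"counts"` attribute.
#'
#' @param events tibble with columns `condition`, `cell`, `day` and a
#'   `trace` list-column of single-event traces (see
#'   [make_condition_dataset()] with `traces = TRUE`).
#' @param config a [fit_config()]; its `fixed_params` are extended by the
#'   per-condition GEPH values.
#' @param amplitude_ref optional tibble (`condition`, `mean`, `sd`) of
#'   reference peak amplitudes for the consistency screen; `NULL` skips the
#'   screen.
#' @param geph_fixed optional named vector of GEPH values per condition
#'   label (e.g. from [geph_from_frequency()]).
#' @param k width of the amplitude-consistency band in SDs.
#' @return A tibble with the ten parameter columns, `rmse`,
#'   `rmse_over_peak`, `accepted`, `peak_pa`, `condition`, `cell`, `day`,
#'   `seed`; attribute `"counts"` holds per-condition totals
#'   (`n_raw`, `n_selected`, `n_accepted`, `acceptance_pct`).
#' @export
fit_dataset <- function(events, config = fit_config(),
                        amplitude_ref = NULL, geph_fixed = NULL, k = 2) {
  cols <- c(fittable_params(), "rmse", "rmse_over_peak", "accepted",
            "peak_pa", "condition", "cell", "day", "seed")
  if (nrow(events) == 0) {
    out <- tibble::as_tibble(stats::setNames(
      lapply(cols, function(x) if (x %in% c("accepted")) logical()
             else if (x %in% c("condition", "cell", "day")) character()
             else numeric()), cols))
    attr(out, "counts") <- tibble::tibble(condition = character(),
                                          n_raw = integer(),
                                          n_selected = integer(),
                                          n_accepted = integer(),
                                          acceptance_pct = double())
    return(out)
  }
  events$peak_pa <- purrr::map_dbl(events$trace, function(tr) {
    on <- attr(tr, "onset_ms") %||% 0
    base <- mean(tr$i[tr$t < on])
    max(abs(tr$i[tr$t >= on] - base))
  })
  n_raw <- dplyr::count(events, .data$condition, name = "n_raw")
  if (!is.null(amplitude_ref)) {
    events <- dplyr::group_modify(
      dplyr::group_by(events, .data$condition), function(df, g) {
        ref <- amplitude_ref[amplitude_ref$condition == g$condition, ]
        if (nrow(ref) == 0) return(df)
        df[abs(df$peak_pa - ref$mean) <= k * ref$sd, ]
      })
    events <- dplyr::ungroup(events)
  }
  n_sel <- dplyr::count(events, .data$condition, name = "n_selected")

  fit_one <- function(r) {
    cond <- events$condition[r]
    cfg <- config
    if (!is.null(geph_fixed) && cond %in% names(geph_fixed))
      cfg$fixed_params <- c(cfg$fixed_params,
                            c(GEPH = unname(geph_fixed[cond])))
    cfg$seed <- config$seed + r
    f <- fit_event(events$trace[[r]], cfg)
    out <- tibble::as_tibble(unclass(f$params)[fittable_params()])
    out$rmse <- f$rmse
    out$rmse_over_peak <- f$rmse_over_peak
    out$accepted <- f$accepted
    out$peak_pa <- f$peak_pa
    out$condition <- cond
    out$cell <- events$cell[r]
    out$day <- events$day[r]
    out$seed <- cfg$seed
    out
  }
  fits <- dplyr::bind_rows(purrr::map(seq_len(nrow(events)), fit_one))
  counts <- dplyr::left_join(n_raw, n_sel, by = "condition")
  counts$n_selected[is.na(counts$n_selected)] <- 0L
  acc <- dplyr::count(fits[fits$accepted, ], .data$condition,
                      name = "n_accepted")
  counts <- dplyr::left_join(counts, acc, by = "condition")
  counts$n_accepted[is.na(counts$n_accepted)] <- 0L
  counts$acceptance_pct <- ifelse(counts$n_raw > 0,
                                  acceptance_rate(counts$n_accepted,
                                                  counts$n_raw), NA_real_)
  attr(fits, "counts") <- counts
  fits
}
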