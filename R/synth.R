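# Synthetic voltage-clamp data: ground-truth parameter draws, single-event
# traces, Poisson event trains and labelled multi-condition datasets.

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Acquisition settings for synthetic recordings
#'
#' Describes the emulated patch-clamp acquisition: 10 kHz sampling with a
#' 2 kHz low-pass cutoff by default.
#'
#' @param sampling_rate sampling rate (Hz); must be at least twice the
#'   filter cutoff.
#' @param filter_cutoff low-pass cutoff (Hz); `NA` disables filtering.
#' @param noise_sd additive baseline noise SD (pA) before filtering.
#' @param duration recording duration (s), used by train generation.
#' @param holding_potential holding potential (mV).
#' @return A list of class `acq_spec`.
#' @export
acquisition_spec <- function(sampling_rate = 10000, filter_cutoff = 2000,
                             noise_sd = 2, duration = 60,
                             holding_potential = -70) {
  if (!is.na(filter_cutoff) && sampling_rate < 2 * filter_cutoff)
    stop("sampling_rate must be >= 2 * filter_cutoff", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(sampling_rate = sampling_rate,
                 filter_cutoff = filter_cutoff,
                 noise_sd = noise_sd, duration = duration,
                 holding_potential = holding_potential),
            class = "acq_spec")
}

#' Experimental condition settings for synthetic datasets
#'
#' @param label condition label (e.g. `"control"`, `"cyto"`, `"nls"`,
#'   `"delta2-188"`).
#' @param n_cells,n_days numbers of cells and recording days to spread
#'   events over.
#' @param event_frequency mean spontaneous event frequency (Hz).
#' @param geph_scale multiplier applied to the control GEPH level, in
#'   (0, 1].
#' @param param_perturbations named numeric vector of multiplicative shifts
#'   applied to reference parameter means (e.g. `c(w = 0.7)`).
#' @return A list of class `condition_spec`.
#' @export
condition_spec <- function(label, n_cells = 5, n_days = 3,
                           event_frequency = 1.5, geph_scale = 1,
                           param_perturbations = NULL) {
  if (event_frequency <= 0) stop("event_frequency must be > 0", call. = FALSE)
  if (geph_scale <= 0 || geph_scale > 1)
    stop("geph_scale must lie in (0, 1]", call. = FALSE)
  if (!is.null(param_perturbations) &&
      !all(names(param_perturbations) %in% fittable_params()))
    stop("param_perturbations names must be fittable parameters",
         call. = FALSE)
  structure(list(label = label, n_cells = n_cells, n_days = n_days,
                 event_frequency = event_frequency, geph_scale = geph_scale,
                 param_perturbations = param_perturbations),
            class = "condition_spec")
}

# one truncated draw per parameter; resamples into the valid region
.draw_truncnorm <- function(n, mean, sd, lower = 0, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= lower | out >= upper)
  tries <- 0L
  while (length(bad) > 0 && tries < 1000L) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lower | out[bad] >= upper]
    tries <- tries + 1L
  }
  if (length(bad) > 0) out[bad] <- mean # pathological sd; fall back to mean
  out
}

#' Draw ground-truth kinetic parameter sets
#'
#' Draws parameter vectors either from truncated normals around a reference
#' mean/SD table (`"around-reference"`) or log-uniformly over a wide range
#' (`"log-uniform-range"`, +/- `decades` decades in log10 around the
#' reference means — the regime used to initialize multi-start fits).
#' Validity is enforced by resampling: all rates non-negative, `phi` in
#' (0, 2), `tau_r < tau_d`.
#'
#' @param reference a tibble with columns `parameter`, `mean`, `sd` (see
#'   [control_reference()]).
#' @param n number of parameter sets.
#' @param mode `"around-reference"` or `"log-uniform-range"`.
#' @param decades half-width of the log-uniform range (decades).
#' @param seed optional RNG seed.
#' @param v,c1,erev acquisition constants attached to each draw.
#' @return A tibble with `n` rows and the ten fittable parameter columns.
#' @export
#' @examples
#' sample_params(control_reference("A"), n = 3, seed = 1)
sample_params <- function(reference, n = 1,
                          mode = c("around-reference", "log-uniform-range"),
                          decades = 2.5, seed = NULL,
                          v = attr(reference, "v") %||% -70,
                          c1 = 1, erev = 0) {
  mode <- match.arg(mode)
  if (!all(c("parameter", "mean", "sd") %in% names(reference)) ||
      !all(fittable_params() %in% reference$parameter))
    stop("reference must carry mean and sd for the ten fittable parameters",
         call. = FALSE)
  m <- stats::setNames(reference$mean, reference$parameter)
  s <- stats::setNames(reference$sd, reference$parameter)
  if (any(m <= 0)) stop("reference means must be positive", call. = FALSE)
  if (any(s < 0)) stop("reference SDs must be >= 0", call. = FALSE)

  with_seed(seed, {
    draws <- matrix(NA_real_, n, length(fittable_params()),
                    dimnames = list(NULL, fittable_params()))
    for (nm in fittable_params()) {
      upper <- if (nm == "phi") 2 else Inf
      draws[, nm] <- switch(mode,
        "around-reference" = .draw_truncnorm(n, m[nm], s[nm], 0, upper),
        "log-uniform-range" = {
          x <- 10^stats::runif(n, log10(m[nm]) - decades,
                               log10(m[nm]) + decades)
          if (nm == "phi") pmin(x, 2 - 1e-9) else x
        })
    }
    # enforce tau_r < tau_d by resampling the pair
    bad <- which(draws[, "tau_r"] >= draws[, "tau_d"])
    tries <- 0L
    while (length(bad) > 0 && tries < 1000L) {
      draws[bad, "tau_r"] <- switch(mode,
        "around-reference" = .draw_truncnorm(length(bad), m["tau_r"],
                                             s["tau_r"]),
        "log-uniform-range" = 10^stats::runif(length(bad),
                                              log10(m["tau_r"]) - decades,
                                              log10(m["tau_r"]) + decades))
      bad <- bad[draws[bad, "tau_r"] >= draws[bad, "tau_d"]]
      tries <- tries + 1L
    }
    if (length(bad) > 0)
      draws[bad, "tau_r"] <- draws[bad, "tau_d"] / 10
    out <- tibble::as_tibble(as.data.frame(draws))
    out$c1 <- c1; out$erev <- erev; out$v <- v
    out
  })
}

#' Convert one row of a parameter table to a `syn_params` object
#'
#' @param row a one-row data frame (or list) carrying the ten fittable
#'   parameters and optionally `c1`, `erev`, `v`.
#' @return A [syn_params()] object.
#' @export
params_from_row <- function(row) {
  row <- as.list(row)
  do.call(syn_params, c(row[fittable_params()],
                        list(c1 = row$c1 %||% 1, erev = row$erev %||% 0,
                             v = row$v %||% -70)))
}

# zero-phase 4th-order Butterworth low-pass
.lowpass <- function(x, sampling_rate, cutoff) {
  if (is.na(cutoff)) return(x)
  bf <- signal::butter(4, 2 * cutoff / sampling_rate, type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

.new_trace <- function(t_ms, i_pa, sampling_rate, condition = NA_character_,
                       cell = NA_character_, day = NA_character_) {
  tibble::tibble(t = t_ms, i = i_pa, sampling_rate = sampling_rate,
                 condition = condition, cell = cell, day = day)
}

#' Generate a single synthetic event trace
#'
#' Model current on a uniform grid (zero during the pre-onset baseline,
#' closed-form current after onset), plus additive white Gaussian noise of
#' SD `acq$noise_sd`, then zero-phase low-pass filtering at
#' `acq$filter_cutoff`.
#'
#' @param params a [syn_params()] object (ground truth).
#' @param acq an [acquisition_spec()].
#' @param pre_event_ms baseline duration before the event onset (ms).
#' @param post_event_ms trace duration after onset (ms).
#' @param seed optional RNG seed.
#' @param filter logical; apply the low-pass filter?
#' @return A trace tibble (`t` in ms, `i` in pA, `sampling_rate`) with
#'   attributes `onset_ms` and `ground_truth` (the `syn_params` used).
#' @export
make_event_trace <- function(params, acq = acquisition_spec(),
                             pre_event_ms = 20, post_event_ms = 300,
                             seed = NULL, filter = TRUE) {
  stopifnot(is_syn_params(params), inherits(acq, "acq_spec"))
  dt <- 1000 / acq$sampling_rate
  t <- seq(0, pre_event_ms + post_event_ms, by = dt)
  i <- numeric(length(t))
  post <- t >= pre_event_ms
  i[post] <- analytic_current(params, t[post] - pre_event_ms)
  with_seed(seed, {
    if (acq$noise_sd > 0) i <- i + stats::rnorm(length(i), 0, acq$noise_sd)
    if (filter && acq$noise_sd > 0)
      i <- .lowpass(i, acq$sampling_rate, acq$filter_cutoff)
    out <- .new_trace(t, i, acq$sampling_rate)
    attr(out, "onset_ms") <- pre_event_ms
    attr(out, "ground_truth") <- params
    out
  })
}

#' Sample peak amplitudes from a pseudo-Voigt distribution
#'
#' Draws positive amplitudes with density proportional to the 4-parameter
#' pseudo-Voigt profile (see [pseudo_voigt()]): a mixture of a Cauchy
#' (weight `c * pi * b`) and a Gaussian (weight `(1 - c) * sqrt(2 pi) * b`)
#' branch sharing centre `x0` and width `b`, with non-positive draws
#' rejected and resampled.
#'
#' @param pv a list/one-row data frame with `a`, `b`, `c`, `x0` (e.g. one
#'   row of [pv_reference()]); `a` only scales the profile and does not
#'   affect sampling.
#' @param n number of draws.
#' @param seed optional RNG seed.
#' @return Numeric vector of `n` positive amplitudes (pA).
#' @export
#' @examples
#' amps <- sample_peak_amplitudes(pv_reference("A", "nls"), 1000, seed = 1)
sample_peak_amplitudes <- function(pv, n, seed = NULL) {
  pv <- as.list(pv)
  if (pv$b <= 0 || pv$c < 0 || pv$c > 1 || n < 1)
    stop("invalid pseudo-Voigt shape: need b > 0, c in [0,1], n >= 1",
         call. = FALSE)
  w_lor <- pv$c * pi * pv$b
  w_gau <- (1 - pv$c) * sqrt(2 * pi) * pv$b
  p_lor <- w_lor / (w_lor + w_gau)
  with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      k <- n - length(out)
      branch <- stats::runif(k) < p_lor
      x <- numeric(k)
      x[branch] <- stats::rcauchy(sum(branch), pv$x0, pv$b)
      x[!branch] <- stats::rnorm(sum(!branch), pv$x0, pv$b)
      out <- c(out, x[x > 0])
    }
    out[seq_len(n)]
  })
}

#' Generate a continuous trace with Poisson-timed events
#'
#' Event onsets are drawn from a homogeneous Poisson process at `freq_hz`;
#' each event's `w` is rescaled so its noiseless peak equals an amplitude
#' drawn from `amplitude_sampler`; event currents are summed linearly onto
#' a noisy baseline. Events whose onsets fall within `overlap_window_ms` of
#' a neighbour are flagged `overlapping` in the ground truth.
#'
#' @param freq_hz mean event frequency (Hz).
#' @param duration_s trace duration (s).
#' @param amplitude_sampler function(n) returning `n` positive peak
#'   amplitudes (pA); default samples the control pseudo-Voigt reference of
#'   experiment A.
#' @param event_shape_params a [syn_params()] object giving the event shape;
#'   defaults to [reference_params()]`("benchmark")` (IPSC-like ~50 ms
#'   decay).
#' @param acq an [acquisition_spec()].
#' @param seed optional RNG seed.
#' @param overlap_window_ms onset separation below which events are flagged
#'   overlapping.
#' @param min_separation_ms if positive, re-draw onsets closer than this to
#'   their predecessor (thinned process used by the detection benchmark);
#'   0 keeps the raw Poisson process.
#' @return A list with `trace` (tibble `t`, `i`, `sampling_rate`) and
#'   `events` (tibble `onset_ms`, `amplitude_pa`, `overlapping`).
#' @export
make_event_train <- function(freq_hz, duration_s,
                             amplitude_sampler = function(n)
                               sample_peak_amplitudes(
                                 pv_reference("A", "control"), n),
                             event_shape_params =
                               reference_params("benchmark"),
                             acq = acquisition_spec(duration = duration_s),
                             seed = NULL, overlap_window_ms = 20,
                             min_separation_ms = 0) {
  if (freq_hz <= 0) stop("freq_hz must be > 0", call. = FALSE)
  stopifnot(is_syn_params(event_shape_params))
  with_seed(seed, {
    dt <- 1000 / acq$sampling_rate
    n_samp <- round(duration_s * 1000 / dt) + 1L
    t <- (seq_len(n_samp) - 1L) * dt
    n_ev <- stats::rpois(1, freq_hz * duration_s)
    onsets <- sort(stats::runif(n_ev, 0, duration_s * 1000))
    if (min_separation_ms > 0 && n_ev > 1) {
      for (rep in 1:50) {
        gaps <- diff(c(-Inf, onsets))
        bad <- which(gaps < min_separation_ms)
        if (length(bad) == 0) break
        onsets[bad] <- stats::runif(length(bad), 0, duration_s * 1000)
        onsets <- sort(onsets)
      }
      keep <- c(TRUE, diff(onsets) >= min_separation_ms)
      onsets <- onsets[keep]
      n_ev <- length(onsets)
    }
    i <- numeric(n_samp)
    amps <- if (n_ev > 0) amplitude_sampler(n_ev) else numeric(0)
    unit_peak <- peak_current(event_shape_params)$peak
    span_ms <- 400 # event kernel support; shape decays well within this
    kern_n <- round(span_ms / dt)
    kern_t <- (seq_len(kern_n) - 1L) * dt
    unit_kernel <- analytic_current(event_shape_params, kern_t) / unit_peak
    for (k in seq_len(n_ev)) {
      i0 <- round(onsets[k] / dt) + 1L
      idx <- i0:min(n_samp, i0 + kern_n - 1L)
      i[idx] <- i[idx] + amps[k] * unit_kernel[seq_along(idx)]
    }
    if (acq$noise_sd > 0) {
      i <- i + stats::rnorm(n_samp, 0, acq$noise_sd)
      i <- .lowpass(i, acq$sampling_rate, acq$filter_cutoff)
    }
    overlapping <- if (n_ev > 0) {
      gaps_prev <- c(Inf, diff(onsets)); gaps_next <- c(diff(onsets), Inf)
      gaps_prev < overlap_window_ms | gaps_next < overlap_window_ms
    } else logical(0)
    list(trace = .new_trace(t, i, acq$sampling_rate),
         events = tibble::tibble(onset_ms = onsets, amplitude_pa = amps,
                                 overlapping = overlapping))
  })
}

#' Generate a labelled multi-condition dataset
#'
#' Draws ground-truth parameter sets for a control and a blocked condition
#' (the latter with GEPH scaled by `geph_scale` and any stated parameter
#' perturbations applied to the reference means), attaches per-cell and
#' per-day identifiers, and optionally renders each event as a noisy trace.
#'
#' @param control_spec,blocked_spec [condition_spec()] objects.
#' @param n_events_per_condition events per condition.
#' @param reference control reference distribution (see
#'   [control_reference()]).
#' @param acq an [acquisition_spec()].
#' @param seed RNG seed (recorded in the manifest).
#' @param traces logical; render each event as a trace (list-column
#'   `trace`)?
#' @return A list of class `ipsc_dataset` with `events` (tibble: condition,
#'   cell, day, the ten ground-truth parameter columns, `true_peak_pa`, and
#'   optionally `trace`) and `manifest` (seed + condition settings,
#'   sufficient to regenerate the dataset).
#' @export
make_condition_dataset <- function(control_spec, blocked_spec,
                                   n_events_per_condition = 100,
                                   reference = control_reference("benchmark"),
                                   acq = acquisition_spec(),
                                   seed = 1, traces = FALSE) {
  stopifnot(inherits(control_spec, "condition_spec"),
            inherits(blocked_spec, "condition_spec"))
  gen_one <- function(spec, sub_seed) {
    ref <- reference
    shift <- stats::setNames(rep(1, length(fittable_params())),
                             fittable_params())
    if (!is.null(spec$param_perturbations))
      shift[names(spec$param_perturbations)] <- spec$param_perturbations
    shift["GEPH"] <- shift["GEPH"] * spec$geph_scale
    ref$mean <- ref$mean * unname(shift[ref$parameter])
    ref$sd <- ref$sd * unname(shift[ref$parameter])
    draws <- sample_params(ref, n = n_events_per_condition, seed = sub_seed,
                           v = attr(reference, "v") %||% -70)
    draws$condition <- spec$label
    draws$cell <- paste0(spec$label, "_cell",
                         rep_len(seq_len(spec$n_cells),
                                 n_events_per_condition))
    draws$day <- paste0("day", sort(rep_len(seq_len(spec$n_days),
                                            n_events_per_condition)))
    draws$true_peak_pa <- purrr::map_dbl(seq_len(nrow(draws)), function(r)
      peak_current(params_from_row(draws[r, ]))$peak)
    draws
  }
  events <- dplyr::bind_rows(gen_one(control_spec, seed),
                             gen_one(blocked_spec, seed + 1L))
  if (traces) {
    events$trace <- purrr::map(seq_len(nrow(events)), function(r)
      make_event_trace(params_from_row(events[r, ]), acq = acq,
                       seed = seed + 100L + r))
  }
  manifest <- list(
    seed = seed, n_events_per_condition = n_events_per_condition,
    traces = traces,
    acquisition = unclass(acq),
    reference = list(parameter = reference$parameter,
                     mean = reference$mean, sd = reference$sd,
                     v = attr(reference, "v") %||% -70),
    conditions = list(control = unclass(control_spec),
                      blocked = unclass(blocked_spec)))
  structure(list(events = events, manifest = manifest),
            class = "ipsc_dataset")
}

#' Write / read / replay a dataset manifest
#'
#' The manifest plus its recorded seed are sufficient to regenerate every
#' trace bit-for-bit.
#'
#' @param dataset an `ipsc_dataset` (or its `manifest`).
#' @param path JSON file path.
#' @return `write_manifest()` returns `path` invisibly; `read_manifest()`
#'   the manifest list; `regenerate_dataset()` a new `ipsc_dataset`.
#' @export
write_manifest <- function(dataset, path) {
  manifest <- if (inherits(dataset, "ipsc_dataset")) dataset$manifest
  else dataset
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) jsonlite::fromJSON(path,
                                                   simplifyVector = TRUE)

#' @rdname write_manifest
#' @param manifest a manifest list as read by [read_manifest()].
#' @export
regenerate_dataset <- function(manifest) {
  ref <- tibble::tibble(parameter = manifest$reference$parameter,
                        mean = manifest$reference$mean,
                        sd = manifest$reference$sd)
  attr(ref, "v") <- manifest$reference$v
  mk_spec <- function(x) do.call(condition_spec, x[!vapply(x, is.null,
                                                           logical(1))])
  acq <- do.call(acquisition_spec, manifest$acquisition)
  make_condition_dataset(mk_spec(manifest$conditions$control),
                         mk_spec(manifest$conditions$blocked),
                         n_events_per_condition =
                           manifest$n_events_per_condition,
                         reference = ref, acq = acq,
                         seed = manifest$seed, traces = manifest$traces)
}
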