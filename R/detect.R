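# Event detection by optimally-scaled sliding template matching, window
# segmentation and event-level measurements.

#' Default detection template
#'
#' Negative-going double-exponential kernel (inward IPSC polarity) with
#' rise 1 ms and decay 30 ms, length `length_factor * tau_d`. The default
#' length (2 decay time constants, 60 ms) keeps the matching window short
#' enough that a neighbouring event at least ~50 ms away does not inflate
#' the fit error and mask the detection.
#'
#' @param tau_r,tau_d rise and decay time constants (ms).
#' @param sampling_rate sampling rate (Hz).
#' @param length_factor template length in units of `tau_d`.
#' @return Numeric vector (template samples, peak -1).
#' @export
default_template <- function(tau_r = 1, tau_d = 30, sampling_rate = 10000,
                             length_factor = 2) {
  dt <- 1000 / sampling_rate
  t <- seq(0, length_factor * tau_d, by = dt)
  y <- -(exp(-t / tau_d) - exp(-t / tau_r))
  y / max(abs(y))
}

# rolling window sums via cumulative sums; returns vector of length
# n - k + 1 with sum of x[j..j+k-1]
.rollsum <- function(x, k) {
  cs <- cumsum(x)
  cs[k:length(x)] - c(0, cs)[seq_len(length(x) - k + 1L)]
}

# cross-correlation cc[j] = sum_i x[j+i-1] * y[i], FFT on a padded
# power-of-two length (arbitrary-length FFTs can hit slow prime factors)
.xcorr <- function(x, y) {
  n <- length(x); k <- length(y)
  L <- stats::nextn(n + k - 1L, 2)
  X <- stats::fft(c(x, numeric(L - n)))
  Y <- stats::fft(c(y, numeric(L - k)))
  cc <- Re(stats::fft(X * Conj(Y), inverse = TRUE)) / L
  cc[seq_len(n - k + 1L)]
}

#' Detect events by scaled sliding-template matching
#'
#' The template is slid along the trace one sample at a time; at each
#' offset the scale and baseline offset minimizing the sum of squared
#' errors between the scaled template and the data are computed in closed
#' form, and the detection criterion is the scale divided by the standard
#' error of the fit. Local maxima of the criterion above
#' `criterion_threshold`, separated by at least `refractory_ms`, become
#' events; each detection is segmented ([segment_event()]) and measured
#' ([measure_event()]).
#'
#' @param trace a trace tibble (columns `t` in ms, `i` in pA,
#'   `sampling_rate`).
#' @param template event-shaped kernel ([default_template()] by default);
#'   must be shorter than the trace.
#' @param criterion_threshold detection threshold on scale/SE (default 4).
#' @param refractory_ms minimum separation between detections (ms).
#' @param min_peak_snr veto: a detection is kept only if its measured peak
#'   exceeds this multiple of the trace noise SD (estimated robustly as the
#'   median template-fit SE over all offsets). Set to 0 to disable.
#' @param max_ttp_ms veto: maximum allowed time-to-peak (ms); detections
#'   whose extremum occurs later than this after the onset are not
#'   template-shaped (threshold grazes on noise or decay tails). `Inf`
#'   disables.
#' @param max_rise_ms veto: maximum allowed 20-80% rise time (ms);
#'   decay-tail re-triggers rise over tens of ms while template-shaped
#'   events rise in a few. `Inf` disables.
#' @return An event tibble: `onset_idx` (1-based sample index), `onset_ms`,
#'   `criterion`, plus the window and measurement columns of
#'   [measure_event()]. Zero rows when nothing crosses threshold.
#' @export
sliding_template_detect <- function(trace, template = NULL,
                                    criterion_threshold = 4,
                                    refractory_ms = 20,
                                    min_peak_snr = 4, max_ttp_ms = 50,
                                    max_rise_ms = 10) {
  if (nrow(trace) == 0) stop("empty trace", call. = FALSE)
  if (criterion_threshold <= 0)
    stop("criterion_threshold must be > 0", call. = FALSE)
  fs <- trace$sampling_rate[1]
  if (is.null(template)) template <- default_template(sampling_rate = fs)
  k <- length(template)
  n <- nrow(trace)
  if (k >= n) stop("template longer than trace", call. = FALSE)

  d <- trace$i
  sum_t <- sum(template)
  sum_t2 <- sum(template^2)
  sum_d <- .rollsum(d, k)
  sum_d2 <- .rollsum(d^2, k)
  sum_td <- .xcorr(d, template)
  denom <- sum_t2 - sum_t^2 / k
  scale <- (sum_td - sum_t * sum_d / k) / denom
  offset <- (sum_d - scale * sum_t) / k
  sse <- sum_d2 + scale^2 * sum_t2 + k * offset^2 -
    2 * (scale * sum_td + offset * sum_d - scale * offset * sum_t)
  sse[sse < 0] <- 0
  crit <- scale / sqrt(sse / (k - 1))
  crit[!is.finite(crit)] <- 0 # flat segments: zero scale over zero SE

  empty <- tibble::tibble(onset_idx = integer(), onset_ms = double(),
                          criterion = double(), rise_ms = double())
  # local maxima of the criterion above threshold (a run of the criterion
  # can span several events when decay tails keep it elevated)
  m <- length(crit)
  is_max <- c(FALSE, crit[2:(m - 1)] >= crit[1:(m - 2)] &
                crit[2:(m - 1)] > crit[3:m], FALSE)
  peaks <- which(is_max & crit > criterion_threshold)
  if (length(peaks) == 0) return(empty)
  # time-ordered arming: scan criterion maxima in time order; a maximum is
  # accepted if it lies beyond the refractory gap of the last ACCEPTED
  # detection and shows a template-like fast rise at its refined onset.
  # Rejected maxima (decay-tail re-triggers, threshold grazes) do not reset
  # the refractory clock, so they cannot mask a following true event.
  gap <- round(refractory_ms * fs / 1000)
  kept_idx <- integer(0); kept_crit <- double(0); kept_rise <- double(0)
  last <- -Inf
  for (p in peaks) {
    if (p - last < gap) next
    ref <- .refine_onset(p, trace, fs)
    if (!is.finite(ref[2]) || ref[2] > max_rise_ms) next
    if (length(kept_idx) > 0 && ref[1] - kept_idx[length(kept_idx)] < gap)
      next # second maximum of the same event
    kept_idx <- c(kept_idx, as.integer(ref[1]))
    kept_crit <- c(kept_crit, crit[p])
    kept_rise <- c(kept_rise, ref[2])
    last <- p
  }
  if (length(kept_idx) == 0) return(empty)
  ev <- tibble::tibble(onset_idx = kept_idx, onset_ms = trace$t[kept_idx],
                       criterion = kept_crit, rise_ms = kept_rise)
  meas <- purrr::map(seq_len(nrow(ev)), function(r) {
    w <- segment_event(trace, ev$onset_idx[r],
                       next_onset_idx = if (r < nrow(ev))
                         ev$onset_idx[r + 1L] else NA_integer_)
    measure_event(trace, w)
  })
  ev <- dplyr::bind_cols(ev, dplyr::bind_rows(meas))
  noise_sd_est <- stats::median(sqrt(sse / (k - 1)))
  ev[ev$peak_pa >= min_peak_snr * noise_sd_est &
       ev$ttp_ms <= max_ttp_ms, ]
}

# Refine a detection index to the event onset by extrapolating the 20-80%
# rise line back to baseline (standard electrophysiology practice; the raw
# criterion maximum lags the onset by a shape-dependent ~2 ms). Returns
# c(onset index, 20-80% rise time in ms); the rise time is Inf when no
# template-like rise exists in the search window (mid-decay trigger).
.refine_onset <- function(det_idx, trace, fs) {
  n <- nrow(trace)
  pre <- as.integer(round(5 * fs / 1000)) # criterion maximum lags the onset
  base_idx <- max(1L, det_idx - pre - round(10 * fs / 1000)):
    max(1L, det_idx - pre - 1L)
  base <- mean(trace$i[base_idx])
  start <- max(1L, det_idx - pre)
  search <- start:min(n, det_idx + round(50 * fs / 1000))
  seg <- abs(trace$i[search] - base)
  pk_rel <- which.max(seg)
  pk <- seg[pk_rel]
  if (pk <= 0 || pk_rel < 3L) return(c(det_idx, Inf))
  rise <- seg[seq_len(pk_rel)]
  cross <- function(frac) {
    below <- which(rise[seq_len(pk_rel - 1L)] < frac * pk &
                     rise[-1] >= frac * pk)
    if (length(below) == 0) return(NA_real_)
    j <- below[length(below)] # last crossing before the peak
    j + (frac * pk - rise[j]) / (rise[j + 1L] - rise[j]) - 1
  }
  c20 <- cross(0.2); c80 <- cross(0.8)
  if (is.na(c20) || is.na(c80) || c80 <= c20) return(c(det_idx, Inf))
  onset_rel <- c20 - 0.2 * (c80 - c20) / 0.6
  c(max(1L, start + as.integer(round(onset_rel))),
    (c80 - c20) * 1000 / fs)
}

#' Segment the fit window around a detected onset
#'
#' The window runs from `pre_ms` before the onset to the first sample at
#' which the baseline-subtracted current has decayed (after its peak) to
#' `decay_frac` of the peak, capped at `max_ms` after onset and truncated
#' before the next event's onset when one is given.
#'
#' @param trace a trace tibble.
#' @param onset_idx 1-based onset sample index.
#' @param pre_ms pre-onset baseline span (ms) included in the window.
#' @param max_ms hard cap on the post-onset window span (ms).
#' @param decay_frac fraction of peak defining the end of the decay.
#' @param next_onset_idx optional onset of the following event.
#' @return A list with `fit_start`, `fit_end` (1-based, half-open
#'   `[fit_start, fit_end)`), and `onset_idx`.
#' @export
segment_event <- function(trace, onset_idx, pre_ms = 2, max_ms = 300,
                          decay_frac = 0.10, next_onset_idx = NA) {
  fs <- trace$sampling_rate[1]
  n <- nrow(trace)
  pre_n <- round(pre_ms * fs / 1000)
  fit_start <- max(1L, onset_idx - pre_n)
  end_cap <- min(n + 1L, onset_idx + round(max_ms * fs / 1000))
  if (!is.na(next_onset_idx)) end_cap <- min(end_cap, next_onset_idx)
  base <- mean(trace$i[fit_start:max(fit_start, onset_idx - 1L)])
  seg <- trace$i[onset_idx:(end_cap - 1L)] - base
  pk <- which.max(abs(seg))
  post_peak <- abs(seg[pk:length(seg)])
  dec <- which(post_peak <= decay_frac * abs(seg[pk]))
  fit_end <- if (length(dec) > 0) onset_idx + pk - 1L + dec[1] else end_cap
  list(fit_start = fit_start, fit_end = min(fit_end, n + 1L),
       onset_idx = onset_idx)
}

#' Measure baseline, peak and time-to-peak of one event
#'
#' Baseline is the mean of the pre-onset segment of the window; peak
#' amplitude is the absolute value of the baseline-subtracted extremum;
#' time-to-peak is measured from the onset.
#'
#' @param trace a trace tibble.
#' @param window a window as returned by [segment_event()].
#' @return A one-row tibble: `fit_start`, `fit_end`, `baseline_pa`,
#'   `peak_pa`, `peak_idx`, `ttp_ms`.
#' @export
measure_event <- function(trace, window) {
  n <- nrow(trace)
  if (window$fit_start < 1L || window$fit_end > n + 1L ||
      window$fit_start >= window$fit_end)
    stop("window out of trace range", call. = FALSE)
  fs <- trace$sampling_rate[1]
  on <- window$onset_idx
  base_idx <- window$fit_start:max(window$fit_start, on - 1L)
  baseline <- mean(trace$i[base_idx])
  seg_idx <- on:(window$fit_end - 1L)
  seg <- trace$i[seg_idx] - baseline
  pk_rel <- which.max(abs(seg))
  tibble::tibble(fit_start = window$fit_start, fit_end = window$fit_end,
                 baseline_pa = baseline, peak_pa = abs(seg[pk_rel]),
                 peak_idx = seg_idx[pk_rel],
                 ttp_ms = (pk_rel - 1L) * 1000 / fs)
}

#' Remove events with overlapping neighbours
#'
#' Any event whose onset lies within `min_separation_ms` of a neighbouring
#' event's onset is removed (both members of a close pair are dropped —
#' their waveforms contaminate each other's fit windows). The neighbour
#' structure is evaluated against `all_events` (by default the input
#' itself), so the overlap predicate commutes with row-wise screens such as
#' [amplitude_consistency_filter()] when the raw event list is supplied.
#'
#' @param events event tibble with an `onset_ms` column, time-ordered.
#' @param min_separation_ms minimum allowed onset separation (ms).
#' @param all_events event tibble defining the neighbour structure
#'   (defaults to `events`).
#' @return The filtered event tibble.
#' @export
exclude_overlaps <- function(events, min_separation_ms = 20,
                             all_events = events) {
  if (nrow(events) <= 1 && nrow(all_events) <= 1) return(events)
  if (is.unsorted(events$onset_ms) || is.unsorted(all_events$onset_ms))
    stop("events must be time-ordered", call. = FALSE)
  ok <- vapply(events$onset_ms, function(o) {
    gaps <- abs(all_events$onset_ms - o)
    all(gaps[gaps > 0] >= min_separation_ms)
  }, logical(1))
  events[ok, ]
}

#' Keep events with amplitudes consistent with a reference distribution
#'
#' Retains events whose peak amplitude lies within `k` reference SDs of the
#' reference mean (default `k = 2`, about 95% normal coverage) — the
#' physiological-plausibility screen applied before fitting.
#'
#' @param events event tibble with a `peak_pa` column.
#' @param ref_mean,ref_sd reference amplitude mean and SD (pA).
#' @param k width of the acceptance band in SDs.
#' @return The filtered event tibble.
#' @export
amplitude_consistency_filter <- function(events, ref_mean, ref_sd, k = 2) {
  if (ref_sd < 0) stop("ref_sd must be >= 0", call. = FALSE)
  if (k <= 0) stop("k must be > 0", call. = FALSE)
  events[abs(events$peak_pa - ref_mean) <= k * ref_sd, ]
}
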