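# Published calibration constants used as generator references and as the
# worked-example inputs. Values are the control-condition fit summaries and
# acquisition descriptors of the three interference experiments:
#   A - cortical mIPSCs: EGFP control / scFv-gephyrin cytoplasmic /
#       scFv-gephyrin NLS, held at -60 mV
#   B - hippocampal sIPSCs: control / scFv-gephyrin NLS, held at -70 mV
#   C - hippocampal sIPSCs: control / delta 2-188 dominant-negative, -70 mV

.control_ref <- list(
  A = list(
    mean = c(h = 0.0193, h1 = 0.1279, alpha_f = 0.0246, alpha_b = 1.5870e-05,
             beta = 56.2268, tau_d = 55.9307, tau_r = 0.7941, phi = 0.3477,
             GEPH = 2.2645, w = 8.7916e-04),
    sd   = c(h = 0.0152, h1 = 0.0754, alpha_f = 0.0179, alpha_b = 2.2676e-05,
             beta = 34.3897, tau_d = 24.5969, tau_r = 0.4377, phi = 0.1967,
             GEPH = 1.4180, w = 6.4561e-04),
    v = -60),
  B = list(
    mean = c(h = 0.0194, h1 = 0.0988, alpha_f = 0.0261, alpha_b = 9.6953e-06,
             beta = 59.2422, tau_d = 28.4567, tau_r = 0.7498, phi = 0.3345,
             GEPH = 2.8081, w = 9.0514e-04),
    sd   = c(h = 0.0142, h1 = 0.0633, alpha_f = 0.0202, alpha_b = 1.7484e-05,
             beta = 44.8992, tau_d = 11.7380, tau_r = 0.5063, phi = 0.2194,
             GEPH = 1.6634, w = 6.8666e-04),
    v = -70),
  C = list(
    mean = c(h = 0.0168, h1 = 0.1220, alpha_f = 0.0292, alpha_b = 1.4038e-05,
             beta = 58.8211, tau_d = 29.7180, tau_r = 1.5015, phi = 0.3191,
             GEPH = 2.6868, w = 0.0011),
    sd   = c(h = 0.0116, h1 = 0.0801, alpha_f = 0.0206, alpha_b = 2.0468e-05,
             beta = 44.3356, tau_d = 13.9137, tau_r = 1.0914, phi = 0.1852,
             GEPH = 1.6748, w = 9.2808e-04),
    v = -70)
)

# Benchmark reference for detection / parameter-recovery checks: same scales
# as the control references, except alpha_b raised to 0.5/ms so the current
# is IPSC-shaped (time-to-peak ~7 ms, decay to 10% within ~80 ms) and all
# four identifiable quantities (tau_d, tau_r, alpha_b, I_FACT) visibly shape
# the trace within the fit window. See the methods vignette.
# w centred so the mean event peak lands near the experimental mIPSC
# amplitude scale (~50 pA), giving synthetic SNR ~10-25 at the default
# 2 pA baseline noise.
.benchmark_ref <- list(
  mean = c(h = 0.0193, h1 = 0.1279, alpha_f = 0.0246, alpha_b = 0.5,
           beta = 56.2268, tau_d = 30, tau_r = 0.8, phi = 0.3477,
           GEPH = 2.2645, w = 0.18),
  sd   = c(h = 0.006, h1 = 0.04, alpha_f = 0.008, alpha_b = 0.12,
           beta = 17, tau_d = 8, tau_r = 0.25, phi = 0.10,
           GEPH = 0.7, w = 0.05),
  v = -70
)

#' Control reference parameter distributions
#'
#' Per-parameter mean and standard deviation of the optimized kinetic
#' parameters under control conditions for the three interference
#' experiments, plus a `"benchmark"` set used by the package's detection and
#' parameter-recovery checks (identical scales but `alpha_b` = 0.02/ms so
#' events decay within the fit window).
#'
#' @param experiment one of `"A"`, `"B"`, `"C"` or `"benchmark"`.
#' @return A tibble with columns `parameter`, `mean`, `sd` and an attribute
#'   `v` holding the experiment's holding potential (mV).
#' @export
#' @examples
#' control_reference("A")
control_reference <- function(experiment = c("A", "B", "C", "benchmark")) {
  experiment <- match.arg(experiment)
  ref <- if (experiment == "benchmark") .benchmark_ref else
    .control_ref[[experiment]]
  out <- tibble::tibble(parameter = fittable_params(),
                        mean = unname(ref$mean[fittable_params()]),
                        sd = unname(ref$sd[fittable_params()]))
  attr(out, "v") <- ref$v
  out
}

#' Reference parameter means as a `syn_params` object
#'
#' @inheritParams control_reference
#' @return A `syn_params` object at the reference means (with the
#'   experiment's holding potential, `c1 = 1`, `erev = 0`).
#' @export
reference_params <- function(experiment = c("A", "B", "C", "benchmark")) {
  experiment <- match.arg(experiment)
  ref <- control_reference(experiment)
  m <- stats::setNames(ref$mean, ref$parameter)
  do.call(syn_params, c(as.list(m), list(v = attr(ref, "v"))))
}

.pv_ref <- tibble::tibble(
  experiment = c("A", "A", "A", "B", "B", "C", "C"),
  condition  = c("control", "cyto", "nls", "control", "nls",
                 "control", "delta2-188"),
  a  = c(0.1652, 0.1239, 0.2258, 0.0409, 0.1252, 0.0556, 0.1022),
  b  = c(23.0536, 32.0002, 16.5380, 90.5464, 27.7427, 76.2090, 37.1999),
  c  = c(0.4555, 0.4609, 0.3102, 1.0000, 1.0000, 1.0000, 1.0000),
  x0 = c(54.5599, 61.8422, 42.5906, 84.2955, 70.6842, 79.6038, 55.9272),
  r  = c(0.9768, 0.9568, 0.9638, 0.8364, 0.9524, 0.8487, 0.9324)
)

#' Reference pseudo-Voigt peak-amplitude distributions
#'
#' Published 4-parameter pseudo-Voigt fits of the peak-current
#' distributions for each experiment and condition (`a` height, `b` width,
#' `c` Lorentzian fraction, `x0` centre in pA, `r` correlation of the fit).
#'
#' @param experiment optional filter, one of `"A"`, `"B"`, `"C"`.
#' @param condition optional condition filter
#'   (`"control"`, `"cyto"`, `"nls"`, `"delta2-188"`).
#' @return A tibble with one row per (experiment, condition).
#' @export
pv_reference <- function(experiment = NULL, condition = NULL) {
  out <- .pv_ref
  if (!is.null(experiment))
    out <- dplyr::filter(out, .data$experiment %in% !!experiment)
  if (!is.null(condition))
    out <- dplyr::filter(out, .data$condition %in% !!condition)
  out
}

.cond_ref <- tibble::tibble(
  experiment = c("A", "A", "A", "B", "B", "C", "C"),
  condition  = c("control", "cyto", "nls", "control", "nls",
                 "control", "delta2-188"),
  frequency_hz = c(1.5, 1.8, 1.1, 1.4, 0.6, 0.91, 0.42),
  amplitude_pa = c(53.2, 48.1, 37.9, 156.4, 75.8, 129.4, 81.9),
  amplitude_sem = c(2.8, 3.5, 1.7, 30, 19.2, 18.8, 13.2),
  n_events_selected = c(290, 272, 70, 267, 203, 144, 112)
)

#' Reference event frequencies and amplitudes per condition
#'
#' Mean spontaneous/miniature IPSC frequencies (Hz), amplitudes (pA, with
#' the reported dispersion of the mean) and the number of
#' amplitude-consistent events selected for fitting, per experiment and
#' condition.
#'
#' @inheritParams pv_reference
#' @return A tibble with one row per (experiment, condition).
#' @export
condition_reference <- function(experiment = NULL, condition = NULL) {
  out <- .cond_ref
  if (!is.null(experiment))
    out <- dplyr::filter(out, .data$experiment %in% !!experiment)
  if (!is.null(condition))
    out <- dplyr::filter(out, .data$condition %in% !!condition)
  out
}
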