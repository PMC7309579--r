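#' Kinetic model parameter set
#'
#' Constructs and validates the parameter set of the gephyrin-dependent
#' kinetic model of inhibitory synaptic transmission. Ten parameters are
#' fittable; `c1`, `erev` and `v` are acquisition constants fixed per
#' dataset.
#'
#' @param w synaptic weight scaling neurotransmitter release (conductance
#'   scale, absorbed units). Must be positive.
#' @param tau_r,tau_d rise and decay time constants of the conductance
#'   waveform (ms); `tau_r < tau_d` strictly.
#' @param beta neurotransmitter generation rate per unit conductance (1/ms).
#' @param alpha_f forward coupling efficiency (dimensionless).
#' @param alpha_b neurotransmitter clearance rate (1/ms).
#' @param phi NLG2/NRXN turnover rate (1/ms); must lie in (0, 2) so that the
#'   NLG2 steady state is positive.
#' @param GEPH gephyrin cluster level (dimensionless).
#' @param h receptor scaffolding rate (1/ms).
#' @param h1 receptor removal rate (1/ms); must be positive.
#' @param c1 current scaling constant; fixed to 1 by convention, all scale
#'   being absorbed by `w`.
#' @param erev GABA-A reversal potential (mV); 0 mV under symmetric
#'   high-chloride solutions.
#' @param v holding potential (mV).
#'
#' @return An object of class `syn_params` (a named list).
#' @seealso [fittable_params()] for the names of the ten free parameters,
#'   [i_fact()] for the closed-form amplitude factor.
#' @export
#' @examples
#' p <- syn_params(w = 8.7916e-4, tau_r = 0.794, tau_d = 55.93,
#'                 beta = 56.23, alpha_f = 0.0246, alpha_b = 1.587e-5,
#'                 phi = 0.3477, GEPH = 2.2645, h = 0.0193, h1 = 0.1279)
#' i_fact(p)
syn_params <- function(w, tau_r, tau_d, beta, alpha_f, alpha_b, phi, GEPH,
                       h, h1, c1 = 1, erev = 0, v = -70) {
  p <- list(w = w, tau_r = tau_r, tau_d = tau_d, beta = beta,
            alpha_f = alpha_f, alpha_b = alpha_b, phi = phi, GEPH = GEPH,
            h = h, h1 = h1, c1 = c1, erev = erev, v = v)
  p <- lapply(p, as.numeric)
  class(p) <- "syn_params"
  validate_syn_params(p)
  p
}

#' @rdname syn_params
#' @param x object to test or coerce.
#' @export
is_syn_params <- function(x) inherits(x, "syn_params")

validate_syn_params <- function(p) {
  stopifnot(is.list(p))
  num1 <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  for (nm in c(fittable_params(), "c1", "erev", "v")) {
    if (!num1(p[[nm]])) stop("parameter '", nm, "' must be a finite scalar",
                             call. = FALSE)
  }
  if (p$w <= 0) stop("w must be > 0", call. = FALSE)
  if (p$tau_r <= 0 || p$tau_d <= 0)
    stop("time constants must be positive", call. = FALSE)
  if (p$tau_r >= p$tau_d)
    stop("tau_r must be strictly smaller than tau_d", call. = FALSE)
  if (abs(p$tau_d - p$tau_r) < 1e-9)
    stop("degenerate time constants: |tau_d - tau_r| below tolerance",
         call. = FALSE)
  for (nm in c("beta", "alpha_f", "alpha_b", "h", "h1", "GEPH")) {
    if (p[[nm]] < 0) stop(nm, " must be >= 0", call. = FALSE)
  }
  if (p$phi <= 0 || p$phi >= 2)
    stop("phi must lie strictly inside (0, 2)", call. = FALSE)
  invisible(p)
}

#' Names of the ten fittable parameters
#'
#' Column order used throughout fit tables and summaries.
#' @return Character vector of length 10.
#' @export
fittable_params <- function() {
  c("h", "h1", "alpha_f", "alpha_b", "beta", "tau_d", "tau_r", "phi",
    "GEPH", "w")
}

#' @export
format.syn_params <- function(x, ...) {
  vals <- unlist(x[fittable_params()])
  paste0("<syn_params> ",
         paste(sprintf("%s=%.4g", names(vals), vals), collapse = ", "),
         sprintf(" | c1=%g erev=%g mV v=%g mV", x$c1, x$erev, x$v))
}

#' @export
print.syn_params <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.list.syn_params <- function(x, ...) unclass(x)

#' Coerce a parameter set to a one-row tibble
#'
#' @param x a `syn_params` object.
#' @param ... unused.
#' @return A one-row tibble with the 10 fittable columns plus `c1`, `erev`,
#'   `v`.
#' @export
as_tibble.syn_params <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c(fittable_params(), "c1", "erev", "v")])
}

#' Serialize / deserialize parameter sets as flat JSON records
#'
#' The JSON record carries exactly the ten fittable keys plus `c1`, `erev`
#' and `v`.
#'
#' @param params a `syn_params` object.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return `params_to_json()`: the path (invisibly) or a JSON string;
#'   `params_from_json()`: a `syn_params` object.
#' @export
params_to_json <- function(params, path = NULL) {
  stopifnot(is_syn_params(params))
  x <- unclass(params)[c(fittable_params(), "c1", "erev", "v")]
  if (is.null(path))
    return(as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname params_to_json
#' @param json a JSON string or file path produced by [params_to_json()].
#' @export
params_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  do.call(syn_params, x[c(fittable_params(), "c1", "erev", "v")])
}

#' Update a parameter set
#'
#' Returns a copy of `params` with the named fields replaced, re-validated.
#'
#' @param params a `syn_params` object.
#' @param ... name = value pairs to replace.
#' @return A `syn_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(is_syn_params(params))
  repl <- list(...)
  p <- unclass(params)
  p[names(repl)] <- lapply(repl, as.numeric)
  class(p) <- "syn_params"
  validate_syn_params(p)
  p
}
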