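# broom-style tidy()/glance() methods for fitted objects.

#' Tidy a fitted event
#'
#' @param x an `ipsc_fit` object.
#' @param ... unused.
#' @return One row per fitted parameter: `term`, `estimate`.
#' @export
tidy.ipsc_fit <- function(x, ...) {
  tibble::tibble(term = fittable_params(),
                 estimate = unlist(unclass(x$params)[fittable_params()]))
}

#' @rdname tidy.ipsc_fit
#' @return `glance()`: a one-row tibble with `rmse`, `peak_pa`,
#'   `rmse_over_peak`, `accepted`, `start_index`, `iterations`,
#'   `converged`, `i_fact`.
#' @export
glance.ipsc_fit <- function(x, ...) {
  tibble::tibble(rmse = x$rmse, peak_pa = x$peak_pa,
                 rmse_over_peak = x$rmse_over_peak, accepted = x$accepted,
                 start_index = x$start_index, iterations = x$iterations,
                 converged = x$converged, i_fact = i_fact(x$params))
}

#' Tidy a pseudo-Voigt fit
#'
#' @param x a `pv_fit` object.
#' @param ... unused.
#' @return `tidy()`: one row per parameter (`term`, `estimate`);
#'   `glance()`: one row with `a`, `b`, `c`, `x0`, `r`, `n`.
#' @export
tidy.pv_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "c", "x0"),
                 estimate = unlist(x$params[c("a", "b", "c", "x0")]))
}

#' @rdname tidy.pv_fit
#' @export
glance.pv_fit <- function(x, ...) {
  dplyr::mutate(x$params, n = x$n)
}

#' Tidy a cross-validation result
#'
#' @param x an `ipsc_cv` object.
#' @param ... unused.
#' @return `tidy()`: the confusion matrix in long form (`truth`,
#'   `prediction`, `n`); `glance()`: one row with `accuracy`, `method`,
#'   `folds`, `n`.
#' @export
tidy.ipsc_cv <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x$confusion,
                                  responseName = "n"))
}

#' @rdname tidy.ipsc_cv
#' @export
glance.ipsc_cv <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, method = x$method,
                 folds = x$folds, n = x$n)
}
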