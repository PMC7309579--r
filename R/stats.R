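# Condition-level statistics: pseudo-Voigt amplitude distributions,
# per-condition parameter summaries, day-wise control-variability
# screening, rank-based multi-group comparison and effect classification.

#' Pseudo-Voigt profile
#'
#' The 4-parameter pseudo-Voigt used to model peak-amplitude histograms:
#' `f(x) = a * (c / (1 + ((x - x0)/b)^2) + (1 - c) * exp(-0.5 ((x - x0)/b)^2))`
#' — a Lorentzian and a Gaussian of shared centre `x0` and width `b`, mixed
#' by the Lorentzian fraction `c`.
#'
#' @param x evaluation points.
#' @param pv list/one-row data frame with `a`, `b`, `c`, `x0`.
#' @return Profile values at `x`.
#' @export
pseudo_voigt <- function(x, pv) {
  pv <- as.list(pv)
  z <- (x - pv$x0) / pv$b
  pv$a * (pv$c / (1 + z^2) + (1 - pv$c) * exp(-0.5 * z^2))
}

#' Fit a pseudo-Voigt profile to a peak-amplitude sample
#'
#' Bins the amplitudes into a density-normalized histogram (30 equal-width
#' bins over `[0, max]` by default) and least-squares fits `(a, b, c, x0)`
#' with `c` constrained to `[0, 1]`, reporting the correlation `r` between
#' fitted and observed bin heights.
#'
#' @param peak_amplitudes numeric vector of positive amplitudes (pA);
#'   at least 50 values.
#' @param n_bins number of histogram bins.
#' @return An object of class `pv_fit`: list with `params` (tibble `a`,
#'   `b`, `c`, `x0`, `r`), `histogram` (tibble `mid`, `density`,
#'   `fitted`), and `n`.
#' @export
fit_pseudo_voigt <- function(peak_amplitudes, n_bins = 30) {
  x <- peak_amplitudes[is.finite(peak_amplitudes)]
  if (length(x) < 50)
    stop("insufficient data: need at least 50 amplitudes", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("degenerate sample: all amplitudes identical", call. = FALSE)
  # heavy Lorentzian tails produce extreme outliers that would collapse an
  # equal-width histogram; bin over a robust upper range instead
  upper <- min(max(x), stats::quantile(x, 0.99))
  x_binned <- x[x <= upper]
  brk <- seq(0, upper, length.out = n_bins + 1L)
  h <- graphics::hist(x_binned, breaks = brk, plot = FALSE)
  df <- tibble::tibble(mid = h$mids, density = h$density)
  x0_start <- df$mid[which.max(df$density)]
  sd_core <- stats::sd(x_binned)
  # the (b, c) surface has boundary local optima (a narrow-start Gaussian
  # can drive c to 1); use a small start grid and keep the best fit
  best <- NULL
  for (b0 in c(sd_core / 2, sd_core, 2 * sd_core)) {
    for (c0 in c(0.05, 0.5, 0.95)) {
      fit <- try(minpack.lm::nlsLM(
        density ~ a * (c / (1 + ((mid - x0) / b)^2) +
                         (1 - c) * exp(-0.5 * ((mid - x0) / b)^2)),
        data = df,
        start = list(a = max(df$density), b = b0, c = c0, x0 = x0_start),
        lower = c(a = 0, b = 1e-9, c = 0, x0 = min(x)),
        upper = c(a = Inf, b = Inf, c = 1, x0 = max(x)),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
        silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (is.null(best) || stats::deviance(fit) < stats::deviance(best))
        best <- fit
    }
  }
  if (is.null(best)) stop("pseudo-Voigt fit failed", call. = FALSE)
  cf <- stats::coef(best)
  df$fitted <- pseudo_voigt(df$mid, as.list(cf))
  structure(list(
    params = tibble::tibble(a = cf[["a"]], b = cf[["b"]], c = cf[["c"]],
                            x0 = cf[["x0"]],
                            r = stats::cor(df$fitted, df$density)),
    histogram = df, n = length(x)), class = "pv_fit")
}

#' @export
print.pv_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<pv_fit> n=%d  a=%.4f b=%.3f c=%.3f x0=%.3f (r=%.4f)\n",
    x$n, p$a, p$b, p$c, p$x0, p$r))
  invisible(x)
}

#' Per-condition parameter summary
#'
#' Mean and SD of each fitted parameter per condition (the layout of the
#' published condition tables). Parameters with zero spread within a
#' condition (i.e. held fixed during fitting, such as a
#' frequency-constrained GEPH) are reported with `sd = NA`.
#'
#' @param fit_table a fit table (see [fit_dataset()]); only accepted fits
#'   are summarized when an `accepted` column is present.
#' @param params parameter columns to summarize.
#' @param fixed_params names of parameters held fixed during fitting,
#'   reported with `sd = NA`.
#' @return A tidy tibble: `condition`, `parameter`, `mean`, `sd`, `n`.
#' @export
summarize_params <- function(fit_table, params = fittable_params(),
                             fixed_params = NULL) {
  if (nrow(fit_table) == 0) stop("empty fit table", call. = FALSE)
  if ("accepted" %in% names(fit_table))
    fit_table <- fit_table[fit_table$accepted, ]
  if (nrow(fit_table) == 0) stop("no accepted fits", call. = FALSE)
  long <- tidyr::pivot_longer(
    fit_table[, c("condition", params)], -"condition",
    names_to = "parameter", values_to = "value")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$condition, .data$parameter),
    mean = mean(.data$value),
    sd = stats::sd(.data$value),
    n = dplyr::n(), .groups = "drop")
  if (!is.null(fixed_params))
    out$sd[out$parameter %in% fixed_params] <- NA_real_
  out$parameter <- factor(out$parameter, levels = params)
  dplyr::arrange(out, .data$condition, .data$parameter)
}

#' Day-to-day control variability
#'
#' For each parameter, computes the relative differences between day
#' centres under control conditions and returns the maximum absolute value
#' (in %). These set the minimum effect size considered meaningful when
#' comparing conditions: a parameter change smaller than its own
#' control-condition fluctuation cannot be attributed to the intervention.
#' Centres are medians by default; with `center = "mean-if-normal"` the
#' mean is used for a day pair when a Shapiro-Wilk test accepts normality
#' in both days (alpha 0.05).
#'
#' @param fit_table control-condition fit table with a `day` column.
#' @param params parameter columns to screen.
#' @param center `"median"` or `"mean-if-normal"`.
#' @param alpha significance level of the normality test.
#' @return A tibble: `parameter`, `max_abs_diff_pct`, plus a `pairs`
#'   list-column of the signed pairwise differences.
#' @export
control_variability <- function(fit_table, params = fittable_params(),
                                center = c("median", "mean-if-normal"),
                                alpha = 0.05) {
  center <- match.arg(center)
  if ("accepted" %in% names(fit_table))
    fit_table <- fit_table[fit_table$accepted, ]
  days <- split(fit_table, fit_table$day)
  if (length(days) < 2)
    stop("need at least two day groups", call. = FALSE)
  one_param <- function(pm) {
    vals <- lapply(days, `[[`, pm)
    nd <- length(vals)
    combs <- utils::combn(nd, 2)
    diffs <- apply(combs, 2, function(ij) {
      x <- vals[[ij[1]]]; y <- vals[[ij[2]]]
      use_mean <- center == "mean-if-normal" &&
        length(unique(x)) > 2 && length(unique(y)) > 2 &&
        stats::shapiro.test(x)$p.value > alpha &&
        stats::shapiro.test(y)$p.value > alpha
      cx <- if (use_mean) mean(x) else stats::median(x)
      cy <- if (use_mean) mean(y) else stats::median(y)
      if (cx == 0) return(NA_real_)
      100 * (cy - cx) / cx
    })
    tibble::tibble(parameter = pm,
                   max_abs_diff_pct = max(abs(diffs), na.rm = TRUE),
                   pairs = list(diffs))
  }
  dplyr::bind_rows(lapply(params, one_param))
}

# Dunn's rank-sum z statistic with tie correction for groups i, j of a
# pooled ranking (no installed package provides this post-hoc procedure)
.dunn_pairs <- function(values, groups, p_adjust = "none") {
  groups <- as.factor(groups)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  n <- tapply(r, groups, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  levs <- levels(groups)
  combs <- utils::combn(length(levs), 2)
  out <- apply(combs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    z <- (rbar[i] - rbar[j]) / sqrt(s2 * (1 / n[i] + 1 / n[j]))
    tibble::tibble(group1 = levs[i], group2 = levs[j], z = unname(z),
                   p_value = 2 * stats::pnorm(-abs(z)))
  })
  out <- dplyr::bind_rows(out)
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out
}

#' Compare fitted parameters across conditions
#'
#' For each parameter: a Kruskal-Wallis omnibus test across the groups
#' followed by Dunn's pairwise z-comparisons on the pooled ranks (tie
#' corrected). Directions and relative changes are computed from the group
#' medians, `100 * (median_other - median_control) / median_control` with
#' the first (or named) group as control.
#'
#' @param fit_table fit table with a `condition` column (accepted fits
#'   only are used when an `accepted` column is present).
#' @param params parameter columns to compare.
#' @param control label of the control group; defaults to the first level.
#' @param p_adjust multiplicity adjustment for the Dunn p-values
#'   (`"none"` by default; any [stats::p.adjust()] method).
#' @param min_group_size minimum fits per group.
#' @return A tibble with one row per parameter and group pair: `parameter`,
#'   `group1`, `group2`, `kw_p`, `z`, `p_value`, `direction`
#'   (sign of the non-control median minus control median),
#'   `relative_change` (%).
#' @export
compare_conditions <- function(fit_table, params = fittable_params(),
                               control = NULL, p_adjust = "none",
                               min_group_size = 8) {
  if ("accepted" %in% names(fit_table))
    fit_table <- fit_table[fit_table$accepted, ]
  fit_table$condition <- as.character(fit_table$condition)
  sizes <- table(fit_table$condition)
  if (length(sizes) < 2) stop("need at least two groups", call. = FALSE)
  if (any(sizes < min_group_size))
    stop("insufficient group size: need at least ", min_group_size,
         " fits per group", call. = FALSE)
  if (is.null(control)) control <- names(sizes)[1]
  one_param <- function(pm) {
    v <- fit_table[[pm]]
    g <- fit_table$condition
    kw <- stats::kruskal.test(v, as.factor(g))$p.value
    dn <- .dunn_pairs(v, g, p_adjust = p_adjust)
    meds <- tapply(v, g, stats::median)
    dn$parameter <- pm
    dn$kw_p <- kw
    # orient each pair as control vs other where possible
    oriented <- dn
    flip <- oriented$group2 == control
    tmp <- oriented$group1[flip]
    oriented$group1[flip] <- oriented$group2[flip]
    oriented$group2[flip] <- tmp
    oriented$z[flip] <- -oriented$z[flip]
    oriented$direction <- unname(sign(meds[oriented$group2] -
                                        meds[oriented$group1]))
    oriented$relative_change <-
      unname(100 * (meds[oriented$group2] - meds[oriented$group1]) /
               meds[oriented$group1])
    oriented
  }
  out <- dplyr::bind_rows(lapply(params, one_param))
  out[, c("parameter", "group1", "group2", "kw_p", "z", "p_value",
          "direction", "relative_change")]
}

#' Classify per-parameter effects of an intervention
#'
#' Applies the four-way labelling rule: no statistically significant
#' difference gives `no-difference` (empty box); a significant difference
#' whose relative change does not exceed the day-to-day fluctuation seen
#' under control conditions gives `within-control-range` (gray);
#' otherwise `significant-increase` (control median lower, blue) or
#' `significant-decrease` (control median higher, cyan).
#'
#' @param comparison output of [compare_conditions()] (one comparison
#'   pair).
#' @param control_var output of [control_variability()] on the control
#'   fits.
#' @param alpha significance threshold (0.05).
#' @return A tibble: `parameter`, `direction`, `p_value`,
#'   `relative_change`, `control_max_change`, `label`.
#' @export
classify_effects <- function(comparison, control_var, alpha = 0.05) {
  m <- dplyr::left_join(
    comparison,
    control_var[, c("parameter", "max_abs_diff_pct")], by = "parameter")
  lab <- function(p, rc, cmax, dir) {
    if (is.na(p) || p >= alpha) return("no-difference")
    if (!is.na(cmax) && abs(rc) <= cmax) return("within-control-range")
    if (dir > 0) "significant-increase" else "significant-decrease"
  }
  tibble::tibble(
    parameter = m$parameter,
    direction = dplyr::case_when(m$direction > 0 ~ "higher",
                                 m$direction < 0 ~ "lower",
                                 TRUE ~ "none"),
    p_value = m$p_value,
    relative_change = m$relative_change,
    control_max_change = m$max_abs_diff_pct,
    label = purrr::pmap_chr(
      list(m$p_value, m$relative_change, m$max_abs_diff_pct, m$direction),
      lab))
}
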