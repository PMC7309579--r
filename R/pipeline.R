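# End-to-end pipeline: synth -> measure -> filter -> fit -> analyze ->
# classify, with every stage's outputs and the resolved configuration
# persisted to a results directory.

.default_config <- function() {
  list(
    seed = 1,
    outdir = "ipscfit-results",
    synth = list(
      n_events_per_condition = 40,
      reference = "benchmark",
      noise_sd = 2,
      control = list(label = "control", n_cells = 5, n_days = 3,
                     event_frequency = 1.5, geph_scale = 1),
      blocked = list(label = "nls", n_cells = 5, n_days = 3,
                     event_frequency = 1.1, geph_scale = 1)
    ),
    filter = list(k = 2),
    fit = list(n_starts = 8, max_iterations = 500, decades = 2.5,
               rmse_accept_fraction = 0.10, fix_geph = TRUE),
    analyze = list(alpha = 0.05, center = "median", p_adjust = "none"),
    classify = list(method = "knn", folds = 10)
  )
}

# overlay user config onto defaults, recursively
.merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes synth (or manifest replay) -> measure -> amplitude filter ->
#' fit (with two-pass frequency-proportional GEPH fixing: control events
#' are fitted unconstrained, the blocked condition is then fitted with GEPH
#' fixed to the control mean scaled by the event-frequency ratio) ->
#' analyze (summaries, day-wise control variability, rank-based comparison,
#' effect labels) -> classify. Every stage's outputs, the resolved
#' configuration and all seeds are written to `config$outdir`; a run log
#' records the event counts surviving each screen.
#'
#' @param config a named list (see Details) or a path readable by
#'   [read_config()]. Only `outdir` is required; all other entries have
#'   defaults. Provide either `synth` settings or `manifest` (path to a
#'   dataset manifest JSON).
#' @return Invisibly, a list with `events`, `fits`, `counts`, `summary`,
#'   `control_variability`, `comparison`, `effects`, `classification`,
#'   `config`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  user <- config
  config <- .merge_config(.default_config(), user)
  if (is.null(user$outdir)) stop("config must name an outdir",
                                 call. = FALSE)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  # -- stage 0/1: inputs ---------------------------------------------------
  dataset <- .stage("synth", {
    if (!is.null(config$manifest)) {
      if (!file.exists(config$manifest))
        stop("input manifest not found: ", config$manifest)
      regenerate_dataset(read_manifest(config$manifest))
    } else if (!is.null(config$synth)) {
      sy <- config$synth
      mk <- function(sp) condition_spec(
        label = sp$label, n_cells = sp$n_cells, n_days = sp$n_days,
        event_frequency = sp$event_frequency, geph_scale = sp$geph_scale,
        param_perturbations = unlist(sp$param_perturbations))
      make_condition_dataset(
        mk(sy$control), mk(sy$blocked),
        n_events_per_condition = sy$n_events_per_condition,
        reference = control_reference(sy$reference),
        acq = acquisition_spec(noise_sd = sy$noise_sd),
        seed = config$seed, traces = TRUE)
    } else stop("no input manifest or synthetic-data settings")
  })
  events <- dataset$events
  write_manifest(dataset, file.path(config$outdir, "manifest.json"))
  say("synth: %d events (%s)", nrow(events),
      paste(sprintf("%s=%d", names(table(events$condition)),
                    table(events$condition)), collapse = ", "))

  # -- stage 2: measure + reference amplitudes -----------------------------
  events <- .stage("measure", {
    events$peak_pa <- purrr::map_dbl(events$trace, function(tr) {
      on <- attr(tr, "onset_ms") %||% 0
      base <- mean(tr$i[tr$t < on])
      max(abs(tr$i[tr$t >= on] - base))
    })
    events
  })

  # -- stage 3: amplitude-consistency filter -------------------------------
  amp_ref <- dplyr::summarise(
    dplyr::group_by(events, .data$condition),
    mean = mean(.data$peak_pa), sd = stats::sd(.data$peak_pa),
    .groups = "drop")
  n_before <- table(events$condition)
  events <- .stage("filter", {
    keep <- purrr::map_lgl(seq_len(nrow(events)), function(r) {
      ref <- amp_ref[amp_ref$condition == events$condition[r], ]
      abs(events$peak_pa[r] - ref$mean) <= config$filter$k * ref$sd
    })
    events[keep, ]
  })
  n_after <- table(events$condition)
  for (cond in names(n_before))
    say("filter: %s %d -> %d events (amplitude-consistency, k=%g)",
        cond, n_before[[cond]], n_after[[cond]] %||% 0, config$filter$k)

  # -- stage 4: fit (two-pass GEPH fixing) ---------------------------------
  ctrl_label <- config$synth$control$label
  blk_label <- config$synth$blocked$label
  fits <- .stage("fit", {
    cfg <- fit_config(
      n_starts = config$fit$n_starts,
      max_iterations = config$fit$max_iterations,
      decades = config$fit$decades,
      reference = control_reference(config$synth$reference),
      rmse_accept_fraction = config$fit$rmse_accept_fraction,
      seed = config$seed)
    ctrl_fits <- fit_dataset(events[events$condition == ctrl_label, ], cfg)
    geph_fixed <- NULL
    if (isTRUE(config$fit$fix_geph)) {
      geph_ctrl <- mean(ctrl_fits$GEPH[ctrl_fits$accepted])
      if (!is.finite(geph_ctrl)) { # no accepted control fits at all
        geph_ctrl <- mean(ctrl_fits$GEPH)
        say("fit: no accepted control fits; control GEPH taken over all fits")
      }
      geph_blk <- geph_from_frequency(
        geph_ctrl,
        config$synth$control$event_frequency,
        config$synth$blocked$event_frequency)
      say("fit: control mean GEPH %.4f; %s GEPH fixed to %.4f (frequencies %.3g -> %.3g Hz)",
          geph_ctrl, blk_label, geph_blk,
          config$synth$control$event_frequency,
          config$synth$blocked$event_frequency)
      geph_fixed <- stats::setNames(geph_blk, blk_label)
    }
    blk_fits <- fit_dataset(events[events$condition == blk_label, ], cfg,
                            geph_fixed = geph_fixed)
    dplyr::bind_rows(ctrl_fits, blk_fits)
  })
  counts <- dplyr::summarise(
    dplyr::group_by(fits, .data$condition),
    n_fitted = dplyr::n(), n_accepted = sum(.data$accepted),
    acceptance_pct = acceptance_rate(sum(.data$accepted), dplyr::n()),
    .groups = "drop")
  for (r in seq_len(nrow(counts)))
    say("fit: %s %d fitted, %d accepted (%.2f%%)",
        counts$condition[r], counts$n_fitted[r], counts$n_accepted[r],
        counts$acceptance_pct[r])

  # -- stage 5: analyze ----------------------------------------------------
  analysis <- .stage("analyze", {
    afits <- fits[fits$accepted, ]
    enough <- length(unique(afits$condition)) >= 2 &&
      all(table(afits$condition) >= 8) &&
      length(unique(afits$day[afits$condition == ctrl_label])) >= 2
    if (!enough) { # sparse acceptance: analyze all fits, flagged in the log
      afits <- fits
      afits$accepted <- NULL
      say("analyze: too few accepted fits, using all fits")
    }
    smry <- summarize_params(afits)
    cv <- control_variability(afits[afits$condition == ctrl_label, ],
                              center = config$analyze$center)
    cmp <- compare_conditions(afits, control = ctrl_label,
                              p_adjust = config$analyze$p_adjust)
    eff <- classify_effects(cmp, cv, alpha = config$analyze$alpha)
    list(summary = smry, control_variability = cv, comparison = cmp,
         effects = eff)
  })
  say("analyze: %d/%d parameters labelled %s",
      sum(analysis$effects$label %in%
            c("no-difference", "within-control-range")),
      nrow(analysis$effects), "no-difference/within-control-range")

  # -- stage 6: classify ---------------------------------------------------
  cls <- .stage("classify", {
    acc_fits <- fits[fits$accepted, ]
    if (any(table(acc_fits$condition) < 20) ||
        length(unique(acc_fits$condition)) < 2)
      acc_fits <- fits # sparse acceptance: classify all fits
    if (length(unique(acc_fits$condition)) < 2 ||
        any(table(acc_fits$condition) < 20)) {
      say("classify: skipped (fewer than 20 events per class)")
      NULL
    } else {
      cv <- cross_validated_classify(acc_fits[, fittable_params()],
                                     acc_fits$condition,
                                     method = config$classify$method,
                                     folds = config$classify$folds,
                                     seed = config$seed)
      say("classify: %s accuracy %.1f%%", cv$method, 100 * cv$accuracy)
      cv
    }
  })

  # -- persist -------------------------------------------------------------
  out <- config$outdir
  utils::write.csv(dplyr::select(events, -"trace"),
                   file.path(out, "events.csv"), row.names = FALSE)
  utils::write.csv(fits, file.path(out, "fits.csv"), row.names = FALSE)
  utils::write.csv(analysis$summary, file.path(out, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(
    dplyr::select(analysis$control_variability, -"pairs"),
    file.path(out, "control_variability.csv"), row.names = FALSE)
  utils::write.csv(analysis$comparison, file.path(out, "comparison.csv"),
                   row.names = FALSE)
  utils::write.csv(analysis$effects, file.path(out, "effects.csv"),
                   row.names = FALSE)
  if (!is.null(cls))
    write_classification_report(cls, file.path(out, "classification.json"))
  jsonlite::write_json(config, file.path(out, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(log_lines, file.path(out, "run_log.txt"))

  invisible(list(events = events, fits = fits, counts = counts,
                 summary = analysis$summary,
                 control_variability = analysis$control_variability,
                 comparison = analysis$comparison,
                 effects = analysis$effects, classification = cls,
                 config = config))
}
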