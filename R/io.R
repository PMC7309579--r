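# Trace / event / config file formats. Traces are 2-column CSV
# (time_ms, current_pA) with '#' metadata header lines.

#' Write and read trace files
#'
#' Traces are stored as 2-column CSV (`time_ms`, `current_pA`) preceded by
#' `#`-prefixed metadata lines (`sampling_rate`, `holding_mv`, `condition`,
#' `cell`, `day`). Samples are written with full precision so a
#' write-then-read round trip reproduces them bit-for-bit.
#'
#' @param trace a trace tibble (columns `t`, `i`, `sampling_rate`, and
#'   optionally `condition`, `cell`, `day`).
#' @param path file path.
#' @param holding_mv holding potential recorded in the header (mV).
#' @return `write_trace()` returns `path` invisibly; `read_trace()` a
#'   trace tibble.
#' @export
write_trace <- function(trace, path, holding_mv = -70) {
  meta <- c(
    sprintf("# sampling_rate %.17g", trace$sampling_rate[1]),
    sprintf("# holding_mv %.17g", holding_mv),
    sprintf("# condition %s", trace$condition[1] %||% NA),
    sprintf("# cell %s", trace$cell[1] %||% NA),
    sprintf("# day %s", trace$day[1] %||% NA))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines("time_ms,current_pA", con)
  writeLines(sprintf("%.17g,%.17g", trace$t, trace$i), con)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- lines[is_meta]
  get_meta <- function(key) {
    m <- meta[grepl(paste0("^# ", key, " "), meta)]
    if (length(m) == 0) return(NA_character_)
    sub(paste0("^# ", key, " "), "", m[1])
  }
  body <- lines[!is_meta]
  if (length(body) < 2 || body[1] != "time_ms,current_pA")
    stop("malformed trace file: ", path, call. = FALSE)
  dat <- utils::read.csv(text = body, colClasses = "numeric")
  if (nrow(dat) < 2) stop("malformed trace file: too few samples",
                          call. = FALSE)
  dt <- diff(dat$time_ms)
  if (any(abs(dt - dt[1]) > 1e-9 * max(abs(dt[1]), 1)))
    stop("non-uniform time grid in ", path, call. = FALSE)
  fs_header <- as.numeric(get_meta("sampling_rate"))
  fs_grid <- 1000 / dt[1]
  if (is.na(fs_header)) {
    fs_header <- fs_grid
  } else if (abs(fs_header - fs_grid) > 1e-6 * fs_grid) {
    stop("malformed trace file: header sampling_rate ", fs_header,
         " disagrees with the time column (", fs_grid, ")", call. = FALSE)
  }
  chr_or_na <- function(x) if (is.na(x) || x == "NA") NA_character_ else x
  tibble::tibble(t = dat$time_ms, i = dat$current_pA,
                 sampling_rate = fs_header,
                 condition = chr_or_na(get_meta("condition")),
                 cell = chr_or_na(get_meta("cell")),
                 day = chr_or_na(get_meta("day")))
}

#' Write and read event tables
#'
#' Event lists are CSV with 0-based indices and half-open
#' `[fit_start, fit_end)` windows.
#'
#' @param events event tibble (see [sliding_template_detect()]).
#' @param path file path.
#' @return `write_events()` returns `path` invisibly; `read_events()` the
#'   event tibble (1-based indices restored).
#' @export
write_events <- function(events, path) {
  out <- as.data.frame(events)
  for (col in intersect(c("onset_idx", "fit_start", "fit_end", "peak_idx"),
                        names(out)))
    out[[col]] <- out[[col]] - 1L # 0-based on disk
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  out <- utils::read.csv(path)
  for (col in intersect(c("onset_idx", "fit_start", "fit_end", "peak_idx"),
                        names(out)))
    out[[col]] <- out[[col]] + 1L
  tibble::as_tibble(out)
}

#' Read a pipeline configuration file
#'
#' YAML or JSON, by extension.
#'
#' @param path config file path.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
}
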