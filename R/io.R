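#' Write / read a set of sweeps
#'
#' A sweep set is a long tibble with a `sweep` identifier column plus the
#' trace columns `time` and `current`; all sweeps must share one sampling
#' rate.  On disk each sweep becomes a two-column TSV (`time_s`,
#' `current_pA`) with one header line, tied together by a JSON manifest
#' recording sweep ids, files, the common rate and optional per-sweep
#' labels (condition, protocol, ...).  Numeric values round-trip exactly
#' (shortest round-trip decimal representation).
#'
#' @param sweeps Long tibble with columns `sweep`, `time`, `current`.
#' @param dir Directory to create/write into.
#' @param labels Optional tibble of per-sweep metadata with a `sweep` column.
#' @return `write_sweeps()` returns `dir` invisibly; `read_sweeps()` returns
#'   the long tibble with the labels tibble attached as attribute `"labels"`.
#' @export
write_sweeps <- function(sweeps, dir, labels = NULL) {
  if (!all(c("sweep", "time", "current") %in% names(sweeps)))
    abort("`sweeps` must have columns sweep, time, current.")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- unique(sweeps$sweep)
  rates <- vapply(ids, function(id)
    trace_rate(dplyr::filter(sweeps, .data$sweep == id)), numeric(1))
  if (diff(range(rates)) > 1e-6 * rates[1])
    abort("all sweeps in a set must share one sampling rate.")
  files <- sprintf("sweep_%03d.tsv", seq_along(ids))
  for (k in seq_along(ids)) {
    tr <- dplyr::filter(sweeps, .data$sweep == ids[k])
    readr::write_tsv(
      full_precision(tibble::tibble(time_s = tr$time, current_pA = tr$current)),
      file.path(dir, files[k])
    )
  }
  manifest <- list(
    format = "synaptoscope-sweeps-v1",
    rate_hz = rates[1],
    sweeps = data.frame(sweep = as.character(ids), file = files,
                        stringsAsFactors = FALSE)
  )
  if (!is.null(labels)) manifest$labels <- as.data.frame(labels)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_sweeps
#' @export
read_sweeps <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) abort(sprintf("no manifest.json found in '%s'.", dir))
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  out <- purrr::map2_dfr(
    manifest$sweeps$sweep, manifest$sweeps$file,
    function(id, f) {
      x <- read_checked_tsv(file.path(dir, f), c("time_s", "current_pA"))
      tibble::tibble(sweep = id, time = x$time_s, current = x$current_pA)
    }
  )
  attr(out, "labels") <-
    if (!is.null(manifest$labels)) tibble::as_tibble(manifest$labels) else NULL
  out
}

# feature columns used for clustering; amplitude and flags ride along
event_table_columns <- function() {
  c("event", "t_peak", "amplitude",
    "rise_10_90", "rise_20_80", "rise_30_70",
    "max_rise_slope", "max_rise_slope_norm", "rise_slope_norm",
    "iei", "inst_freq", "burst_window", "burst_cv",
    "clean_rise", "clean_decay")
}

#' Write / read an event table
#'
#' Event tables are TSV files with one row per detected event and fixed,
#' documented column names (see `event_table_columns()`); extra columns
#' (cell id, condition, ...) are preserved in order.
#'
#' @param events Event tibble.
#' @param path File path.
#' @param required Columns that must be present on read.
#' @return `read_events()` returns the event tibble.
#' @export
write_events <- function(events, path) {
  readr::write_tsv(full_precision(events), path)
  invisible(path)
}

# doubles rendered with 17 significant digits so the decimal text
# round-trips bit-exactly
full_precision <- function(df) {
  for (cl in names(df))
    if (is.double(df[[cl]]))
      df[[cl]] <- ifelse(is.na(df[[cl]]), NA_character_,
                         sprintf("%.17g", df[[cl]]))
  df
}

#' @rdname write_events
#' @export
read_events <- function(path, required = c("event", "t_peak", "amplitude")) {
  read_checked_tsv(path, required)
}

read_checked_tsv <- function(path, required) {
  if (!file.exists(path)) abort(sprintf("file '%s' does not exist.", path))
  # columns come in as text and are converted with base R's strtod-backed
  # parser, which round-trips %.17g decimals bit-exactly
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       lazy = FALSE,
                       col_types = readr::cols(.default = "c"))
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    abort(sprintf("parse error in '%s' (header line 1): missing required column(s) %s.",
                  path, paste0("'", missing_cols, "'", collapse = ", ")))
  tibble::as_tibble(utils::type.convert(as.data.frame(x), as.is = TRUE))
}
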