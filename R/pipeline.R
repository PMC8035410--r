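#' Configure an end-to-end simulated experiment
#'
#' Describes a multi-condition study run entirely inside the package: each
#' condition has a name, a number of cells and a [train_config()]
#' generating that condition's sIPSC trains.  Detection, fluctuation
#' analysis and clustering parameters are carried alongside.
#'
#' @param conditions List of `list(name =, n_cells =, config = train_config)`.
#' @param template Detection template ([event_template()]).
#' @param threshold Detection threshold.
#' @param nsfa_min_events Minimum clean-decay events for the per-cell
#'   parabola fit.
#' @param cluster `NULL` to skip clustering, or a list with `G` (fixed
#'   component count) or `G_range`, plus optional `n_start`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(conditions, template = event_template(),
                       threshold = 4, nsfa_min_events = 25,
                       cluster = NULL) {
  for (cd in conditions)
    if (is.null(cd$name) || is.null(cd$n_cells) || is.null(cd$config))
      abort("each condition needs `name`, `n_cells` and `config`.")
  structure(list(conditions = conditions, template = template,
                 threshold = threshold, nsfa_min_events = nsfa_min_events,
                 cluster = cluster),
            class = "run_config")
}

#' Run the full analysis pipeline on simulated conditions
#'
#' For every cell of every condition: simulate an sIPSC train, detect
#' events, apply the clean-rise/clean-decay selection rules, extract
#' features, fit the averaged-waveform decay, and run peak-scaled
#' fluctuation analysis.  Per-cell summaries (mean clean-rise amplitude,
#' median interevent interval, mean 20-80% rise time, weighted decay time
#' constant, unitary current and receptor number) are then compared across
#' conditions with [group_compare()], and the pooled amplitude-independent
#' feature set is clustered if requested.  Fully deterministic given
#' `seed`.
#'
#' @param config A [run_config()].
#' @param seed Integer seed.
#' @param out_dir Optional directory; when given, per-cell summaries,
#'   event tables, test results and a JSON manifest (seed, configuration
#'   hash) are written as TSV/JSON.
#' @return A list: `cells` (per-cell summary tibble), `events` (pooled
#'   event tibble), `tests` (group comparisons), `cluster` (clustering
#'   results or `NULL`), `manifest`.
#' @export
run_pipeline <- function(config, seed = 1, out_dir = NULL) {
  if (!inherits(config, "run_config")) abort("`config` must be a run_config.")
  set.seed(seed)
  cell_seeds <- sample.int(2^31 - 2, sum(vapply(config$conditions,
                                                function(cd) cd$n_cells,
                                                numeric(1))))
  k <- 0L
  cells <- list(); events <- list()
  for (cd in config$conditions) {
    for (cell in seq_len(cd$n_cells)) {
      k <- k + 1L
      res <- analyse_cell(cd, cell, config, cell_seeds[k])
      cells[[k]] <- res$summary
      events[[k]] <- res$events
    }
  }
  cells <- dplyr::bind_rows(cells)
  events <- dplyr::bind_rows(events)

  metrics <- c("mean_amplitude", "median_iei", "mean_rise_20_80",
               "tau_w_ms", "nsfa_i", "nsfa_n")
  tests <- purrr::map_dfr(metrics, function(mt) {
    ok <- is.finite(cells[[mt]])
    counts <- table(cells$condition[ok])
    if (length(counts) < 2 || any(counts < 2)) return(NULL)
    dplyr::mutate(
      group_compare(cells[ok, ], value = mt, group = "condition"),
      metric = mt, .before = 1)
  })

  clust <- NULL
  if (!is.null(config$cluster)) {
    feats <- dplyr::select(events, dplyr::all_of(clustering_features()))
    keep <- rowSums(!is.finite(as.matrix(feats))) == 0
    Xs <- standardize(feats[keep, ])
    clust <- if (!is.null(config$cluster$G)) {
      list(best = fit_skewt_mixture(as.matrix(Xs), config$cluster$G,
                                    seed = seed,
                                    n_start = config$cluster$n_start %||% 3))
    } else {
      select_components(as.matrix(Xs),
                        G_range = config$cluster$G_range %||% 1:6,
                        seed = seed,
                        n_start = config$cluster$n_start %||% 3)
    }
    clust$summary <- cluster_condition_summary(
      clust$best$labels, events$condition[keep],
      extras = events[keep, c("amplitude", "rise_10_90", "inst_freq",
                              "rise_slope_norm", "max_rise_slope")])
    clust$kept <- keep
  }

  manifest <- list(seed = seed, n_cells = nrow(cells),
                   n_events = nrow(events),
                   config_hash = rlang::hash(config))
  out <- list(cells = cells, events = events, tests = tests,
              cluster = clust, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(cells, file.path(out_dir, "cells.tsv"))
    readr::write_tsv(events, file.path(out_dir, "events.tsv"))
    readr::write_tsv(tests, file.path(out_dir, "tests.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

# the nine amplitude-independent features used for clustering
clustering_features <- function() {
  c("inst_freq", "rise_10_90", "rise_20_80", "rise_30_70",
    "max_rise_slope_norm", "rise_slope_norm", "iei",
    "burst_window", "burst_cv")
}

analyse_cell <- function(cd, cell, config, seed) {
  sim <- simulate_train(cd$config, seed = seed)
  ev <- detect_events(sim$trace, config$template, config$threshold)
  ev <- flag_selection(ev, sim$trace)
  ev <- extract_features(ev, sim$trace)
  cell_id <- sprintf("%s_%02d", cd$name, cell)
  ev <- dplyr::mutate(ev, cell = cell_id, condition = cd$name)

  # averaging and fluctuation analysis additionally require isolation:
  # no following event inside the decay window
  gap_next <- c(diff(ev$t_peak), Inf)
  ev_iso <- ev[gap_next > 0.05, , drop = FALSE]

  tau_w <- tryCatch({
    aw <- average_waveform(ev_iso, sim$trace, align = "peak", use = "clean_decay")
    pk <- aw$peak_index
    m <- aw$mean$current
    # fit the decay only down to 5% of the peak; later samples are
    # dominated by neighbouring events and baseline noise
    stop_at <- which(seq_along(m) > pk & abs(m) <= 0.05 * abs(m[pk]))[1]
    if (is.na(stop_at)) stop_at <- length(m)
    dec <- tibble::tibble(time = aw$mean$time[pk:stop_at],
                          current = aw$mean$current[pk:stop_at])
    weighted_tau(fit_exponentials(dec, max_components = 2))
  }, error = function(e) NA_real_)

  nres <- tryCatch(
    nsfa(ev_iso, sim$trace, min_events = config$nsfa_min_events),
    error = function(e) NULL)

  summary <- tibble::tibble(
    cell = cell_id, condition = cd$name,
    n_events = nrow(ev),
    n_clean_rise = sum(isTRUE_vec(ev$clean_rise)),
    n_clean_decay = sum(isTRUE_vec(ev$clean_decay)),
    mean_amplitude = mean(ev$amplitude[isTRUE_vec(ev$clean_rise)]),
    median_iei = median(ev$iei, na.rm = TRUE),
    mean_rise_20_80 = mean(ev$rise_20_80, na.rm = TRUE),
    tau_w_ms = tau_w,
    nsfa_i = if (is.null(nres)) NA_real_ else nres$i,
    nsfa_n = if (is.null(nres)) NA_real_ else nres$n_channels
  )
  list(summary = summary, events = ev)
}

#' Compare per-cell summaries across groups
#'
#' Two groups are compared with a two-tailed Student's t-test (equal
#' variances by default, Welch by flag); more than two with a one-way
#' ANOVA followed by Tukey's HSD.  Inputs should be per-cell summaries —
#' aggregate events to cells first, never test event-level replicates.
#'
#' @param data Data frame of per-cell values.
#' @param value Name of the value column.
#' @param group Name of the grouping column.
#' @param var_equal Use the equal-variance t statistic (default `TRUE`).
#' @return A tibble with `comparison`, `method`, `statistic`, `df`,
#'   `p_value` (one row per comparison; ANOVA adds the omnibus F row and
#'   one row per Tukey pair).
#' @export
group_compare <- function(data, value, group, var_equal = TRUE) {
  v <- data[[value]]; g <- factor(data[[group]])
  if (any(table(g) < 2)) abort("every group needs at least 2 cells.")
  if (nlevels(g) < 2) abort("need at least 2 groups.")
  if (nlevels(g) == 2) {
    tt <- t.test(v ~ g, var.equal = var_equal)
    tibble::tibble(
      comparison = paste(levels(g), collapse = " vs "),
      method = if (var_equal) "Student t" else "Welch t",
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value)
  } else {
    fit <- aov(v ~ g)
    an <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$g
    dplyr::bind_rows(
      tibble::tibble(comparison = "omnibus", method = "one-way ANOVA",
                     statistic = an[["F value"]][1], df = an[["Df"]][1],
                     p_value = an[["Pr(>F)"]][1]),
      tibble::tibble(comparison = gsub("-", " vs ", rownames(tk)),
                     method = "Tukey HSD", statistic = tk[, "diff"],
                     df = an[["Df"]][2], p_value = tk[, "p adj"])
    )
  }
}

#' Mean cumulative probability across cells
#'
#' Evaluates each cell's empirical CDF of `value` on a common grid and
#' averages across cells, so every cell carries equal weight regardless of
#' its event count.
#'
#' @param events Event tibble with a `cell` column.
#' @param value Column to summarise (e.g. `"amplitude"`).
#' @param grid_n Grid resolution.
#' @return A tibble with `value` and `cum_prob`.
#' @export
mean_cumulative_probability <- function(events, value, grid_n = 200) {
  x <- events[[value]]
  grid <- seq(min(x, na.rm = TRUE), max(x, na.rm = TRUE),
              length.out = grid_n)
  per_cell <- events |>
    dplyr::group_by(.data$cell) |>
    dplyr::group_map(~ stats::ecdf(.x[[value]])(grid))
  tibble::tibble(value = grid,
                 cum_prob = rowMeans(do.call(cbind, per_cell)))
}
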