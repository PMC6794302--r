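#' Run the full trajectory-mining pipeline
#'
#' Orchestrates the stages end to end: (optionally) simulate or read a
#' registry, merge editions with the deceased-only rule, round diagnoses to
#' the three-digit level, drop non-disease admissions, build first-diagnosis
#' timelines, compute pair associations (RA, binomial test, BH-FDR), orient
#' the significant pairs in time (directionality score, sign test, BH-FDR),
#' and concatenate them into trajectory DAGs. Identical input and seed give
#' identical outputs.
#'
#' @param input One of: an admission tibble, a path to a delimited admission
#'   file (see [read_admissions()]), or a [sim_config()] to simulate from.
#' @param window_days Pairwise and consecutive-step window (default 365).
#' @param ra_min RA selection threshold (default 1).
#' @param fdr FDR threshold applied at both the association and the
#'   direction stage (default 0.1).
#' @param latest_edition Passed to [merge_editions()].
#' @param outdir Optional output directory; when given, writes
#'   `pair_stats.tsv`, `directed_pairs.tsv`, `paths.tsv`,
#'   `filter_report.json`, `manifest.json` and one serialized DAG per root
#'   under `dags/`.
#' @param export_formats DAG export formats when writing (default "json").
#' @return A `trajmine_run` object: list with `timelines`, `pair_stats`,
#'   `significant`, `directed`, `dags`, `filter_report` and `manifest` (the
#'   per-stage record counts, thresholds and seed).
#' @export
run_pipeline <- function(input, window_days = 365, ra_min = 1, fdr = 0.1,
                         latest_edition = NULL, outdir = NULL,
                         export_formats = "json") {
  seed <- NA_integer_
  if (inherits(input, "sim_config")) {
    seed <- input$seed
    records <- generate_registry(input)
  } else if (is.character(input)) {
    records <- read_admissions(input)
  } else {
    records <- as_admissions(input)
  }

  prep <- prepare_timelines(records, latest_edition = latest_edition)
  stats_tbl <- pair_associations(prep$timelines, window_days = window_days,
                                 n_total = prep$n_cohort)
  sig <- significant_pairs(stats_tbl, ra_min = ra_min, fdr = fdr)
  directed <- directed_pairs(prep$timelines, sig, window_days = window_days,
                             fdr = fdr)
  dags <- build_trajectories(directed, prep$timelines,
                             window_days = window_days)
  paths_tbl <- purrr::map_dfr(dags, function(d) {
    dplyr::mutate(d$paths, root = d$root, .before = 1)
  })

  manifest <- list(
    seed = seed,
    window_days = window_days,
    ra_min = ra_min,
    fdr = fdr,
    package_version = as.character(utils::packageVersion("trajmine")),
    n_records_raw = nrow(records),
    n_records_merged = nrow(prep$merged),
    n_cohort = prep$n_cohort,
    n_timeline_entries = nrow(prep$timelines),
    n_codes = dplyr::n_distinct(prep$timelines$code),
    n_pairs_tested = nrow(stats_tbl),
    n_pairs_significant = nrow(sig),
    n_directed_pairs = nrow(directed),
    n_dags = length(dags),
    n_paths = nrow(paths_tbl)
  )

  run <- structure(
    list(
      timelines = prep$timelines,
      pair_stats = stats_tbl,
      significant = sig,
      directed = directed,
      dags = dags,
      filter_report = prep$filter_report,
      manifest = manifest
    ),
    class = "trajmine_run"
  )
  if (!is.null(outdir)) write_run(run, outdir, export_formats)
  run
}

write_run <- function(run, outdir, export_formats = "json") {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(run$pair_stats, file.path(outdir, "pair_stats.tsv"),
                   progress = FALSE)
  readr::write_tsv(run$directed, file.path(outdir, "directed_pairs.tsv"),
                   progress = FALSE)
  paths_tbl <- purrr::map_dfr(run$dags, function(d) {
    dplyr::mutate(d$paths, root = d$root, .before = 1)
  })
  readr::write_tsv(paths_tbl, file.path(outdir, "paths.tsv"),
                   progress = FALSE)
  jsonlite::write_json(run$filter_report, file.path(outdir, "filter_report.json"))
  jsonlite::write_json(run$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (length(run$dags) > 0) {
    dir.create(file.path(outdir, "dags"), showWarnings = FALSE)
    for (d in run$dags) {
      for (fmt in export_formats) {
        ext <- switch(fmt, json = "json", dot = "dot", graphml = "graphml")
        export_dag(d, fmt,
                   path = file.path(outdir, "dags",
                                    paste0(d$root, ".", ext)))
      }
    }
  }
  invisible(outdir)
}

#' @export
print.trajmine_run <- function(x, ...) {
  m <- x$manifest
  cat("trajmine pipeline run\n")
  cat("  cohort:", m$n_cohort, "patients,", m$n_codes, "disease codes\n")
  cat("  pairs tested:", m$n_pairs_tested,
      " significant (RA >", m$ra_min, ", FDR <", m$fdr, "):",
      m$n_pairs_significant, "\n")
  cat("  directed pairs:", m$n_directed_pairs,
      " trajectory DAGs:", m$n_dags, " paths:", m$n_paths, "\n")
  invisible(x)
}

#' Tidy a pipeline run into its directed-pair table
#'
#' @param x A `trajmine_run`.
#' @param ... Unused.
#' @return The directed-pair tibble.
#' @export
tidy.trajmine_run <- function(x, ...) x$directed

#' One-row summary of a pipeline run
#'
#' @param x A `trajmine_run`.
#' @param ... Unused.
#' @return Tibble of the manifest's stage counts and thresholds.
#' @export
glance.trajmine_run <- function(x, ...) {
  tibble::as_tibble(x$manifest[c(
    "n_cohort", "n_codes", "n_pairs_tested", "n_pairs_significant",
    "n_directed_pairs", "n_dags", "n_paths", "window_days", "ra_min", "fdr"
  )])
}

#' Volcano-style plot of pair associations
#'
#' RA (log scale) against -log10 q-value, with the selection region (RA
#' above `ra_min`, q below `fdr`) highlighted.
#'
#' @param stats Pair-statistic tibble from [pair_associations()].
#' @param ra_min,fdr Selection thresholds drawn as reference lines.
#' @return A ggplot object.
#' @export
plot_pair_associations <- function(stats, ra_min = 1, fdr = 0.1) {
  df <- dplyr::mutate(
    stats,
    selected = .data$ra > ra_min & .data$q_value < fdr,
    mlq = -log10(pmax(.data$q_value, 1e-300))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ra, y = .data$mlq,
                                   colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = ra_min, linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(fdr), linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "relative association (RA)",
                  y = expression(-log[10] ~ "q"),
                  colour = "selected") +
    ggplot2::theme_minimal()
}
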