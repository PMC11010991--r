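#' Read and validate a segmented-cell table
#'
#' Reads a CSV cell table and validates the schema the pipeline relies on:
#' `cell_id`, `patient_id`, `spot_id`, finite `x_um`/`y_um` coordinates, and
#' either the eight `<marker>_intensity` columns (see [marker_panel()]) or a
#' pre-assigned `cell_type` column. Errors name the offending column or row.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_cell_table <- function(path) {
  cells <- readr::read_csv(path, show_col_types = FALSE)
  validate_cell_table(cells)
}

validate_cell_table <- function(cells) {
  req <- c("cell_id", "patient_id", "spot_id", "x_um", "y_um")
  missing <- setdiff(req, names(cells))
  if (length(missing) > 0) {
    abort(paste0("cell table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  dup <- cells |>
    dplyr::count(.data$spot_id, .data$cell_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate cell_id '%s' in spot '%s'.",
                  dup$cell_id[1], dup$spot_id[1]))
  }
  for (cc in c("x_um", "y_um")) {
    bad <- which(!is.finite(cells[[cc]]))
    if (length(bad) > 0) {
      abort(sprintf("non-finite coordinate in column '%s' at row %d.",
                    cc, bad[1]))
    }
  }
  if (!"cell_type" %in% names(cells)) {
    missing_int <- setdiff(marker_columns(), names(cells))
    if (length(missing_int) > 0) {
      abort(paste0(
        "cell table needs either a cell_type column or all marker ",
        "intensities; missing: ", paste(missing_int, collapse = ", ")
      ))
    }
  }
  tibble::as_tibble(cells)
}

#' @rdname read_cell_table
#' @param cells Cell table to write.
#' @param path Output CSV path.
#' @export
write_cell_table <- function(cells, path) {
  readr::write_csv(cells, path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis. `config` round-trips
#' through YAML via [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param thresholds Marker positivity thresholds ([default_thresholds()]).
#' @param window_size,k,merge_mode,merge_threshold,merge_map Neighborhood
#'   parameters (see [detect_neighborhoods()]).
#' @param score_center,score_a,score_b Spatial-score specification
#'   ([spatial_scores()]).
#' @param grouping_rule Patient dichotomization rule ([dichotomize()]).
#' @param seed Global seed propagated to every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(thresholds = default_thresholds(),
                            window_size = 10, k = 10,
                            merge_mode = "auto_threshold",
                            merge_threshold = 0.25, merge_map = NULL,
                            score_center = "CD8_T", score_a = "Tumor",
                            score_b = "CD4_T",
                            grouping_rule = "median_split",
                            seed = 1L) {
  structure(
    list(
      thresholds = thresholds, window_size = window_size, k = k,
      merge_mode = merge_mode, merge_threshold = merge_threshold,
      merge_map = merge_map, score_center = score_center,
      score_a = score_a, score_b = score_b,
      grouping_rule = grouping_rule, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  raw <- unclass(config)
  raw$thresholds <- as.list(raw$thresholds) # keep marker names in YAML
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  cfg[names(raw)] <- raw
  cfg$thresholds <- unlist(cfg$thresholds)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes phenotyping, neighborhood detection, proximity analysis and the
#' outcome association suite in order, writing every artifact plus a run
#' manifest to `out_dir`:
#'
#' * `cells_labeled.csv` — input cells with `cell_type`, `cn_initial`,
#'   `cn_final`;
#' * `centroids.csv`, `enrichment.csv` — the fitted neighborhood model;
#' * `cn_frequencies.csv` — per-patient neighborhood frequencies;
#' * `spot_summary.csv` — per-patient mean CD8-to-tumor / CD8-to-CD4
#'   distances and the spatial score;
#' * `report.csv` and `report.md` — the association suite;
#' * `manifest.json` — config hash, package version, seeds, per-stage row
#'   and exclusion counts (the run's reproducibility record).
#'
#' Reruns with an identical configuration and inputs produce identical
#' outputs.
#'
#' @param cells Cell table (or path to one; see [read_cell_table()]).
#' @param survival Survival table (`patient_id`, `time_months`, `event`) or
#'   CSV path.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `cells`, `model`, `frequencies`,
#'   `spot_summary`, `report`, `manifest`.
#' @export
run_pipeline <- function(cells, survival, config = pipeline_config(),
                         out_dir) {
  if (is.character(cells)) cells <- read_cell_table(cells)
  cells <- validate_cell_table(cells)
  if (is.character(survival)) {
    survival <- readr::read_csv(survival, show_col_types = FALSE)
  }
  check_survival_records(survival)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }
  exclusions <- list()

  labeled <- stage("phenotyping", {
    if ("cell_type" %in% names(cells)) {
      cells
    } else {
      out <- assign_cell_types(cells, default_gating_scheme(config$thresholds))
      exclusions$dapi_negative <- attr(out, "dropped_dapi_negative")
      out
    }
  })

  model <- stage("neighborhoods", detect_neighborhoods(
    labeled, window_size = config$window_size, k = config$k,
    seed = config$seed, merge_mode = config$merge_mode,
    merge_threshold = config$merge_threshold, merge_map = config$merge_map
  ))
  freqs <- stage("neighborhoods", cn_frequencies(model$cells))

  spot_summary <- stage("proximity", {
    d_tumor <- mean_nearest_distance(
      nearest_distances(model$cells, config$score_center, config$score_a)
    )
    d_b <- mean_nearest_distance(
      nearest_distances(model$cells, config$score_center, config$score_b)
    )
    sc <- spatial_scores(model$cells, config$score_center, config$score_a,
                         config$score_b)
    exclusions$undefined_scores <- sum(is.na(sc$score))
    sc_spot <- spatial_score_by_spot(sc)
    freqs |>
      tidyr::pivot_wider(names_from = "cn_final",
                         values_from = "frequency") |>
      dplyr::left_join(
        dplyr::select(d_tumor, "patient_id",
                      mean_dist_to_a = "mean_distance"),
        by = "patient_id"
      ) |>
      dplyr::left_join(
        dplyr::select(d_b, "patient_id", mean_dist_to_b = "mean_distance"),
        by = "patient_id"
      ) |>
      dplyr::left_join(
        dplyr::select(sc_spot, "patient_id", "spatial_score"),
        by = "patient_id"
      )
  })

  report <- stage("outcome_stats",
                  run_association_suite(model$cells, survival))

  write_cell_table(model$cells, file.path(out_dir, "cells_labeled.csv"))
  readr::write_csv(
    tibble::as_tibble(model$centroids, rownames = "cluster"),
    file.path(out_dir, "centroids.csv")
  )
  readr::write_csv(
    tibble::as_tibble(model$enrichment, rownames = "cn_final"),
    file.path(out_dir, "enrichment.csv")
  )
  readr::write_csv(freqs, file.path(out_dir, "cn_frequencies.csv"))
  readr::write_csv(spot_summary, file.path(out_dir, "spot_summary.csv"))
  readr::write_csv(report, file.path(out_dir, "report.csv"))
  writeLines(format_report_md(report), file.path(out_dir, "report.md"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("cnscape")),
    config = unclass(config),
    config_hash = config_hash(config),
    seed = config$seed,
    n_cells_in = nrow(cells),
    n_cells_labeled = nrow(labeled),
    n_windows = nrow(model$windows),
    n_final_cns = model$n_final,
    n_patients = nrow(survival),
    exclusions = exclusions,
    focus_cn = attr(report, "focus_cn")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(cells = model$cells, model = model, frequencies = freqs,
                 spot_summary = spot_summary, report = report,
                 manifest = manifest))
}

# deterministic 31-bit polynomial hash of the serialized config
config_hash <- function(config) {
  bytes <- as.integer(serialize(unclass(config), NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

format_report_md <- function(report) {
  c(
    "# Association report",
    "",
    sprintf("Focus neighborhood: %s", attr(report, "focus_cn") %||% "NA"),
    "",
    "| analysis | covariate | test | statistic | p | sig | n |",
    "|---|---|---|---|---|---|---|",
    sprintf("| %s | %s | %s | %.4g | %.4g | %s | %d |",
            report$analysis, report$covariate, report$test,
            report$statistic, report$p_value,
            ifelse(is.na(report$significance), "-", report$significance),
            report$n)
  )
}
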