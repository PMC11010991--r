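#' Association suite: neighborhood metrics versus survival
#'
#' Runs the cohort-level association screen linking tissue architecture to
#' outcome:
#'
#' 1. for every final neighborhood, Kaplan-Meier / log-rank comparison of
#'    patients with high versus low CN frequency (median split);
#' 2. for each tracked cell type, the same comparison on the patient's count
#'    of that type inside the focus neighborhood;
#' 3. Pearson correlations of the focus-CN frequency against the per-patient
#'    mean nearest distance from CD8 T cells to tumor cells and to CD4 T
#'    cells;
#' 4. a two-sample t-test of the per-spot spatial score (CD8 centered,
#'    tumor/CD4 ratio) between high and low focus-CN-frequency patients.
#'
#' The focus neighborhood defaults to the most lymphocyte-rich final CN
#' (highest combined fraction of CD8 and CD4 T cells among its cells).
#' Patients present in only one of the two tables are dropped with a
#' message. Analyses that cannot run on a given cohort (e.g. no split
#' exists, missing populations) yield a row with `NA` statistics and an
#' explanatory note rather than failing the suite.
#'
#' @param cells CN-labeled cell table (from [detect_neighborhoods()]'s
#'   `$cells`).
#' @param survival Survival table: `patient_id`, `time_months`, `event`.
#' @param focus_cn Final CN label to focus analyses 2-4 on; `NULL` picks the
#'   most lymphocyte-rich CN.
#' @param tracked_types Cell types whose in-focus-CN counts are screened.
#' @return A `cn_report` tibble: `analysis`, `covariate`, `test`,
#'   `statistic`, `p_value`, `significance`, `n`, `note`; attribute
#'   `focus_cn`.
#' @export
run_association_suite <- function(cells, survival, focus_cn = NULL,
                                  tracked_types = c("CD8_T", "CD4_T",
                                                    "Stroma")) {
  if (!all(c("cn_final", "cell_type") %in% names(cells))) {
    abort("`cells` must carry cell_type and cn_final labels.")
  }
  check_survival_records(survival)
  common <- intersect(unique(cells$patient_id), survival$patient_id)
  n_drop <- length(unique(cells$patient_id)) + nrow(survival) -
    2 * length(common)
  if (n_drop > 0) {
    inform(sprintf(
      "run_association_suite: %d patient record(s) without a match dropped.",
      n_drop
    ))
  }
  cells <- dplyr::filter(cells, .data$patient_id %in% common)
  survival <- dplyr::filter(survival, .data$patient_id %in% common)

  freqs <- cn_frequencies(cells) |>
    tidyr::pivot_wider(names_from = "cn_final", values_from = "frequency")
  freqs <- freqs[match(survival$patient_id, freqs$patient_id), ]
  cn_levels <- levels(cells$cn_final)

  if (is.null(focus_cn)) {
    lymph <- cells |>
      dplyr::group_by(.data$cn_final) |>
      dplyr::summarise(
        lymph = mean(.data$cell_type %in% c("CD8_T", "CD4_T")),
        .groups = "drop"
      )
    focus_cn <- as.character(lymph$cn_final[which.max(lymph$lymph)])
  }

  logrank_row <- function(analysis, covariate, values) {
    tryCatch({
      grp <- dichotomize(values)
      lr <- logrank_test(dplyr::mutate(survival, group = grp))
      tibble::tibble(
        analysis = analysis, covariate = covariate, test = "logrank",
        statistic = lr$statistic, p_value = lr$p_value,
        significance = significance_stars(lr$p_value),
        n = lr$n1 + lr$n2,
        note = sprintf("median OS low=%.1f, high=%.1f months",
                       lr$median1, lr$median2)
      )
    }, error = function(e) {
      tibble::tibble(analysis = analysis, covariate = covariate,
                     test = "logrank", statistic = NA_real_,
                     p_value = NA_real_, significance = NA_character_,
                     n = length(values), note = conditionMessage(e))
    })
  }

  rows <- purrr::map(cn_levels, function(cn) {
    logrank_row("cn_frequency_survival", cn, freqs[[cn]])
  })

  counts <- cells |>
    dplyr::filter(as.character(.data$cn_final) == focus_cn) |>
    dplyr::count(.data$patient_id, .data$cell_type, .drop = FALSE,
                 name = "n_cells")
  rows <- c(rows, purrr::map(tracked_types, function(tt) {
    v <- counts$n_cells[counts$cell_type == tt]
    v <- v[match(survival$patient_id,
                 counts$patient_id[counts$cell_type == tt])]
    v[is.na(v)] <- 0
    logrank_row("cn_cell_count_survival", paste(tt, "in", focus_cn), v)
  }))

  cor_row <- function(covariate, dist_tbl) {
    tryCatch({
      v <- dist_tbl$mean_distance[match(survival$patient_id,
                                        dist_tbl$patient_id)]
      ok <- !is.na(v)
      ct <- pearson_correlation(freqs[[focus_cn]][ok], v[ok])
      tibble::tibble(
        analysis = "cn_frequency_distance_correlation",
        covariate = covariate, test = "pearson", statistic = ct$r,
        p_value = ct$p_value, significance = ct$significance, n = ct$n,
        note = sprintf("r between %s frequency and mean distance", focus_cn)
      )
    }, error = function(e) {
      tibble::tibble(analysis = "cn_frequency_distance_correlation",
                     covariate = covariate, test = "pearson",
                     statistic = NA_real_, p_value = NA_real_,
                     significance = NA_character_, n = nrow(survival),
                     note = conditionMessage(e))
    })
  }
  d_tumor <- mean_nearest_distance(
    nearest_distances(cells, "CD8_T", "Tumor")
  )
  d_cd4 <- mean_nearest_distance(
    nearest_distances(cells, "CD8_T", "CD4_T")
  )
  rows <- c(rows, list(cor_row("CD8_T to Tumor distance", d_tumor),
                       cor_row("CD8_T to CD4_T distance", d_cd4)))

  score_row <- tryCatch({
    sc <- spatial_score_by_spot(spatial_scores(cells))
    v <- sc$spatial_score[match(survival$patient_id, sc$patient_id)]
    grp <- dichotomize(freqs[[focus_cn]])
    ok <- !is.na(v)
    cg <- compare_groups(v[ok], grp[ok], "two_sample_t")
    tibble::tibble(
      analysis = "spatial_score_group_comparison",
      covariate = paste("spatial score by", focus_cn, "frequency"),
      test = "two_sample_t", statistic = cg$statistic,
      p_value = cg$p_value, significance = cg$significance, n = sum(ok),
      note = sprintf("mean score low=%.2f, high=%.2f",
                     mean(v[ok][grp[ok] == "low"]),
                     mean(v[ok][grp[ok] == "high"]))
    )
  }, error = function(e) {
    tibble::tibble(analysis = "spatial_score_group_comparison",
                   covariate = "spatial score", test = "two_sample_t",
                   statistic = NA_real_, p_value = NA_real_,
                   significance = NA_character_, n = nrow(survival),
                   note = conditionMessage(e))
  })

  out <- purrr::list_rbind(c(rows, list(score_row)))
  attr(out, "focus_cn") <- focus_cn
  class(out) <- c("cn_report", class(out))
  out
}
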