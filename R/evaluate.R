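#' Agreement between detected neighborhoods and planted ground truth
#'
#' For synthetic cohorts, compares the final CN assignment against the
#' planted archetype labels with the Adjusted Rand Index (chance-corrected
#' partition agreement, via \pkg{mclust}), and reports phenotype recovery
#' when ground-truth cell types are present.
#'
#' @param cells Labeled cells carrying `cn_final` and the generator's
#'   `true_cn` column (and optionally `cell_type` + `true_cell_type`).
#' @return One-row tibble: `ari` (CN partition agreement), `n_final`,
#'   `n_planted`, and `type_accuracy` (NA when types are absent).
#' @export
evaluate_recovery <- function(cells) {
  if (!all(c("cn_final", "true_cn") %in% names(cells))) {
    abort("`cells` must carry both cn_final and true_cn.")
  }
  ok <- !is.na(cells$cn_final)
  ari <- mclust::adjustedRandIndex(as.character(cells$cn_final[ok]),
                                   cells$true_cn[ok])
  acc <- if (all(c("cell_type", "true_cell_type") %in% names(cells))) {
    mean(as.character(cells$cell_type) == cells$true_cell_type)
  } else {
    NA_real_
  }
  tibble::tibble(
    ari = ari,
    n_final = length(unique(as.character(cells$cn_final[ok]))),
    n_planted = length(unique(cells$true_cn)),
    type_accuracy = acc
  )
}
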