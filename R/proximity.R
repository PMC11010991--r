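#' Nearest-cell distances between phenotype strata
#'
#' For every source cell, the Euclidean distance (micrometres) to the
#' nearest target cell in the same spot. Spots are treated independently:
#' distances never cross spot boundaries. When the source and target
#' selections coincide and `exclude_self = TRUE` (default), a cell is never
#' its own nearest target. Source cells in spots with no eligible target get
#' `NA` and are excluded from downstream averages; the exclusion count is
#' reported with a message.
#'
#' @param cells Cell table with `cell_id`, `patient_id`, `spot_id`, `x_um`,
#'   `y_um`, `cell_type` (and `cn_final` if CN filters are used).
#' @param source_type,target_type Phenotype labels selecting source and
#'   target cells.
#' @param source_cn,target_cn Optional final-CN filters (e.g. `"CN3"`)
#'   applied on top of the type selectors.
#' @param exclude_self Drop the source cell itself from its target set.
#' @return Tibble, one row per source cell: identifiers, `cell_type`,
#'   `cn_final` (if present), and `distance` (µm, `NA` when no target).
#' @examples
#' cells <- tibble::tibble(
#'   cell_id = c("a", "b"), patient_id = "P1", spot_id = "s",
#'   x_um = c(0, 3), y_um = c(0, 4), cell_type = c("CD8_T", "Tumor")
#' )
#' nearest_distances(cells, "CD8_T", "Tumor")$distance # 5
#' @export
nearest_distances <- function(cells, source_type, target_type,
                              source_cn = NULL, target_cn = NULL,
                              exclude_self = TRUE) {
  sel <- function(type, cn) {
    ok <- cells$cell_type == type
    if (!is.null(cn)) {
      if (!"cn_final" %in% names(cells)) {
        abort("CN filter requested but `cells` has no cn_final column.")
      }
      ok <- ok & as.character(cells$cn_final) == cn
    }
    ok & !is.na(ok)
  }
  src <- cells[sel(source_type, source_cn), , drop = FALSE]
  tgt <- cells[sel(target_type, target_cn), , drop = FALSE]
  keep <- intersect(
    c("cell_id", "patient_id", "spot_id", "cell_type", "cn_final"),
    names(src)
  )
  out <- tibble::as_tibble(src[keep])
  out$distance <- NA_real_
  for (sp in unique(src$spot_id)) {
    si <- which(src$spot_id == sp)
    ti <- which(tgt$spot_id == sp)
    if (length(ti) == 0) next
    d2 <- outer(src$x_um[si], tgt$x_um[ti], `-`)^2 +
      outer(src$y_um[si], tgt$y_um[ti], `-`)^2
    if (exclude_self) {
      same <- outer(src$cell_id[si], tgt$cell_id[ti], `==`)
      d2[same] <- Inf
    }
    mins <- apply(d2, 1, min)
    out$distance[si] <- ifelse(is.finite(mins), sqrt(mins), NA_real_)
  }
  n_undef <- sum(is.na(out$distance))
  if (n_undef > 0) {
    inform(sprintf(
      "nearest_distances: %d source cell(s) with no eligible %s target excluded.",
      n_undef, target_type
    ))
  }
  out
}

#' Per-spot average of nearest-cell distances
#'
#' Arithmetic mean of the defined per-cell minimal distances within each
#' patient's spot (the per-patient summary used to correlate proximity with
#' neighborhood frequencies). Spots whose distances are all undefined are
#' excluded.
#'
#' @param distances Output of [nearest_distances()].
#' @return Tibble: `patient_id`, `spot_id`, `mean_distance`, `n_cells`.
#' @export
mean_nearest_distance <- function(distances) {
  distances |>
    dplyr::filter(!is.na(.data$distance)) |>
    dplyr::group_by(.data$patient_id, .data$spot_id) |>
    dplyr::summarise(mean_distance = mean(.data$distance),
                     n_cells = dplyr::n(), .groups = "drop")
}

#' Spatial score: relative proximity of a center type to two identities
#'
#' For each center cell, the spatial score is the ratio of the distance to
#' its nearest identity-A cell over the distance to its nearest identity-B
#' cell. A score above 1 means the center cell sits closer to identity B
#' than to identity A. The default specification centers CD8 T cells and
#' compares tumor cells (A) against CD4 T cells (B), so high scores flag
#' CD8 T cells held near CD4 T cells and away from the tumor.
#'
#' Center cells whose nearest-B distance is zero (coincident centroids) are
#' excluded with a message, as are spots missing either identity.
#'
#' @param cells Labeled cell table (see [nearest_distances()]).
#' @param center_type,type_a,type_b Phenotype labels: center population,
#'   numerator target (A), denominator target (B).
#' @return Tibble, one row per center cell: identifiers, `dist_a`, `dist_b`
#'   (µm) and `score`; `NA` score where undefined.
#' @seealso [spatial_score_by_spot()] for the per-spot aggregate.
#' @export
spatial_scores <- function(cells, center_type = "CD8_T", type_a = "Tumor",
                           type_b = "CD4_T") {
  da <- nearest_distances(cells, center_type, type_a)
  db <- nearest_distances(cells, center_type, type_b)
  out <- da |>
    dplyr::rename(dist_a = "distance") |>
    dplyr::mutate(dist_b = db$distance[match(.data$cell_id, db$cell_id)])
  zero_b <- !is.na(out$dist_b) & out$dist_b == 0
  if (any(zero_b)) {
    inform(sprintf(
      "spatial_scores: %d center cell(s) with zero denominator distance excluded.",
      sum(zero_b)
    ))
  }
  out |>
    dplyr::mutate(score = dplyr::if_else(
      is.na(.data$dist_a) | is.na(.data$dist_b) | .data$dist_b == 0,
      NA_real_, .data$dist_a / .data$dist_b
    ))
}

#' Aggregate per-cell spatial scores to one value per spot
#'
#' @param scores Output of [spatial_scores()].
#' @param method `"mean_of_ratios"` (default): mean of the defined per-cell
#'   score ratios. `"ratio_of_means"`: mean nearest-A distance divided by
#'   mean nearest-B distance over the same cells.
#' @return Tibble: `patient_id`, `spot_id`, `spatial_score`, `n_cells`.
#' @export
spatial_score_by_spot <- function(scores,
                                  method = c("mean_of_ratios",
                                             "ratio_of_means")) {
  method <- match.arg(method)
  scores |>
    dplyr::filter(!is.na(.data$score)) |>
    dplyr::group_by(.data$patient_id, .data$spot_id) |>
    dplyr::summarise(
      spatial_score = if (method == "mean_of_ratios") {
        mean(.data$score)
      } else {
        mean(.data$dist_a) / mean(.data$dist_b)
      },
      n_cells = dplyr::n(), .groups = "drop"
    )
}

#' Stratify nearest-cell distances by the source cell's neighborhood
#'
#' Splits a per-cell distance table by the final CN of the source cell and
#' adds a binary in/out split for a designated neighborhood (e.g. to compare
#' CD8-to-tumor distances of CD8 T cells inside a lymphocyte-enriched CN
#' against all other CD8 T cells).
#'
#' @param distances Output of [nearest_distances()] on cells carrying
#'   `cn_final`.
#' @param designated_cn Final CN label for the binary split (optional).
#' @return `distances` (defined rows only) plus `in_designated` when a
#'   designated CN is given.
#' @export
distances_by_cn <- function(distances, designated_cn = NULL) {
  if (!"cn_final" %in% names(distances)) {
    abort("`distances` lacks cn_final; compute distances on CN-labeled cells.")
  }
  out <- dplyr::filter(distances, !is.na(.data$distance))
  if (!is.null(designated_cn)) {
    out$in_designated <- as.character(out$cn_final) == designated_cn
  }
  out
}
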