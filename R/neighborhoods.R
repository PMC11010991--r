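#' Cluster composition windows into initial neighborhoods
#'
#' Runs mini-batch k-means (k-means++ initialisation, per-center learning
#' rates, final full-data assignment) on the raw window frequency rows. Raw
#' frequencies are clustered without rescaling: composition coordinates are
#' already commensurate. Re-runs with the same seed on the same input are
#' identical.
#'
#' @param comp Windows-by-types frequency matrix from [composition_matrix()].
#' @param k Number of initial clusters (default 10).
#' @param seed Integer seed for initialisation and batch sampling.
#' @param batch_size Mini-batch size (default 1024, capped at `nrow(comp)`).
#' @param max_iter Mini-batch iterations (default 100).
#' @return List: `centroids` (`k` x 8 matrix), `assignment` (integer per
#'   window), `inertia`, `empty` (ids of clusters left empty, normally none).
#' @export
cluster_windows <- function(comp, k = 10, seed = 1L, batch_size = 1024L,
                            max_iter = 100L) {
  fit <- mini_batch_kmeans(comp, k = k, seed = seed,
                           batch_size = batch_size, max_iter = max_iter)
  rownames(fit$centers) <- paste0("c", seq_len(k))
  list(centroids = fit$centers, assignment = fit$assignment,
       inertia = fit$inertia, empty = fit$empty)
}

# pairwise cosine distance between rows
cosine_distance <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  nrm[nrm == 0] <- 1
  s <- (m / nrm) %*% t(m / nrm)
  d <- 1 - s
  d[d < 0] <- 0
  stats::as.dist(d)
}

#' Merge initial clusters into final cellular neighborhoods
#'
#' Initial window clusters that represent the same local architecture are
#' merged. Two modes:
#' * `explicit_map`: a user-supplied mapping from initial cluster id to
#'   final neighborhood id is applied verbatim (the reference mode for
#'   reproducing a labeled merging scheme).
#' * `auto_threshold`: average-linkage agglomeration on the cosine distance
#'   between cluster centroids, cut at `threshold` (default 0.25, sized to re-merge sub-clusters of one architecture that k-means splits along the sampling noise of 10-cell windows); clusters
#'   whose centroids point in nearly the same composition direction merge.
#'
#' Final neighborhoods are renumbered 1..n_final by decreasing total window
#' count, so CN1 is always the most abundant architecture.
#'
#' @param clust Output of [cluster_windows()].
#' @param mode `"auto_threshold"` or `"explicit_map"`.
#' @param threshold Cosine-distance cut height for `auto_threshold`.
#' @param map Integer vector for `explicit_map`: `map[i]` is the merged
#'   group of initial cluster `i`; must cover every initial cluster.
#' @return Integer vector `merge_map` of length k: final CN id per initial
#'   cluster (NA for clusters with zero windows, which are dropped).
#' @export
merge_neighborhoods <- function(clust,
                                mode = c("auto_threshold", "explicit_map"),
                                threshold = 0.25, map = NULL) {
  mode <- match.arg(mode)
  k <- nrow(clust$centroids)
  n_windows <- tabulate(clust$assignment, nbins = k)
  live <- which(n_windows > 0)
  if (length(live) < k) {
    warn(sprintf("dropping %d zero-window cluster(s) before merging.",
                 k - length(live)))
  }
  if (mode == "explicit_map") {
    if (is.null(map) || length(map) != k || anyNA(map)) {
      abort("`map` must assign every initial cluster a merged group id.")
    }
    groups <- as.integer(as.factor(map[live]))
  } else if (length(live) == 1) {
    groups <- 1L
  } else {
    hc <- stats::hclust(cosine_distance(clust$centroids[live, , drop = FALSE]),
                        method = "average")
    groups <- stats::cutree(hc, h = threshold)
  }
  # relabel final CNs by descending window count
  grp_windows <- tapply(n_windows[live], groups, sum)
  new_id <- integer(max(groups))
  new_id[order(grp_windows, decreasing = TRUE)] <- seq_along(grp_windows)
  merge_map <- rep(NA_integer_, k)
  merge_map[live] <- new_id[groups]
  merge_map
}

#' Scaled enrichment scores of cell types within neighborhoods
#'
#' Quantifies over/under-representation of each cell type within each final
#' neighborhood: entry (c, t) is the z-score, taken across neighborhoods, of
#' the mean frequency of type t among the windows assigned to neighborhood
#' c. Each type's column therefore has mean 0 and unit variance across
#' neighborhoods; a type whose mean frequency does not vary across
#' neighborhoods scores 0 everywhere. This scaled score is what labels a
#' neighborhood ("tumor-rich", "lymphocyte-rich", ...) on the cluster map.
#'
#' @param assignment Integer initial-cluster id per window.
#' @param comp Window composition matrix (same row order as `assignment`).
#' @param merge_map Final CN id per initial cluster ([merge_neighborhoods()]).
#' @return Matrix `n_final` x 8 of z-scores, rownames `CN1..CNn`.
#' @export
enrichment_scores <- function(assignment, comp, merge_map) {
  final <- merge_map[assignment]
  keep <- !is.na(final)
  if (!all(keep)) {
    warn(sprintf("%d window(s) in dropped clusters excluded from enrichment.",
                 sum(!keep)))
  }
  means <- rowsum(comp[keep, , drop = FALSE], final[keep]) /
    as.vector(table(final[keep]))
  z <- scale(means)
  z[, attr(z, "scaled:scale") == 0] <- 0
  z <- z[, , drop = FALSE]
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  rownames(z) <- paste0("CN", rownames(means))
  z
}

#' Detect cellular neighborhoods in a labeled cell table
#'
#' End-to-end neighborhood discovery: builds k-nearest-neighbor composition
#' windows per spot ([build_windows()]), pools the windows of all spots into
#' one composition matrix (neighborhood identities must be comparable across
#' patients), clusters them with mini-batch k-means ([cluster_windows()]),
#' merges similar clusters ([merge_neighborhoods()]), scores enrichment
#' ([enrichment_scores()]), and assigns every cell the final neighborhood of
#' its own window.
#'
#' @param cells Labeled cell table (needs `cell_id`, `patient_id`,
#'   `spot_id`, `x_um`, `y_um`, `cell_type`).
#' @param window_size Cells per window including the center (default 10).
#' @param k Initial cluster count (default 10).
#' @param seed Clustering seed.
#' @param merge_mode,merge_threshold,merge_map Passed to
#'   [merge_neighborhoods()].
#' @param batch_size,max_iter Passed to [cluster_windows()].
#' @return A `cn_model` object: list with `cells` (input plus `cn_initial`
#'   and `cn_final` columns, `cn_final` a factor `CN1..CNn`), `centroids`,
#'   `enrichment`, `merge_map`, `assignment`, `windows`, and fit metadata.
#' @examples
#' cfg <- synth_config(n_patients = 2, cells_per_spot = 400, seed = 3)
#' cells <- assign_cell_types(simulate_spot(cfg, "P1"))
#' fit <- detect_neighborhoods(cells, k = 6, seed = 3)
#' glance(fit)
#' @export
detect_neighborhoods <- function(cells, window_size = 10, k = 10, seed = 1L,
                                 merge_mode = c("auto_threshold",
                                                "explicit_map"),
                                 merge_threshold = 0.25, merge_map = NULL,
                                 batch_size = 1024L, max_iter = 100L) {
  merge_mode <- match.arg(merge_mode)
  if (!"cell_type" %in% names(cells)) {
    abort("`cells` lacks a cell_type column; run assign_cell_types() first.")
  }
  windows <- build_windows(cells, window_size)
  comp <- composition_matrix(windows, cells)
  clust <- cluster_windows(comp, k = k, seed = seed,
                           batch_size = batch_size, max_iter = max_iter)
  mmap <- merge_neighborhoods(clust, mode = merge_mode,
                              threshold = merge_threshold, map = merge_map)
  enrich <- enrichment_scores(clust$assignment, comp, mmap)
  labeled <- assign_cells(cells, windows, clust$assignment, mmap)
  structure(
    list(
      cells = labeled, windows = windows, centroids = clust$centroids,
      assignment = clust$assignment, merge_map = mmap, enrichment = enrich,
      inertia = clust$inertia, window_size = window_size, k_initial = k,
      n_final = length(unique(stats::na.omit(mmap))), seed = seed,
      merge_mode = merge_mode, merge_threshold = merge_threshold
    ),
    class = "cn_model"
  )
}

#' Propagate window clusters to per-cell neighborhood labels
#'
#' Each cell inherits the cluster of its own window (the window it anchors),
#' then the merge map coarsens initial clusters to final neighborhoods.
#'
#' @param cells Cell table used to build `windows`.
#' @param windows [build_windows()] output.
#' @param assignment Initial cluster per window ([cluster_windows()]).
#' @param merge_map Final CN per initial cluster ([merge_neighborhoods()]).
#' @return `cells` as a tibble with `cn_initial` (integer) and `cn_final`
#'   (factor `CN1..CNn`) columns.
#' @export
assign_cells <- function(cells, windows, assignment, merge_map) {
  idx <- match(as.character(cells$cell_id), windows$cell_id)
  if (anyNA(idx)) abort("every cell must anchor exactly one window.")
  cn_initial <- assignment[idx]
  final <- merge_map[cn_initial]
  n_final <- length(unique(stats::na.omit(merge_map)))
  tibble::as_tibble(cells) |>
    dplyr::mutate(
      cn_initial = cn_initial,
      cn_final = factor(paste0("CN", final),
                        levels = paste0("CN", seq_len(n_final)))
    )
}

#' Per-patient neighborhood frequencies
#'
#' Fraction of each patient's cells assigned to each final neighborhood;
#' the per-patient fractions sum to 1. Patients with no labeled cells are
#' excluded with a warning.
#'
#' @param cells Cell table carrying `patient_id` and `cn_final`.
#' @return Tidy tibble: `patient_id`, `cn_final`, `frequency` (all final
#'   CN levels present for every patient, zero-filled).
#' @export
cn_frequencies <- function(cells) {
  if (!"cn_final" %in% names(cells)) {
    abort("`cells` lacks cn_final; run detect_neighborhoods() first.")
  }
  ok <- !is.na(cells$cn_final)
  if (!all(ok)) {
    warn(sprintf("%d cell(s) without a final CN excluded.", sum(!ok)))
  }
  cells[ok, ] |>
    dplyr::count(.data$patient_id, .data$cn_final, .drop = FALSE,
                 name = "n_cells") |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(frequency = .data$n_cells / sum(.data$n_cells)) |>
    dplyr::ungroup() |>
    dplyr::select("patient_id", "cn_final", "frequency")
}

#' @export
print.cn_model <- function(x, ...) {
  cat(sprintf(
    "<cn_model> %d cells, %d windows of %d cells; k = %d -> %d final CNs (%s)\n",
    nrow(x$cells), nrow(x$windows), x$window_size, x$k_initial, x$n_final,
    x$merge_mode
  ))
  invisible(x)
}

#' Tidy methods for fitted neighborhood models
#'
#' `tidy()` returns the enrichment matrix in long form (one row per final
#' neighborhood and cell type, with the merged centroid composition and the
#' scaled enrichment score); `glance()` returns a one-row fit summary.
#'
#' @param x A `cn_model` from [detect_neighborhoods()].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy cn_model
#' @export
tidy.cn_model <- function(x, ...) {
  live <- !is.na(x$merge_map)
  w <- tabulate(x$assignment, nbins = x$k_initial)
  comp_means <- rowsum(x$centroids[live, , drop = FALSE] * w[live],
                       x$merge_map[live]) /
    as.vector(tapply(w[live], x$merge_map[live], sum))
  rownames(comp_means) <- paste0("CN", rownames(comp_means))
  sizes <- table(x$cells$cn_final)
  cns <- rownames(x$enrichment)
  types <- colnames(x$enrichment)
  tibble::tibble(
    cn_final = rep(cns, times = length(types)),
    cell_type = rep(types, each = length(cns)),
    mean_frequency = as.vector(comp_means[cns, types]),
    enrichment = as.vector(x$enrichment),
    n_cells = as.vector(sizes[rep(cns, times = length(types))])
  )
}

#' @rdname tidy.cn_model
#' @method glance cn_model
#' @export
glance.cn_model <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$cells),
    n_windows = nrow(x$windows),
    window_size = x$window_size,
    k_initial = x$k_initial,
    n_final = x$n_final,
    inertia = x$inertia,
    merge_mode = x$merge_mode,
    seed = x$seed
  )
}
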