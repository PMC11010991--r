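#' Build k-nearest-neighbor composition windows
#'
#' For every cell, collects the window formed by the cell itself plus its
#' `window_size - 1` nearest cells by Euclidean distance on the x/y
#' centroids. Windows never cross spot boundaries (tissue-microarray cores
#' are physically separate); distance ties are broken by ascending
#' `cell_id`, and the central cell is always the first member. A spot with
#' fewer than `window_size` cells contributes full-spot windows and a
#' warning.
#'
#' @param cells Data frame with `cell_id`, `spot_id`, `x_um`, `y_um`.
#'   `cell_id` must be unique within a spot; coordinates must be finite.
#' @param window_size Cells per window including the center (default 10,
#'   i.e. the center anchored to its nine nearest neighbors).
#' @return A tibble with one row per cell: `cell_id`, `spot_id`, `n_members`,
#'   and a `members` list-column of member `cell_id`s (center first, then by
#'   increasing distance).
#' @examples
#' cells <- tibble::tibble(
#'   cell_id = as.character(1:3), spot_id = "s1",
#'   x_um = c(0, 1, 3), y_um = 0
#' )
#' build_windows(cells, window_size = 2)$members
#' @export
build_windows <- function(cells, window_size = 10) {
  stopifnot(window_size >= 2)
  req <- c("cell_id", "spot_id", "x_um", "y_um")
  missing <- setdiff(req, names(cells))
  if (length(missing) > 0) {
    abort(paste0("cell table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(cells$x_um)) || any(!is.finite(cells$y_um))) {
    abort("cell coordinates must be finite.")
  }
  short_spots <- character(0)
  out <- cells |>
    dplyr::group_by(.data$spot_id) |>
    dplyr::group_map(function(spot, key) {
      ids <- as.character(spot$cell_id)
      if (anyDuplicated(ids)) {
        abort(sprintf("duplicate cell_id within spot '%s'.", key$spot_id))
      }
      n <- nrow(spot)
      if (n < 2) abort(sprintf("spot '%s' has fewer than 2 cells.", key$spot_id))
      k <- window_size
      if (n < k) {
        short_spots <<- c(short_spots, as.character(key$spot_id))
        k <- n
      }
      id_rank <- rank(ids, ties.method = "first")
      d2 <- outer(spot$x_um, spot$x_um, `-`)^2 +
        outer(spot$y_um, spot$y_um, `-`)^2
      members <- lapply(seq_len(n), function(i) {
        ord <- order(d2[i, ], id_rank)
        ord <- c(i, ord[ord != i]) # center anchored first
        ids[ord[seq_len(k)]]
      })
      tibble::tibble(
        cell_id = ids, spot_id = as.character(key$spot_id),
        n_members = k, members = members
      )
    }) |>
    purrr::list_rbind()
  if (length(short_spots) > 0) {
    warn(sprintf(
      "%d spot(s) have fewer than %d cells; full-spot windows used: %s",
      length(short_spots), window_size, paste(short_spots, collapse = ", ")
    ))
  }
  out
}

#' Cell-type composition matrix of windows
#'
#' Converts windows into the windows-by-types frequency matrix that is
#' clustered into cellular neighborhoods: row i holds the cell-type counts
#' of window i divided by its member count. Column order is fixed by
#' [cell_type_vocabulary()], so compositions are comparable across spots and
#' cohorts.
#'
#' @param windows Output of [build_windows()].
#' @param cells The labeled cell table ([assign_cell_types()] output, or any
#'   table with `cell_id` and `cell_type`). Every window member must be
#'   labeled.
#' @return Numeric matrix (`n_windows` x 8), rows summing to 1, rownames set
#'   to the window's central `cell_id`.
#' @export
composition_matrix <- function(windows, cells) {
  vocab <- cell_type_vocabulary()
  type_of <- setNames(as.character(cells$cell_type), cells$cell_id)
  flat <- unlist(windows$members, use.names = FALSE)
  types <- type_of[flat]
  if (anyNA(types)) {
    abort("window member(s) without a cell_type label; run assign_cell_types() first.")
  }
  codes <- match(types, vocab)
  win_idx <- rep.int(seq_len(nrow(windows)), windows$n_members)
  counts <- matrix(0, nrow(windows), length(vocab),
                   dimnames = list(windows$cell_id, vocab))
  for (j in seq_along(vocab)) {
    sel <- codes == j
    if (any(sel)) {
      tab <- tabulate(win_idx[sel], nbins = nrow(windows))
      counts[, j] <- tab
    }
  }
  counts / windows$n_members
}
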