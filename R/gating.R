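#' Threshold gating scheme for phenotype assignment
#'
#' Builds the priority-ordered gating scheme that maps per-cell marker
#' intensities to the eight phenotypes of [cell_type_vocabulary()]. A cell is
#' positive for a marker when its intensity strictly exceeds that marker's
#' threshold. DAPI-negative cells are excluded (not nucleated); among
#' DAPI-positive cells the first matching rule wins:
#'
#' 1. PanCK+ -> Tumor
#' 2. CD31+ -> Endothelial
#' 3. CD3+ CD8+ -> CD8_T
#' 4. CD3+ CD4+ -> CD4_T
#' 5. CD3+ (CD8- CD4-) -> Other_T
#' 6. CD68+ -> Macrophage
#' 7. CD20+ -> B_cell
#' 8. otherwise -> Stroma (fallback: DAPI+ with no lineage marker)
#'
#' The ordering resolves multi-positive cells deterministically (epithelial
#' and endothelial identity take precedence over immune lineages; within the
#' T lineage CD8 is checked before CD4, so a CD3+CD8+CD4+ cell is CD8_T).
#' Reorder or edit `rules` to change that convention.
#'
#' @param thresholds Named numeric vector of positivity thresholds, one per
#'   marker in [marker_panel()]. `default_thresholds()` supplies a single
#'   global cutoff of 15 intensity units per marker, the geometric midpoint
#'   of the generator's negative and positive emission channels.
#' @return A `gating_scheme` object: `thresholds` plus an ordered list of
#'   rules `(label, positive, negative)`.
#' @examples
#' scheme <- default_gating_scheme()
#' scheme
#' @export
default_gating_scheme <- function(thresholds = default_thresholds()) {
  missing <- setdiff(marker_panel(), names(thresholds))
  if (length(missing) > 0) {
    abort(paste0("missing positivity threshold for marker(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (any(!is.finite(thresholds[marker_panel()]))) {
    abort("all marker thresholds must be finite numbers.")
  }
  rules <- list(
    list(label = "Tumor",       positive = "PanCK",         negative = character(0)),
    list(label = "Endothelial", positive = "CD31",          negative = character(0)),
    list(label = "CD8_T",       positive = c("CD3", "CD8"), negative = character(0)),
    list(label = "CD4_T",       positive = c("CD3", "CD4"), negative = character(0)),
    list(label = "Other_T",     positive = "CD3",           negative = c("CD8", "CD4")),
    list(label = "Macrophage",  positive = "CD68",          negative = character(0)),
    list(label = "B_cell",      positive = "CD20",          negative = character(0)),
    list(label = "Stroma",      positive = character(0),    negative = character(0))
  )
  structure(
    list(thresholds = thresholds[marker_panel()], rules = rules),
    class = "gating_scheme"
  )
}

#' @rdname default_gating_scheme
#' @export
default_thresholds <- function() {
  setNames(rep(15, length(marker_panel())), marker_panel())
}

#' @export
print.gating_scheme <- function(x, ...) {
  cat("<gating_scheme> DAPI- cells excluded; first matching rule wins:\n")
  for (r in x$rules) {
    pos <- if (length(r$positive)) {
      paste0(r$positive, "+", collapse = " ")
    } else {
      "(fallback)"
    }
    neg <- if (length(r$negative)) {
      paste0(" ", paste0(r$negative, "-", collapse = " "))
    } else {
      ""
    }
    cat(sprintf("  %-12s <- %s%s\n", r$label, pos, neg))
  }
  cat("thresholds: ",
      paste(names(x$thresholds), x$thresholds, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Assign phenotypes to cells by threshold gating
#'
#' Applies a [default_gating_scheme()] to a cell table with the eight
#' `<marker>_intensity` columns. DAPI-negative cells are dropped (the count
#' is reported via a message and stored in the `dropped_dapi_negative`
#' attribute); every retained cell receives exactly one `cell_type` label.
#'
#' @param cells Data frame with `<marker>_intensity` columns for all markers
#'   in [marker_panel()]. Intensities must be finite and non-missing.
#' @param scheme A `gating_scheme`; defaults to [default_gating_scheme()].
#' @return The retained rows of `cells`, as a tibble, with a `cell_type`
#'   factor column levelled by [cell_type_vocabulary()].
#' @export
assign_cell_types <- function(cells, scheme = default_gating_scheme()) {
  stopifnot(inherits(scheme, "gating_scheme"))
  cols <- marker_columns()
  missing <- setdiff(cols, names(cells))
  if (length(missing) > 0) {
    abort(paste0("cell table lacks intensity column(s): ",
                 paste(missing, collapse = ", ")))
  }
  inten <- as.matrix(cells[cols])
  if (any(!is.finite(inten))) {
    abort("marker intensities contain missing or non-finite values.")
  }
  thr <- scheme$thresholds[marker_panel()]
  positive <- sweep(inten, 2, thr, `>`)
  colnames(positive) <- marker_panel()

  keep <- positive[, "DAPI"]
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    inform(sprintf("assign_cell_types: dropped %d DAPI-negative cell(s).",
                   n_drop))
  }
  positive <- positive[keep, , drop = FALSE]
  out <- tibble::as_tibble(cells[keep, , drop = FALSE])

  label <- rep(NA_character_, nrow(out))
  for (r in scheme$rules) {
    hit <- rep(TRUE, nrow(out))
    for (m in r$positive) hit <- hit & positive[, m]
    for (m in r$negative) hit <- hit & !positive[, m]
    label[is.na(label) & hit] <- r$label
  }
  out$cell_type <- factor(label, levels = cell_type_vocabulary())
  attr(out, "dropped_dapi_negative") <- n_drop
  out
}
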