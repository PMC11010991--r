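#' Cell-type vocabulary and marker panel
#'
#' The package works with a fixed, ordered vocabulary of eight phenotypes
#' typical of a solid-tumor microenvironment panel (tumor epithelium,
#' endothelium, three T-cell classes, macrophages, B cells, and a stromal
#' fallback), and a matching eight-marker panel (DAPI nuclear counterstain
#' plus seven lineage markers). The ordering is stable: every composition
#' vector, centroid matrix and enrichment matrix downstream uses columns in
#' `cell_type_vocabulary()` order.
#'
#' @return `cell_type_vocabulary()`: character vector of the eight phenotype
#'   labels. `marker_panel()`: character vector of the eight marker names.
#' @examples
#' cell_type_vocabulary()
#' marker_panel()
#' @export
cell_type_vocabulary <- function() {
  c("Tumor", "Endothelial", "CD8_T", "CD4_T", "Other_T",
    "Macrophage", "B_cell", "Stroma")
}

#' @rdname cell_type_vocabulary
#' @export
marker_panel <- function() {
  c("DAPI", "PanCK", "CD31", "CD3", "CD4", "CD8", "CD68", "CD20")
}

# intensity column names in cell tables: <marker>_intensity
marker_columns <- function() paste0(marker_panel(), "_intensity")

# lineage-defining markers per phenotype; DAPI is implicit (all nucleated)
defining_markers <- function() {
  list(
    Tumor       = "PanCK",
    Endothelial = "CD31",
    CD8_T       = c("CD3", "CD8"),
    CD4_T       = c("CD3", "CD4"),
    Other_T     = "CD3",
    Macrophage  = "CD68",
    B_cell      = "CD20",
    Stroma      = character(0)
  )
}
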