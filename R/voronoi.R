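# Voronoi tessellation by half-plane clipping: each cell's polygon is the
# intersection of the (polygonised) spot disk with the bisector half-planes
# against its neighbors, visited in distance order with an early exit once
# no farther neighbor can cut the polygon. O(n log n) in practice.

# Sutherland-Hodgman clip of polygon `poly` (n x 2) by half-plane a.p <= b
clip_halfplane <- function(poly, a, b) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  val <- poly %*% a - b
  keep_pts <- list()
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    in_i <- val[i] <= 1e-12
    in_j <- val[j] <= 1e-12
    if (in_i) keep_pts[[length(keep_pts) + 1]] <- poly[i, ]
    if (xor(in_i, in_j)) {
      t <- val[i] / (val[i] - val[j])
      keep_pts[[length(keep_pts) + 1]] <-
        poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  if (length(keep_pts) == 0) {
    return(matrix(numeric(0), ncol = 2))
  }
  do.call(rbind, keep_pts)
}

#' Voronoi tessellation of cell centroids within a spot
#'
#' Computes, per spot, the Voronoi polygon of every cell clipped to the
#' circular spot boundary, so the polygons tile the spot and visualise the
#' spatial extent of each cell (and, via its labels, of each neighborhood —
#' the standard way to render tissue architecture from segmented cells).
#'
#' @param cells Cell table with `cell_id`, `spot_id`, `x_um`, `y_um`; any
#'   label columns (e.g. `cell_type`, `cn_final`) are carried through.
#' @param spot_diameter Spot diameter in micrometres; the disk is centred at
#'   (`d/2`, `d/2`) in the per-spot frame. If `NULL` a circumscribing disk
#'   around the observed centroids is used.
#' @param boundary_segments Number of segments polygonising the disk.
#' @return Tidy tibble of polygon vertices: `cell_id`, `spot_id`, carried
#'   label columns, `vertex`, `vx`, `vy`; one polygon per cell, traversal
#'   order preserved (use `ggplot2::geom_polygon(group = cell_id)`).
#' @export
voronoi_cells <- function(cells, spot_diameter = NULL,
                          boundary_segments = 64L) {
  req <- c("cell_id", "spot_id", "x_um", "y_um")
  if (length(setdiff(req, names(cells))) > 0) {
    abort("`cells` needs cell_id, spot_id, x_um, y_um.")
  }
  cells |>
    dplyr::group_by(.data$spot_id) |>
    dplyr::group_map(function(spot, key) {
      n <- nrow(spot)
      if (n < 3) abort("Voronoi tessellation needs at least 3 cells per spot.")
      x <- spot$x_um
      y <- spot$y_um
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        abort("degenerate geometry: collinear or coincident cell centroids.")
      }
      if (is.null(spot_diameter)) {
        cx <- mean(range(x)); cy <- mean(range(y))
        r <- max(sqrt((x - cx)^2 + (y - cy)^2)) * 1.05 + 1e-9
      } else {
        r <- spot_diameter / 2; cx <- r; cy <- r
      }
      th <- seq(0, 2 * pi, length.out = boundary_segments + 1)[-1]
      disk <- cbind(cx + r * cos(th), cy + r * sin(th))
      polys <- vector("list", n)
      for (i in seq_len(n)) {
        d2 <- (x - x[i])^2 + (y - y[i])^2
        ord <- order(d2)
        ord <- ord[ord != i]
        poly <- disk
        for (j in ord) {
          # farther neighbors cannot cut once the polygon fits inside the
          # ball of radius d_ij / 2 around the cell
          max_r2 <- max((poly[, 1] - x[i])^2 + (poly[, 2] - y[i])^2)
          if (d2[j] >= 4 * max_r2) break
          mid <- c((x[i] + x[j]) / 2, (y[i] + y[j]) / 2)
          a <- c(x[j] - x[i], y[j] - y[i])
          poly <- clip_halfplane(poly, a, sum(a * mid))
          if (nrow(poly) == 0) break
        }
        polys[[i]] <- poly
      }
      keep <- setdiff(names(spot), c("x_um", "y_um"))
      purrr::map2(seq_len(n), polys, function(i, p) {
        if (nrow(p) == 0) return(NULL)
        dplyr::bind_cols(
          spot[rep(i, nrow(p)), keep, drop = FALSE],
          tibble::tibble(spot_id = as.character(key$spot_id),
                         vertex = seq_len(nrow(p)), vx = p[, 1], vy = p[, 2])
        )
      }) |> purrr::list_rbind()
    }) |>
    purrr::list_rbind()
}

#' Export Voronoi polygons as GeoJSON
#'
#' Writes a GeoJSON `FeatureCollection` with one polygon feature per cell;
#' label columns (`cell_type`, `cn_final`, ...) become feature properties.
#' Coordinates are micrometres in the per-spot frame.
#'
#' @param polygons Output of [voronoi_cells()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_voronoi_geojson <- function(polygons, path) {
  props <- setdiff(names(polygons), c("vertex", "vx", "vy"))
  features <- polygons |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_map(function(p, key) {
      ring <- cbind(p$vx, p$vy)
      ring <- rbind(ring, ring[1, , drop = FALSE]) # closed ring
      list(
        type = "Feature",
        properties = lapply(
          stats::setNames(props, props),
          function(cc) as.character(p[[cc]][1])
        ),
        geometry = list(type = "Polygon",
                        coordinates = list(apply(ring, 1, as.list)))
      )
    })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
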