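#' Build an axis-aligned analysis grid
#'
#' Tiles the bounding box with square cells of side `cell_size`, starting
#' at the lower-left corner and extending far enough (`ceiling`) to cover
#' the full extent.  Cell ids are row-major from the lower-left: id 1 is
#' the south-west cell, ids increase eastwards, then northwards.  Cells
#' are half-open intervals `[x0, x1) x [y0, y1)` so every point falls in
#' exactly one cell.
#'
#' @param bounds numeric `c(xmin, ymin, xmax, ymax)` in metres.
#' @param cell_size cell side in metres (the study default is 3.6 m, the
#'   finest resolution at which the energy-balance model is applied).
#' @return data.frame (`cell_grid`) with columns `id`, `x0`, `y0`,
#'   `x1`, `y1`; attributes `cell_size`, `origin`, `nx`, `ny`.
#' @export
make_grid <- function(bounds, cell_size = 3.6) {
  stopifnot(length(bounds) == 4)
  bounds <- as.numeric(bounds)
  w <- bounds[3] - bounds[1]; h <- bounds[4] - bounds[2]
  if (w <= 0 || h <= 0) stop("bounds must have positive width and height")
  if (cell_size <= 0) stop("cell_size must be positive")
  nx <- ceiling(w / cell_size - 1e-9)
  ny <- ceiling(h / cell_size - 1e-9)
  ij <- expand.grid(col = seq_len(nx), row = seq_len(ny))
  g <- data.frame(
    id = seq_len(nx * ny),
    x0 = bounds[1] + (ij$col - 1) * cell_size,
    y0 = bounds[2] + (ij$row - 1) * cell_size
  )
  g$x1 <- g$x0 + cell_size
  g$y1 <- g$y0 + cell_size
  attr(g, "cell_size") <- cell_size
  attr(g, "origin") <- bounds[1:2]
  attr(g, "nx") <- nx
  attr(g, "ny") <- ny
  class(g) <- c("cell_grid", "data.frame")
  g
}

#' Assign points to grid cells (half-open rule)
#'
#' @param grid a [make_grid()] grid.
#' @param x,y point coordinates (m).
#' @return integer cell ids; `NA` for points outside the grid.
#' @export
assign_cells <- function(grid, x, y) {
  cs <- attr(grid, "cell_size"); o <- attr(grid, "origin")
  nx <- attr(grid, "nx"); ny <- attr(grid, "ny")
  col <- floor((x - o[1]) / cs) + 1L
  row <- floor((y - o[2]) / cs) + 1L
  id <- (row - 1L) * nx + col
  id[col < 1L | col > nx | row < 1L | row > ny] <- NA_integer_
  as.integer(id)
}

#' Read / write a polygon grid as GeoJSON
#'
#' Cells are exchanged as a FeatureCollection of axis-aligned rectangular
#' Polygons, each with an integer `id` property.  On read, the cells must
#' form a regular axis-aligned tiling.
#'
#' @param grid a `cell_grid`.
#' @param path file path.
#' @export
write_grid_geojson <- function(grid, path) {
  feats <- lapply(seq_len(nrow(grid)), function(i) {
    r <- grid[i, ]
    ring <- list(c(r$x0, r$y0), c(r$x1, r$y0), c(r$x1, r$y1),
                 c(r$x0, r$y1), c(r$x0, r$y0))
    list(type = "Feature",
         properties = list(id = r$id),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  obj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_grid_geojson
#' @export
read_grid_geojson <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$type, "FeatureCollection")) {
    stop("not a GeoJSON FeatureCollection: ", path)
  }
  rows <- lapply(obj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    xs <- vapply(ring, function(p) as.numeric(p[[1]]), numeric(1))
    ys <- vapply(ring, function(p) as.numeric(p[[2]]), numeric(1))
    data.frame(id = as.integer(f$properties$id),
               x0 = min(xs), y0 = min(ys), x1 = max(xs), y1 = max(ys))
  })
  g <- do.call(rbind, rows)
  g <- g[order(g$id), , drop = FALSE]
  rownames(g) <- NULL
  cs <- g$x1[1] - g$x0[1]
  nx <- length(unique(g$x0)); ny <- length(unique(g$y0))
  if (nrow(g) != nx * ny) stop("grid cells do not form a regular tiling")
  attr(g, "cell_size") <- cs
  attr(g, "origin") <- c(min(g$x0), min(g$y0))
  attr(g, "nx") <- nx
  attr(g, "ny") <- ny
  class(g) <- c("cell_grid", "data.frame")
  g
}
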