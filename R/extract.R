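#' Extraction configuration
#'
#' Thresholds and options for the per-cell structural/spectral extraction.
#' Mode `"I"` derives the ground reference from the point cloud itself
#' (per-cell minimum z of NDVI-classified ground points, a zero-slope
#' assumption); mode `"II"` uses a separate ground point file (LiDAR-like)
#' and assigns each point the elevation of its horizontally nearest ground
#' point, so terrain slope is honoured.
#'
#' @param ndvi_threshold points with NDVI strictly greater are vegetation
#'   (default 0.6).
#' @param vine_height_threshold relative height (m) at or above which a
#'   vegetation point is vine canopy rather than cover crop (default
#'   0.5 m, inclusive on the vine side).
#' @param mode `"I"` or `"II"`.
#' @param min_points minimum points per cell/class for structural metrics;
#'   cells below it are flagged, not dropped.
#' @param max_tin_edge optional maximum planimetric TIN edge (m); removes
#'   triangles bridging real gaps (e.g. between disjoint canopy strips in
#'   one cell).  `NULL` (default) disables the filter.
#' @param search_radius radius (m) for nearest-valid-pixel spectral
#'   attribution fallback over nodata.
#' @param temp_method `"percentile"` or `"fixed"`: how the pure-soil and
#'   pure-canopy NDVI thresholds for temperature partitioning are chosen.
#' @param ndvi_s,ndvi_c fixed thresholds (required for
#'   `temp_method = "fixed"`).
#' @param percentiles soil/canopy NDVI percentiles for
#'   `temp_method = "percentile"` (defaults p5/p95).
#' @return a `extraction_config` list.
#' @export
extraction_config <- function(ndvi_threshold = 0.6,
                          vine_height_threshold = 0.5,
                          mode = c("II", "I"),
                          min_points = 10L,
                          max_tin_edge = NULL,
                          search_radius = 1,
                          temp_method = c("percentile", "fixed"),
                          ndvi_s = NULL, ndvi_c = NULL,
                          percentiles = c(0.05, 0.95)) {
  mode <- match.arg(mode)
  temp_method <- match.arg(temp_method)
  stopifnot(is.finite(ndvi_threshold), is.finite(vine_height_threshold))
  if (temp_method == "fixed" && (is.null(ndvi_s) || is.null(ndvi_c))) {
    stop("temp_method = 'fixed' requires ndvi_s and ndvi_c")
  }
  structure(list(ndvi_threshold = ndvi_threshold,
                 vine_height_threshold = vine_height_threshold,
                 mode = mode, min_points = as.integer(min_points),
                 max_tin_edge = max_tin_edge,
                 search_radius = search_radius,
                 temp_method = temp_method,
                 ndvi_s = ndvi_s, ndvi_c = ndvi_c,
                 percentiles = percentiles),
            class = "extraction_config")
}

#' Normalized difference vegetation index
#'
#' `(N - R) / (N + R)`; returns `NA` where the denominator is zero.
#'
#' @param N,R near-infrared and red reflectance (each >= 0).
#' @return NDVI in \[-1, 1\], `NA` where undefined.
#' @export
ndvi <- function(N, R) {
  if (any(N < 0 | R < 0, na.rm = TRUE)) {
    stop("reflectance must be non-negative")
  }
  out <- (N - R) / (N + R)
  out[(N + R) == 0] <- NA_real_
  out
}

#' Attach raster band values to points by nearest pixel
#'
#' Each point receives, per band, the value of the horizontally nearest
#' valid pixel centre.  For a point inside the raster this is the pixel
#' containing it; ties on a pixel boundary go to the lower (row, col)
#' index.  If that pixel is nodata, the nearest valid pixel centre within
#' `search_radius` is used; points with none are flagged
#' `no_<band>` and keep `NA`.  Bands may differ in resolution (each is
#' looked up in its own geometry).
#'
#' @param points data.frame with `x`, `y` (any extra columns kept).
#' @param rasters a `raster_stack` (named list of [band_raster()]).
#' @param search_radius fallback search radius (m).
#' @return `points` with one numeric column per band plus a `flags`
#'   column.
#' @export
attribute_point_spectra <- function(points, rasters, search_radius = 1) {
  if (!length(rasters)) stop("empty raster stack")
  out <- points
  if (is.null(out$flags)) out$flags <- ""
  for (b in names(rasters)) {
    r <- rasters[[b]]
    v <- lookup_nearest_pixel(r, out$x, out$y, search_radius)
    out[[b]] <- v
    miss <- is.na(v)
    if (any(miss)) out$flags[miss] <- add_flag(out$flags[miss],
                                               paste0("no_", b))
  }
  out
}

lookup_nearest_pixel <- function(r, x, y, search_radius) {
  cs <- r$cellsize
  ytop <- r$yll + r$nrow * cs
  fx <- (x - r$xll) / cs
  fy <- (ytop - y) / cs
  col <- floor(fx) + 1L
  row <- floor(fy) + 1L
  # boundary ties -> lower index
  tie_x <- fx == floor(fx) & fx >= 1
  tie_y <- fy == floor(fy) & fy >= 1
  col[tie_x] <- fx[tie_x]
  row[tie_y] <- fy[tie_y]
  # clamp points just outside to the edge pixel (still nearest centre)
  col <- pmin(pmax(col, 1L), r$ncol)
  row <- pmin(pmax(row, 1L), r$nrow)
  val <- r$values[cbind(row, col)]

  miss <- which(is.na(val))
  if (length(miss)) {
    valid <- which(!is.na(r$values), arr.ind = TRUE)
    if (nrow(valid)) {
      pc <- pixel_centers(r)
      vx <- pc$x[valid[, 2]]; vy <- pc$y[valid[, 1]]
      nn <- RANN::nn2(cbind(vx, vy), cbind(x[miss], y[miss]), k = 1)
      ok <- nn$nn.dists[, 1] <= search_radius
      val[miss[ok]] <- r$values[valid[nn$nn.idx[ok, 1], , drop = FALSE]]
    }
  }
  val
}

#' Assign a ground reference and relative heights within one cell
#'
#' Mode I: ground-class points are those with NDVI at or below the
#' threshold; the cell's single ground elevation is their minimum z
#' (falling back to the minimum z of all points, with a flag, when no
#' ground-class points or no spectral data exist).  Mode II: each point
#' takes the z of its horizontally nearest ground point.  Relative height
#' is `z - ground_z`, floored at zero; points more than 1 cm below their
#' ground reference are flagged `below_ground`.
#'
#' @param cell_points data.frame with `x`, `y`, `z` and (mode I) `NDVI`.
#' @param mode `"I"` or `"II"`.
#' @param ground_points data.frame of ground points (mode II).
#' @param ndvi_threshold ground/vegetation NDVI split (mode I).
#' @param core optional logical mask restricting the mode-I minimum to
#'   the in-cell points when buffer points are present.
#' @return `cell_points` with `ground_z`, `rel_height`, updated `flags`,
#'   and an attribute `cell_flag` (`""`, `"ground_fallback"`).
#' @export
assign_ground_reference <- function(cell_points, mode = c("II", "I"),
                                    ground_points = NULL,
                                    ndvi_threshold = 0.6, core = NULL) {
  mode <- match.arg(mode)
  if (nrow(cell_points) == 0) stop("empty cell")
  if (is.null(cell_points$flags)) cell_points$flags <- ""
  if (is.null(core)) core <- rep(TRUE, nrow(cell_points))
  cell_flag <- ""

  if (mode == "I") {
    has_spec <- "NDVI" %in% names(cell_points) &&
      any(is.finite(cell_points$NDVI[core]))
    if (has_spec) {
      gmask <- core & is.finite(cell_points$NDVI) &
        cell_points$NDVI <= ndvi_threshold
      if (any(gmask)) {
        gz <- min(cell_points$z[gmask])
      } else {
        gz <- min(cell_points$z[core])
        cell_flag <- "ground_fallback"
      }
    } else if (any(core)) {
      gz <- min(cell_points$z[core])
      cell_flag <- "ground_fallback"
    } else {
      gz <- min(cell_points$z)
      cell_flag <- "ground_fallback"
    }
    cell_points$ground_z <- gz
  } else {
    if (is.null(ground_points) || nrow(ground_points) == 0) {
      stop("mode II requires non-empty ground_points")
    }
    nn <- RANN::nn2(ground_points[, c("x", "y")],
                    cell_points[, c("x", "y")], k = 1)
    cell_points$ground_z <- ground_points$z[nn$nn.idx[, 1]]
  }

  rel <- cell_points$z - cell_points$ground_z
  below <- rel < -0.01
  if (any(below)) {
    cell_points$flags[below] <- add_flag(cell_points$flags[below],
                                         "below_ground")
  }
  cell_points$rel_height <- pmax(rel, 0)
  attr(cell_points, "cell_flag") <- cell_flag
  cell_points
}

#' Classify points into ground, cover crop and vine canopy
#'
#' Ground: NDVI at or below the vegetation threshold (or missing NDVI).
#' Vegetation splits at the relative-height threshold: strictly below is
#' cover crop, at or above is vine.
#'
#' @param records data.frame with `NDVI` and `rel_height`.
#' @param config a [extraction_config()].
#' @return `records` with a `class` factor column.
#' @export
classify_points <- function(records, config = extraction_config()) {
  stopifnot("rel_height" %in% names(records))
  nd <- if ("NDVI" %in% names(records)) records$NDVI else NA_real_
  veg <- is.finite(nd) & nd > config$ndvi_threshold
  cls <- ifelse(!veg, "ground",
                ifelse(records$rel_height < config$vine_height_threshold,
                       "cover_crop", "vine"))
  records$class <- factor(cls, levels = c("ground", "cover_crop", "vine"))
  records
}

#' Summarize one grid cell
#'
#' Spectral means over all points, over vegetation (suffix `_v`: cover
#' crop + vine) and over vine only (`_vc`); TIN structural metrics for
#' the vegetation and vine classes; mean relative heights `h_v`, `h_vc`;
#' fractional cover `f_c = Area_vc / cell_area` and canopy width
#' `w_c = row_spacing * f_c`.  Empty or undersized classes yield zero
#' metrics plus flags, never errors.
#'
#' The records may include points from a buffer around the cell: pass
#' `core` to mark the in-cell points (counts, spectral means and mean
#' heights use only those) and `cell_rect` to clip the TIN integration
#' to the cell, which removes the convex-hull undershoot a hard clip at
#' the cell boundary would cause.
#'
#' @param cell_records classified records of one cell (may have 0 rows).
#' @param config a [extraction_config()].
#' @param cell_area cell area (m^2).
#' @param cell_origin optional `c(x0, y0)` recorded in the output.
#' @param cell_id id recorded in the output.
#' @param row_spacing vine row spacing used for `w_c` (m).
#' @param cell_rect optional `c(x0, y0, x1, y1)` TIN integration window.
#' @param core optional logical mask of in-cell records (default all).
#' @return one-row data.frame following the cell CSV schema (without
#'   `Ts`/`Tc`, which temperature partitioning appends).
#' @export
summarize_cell <- function(cell_records, config = extraction_config(),
                           cell_area = 12.96, cell_origin = c(NA, NA),
                           cell_id = NA_integer_, row_spacing = 3.35,
                           cell_rect = NULL, core = NULL) {
  flags <- attr(cell_records, "cell_flag")
  if (is.null(flags) || is.na(flags)) flags <- ""
  if (is.null(core)) core <- rep(TRUE, nrow(cell_records))
  n_all <- sum(core)

  sm <- function(col, mask) {
    if (!col %in% names(cell_records)) return(NA_real_)
    v <- cell_records[[col]][mask]
    if (!length(v) || all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  if (n_all == 0) {
    mask_all <- logical(nrow(cell_records))
    flags <- add_flag(flags, "empty_cell")
  } else {
    mask_all <- core
  }
  is_v <- cell_records$class %in% c("cover_crop", "vine")
  is_vc <- !is.na(cell_records$class) & cell_records$class == "vine"
  if (nrow(cell_records) == 0) { is_v <- logical(0); is_vc <- logical(0) }
  mask_v <- mask_all & is_v
  mask_vc <- mask_all & is_vc

  tinm <- function(mask, label) {
    if (sum(mask & core) < config$min_points) {
      return(list(volume = 0, surface_area = 0, projected_area = 0,
                  flag = if (n_all > 0 && sum(mask & core) > 0)
                    paste0("insufficient_points_", label) else ""))
    }
    m <- tin_metrics(cell_records$x[mask], cell_records$y[mask],
                     cell_records$rel_height[mask],
                     max_edge = config$max_tin_edge,
                     min_points = config$min_points,
                     clip_rect = cell_rect)
    if (m$flag != "") m$flag <- paste0(m$flag, "_", label)
    m
  }
  mv <- tinm(is_v, "veg")
  mvc <- tinm(is_vc, "vine")
  for (f in c(mv$flag, mvc$flag)) if (nzchar(f)) flags <- add_flag(flags, f)

  area_vc <- min(mvc$projected_area, cell_area)
  f_c <- area_vc / cell_area

  out <- data.frame(
    id = cell_id, x_min = cell_origin[1], y_min = cell_origin[2],
    n_all = n_all, n_veg = sum(mask_v), n_vine = sum(mask_vc),
    R = sm("R", mask_all), G = sm("G", mask_all), B = sm("B", mask_all),
    N = sm("N", mask_all), NDVI = sm("NDVI", mask_all),
    Tr = sm("Tr", mask_all),
    N_v = sm("N", mask_v), NDVI_v = sm("NDVI", mask_v),
    Tr_v = sm("Tr", mask_v),
    N_vc = sm("N", mask_vc), NDVI_vc = sm("NDVI", mask_vc),
    Tr_vc = sm("Tr", mask_vc),
    h_v = if (any(mask_v)) mean(cell_records$rel_height[mask_v]) else 0,
    h_vc = if (any(mask_vc)) mean(cell_records$rel_height[mask_vc]) else 0,
    Volume_v = mv$volume, SArea_v = mv$surface_area,
    Area_v = min(mv$projected_area, cell_area),
    Volume_vc = mvc$volume, SArea_vc = mvc$surface_area,
    Area_vc = area_vc,
    f_c = f_c, w_c = row_spacing * f_c,
    flags = flags,
    stringsAsFactors = FALSE
  )
  out
}

#' Run the full per-cell extraction over a scene
#'
#' For every grid cell: clip the point cloud, attribute band values by
#' nearest pixel, build the ground reference (mode I or II), classify
#' ground / cover crop / vine, compute TIN structural metrics and
#' spectral means, and partition the cell's radiometric temperature into
#' soil and canopy components from its NDVI-temperature scatter.  Cells
#' with no points are emitted flagged, never dropped, so the output has
#' one row per grid cell.
#'
#' @param point_cloud data.frame with `x`, `y`, `z`.
#' @param rasters a `raster_stack` with bands among R,G,B,N,Tr.
#' @param grid a [make_grid()] grid.
#' @param config a [extraction_config()].
#' @param ground optional ground point data.frame (required for mode II).
#' @param row_spacing vine row spacing for `w_c` (m).
#' @return data.frame, one row per cell, following the cell CSV schema.
#' @export
run_extraction <- function(point_cloud, rasters, grid,
                           config = extraction_config(), ground = NULL,
                           row_spacing = 3.35) {
  if (config$mode == "II" && (is.null(ground) || nrow(ground) == 0)) {
    stop("mode II requires ground points")
  }
  pts <- attribute_point_spectra(point_cloud, rasters,
                                 config$search_radius)
  if (all(c("N", "R") %in% names(pts))) {
    pts$NDVI <- ndvi(pts$N, pts$R)
  }
  pts$cell <- assign_cells(grid, pts$x, pts$y)

  thermal <- cell_thermal_pixels(rasters, grid)
  thr <- select_thresholds(thermal$NDVI, method = config$temp_method,
                           params = list(ndvi_s = config$ndvi_s,
                                         ndvi_c = config$ndvi_c,
                                         percentiles = config$percentiles))

  cell_area <- attr(grid, "cell_size")^2
  buffer <- 0.5  # m; TIN support beyond the cell, clipped at integration

  rows <- lapply(seq_len(nrow(grid)), function(i) {
    id <- grid$id[i]
    rect <- c(grid$x0[i], grid$y0[i], grid$x1[i], grid$y1[i])
    sel <- pts$x >= rect[1] - buffer & pts$x < rect[3] + buffer &
           pts$y >= rect[2] - buffer & pts$y < rect[4] + buffer
    cp <- pts[sel, , drop = FALSE]
    core <- cp$cell == id & !is.na(cp$cell)
    if (nrow(cp) > 0) {
      cp <- assign_ground_reference(cp, mode = config$mode,
                                    ground_points = ground,
                                    ndvi_threshold = config$ndvi_threshold,
                                    core = core)
      cp <- classify_points(cp, config)
    }
    s <- summarize_cell(cp, config, cell_area,
                        cell_origin = c(grid$x0[i], grid$y0[i]),
                        cell_id = id, row_spacing = row_spacing,
                        cell_rect = rect, core = core)
    tp <- thermal[thermal$cell == id & is.finite(thermal$Tr) &
                    is.finite(thermal$NDVI), , drop = FALSE]
    ct <- partition_cell_temperature(tp$NDVI, tp$Tr, thr[1], thr[2])
    s$Ts <- ct$Ts; s$Tc <- ct$Tc
    if (nzchar(ct$flag)) s$flags <- add_flag(s$flags, ct$flag)
    s
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# thermal-resolution pixel table: Tr value + NDVI aggregated (mean of the
# finer NDVI pixels under each thermal pixel) + owning grid cell
cell_thermal_pixels <- function(rasters, grid) {
  if (!all(c("Tr", "N", "R") %in% names(rasters))) {
    return(data.frame(cell = integer(), x = numeric(), y = numeric(),
                      Tr = numeric(), NDVI = numeric()))
  }
  tr <- rasters$Tr
  pc <- pixel_centers(tr)
  tx <- rep(pc$x, each = tr$nrow)
  ty <- rep(pc$y, times = tr$ncol)
  trv <- as.vector(tr$values)

  # aggregate fine NDVI to the thermal grid
  nb <- rasters$N; rb <- rasters$R
  pn <- pixel_centers(nb)
  fx <- rep(pn$x, each = nb$nrow)
  fy <- rep(pn$y, times = nb$ncol)
  fnd <- ndvi(as.vector(nb$values), as.vector(rb$values))
  ci <- floor((fx - tr$xll) / tr$cellsize) + 1L
  ri <- floor((tr$yll + tr$nrow * tr$cellsize - fy) / tr$cellsize) + 1L
  ok <- ci >= 1L & ci <= tr$ncol & ri >= 1L & ri <= tr$nrow
  lin <- (ci[ok] - 1L) * tr$nrow + ri[ok]
  agg <- tapply(fnd[ok], lin, mean, na.rm = TRUE)
  ndv <- rep(NA_real_, tr$nrow * tr$ncol)
  lin_t <- (rep(seq_len(tr$ncol), each = tr$nrow) - 1L) * tr$nrow +
    rep(seq_len(tr$nrow), times = tr$ncol)
  ndv[match(as.integer(names(agg)), lin_t)] <- agg

  data.frame(cell = assign_cells(grid, tx, ty), x = tx, y = ty,
             Tr = trv, NDVI = ndv)
}
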