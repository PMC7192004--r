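#' Single-band georeferenced raster
#'
#' A light container for one band: a numeric matrix whose first row is the
#' *top* (northernmost) row, an axis-aligned geotransform (lower-left
#' corner + square cell size) and a nodata marker.  Nodata cells are held
#' as `NA` and are propagated, never interpolated, at I/O time.
#'
#' @param values numeric matrix, row 1 = top row.
#' @param xll,yll lower-left corner of the raster extent (m).
#' @param cellsize square pixel size (m).
#' @param nodata value written for `NA` cells on output.
#' @return object of class `band_raster`.
#' @export
band_raster <- function(values, xll, yll, cellsize, nodata = -9999) {
  stopifnot(is.matrix(values), cellsize > 0)
  structure(list(values = values, xll = xll, yll = yll,
                 cellsize = cellsize, nodata = nodata,
                 nrow = nrow(values), ncol = ncol(values)),
            class = "band_raster")
}

raster_extent <- function(r) {
  c(xmin = r$xll, ymin = r$yll,
    xmax = r$xll + r$ncol * r$cellsize,
    ymax = r$yll + r$nrow * r$cellsize)
}

#' @export
print.band_raster <- function(x, ...) {
  e <- raster_extent(x)
  cat(sprintf("band_raster %d x %d @ %g m  extent [%g, %g] x [%g, %g]\n",
              x$nrow, x$ncol, x$cellsize, e["xmin"], e["xmax"],
              e["ymin"], e["ymax"]))
  invisible(x)
}

#' Read / write a band as an ESRI ASCII grid
#'
#' Plain-text `.asc` rasters carry their georeference in the six-line
#' header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `NODATA_value`); rows run top to bottom.
#'
#' @param path file path.
#' @return `read_ascii_grid`: a [band_raster()].
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "[[:space:]]+"))
  keys <- tolower(kv[, 1]); vals <- as.numeric(kv[, 2])
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% keys)) stop("malformed ASCII grid header: ", path)
  nodata <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else -9999
  n_hdr <- if ("nodata_value" %in% keys) 6L else 5L
  v <- scan(path, skip = n_hdr, quiet = TRUE)
  m <- matrix(v, nrow = vals[["nrows"]], ncol = vals[["ncols"]], byrow = TRUE)
  m[m == nodata] <- NA_real_
  band_raster(m, vals[["xllcorner"]], vals[["yllcorner"]],
              vals[["cellsize"]], nodata)
}

#' @param r a [band_raster()].
#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(r, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", r$ncol),
               sprintf("nrows %d", r$nrow),
               sprintf("xllcorner %.10g", r$xll),
               sprintf("yllcorner %.10g", r$yll),
               sprintf("cellsize %.10g", r$cellsize),
               sprintf("NODATA_value %.10g", r$nodata)), con)
  m <- r$values
  m[is.na(m)] <- r$nodata
  utils::write.table(format(m, trim = TRUE, digits = 9, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a co-registered multi-band raster stack
#'
#' Loads one file per band and enforces the pipeline's unit contracts:
#' reflectance bands (`R`, `G`, `B`, `N`) must lie in \[0, 1\] where valid,
#' and the thermal band `Tr` is radiometric temperature in degrees Celsius.
#' Bands may differ in resolution (the thermal band is typically coarser
#' than the optical bands); each keeps its own geotransform.
#'
#' @param paths_by_band named list/vector of file paths; names from
#'   `c("R","G","B","N","Tr")`.
#' @return named list of [band_raster()] objects, class `raster_stack`.
#' @export
read_raster_stack <- function(paths_by_band) {
  paths_by_band <- as.list(paths_by_band)
  known <- c("R", "G", "B", "N", "Tr")
  if (is.null(names(paths_by_band)) ||
      !all(names(paths_by_band) %in% known)) {
    stop("band names must be among: ", paste(known, collapse = ", "))
  }
  stack <- lapply(paths_by_band, read_ascii_grid)
  for (b in intersect(names(stack), c("R", "G", "B", "N"))) {
    v <- stack[[b]]$values
    n_bad <- sum(v < 0 | v > 1, na.rm = TRUE)
    if (n_bad > 0) {
      stop("band ", b, ": ", n_bad,
           " pixel(s) outside the reflectance range [0, 1]")
    }
  }
  structure(stack, class = "raster_stack")
}

#' Write a raster stack, one ASCII grid per band
#'
#' @param stack named list of [band_raster()].
#' @param dir output directory; files are named `<band>.asc`.
#' @return named vector of file paths.
#' @export
write_raster_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(stack), function(b) {
    p <- file.path(dir, paste0(b, ".asc"))
    write_ascii_grid(stack[[b]], p)
    p
  }, character(1))
  paths
}

#' Pixel centre coordinates of a band
#' @keywords internal
pixel_centers <- function(r) {
  xs <- r$xll + (seq_len(r$ncol) - 0.5) * r$cellsize
  ys <- r$yll + (r$nrow - seq_len(r$nrow) + 0.5) * r$cellsize  # row 1 = top
  list(x = xs, y = ys)
}
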