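#' Read a point cloud from LAS or delimited XYZ text
#'
#' Points must be in a planar metric coordinate system (e.g. UTM); the
#' structural metrics downstream are areas and volumes in metres, so
#' geographic (lon/lat) coordinates are rejected rather than silently
#' reprojected.
#'
#' @param path path to a `.las` file or a whitespace/comma delimited text
#'   file whose first three numeric columns are x, y, z in metres.
#'   Additional named columns in a delimited file (e.g. `R,G,B,N,Tr`) are
#'   attached as per-point attributes.
#' @param format `"auto"` (by extension), `"xyz"` or `"las"`.
#' @return a `data.frame` with columns `x`, `y`, `z` (metres) plus any
#'   attribute columns, one row per point, in file order.
#' @export
read_point_cloud <- function(path, format = c("auto", "xyz", "las")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("point cloud file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.las$", path, ignore.case = TRUE)) "las" else "xyz"
  }
  pts <- if (format == "las") read_las(path) else read_xyz(path)
  check_planar_coords(pts)
  pts
}

read_xyz <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  has_header <- {
    toks <- strsplit(trimws(first), if (sep == ",") "," else "[[:space:]]+")[[1]]
    suppressWarnings(any(is.na(as.numeric(toks))))
  }
  df <- utils::read.table(path, sep = sep, header = has_header,
                          stringsAsFactors = FALSE, comment.char = "#",
                          blank.lines.skip = TRUE)
  if (ncol(df) < 3L) stop("XYZ file needs at least 3 columns: ", path)
  if (!has_header) {
    names(df)[1:3] <- c("x", "y", "z")
  } else {
    nm <- tolower(names(df))
    for (i in 1:3) {
      want <- c("x", "y", "z")[i]
      if (!want %in% nm) names(df)[i] <- want
    }
    names(df)[match(c("x", "y", "z"), tolower(names(df)))] <- c("x", "y", "z")
  }
  for (col in c("x", "y", "z")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) {
        stop("non-numeric ", col, " value in point record ", bad[1],
             " of ", path)
      }
      df[[col]] <- vn
    }
  }
  bad <- which(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z))
  if (length(bad)) {
    stop("missing or non-finite coordinates in point record ", bad[1],
         " of ", path)
  }
  df
}

check_planar_coords <- function(pts) {
  # lon/lat clouds have tiny coordinate ranges and |x| <= 360
  if (nrow(pts) > 1L) {
    rngx <- diff(range(pts$x)); rngy <- diff(range(pts$y))
    if (max(abs(pts$x)) <= 360 && max(abs(pts$y)) <= 90 &&
        rngx < 1 && rngy < 1 && (rngx > 0 || rngy > 0)) {
      stop("coordinates look geographic (lon/lat); ",
           "a planar metric CRS is required")
    }
  }
  invisible(pts)
}

#' Write a point cloud
#'
#' @param pts data.frame with `x`, `y`, `z` columns.
#' @param path output path; `.las` selects binary LAS 1.2 (point format 0,
#'   1 mm coordinate resolution), anything else a whitespace-delimited text
#'   file with a header line.
#' @export
write_point_cloud <- function(pts, path) {
  stopifnot(all(c("x", "y", "z") %in% names(pts)))
  if (grepl("\\.las$", path, ignore.case = TRUE)) {
    write_las(pts, path)
  } else {
    utils::write.table(pts, path, sep = " ", row.names = FALSE,
                       col.names = TRUE, quote = FALSE)
  }
  invisible(path)
}

# --- minimal LAS 1.2, point data record format 0 ------------------------
# 227-byte header; coordinates stored as int32 at 1 mm scale relative to
# an offset at the cloud minimum, the usual survey convention.

LAS_SCALE <- 0.001

write_las <- function(pts, path) {
  n <- nrow(pts)
  off <- c(min(pts$x), min(pts$y), min(pts$z))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("LASF", con, 4, eos = NULL)
  writeBin(c(0L, 0L), con, size = 2)              # source id, encoding
  writeBin(raw(16), con)                          # GUID
  writeBin(as.raw(c(1L, 2L)), con)                # version 1.2
  writeChar(formatC("canopyflux", width = 32, flag = "-"), con, 32, eos = NULL)
  writeChar(formatC("canopyflux", width = 32, flag = "-"), con, 32, eos = NULL)
  writeBin(c(1L, 2026L), con, size = 2)           # day, year
  writeBin(227L, con, size = 2)                   # header size
  writeBin(227L, con, size = 4)                   # offset to point data
  writeBin(0L, con, size = 4)                     # number of VLRs
  writeBin(as.raw(0L), con)                       # point format 0
  writeBin(20L, con, size = 2)                    # record length
  writeBin(n, con, size = 4)                      # point count
  writeBin(c(n, 0L, 0L, 0L, 0L), con, size = 4)   # by return
  writeBin(rep(LAS_SCALE, 3), con, size = 8)      # scales
  writeBin(off, con, size = 8)                    # offsets
  writeBin(c(max(pts$x), min(pts$x), max(pts$y), min(pts$y),
             max(pts$z), min(pts$z)), con, size = 8)
  xi <- as.integer(round((pts$x - off[1]) / LAS_SCALE))
  yi <- as.integer(round((pts$y - off[2]) / LAS_SCALE))
  zi <- as.integer(round((pts$z - off[3]) / LAS_SCALE))
  body <- matrix(raw(1), nrow = 20L, ncol = n)
  body[1:4, ]   <- matrix(writeBin(xi, raw(), size = 4), nrow = 4)
  body[5:8, ]   <- matrix(writeBin(yi, raw(), size = 4), nrow = 4)
  body[9:12, ]  <- matrix(writeBin(zi, raw(), size = 4), nrow = 4)
  writeBin(as.vector(body), con)
  invisible(path)
}

read_las <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readChar(con, 4, useBytes = TRUE)
  if (!identical(sig, "LASF")) stop("not a LAS file: ", path)
  invisible(readBin(con, "integer", 2, size = 2))   # source id, encoding
  invisible(readBin(con, "raw", 16))
  ver <- readBin(con, "integer", 2, size = 1)
  invisible(readChar(con, 64, useBytes = TRUE))     # system + software id
  invisible(readBin(con, "integer", 2, size = 2))   # day, year
  invisible(readBin(con, "integer", 1, size = 2))   # header size
  data_off <- readBin(con, "integer", 1, size = 4)
  invisible(readBin(con, "integer", 1, size = 4))   # VLR count
  fmt <- as.integer(readBin(con, "raw", 1))
  rec_len <- readBin(con, "integer", 1, size = 2)
  n <- readBin(con, "integer", 1, size = 4)
  invisible(readBin(con, "integer", 5, size = 4))
  scale <- readBin(con, "double", 3, size = 8)
  off <- readBin(con, "double", 3, size = 8)
  invisible(readBin(con, "double", 6, size = 8))
  seek(con, data_off)
  body <- readBin(con, "raw", rec_len * n)
  dim(body) <- c(rec_len, n)
  xi <- readBin(as.vector(body[1:4, ]),  "integer", n, size = 4)
  yi <- readBin(as.vector(body[5:8, ]),  "integer", n, size = 4)
  zi <- readBin(as.vector(body[9:12, ]), "integer", n, size = 4)
  data.frame(x = xi * scale[1] + off[1],
             y = yi * scale[2] + off[2],
             z = zi * scale[3] + off[3])
}
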