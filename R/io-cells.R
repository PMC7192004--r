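# Fixed CSV schema for per-cell summaries.  Structural columns of flagged
# cells (e.g. insufficient_points) are written as empty fields; the flag
# column records why.

CELL_CSV_COLUMNS <- c(
  "id", "x_min", "y_min", "n_all", "n_veg", "n_vine",
  "R", "G", "B", "N", "NDVI", "Tr",
  "N_v", "NDVI_v", "Tr_v", "N_vc", "NDVI_vc", "Tr_vc",
  "h_v", "h_vc",
  "Volume_v", "SArea_v", "Area_v",
  "Volume_vc", "SArea_vc", "Area_vc",
  "f_c", "w_c", "Ts", "Tc", "flags"
)

#' Write per-cell canopy summaries to CSV
#'
#' Column order is fixed (see `canopyflux:::CELL_CSV_COLUMNS`); numeric
#' fields are written with full precision, missing metrics as empty
#' fields, and the semicolon-separated `flags` column explains any gaps.
#'
#' @param summaries data.frame of cell summaries (see [summarize_cell()]).
#' @param path output CSV path.
#' @export
write_cell_csv <- function(summaries, path) {
  out <- summaries
  for (col in setdiff(CELL_CSV_COLUMNS, names(out))) out[[col]] <- NA
  out <- out[, CELL_CSV_COLUMNS]
  if (is.null(out$flags)) out$flags <- ""
  out$flags[is.na(out$flags)] <- ""
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cell_csv
#' @export
read_cell_csv <- function(path) {
  if (!file.exists(path)) stop("cell summary file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(flags = "character"))
  df$flags[is.na(df$flags)] <- ""
  df
}

add_flag <- function(flags, flag) {
  ifelse(flags == "" | is.na(flags), flag, paste(flags, flag, sep = ";"))
}

has_flag <- function(flags, flag) {
  vapply(strsplit(ifelse(is.na(flags), "", flags), ";"),
         function(f) flag %in% f, logical(1))
}
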