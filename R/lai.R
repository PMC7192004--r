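#' Normalize cell structural metrics for the LAI models
#'
#' Structural metrics are divided by the grid-cell area so the LAI models
#' are independent of cell size: volumes become metres (m^3/m^2), areas
#' dimensionless fractions.  Spectral fields pass through unchanged;
#' temperature stays in degrees Celsius.
#'
#' @param cell_summary one or more rows of the extraction output.
#' @param cell_area grid-cell area (m^2); 12.96 for the 3.6 m grid.
#' @return data.frame of model inputs: `N`, `NDVI`, `Tr`, `N_v`, `N_vc`,
#'   `Volume_v`, `Volume_vc`, `Area_v`, `Area_vc`, `SArea_v`, `SArea_vc`.
#' @export
normalize_inputs <- function(cell_summary, cell_area = 12.96) {
  if (cell_area <= 0) stop("cell_area must be positive")
  structural <- c("Volume_v", "Volume_vc", "Area_v", "Area_vc",
                  "SArea_v", "SArea_vc")
  spectral <- c("N", "NDVI", "Tr", "N_v", "N_vc")
  out <- cell_summary[intersect(c(spectral, structural),
                                names(cell_summary))]
  for (col in intersect(structural, names(out))) {
    out[[col]] <- out[[col]] / cell_area
  }
  as.data.frame(out)
}

#' Published LAI model expressions
#'
#' Three leaf-area-index models over the normalized cell metrics: a
#' spectral-only model (1), a structural-only model (2) and a combined
#' model (3).  Model 1 is unambiguous.  The printed forms of models 2
#' and 3 are typographically ambiguous in their fraction/exponent
#' placement, so both are held as *configurable expressions*; the
#' defaults below are this package's documented reading and should not
#' be treated as authoritative:
#'
#' * Model 1: `5.85 + 17.37*N*N_v + 0.85*NDVI*Tr - 0.52*Tr
#'   - 8.51*N_vc^2 - 14.96*NDVI^2`
#' * Model 2: `0.47 + 2.39*Area_vc - 2.29*Area_vc*Area_v^0.41 *
#'   43.07^(-Volume_v)`
#' * Model 3: `2.69*N*Volume_vc + 0.11*Tr*Area_v - 0.67*Area_v/N_vc
#'   - 0.38*1.54^Tr*N^2*NDVI^2 / (6.92*N_vc^4*Volume_vc)`
#'
#' `Tr` is in degrees Celsius; structural inputs are area-normalized.
#'
#' @param id model id (1, 2 or 3).
#' @param expression optional replacement expression string over the
#'   input names.
#' @param clamp_nonnegative clamp negative predictions at zero
#'   (off by default; the printed forms can go negative).
#' @return a `lai_model_spec` list.
#' @export
lai_model_spec <- function(id, expression = NULL,
                           clamp_nonnegative = FALSE) {
  stopifnot(id %in% 1:3)
  default <- switch(id,
    "5.85 + 17.37*N*N_v + 0.85*NDVI*Tr - 0.52*Tr - 8.51*N_vc^2 - 14.96*NDVI^2",
    "0.47 + 2.39*Area_vc - 2.29*Area_vc*Area_v^0.41*43.07^(-Volume_v)",
    paste0("2.69*N*Volume_vc + 0.11*Tr*Area_v - 0.67*Area_v/N_vc",
           " - 0.38*1.54^Tr*N^2*NDVI^2/(6.92*N_vc^4*Volume_vc)"))
  structure(list(id = id,
                 expression = if (is.null(expression)) default else expression,
                 clamp_nonnegative = clamp_nonnegative),
            class = "lai_model_spec")
}

#' Evaluate an LAI model on normalized inputs
#'
#' Pure, vectorized evaluation of the model expression.  Divisions by
#' zero and negative bases under fractional exponents yield `NA`
#' (flagged missing), never an error; model 3 returns `NA` where
#' `N_vc = 0` or `Volume_vc = 0` makes its rational term undefined.
#'
#' @param inputs data.frame from [normalize_inputs()].
#' @param spec a [lai_model_spec()] (or a model id 1-3).
#' @return numeric LAI vector.
#' @export
lai_model <- function(inputs, spec) {
  if (is.numeric(spec)) spec <- lai_model_spec(spec)
  ex <- parse(text = spec$expression)[[1]]
  v <- eval(ex, envir = inputs, enclos = baseenv())
  v[!is.finite(v)] <- NA_real_
  if (spec$clamp_nonnegative) v <- pmax(v, 0)
  v
}

#' @rdname lai_model
#' @export
lai_model1 <- function(inputs, clamp_nonnegative = FALSE) {
  lai_model(inputs, lai_model_spec(1, clamp_nonnegative = clamp_nonnegative))
}

#' @rdname lai_model
#' @export
lai_model2 <- function(inputs, clamp_nonnegative = FALSE) {
  lai_model(inputs, lai_model_spec(2, clamp_nonnegative = clamp_nonnegative))
}

#' @rdname lai_model
#' @export
lai_model3 <- function(inputs, clamp_nonnegative = FALSE) {
  lai_model(inputs, lai_model_spec(3, clamp_nonnegative = clamp_nonnegative))
}

#' Ordinary least-squares refit of a linear LAI model
#'
#' Fits `LAI ~ terms` by OLS over a table of normalized inputs; used to
#' verify that a known linear structure is recoverable from the
#' extraction outputs (the symbolic search that produced the published
#' models is out of scope).
#'
#' @param inputs_table data.frame of input columns.
#' @param lai observed LAI vector.
#' @param terms character vector of column names to use as regressors.
#' @return list with `coefficients` (named, incl. intercept),
#'   `std_errors`, `r_squared`, `rmse`, `n`.
#' @export
refit_linear <- function(inputs_table, lai, terms) {
  stopifnot(all(terms %in% names(inputs_table)))
  X <- cbind(`(Intercept)` = 1, as.matrix(inputs_table[terms]))
  n <- nrow(X)
  if (n < length(terms) + 2) stop("need n >= number of terms + 2")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm.fit(X, lai)
  res <- fit$residuals
  sigma2 <- sum(res^2) / (n - ncol(X))
  XtXinv <- solve(crossprod(X))
  se <- sqrt(diag(XtXinv) * sigma2)
  names(se) <- colnames(X)
  sst <- sum((lai - mean(lai))^2)
  list(coefficients = fit$coefficients,
       std_errors = se,
       r_squared = if (sst > 0) 1 - sum(res^2) / sst else NA_real_,
       rmse = sqrt(mean(res^2)),
       n = n)
}
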