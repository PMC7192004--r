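#' Least-squares line through a cell's NDVI-temperature scatter
#'
#' Ordinary least squares of radiometric temperature on NDVI over the
#' thermal-resolution pixels of one grid cell.  Soil pixels are warm and
#' bare (low NDVI), canopy pixels cool and green (high NDVI), so the
#' physical expectation is a negative slope.
#'
#' @param ndvi,tr equal-length numeric vectors of pixel pairs.
#' @return list with `slope`, `intercept`, `n`, and `flag`
#'   (`"degenerate"` when fewer than 3 pairs or zero NDVI variance; the
#'   mean temperature is then returned as a flat line).
#' @export
fit_ndvi_tr_line <- function(ndvi, tr) {
  ok <- is.finite(ndvi) & is.finite(tr)
  ndvi <- ndvi[ok]; tr <- tr[ok]
  n <- length(ndvi)
  if (n < 3 || stats::var(ndvi) == 0) {
    mt <- if (n > 0) mean(tr) else NA_real_
    return(list(slope = 0, intercept = mt, n = n, flag = "degenerate"))
  }
  fit <- stats::lm.fit(cbind(1, ndvi), tr)
  list(slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       n = n, flag = "")
}

#' Choose pure-soil and pure-canopy NDVI thresholds
#'
#' `"fixed"` returns user values (the route for thresholds derived from
#' an external LAI-NDVI relationship); `"percentile"` takes low/high
#' percentiles of the scene NDVI histogram (defaults p5/p95) as the
#' histogram-analysis realization.
#'
#' @param scene_ndvi NDVI values over the whole scene (thermal-pixel
#'   aggregation), used by the percentile method.
#' @param method `"fixed"` or `"percentile"`.
#' @param params list: `ndvi_s`, `ndvi_c` (fixed) or `percentiles`.
#' @return numeric `c(NDVI_s, NDVI_c)` with `NDVI_s < NDVI_c`.
#' @export
select_thresholds <- function(scene_ndvi = NULL,
                              method = c("percentile", "fixed"),
                              params = list()) {
  method <- match.arg(method)
  if (method == "fixed") {
    ts <- params$ndvi_s; tc <- params$ndvi_c
    if (is.null(ts) || is.null(tc)) stop("fixed method needs ndvi_s, ndvi_c")
  } else {
    pr <- params$percentiles
    if (is.null(pr)) pr <- c(0.05, 0.95)
    v <- scene_ndvi[is.finite(scene_ndvi)]
    if (!length(v)) stop("no finite NDVI values for percentile thresholds")
    q <- stats::quantile(v, pr, names = FALSE)
    ts <- q[1]; tc <- q[2]
  }
  if (ts >= tc) stop("NDVI_s must be below NDVI_c (got ",
                     signif(ts, 4), " >= ", signif(tc, 4), ")")
  c(NDVI_s = ts, NDVI_c = tc)
}

#' Component temperatures from a fitted NDVI-temperature line
#'
#' Substitutes the soil and canopy NDVI thresholds into the fitted line
#' and assigns the higher temperature to soil (`Ts`), the lower to
#' canopy (`Tc`).  A non-negative slope (canopy warmer than soil) is
#' physically unexpected and flagged `positive_slope`, not rejected.
#'
#' @param line result of [fit_ndvi_tr_line()].
#' @param ndvi_s,ndvi_c soil and canopy NDVI thresholds.
#' @return list with `Ts`, `Tc` (deg C), `slope`, `intercept`,
#'   `NDVI_s`, `NDVI_c`, `n_pixels`, `flag`.
#' @export
partition_temperatures <- function(line, ndvi_s, ndvi_c) {
  stopifnot(ndvi_s < ndvi_c)
  t1 <- line$intercept + line$slope * ndvi_s
  t2 <- line$intercept + line$slope * ndvi_c
  flag <- line$flag
  if (line$flag != "degenerate" && line$slope > 0) {
    flag <- add_flag(flag, "positive_slope")
  }
  list(Ts = max(t1, t2), Tc = min(t1, t2),
       slope = line$slope, intercept = line$intercept,
       NDVI_s = unname(ndvi_s), NDVI_c = unname(ndvi_c),
       n_pixels = line$n, flag = flag)
}

# one-call convenience used by run_extraction
partition_cell_temperature <- function(ndvi, tr, ndvi_s, ndvi_c) {
  line <- fit_ndvi_tr_line(ndvi, tr)
  if (is.na(line$intercept)) {
    return(list(Ts = NA_real_, Tc = NA_real_, flag = "no_thermal_pixels"))
  }
  partition_temperatures(line, ndvi_s, ndvi_c)
}
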