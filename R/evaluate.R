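#' Force eddy-covariance energy-balance closure at the Bowen ratio
#'
#' Redistributes the energy-balance residual `Rn - G - H - LE` over the
#' turbulent fluxes proportionally, preserving the Bowen ratio `H/LE`:
#' `H_BR = H/(H+LE) * (Rn - G - H - LE) + H` and analogously for LE.
#' After closure `H_BR + LE_BR = Rn - G` exactly.  Records with
#' `H + LE = 0` cannot be scaled and are flagged, not closed.
#'
#' @param records data.frame with columns `Rn`, `G`, `H`, `LE`
#'   (W/m^2, hourly).
#' @return `records` with `H_BR`, `LE_BR` and a `closure_flag` column
#'   (`""` or `"zero_turbulent_sum"`).
#' @export
bowen_closure <- function(records) {
  stopifnot(all(c("Rn", "G", "H", "LE") %in% names(records)))
  s <- records$H + records$LE
  resid <- records$Rn - records$G - s
  ok <- s != 0
  records$H_BR <- ifelse(ok, records$H / s * resid + records$H, NA_real_)
  records$LE_BR <- ifelse(ok, records$LE / s * resid + records$LE, NA_real_)
  records$closure_flag <- ifelse(ok, "", "zero_turbulent_sum")
  records
}

#' Model evaluation statistics with the RRMSE rating
#'
#' For measured `M` and estimated `E`:
#' `R2 = 1 - sum((M-E)^2) / sum((M-mean(M))^2)` (can be negative and is
#' reported as computed), `MAE = mean(|M-E|)`,
#' `RMSE = sqrt(mean((M-E)^2))`, `RRMSE = 100 * RMSE / mean(M)` (%),
#' rated excellent (< 10), good (10-20), fair (20-30), poor (> 30); a
#' boundary value falls in the better category.
#'
#' @param M measured values.
#' @param E estimated values (same length, n >= 2).
#' @return list `n`, `mean_measured`, `r_squared`, `mae`, `rmse`,
#'   `rrmse`, `rating`.
#' @export
fit_metrics <- function(M, E) {
  stopifnot(length(M) == length(E))
  ok <- is.finite(M) & is.finite(E)
  M <- M[ok]; E <- E[ok]
  n <- length(M)
  if (n < 2) stop("need at least 2 paired observations")
  sse <- sum((M - E)^2)
  sst <- sum((M - mean(M))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  mae <- mean(abs(M - E))
  rmse <- sqrt(sse / n)
  mbar <- mean(M)
  rrmse <- if (mbar != 0) 100 * rmse / mbar else NA_real_
  list(n = n, mean_measured = mbar, r_squared = r2,
       mae = mae, rmse = rmse, rrmse = rrmse,
       rating = rrmse_rating(rrmse))
}

#' @rdname fit_metrics
#' @param rrmse relative RMSE in percent.
#' @export
rrmse_rating <- function(rrmse) {
  if (!is.finite(rrmse)) return(NA_character_)
  if (rrmse < 0) stop("RRMSE must be non-negative")
  if (rrmse <= 10) "excellent"
  else if (rrmse <= 20) "good"
  else if (rrmse <= 30) "fair"
  else "poor"
}

#' Evaluation report across flux variables
#'
#' Convenience wrapper producing one row of statistics per variable,
#' mirroring the usual flux-evaluation table layout.
#'
#' @param measured,estimated data.frames sharing flux columns.
#' @param variables columns to evaluate (default the common numeric
#'   ones).
#' @return data.frame with one row per variable.
#' @export
evaluation_report <- function(measured, estimated,
                              variables = intersect(names(measured),
                                                    names(estimated))) {
  rows <- lapply(variables, function(v) {
    m <- fit_metrics(measured[[v]], estimated[[v]])
    data.frame(variable = v, n = m$n, r_squared = m$r_squared,
               mae = m$mae, rmse = m$rmse, rrmse = m$rrmse,
               rating = m$rating, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
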