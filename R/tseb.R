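# Two-source energy balance with known component temperatures (TSEB-2T):
# radiation partitioning, soil heat flux, series-resistance sensible heat
# with Monin-Obukhov stability iteration, latent heat as the residual.

SIGMA_SB <- 5.670374419e-8   # W m-2 K-4
VON_KARMAN <- 0.41
GRAVITY <- 9.81
CP_AIR <- 1013               # J kg-1 K-1, moist-air convention

#' Radiation and canopy-structure configuration
#'
#' @param k_L longwave extinction coefficient (default 0.95).
#' @param omega clumping factor (default 1.0; may be a per-cell vector).
#' @param eps_c,eps_s canopy and soil emissivity.
#' @param alpha_c,alpha_s canopy and soil albedo.
#' @param solar_zenith solar zenith angle (degrees) for beam
#'   transmittance.
#' @param c_G soil heat flux fraction of soil net radiation
#'   (default 0.3).
#' @param l_w mean leaf width (m).
#' @param C_rx coefficient of the canopy boundary-layer resistance
#'   (s^1/2 m^-1, default 90).
#' @return a `radiation_config` list.
#' @export
radiation_config <- function(k_L = 0.95, omega = 1.0,
                             eps_c = 0.98, eps_s = 0.95,
                             alpha_c = 0.20, alpha_s = 0.15,
                             solar_zenith = 30, c_G = 0.3,
                             l_w = 0.1, C_rx = 90) {
  stopifnot(eps_c > 0, eps_c <= 1, eps_s > 0, eps_s <= 1,
            alpha_c > 0, alpha_c <= 1, alpha_s > 0, alpha_s <= 1,
            all(omega > 0), all(omega <= 1.2),
            c_G >= 0, c_G <= 1, solar_zenith >= 0, solar_zenith < 90)
  structure(list(k_L = k_L, omega = omega, eps_c = eps_c, eps_s = eps_s,
                 alpha_c = alpha_c, alpha_s = alpha_s,
                 solar_zenith = solar_zenith, c_G = c_G,
                 l_w = l_w, C_rx = C_rx),
            class = "radiation_config")
}

c_to_k <- function(t) t + 273.15

#' Longwave emission of soil, canopy and sky
#'
#' Grey-body emission of the soil and canopy at their component
#' temperatures, and clear-sky downwelling emission with a Brutsaert-type
#' atmospheric emissivity `1.24 * (10*ea / Ta_K)^(1/7)` (ea in kPa).
#'
#' @param Ts,Tc,Ta soil, canopy and air temperature (deg C).
#' @param ea vapour pressure (kPa).
#' @param config a [radiation_config()].
#' @return list `L_s`, `L_c`, `L_sky` (W/m^2).
#' @export
longwave_sources <- function(Ts, Tc, Ta, ea, config = radiation_config()) {
  if (any(c(Ts, Tc, Ta) < -100)) stop("nonphysical temperature below -100 C")
  TsK <- c_to_k(Ts); TcK <- c_to_k(Tc); TaK <- c_to_k(Ta)
  eps_a <- 1.24 * (10 * ea / TaK)^(1 / 7)
  list(L_s = config$eps_s * SIGMA_SB * TsK^4,
       L_c = config$eps_c * SIGMA_SB * TcK^4,
       L_sky = eps_a * SIGMA_SB * TaK^4)
}

#' Partition net longwave radiation between canopy and soil
#'
#' Exponential extinction through the canopy:
#' `Ln_c = (1 - exp(-k_L * Omega * LAI)) * (L_sky + L_s - 2*L_c)` and
#' `Ln_s = exp(-k_L * Omega * LAI) * L_sky +
#'         (1 - exp(-k_L * Omega * LAI)) * L_c - L_s`.
#'
#' @param LAI leaf area index (>= 0).
#' @param config a [radiation_config()].
#' @param L_sky,L_s,L_c longwave sources (W/m^2).
#' @return list `Ln_c`, `Ln_s` (W/m^2).
#' @export
partition_longwave <- function(LAI, config, L_sky, L_s, L_c) {
  stopifnot(all(LAI >= 0))
  ext <- exp(-config$k_L * config$omega * LAI)
  list(Ln_c = (1 - ext) * (L_sky + L_s - 2 * L_c),
       Ln_s = ext * L_sky + (1 - ext) * L_c - L_s)
}

#' Beam solar transmittance through the canopy
#'
#' `tau_s = exp(-K_be(theta) * Omega * LAI)` with the
#' spherical-leaf-angle beam extinction coefficient
#' `K_be = sqrt(1 + tan^2 theta) / (1 + 1.774 * 2.182^-0.733)`
#' (the x = 1 case of the ellipsoidal distribution).
#'
#' @param LAI leaf area index (>= 0).
#' @param omega clumping factor.
#' @param solar_zenith zenith angle (degrees, < 90).
#' @return transmittance in \[0, 1\].
#' @export
solar_transmittance <- function(LAI, omega = 1, solar_zenith = 30) {
  stopifnot(all(LAI >= 0))
  if (any(solar_zenith >= 90)) stop("solar zenith must be below 90 degrees")
  th <- solar_zenith * pi / 180
  x <- 1
  kbe <- sqrt(x^2 + tan(th)^2) / (x + 1.774 * (x + 1.182)^(-0.733))
  pmin(1, exp(-kbe * omega * LAI))
}

#' Net radiation of canopy and soil
#'
#' `Rn_c = Ln_c + (1 - tau_s) * (1 - alpha_c) * S` and
#' `Rn_s = Ln_s + tau_s * (1 - alpha_s) * S`; total `Rn = Rn_c + Rn_s`
#' by construction.
#'
#' @param Ln_c,Ln_s component net longwave (W/m^2).
#' @param tau_s solar transmittance.
#' @param S incoming shortwave (W/m^2, >= 0).
#' @param config a [radiation_config()].
#' @return list `Rn_c`, `Rn_s`, `Rn` (W/m^2).
#' @export
net_radiation <- function(Ln_c, Ln_s, tau_s, S, config = radiation_config()) {
  stopifnot(all(S >= 0))
  Rn_c <- Ln_c + (1 - tau_s) * (1 - config$alpha_c) * S
  Rn_s <- Ln_s + tau_s * (1 - config$alpha_s) * S
  list(Rn_c = Rn_c, Rn_s = Rn_s, Rn = Rn_c + Rn_s)
}

#' Soil heat flux as a fraction of soil net radiation
#'
#' @param Rn_s soil net radiation (W/m^2); negative values (nighttime)
#'   pass through.
#' @param c_G fraction in \[0, 1\] (default 0.3).
#' @return G (W/m^2).
#' @export
soil_heat_flux <- function(Rn_s, c_G = 0.3) {
  stopifnot(c_G >= 0, c_G <= 1)
  c_G * Rn_s
}

#' Canopy boundary-layer resistance
#'
#' `R_x = (C / LAI) * sqrt(l_w / U_d0z0m)` with C = 90 s^1/2 m^-1:
#' inversely proportional to leaf area, square-root in leaf width over
#' the wind speed at height `d0 + z0M` inside the canopy.
#'
#' @param LAI leaf area index (> 0; zero returns `Inf`).
#' @param l_w mean leaf width (m).
#' @param U_d0z0m wind speed at `d0 + z0M` (m/s, > 0).
#' @param C coefficient (s^1/2 m^-1).
#' @return resistance (s/m).
#' @export
canopy_boundary_resistance <- function(LAI, l_w = 0.1, U_d0z0m = 1,
                                       C = 90) {
  stopifnot(all(U_d0z0m > 0))
  ifelse(LAI > 0, (C / LAI) * sqrt(l_w / U_d0z0m), Inf)
}

# Businger-Dyer stability corrections
psi_m <- function(zeta) {
  out <- numeric(length(zeta))
  stab <- zeta >= 0
  out[stab] <- -5 * zeta[stab]
  xx <- (1 - 16 * zeta[!stab])^0.25
  out[!stab] <- 2 * log((1 + xx) / 2) + log((1 + xx^2) / 2) -
    2 * atan(xx) + pi / 2
  out
}

psi_h <- function(zeta) {
  out <- numeric(length(zeta))
  stab <- zeta >= 0
  out[stab] <- -5 * zeta[stab]
  xx <- (1 - 16 * zeta[!stab])^0.5
  out[!stab] <- 2 * log((1 + xx) / 2)
  out
}

#' Aerodynamic and soil-surface resistances
#'
#' Log-profile friction velocity and aerodynamic resistance with
#' Businger-Dyer stability corrections driven by the Monin-Obukhov
#' length; exponential in-canopy wind attenuation (Goudriaan) down to
#' `d0 + z0M` and to 5 cm above the soil; soil resistance
#' `R_s = 1 / (0.004 + 0.012 * u_s)`.  Roughness follows the standard
#' crop rules `d0 = 0.65 h_c`, `z0M = 0.125 h_c`.
#'
#' @param u wind speed at `z_u` (m/s; floored at 0.5 with a flag).
#' @param z_u,z_T measurement heights of wind and temperature (m).
#' @param h_c canopy height (m, < z_u).
#' @param LAI leaf area index (attenuation strength).
#' @param l_w mean leaf width (m).
#' @param L_MO Monin-Obukhov length (m); `Inf` for neutral.
#' @return list `u_star`, `R_a`, `R_s`, `U_d0z0m`, `d0`, `z0M`, `flag`.
#' @export
aero_resistances <- function(u, z_u, z_T, h_c, LAI, l_w = 0.1,
                             L_MO = Inf) {
  flag <- ""
  if (u < 0.5) { u <- 0.5; flag <- "wind_floored" }
  d0 <- 0.65 * h_c
  z0M <- 0.125 * h_c
  if (z_u <= h_c || d0 + z0M >= z_u) {
    stop("measurement height must exceed canopy height")
  }
  zeta_u <- (z_u - d0) / L_MO
  zeta_T <- (z_T - d0) / L_MO
  if (!is.finite(L_MO)) { zeta_u <- 0; zeta_T <- 0 }
  u_star <- VON_KARMAN * u /
    (log((z_u - d0) / z0M) - psi_m(zeta_u) + psi_m(z0M / L_MO * is.finite(L_MO)))
  u_star <- max(u_star, 0.01)
  R_a <- (log((z_T - d0) / z0M) - psi_h(zeta_T) +
            psi_h(z0M / L_MO * is.finite(L_MO))) / (VON_KARMAN * u_star)
  R_a <- max(R_a, 1)

  # wind at canopy top, then Goudriaan exponential attenuation
  u_c <- u_star / VON_KARMAN * log((h_c - d0) / z0M)
  u_c <- max(u_c, 0.1)
  a_g <- 0.28 * max(LAI, 0.1)^(2 / 3) * h_c^(1 / 3) * l_w^(-1 / 3)
  U_d0z0m <- u_c * exp(-a_g * (1 - (d0 + z0M) / h_c))
  u_s <- u_c * exp(-a_g * (1 - 0.05 / h_c))
  R_s <- 1 / (0.004 + 0.012 * u_s)

  list(u_star = u_star, R_a = R_a, R_s = R_s,
       U_d0z0m = max(U_d0z0m, 0.01), d0 = d0, z0M = z0M, flag = flag)
}

air_density <- function(p_kpa, Ta_c, ea_kpa) {
  (p_kpa - 0.378 * ea_kpa) * 1000 / (287.04 * c_to_k(Ta_c))
}

#' Solve the two-source energy balance for one cell
#'
#' Series resistance network: the in-canopy air temperature is the
#' resistance-weighted mean
#' `T_AC = (Ta/R_a + Tc/R_x + Ts/R_s) / (1/R_a + 1/R_x + 1/R_s)`,
#' sensible heat of canopy and soil follow from their temperature
#' differences to `T_AC`, and the Monin-Obukhov length is iterated until
#' it changes by less than `1e-5` m (at most `max_iter` passes; an
#' unconverged run is flagged).  Latent heat is the residual of each
#' component balance: `LE_s = Rn_s - G - H_s`, `LE_c = Rn_c - H_c`.
#'
#' @param Ts,Tc soil and canopy temperature (deg C).
#' @param Ta air temperature (deg C).
#' @param u wind speed (m/s).
#' @param S incoming shortwave (W/m^2).
#' @param ea vapour pressure (kPa).
#' @param p pressure (kPa).
#' @param LAI leaf area index.
#' @param h_c canopy height (m).
#' @param f_c fractional cover (enters through the clumping option and
#'   reporting; radiation partitioning uses LAI directly).
#' @param z_u,z_T measurement heights (m).
#' @param config a [radiation_config()].
#' @param max_iter iteration cap (default 100).
#' @param tol convergence tolerance on `|delta L_MO|` (m).
#' @return list of class `flux_state`: `Rn`, `Rn_c`, `Rn_s`, `G`, `H`,
#'   `H_c`, `H_s`, `LE`, `LE_c`, `LE_s`, `T_AC`, `L_MO`, `u_star`,
#'   `R_a`, `R_x`, `R_s`, `iterations`, `converged`, `flag`.
#' @export
solve_fluxes <- function(Ts, Tc, Ta, u, S, ea, p, LAI, h_c,
                         f_c = NA, z_u = 5, z_T = 5,
                         config = radiation_config(),
                         max_iter = 100L, tol = 1e-5) {
  lw <- longwave_sources(Ts, Tc, Ta, ea, config)
  ln <- partition_longwave(LAI, config, lw$L_sky, lw$L_s, lw$L_c)
  tau <- solar_transmittance(LAI, config$omega, config$solar_zenith)
  rn <- net_radiation(ln$Ln_c, ln$Ln_s, tau, S, config)
  G <- soil_heat_flux(rn$Rn_s, config$c_G)

  rho <- air_density(p, Ta, ea)
  flag <- ""
  L <- Inf  # neutral start
  H <- 0; T_AC <- Ta; res <- NULL; R_x <- NA
  iterations <- 0L; converged <- FALSE
  for (it in seq_len(max_iter)) {
    iterations <- it
    res <- aero_resistances(u, z_u, z_T, h_c, LAI,
                            l_w = config$l_w, L_MO = L)
    if (nzchar(res$flag)) flag <- add_flag(flag, res$flag)
    R_x <- canopy_boundary_resistance(LAI, config$l_w, res$U_d0z0m,
                                      config$C_rx)
    if (any(c(res$R_a, res$R_s) <= 0) || (is.finite(R_x) && R_x <= 0)) {
      stop("nonpositive resistance (R_a=", signif(res$R_a, 4),
           ", R_x=", signif(R_x, 4), ", R_s=", signif(res$R_s, 4), ")")
    }
    wa <- 1 / res$R_a
    wc <- if (is.finite(R_x)) 1 / R_x else 0
    ws <- 1 / res$R_s
    T_AC <- (Ta * wa + Tc * wc + Ts * ws) / (wa + wc + ws)
    H_c <- if (is.finite(R_x)) rho * CP_AIR * (Tc - T_AC) / R_x else 0
    H_s <- rho * CP_AIR * (Ts - T_AC) / res$R_s
    H <- H_c + H_s
    L_new <- if (abs(H) < 1e-9) {
      1e6
    } else {
      -rho * CP_AIR * res$u_star^3 * c_to_k(Ta) /
        (VON_KARMAN * GRAVITY * H)
    }
    L_new <- sign(L_new) * min(abs(L_new), 1e6)
    if (it > 1 && abs(L_new - L_prev) < tol) {
      L <- L_new; converged <- TRUE; break
    }
    L_prev <- L_new
    # damped update stabilizes the strongly stable/unstable branches
    L <- if (is.finite(L)) 0.5 * L + 0.5 * L_new else L_new
  }
  if (!converged) flag <- add_flag(flag, "unconverged")

  H_c <- if (is.finite(R_x)) rho * CP_AIR * (Tc - T_AC) / R_x else 0
  H_s <- rho * CP_AIR * (Ts - T_AC) / res$R_s
  LE_s <- rn$Rn_s - G - H_s
  LE_c <- rn$Rn_c - H_c

  structure(list(
    Rn = rn$Rn, Rn_c = rn$Rn_c, Rn_s = rn$Rn_s, G = G,
    H = H_c + H_s, H_c = H_c, H_s = H_s,
    LE = LE_c + LE_s, LE_c = LE_c, LE_s = LE_s,
    T_AC = T_AC, L_MO = L, u_star = res$u_star,
    R_a = res$R_a, R_x = R_x, R_s = res$R_s,
    iterations = iterations, converged = converged, flag = flag
  ), class = "flux_state")
}
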