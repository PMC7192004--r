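test_that("longwave sources follow grey-body emission", {
  SB <- 5.670374419e-8
  # identical blackbodies emit identically
  cfg1 <- radiation_config(eps_c = 1, eps_s = 1)
  lw <- longwave_sources(20, 20, 20, ea = 1.4, cfg1)
  expect_equal(lw$L_s, lw$L_c)
  expect_equal(lw$L_s, SB * 293.15^4, tolerance = 1e-9)

  # soil at 310 K with emissivity 0.95
  lw2 <- longwave_sources(310 - 273.15, 25, 25, 1.4, radiation_config())
  expect_equal(lw2$L_s, 0.95 * SB * 310^4, tolerance = 1e-9)

  # cooler canopy emits less at equal emissivity
  lw3 <- longwave_sources(45, 32, 30, 1.4, cfg1)
  expect_lt(lw3$L_c, lw3$L_s)
  expect_error(longwave_sources(-150, 20, 20, 1.4), "nonphysical")
})

test_that("longwave partitioning matches its closed forms and limits", {
  cfg <- radiation_config(k_L = 0.95, omega = 1)
  # LAI = 0: no canopy interception
  p0 <- partition_longwave(0, cfg, L_sky = 300, L_s = 450, L_c = 430)
  expect_equal(p0$Ln_c, 0, tolerance = 1e-9)
  expect_equal(p0$Ln_s, 300 - 450, tolerance = 1e-9)

  # LAI -> infinity: full interception
  pinf <- partition_longwave(1e6, cfg, 300, 450, 430)
  expect_equal(pinf$Ln_c, 300 + 450 - 2 * 430, tolerance = 1e-9)
  expect_equal(pinf$Ln_s, 430 - 450, tolerance = 1e-9)

  # worked mid-range case, direct substitution
  p1 <- partition_longwave(1, cfg, 300, 450, 430)
  ext <- exp(-0.95)
  expect_equal(p1$Ln_c, (1 - ext) * (300 + 450 - 2 * 430), tolerance = 1e-12)
  expect_equal(p1$Ln_s, ext * 300 + (1 - ext) * 430 - 450, tolerance = 1e-12)
  expect_equal(p1$Ln_c, -67.47, tolerance = 1e-3)
  expect_equal(p1$Ln_s, -70.28, tolerance = 1e-3)
})

test_that("solar transmittance is 1 at zero LAI and decreases monotonically", {
  expect_equal(solar_transmittance(0), 1)
  lai <- seq(0, 6, by = 0.25)
  tau <- solar_transmittance(lai, omega = 1, solar_zenith = 30)
  expect_true(all(diff(tau) < 0))
  expect_true(all(tau >= 0 & tau <= 1))
  # nadir sun, spherical leaves: K_be(0) ~ 0.5
  kbe0 <- 1 / (1 + 1.774 * (1 + 1.182)^(-0.733))
  expect_equal(solar_transmittance(2, 1, 0), exp(-kbe0 * 2), tolerance = 1e-12)
  expect_equal(kbe0, 0.5, tolerance = 0.01)
  expect_error(solar_transmittance(1, 1, 95), "zenith")
})

test_that("net radiation splits shortwave by transmittance and always sums", {
  cfg <- radiation_config(alpha_c = 0.2, alpha_s = 0.15)
  r0 <- net_radiation(-67.5, -70.3, tau_s = 0.4, S = 0, cfg)
  expect_equal(r0$Rn_c, -67.5); expect_equal(r0$Rn_s, -70.3)

  r1 <- net_radiation(-67.5, -70.3, tau_s = 1, S = 800, cfg)
  expect_equal(r1$Rn_c, -67.5)  # fully transparent canopy absorbs nothing

  r2 <- net_radiation(-67.5, -70.3, tau_s = 0.4, S = 800, cfg)
  expect_equal(r2$Rn_c, -67.5 + 0.6 * 0.8 * 800, tolerance = 1e-12)  # 316.5
  expect_equal(r2$Rn_s, -70.3 + 0.4 * 0.85 * 800, tolerance = 1e-12)
  expect_identical(r2$Rn, r2$Rn_c + r2$Rn_s)
})

test_that("soil heat flux is the configured fraction of soil net radiation", {
  expect_equal(soil_heat_flux(200), 60)
  expect_equal(soil_heat_flux(200, 0), 0)
  expect_equal(soil_heat_flux(-50), -15)  # nighttime passes through
})

test_that("canopy boundary resistance scales as printed", {
  expect_equal(canopy_boundary_resistance(2, 0.1, 1), 45 * sqrt(0.1),
               tolerance = 1e-12)   # ~14.23 s/m
  r1 <- canopy_boundary_resistance(1, 0.1, 1)
  expect_equal(canopy_boundary_resistance(2, 0.1, 1), r1 / 2)  # 1/LAI
  expect_equal(canopy_boundary_resistance(1, 0.1, 4), r1 / 2)  # sqrt(U)
  expect_true(is.infinite(canopy_boundary_resistance(0, 0.1, 1)))
})

test_that("aerodynamic resistances obey the neutral log-profile limits", {
  res <- aero_resistances(u = 2, z_u = 5, z_T = 5, h_c = 2.2, LAI = 1.5)
  expect_equal(res$d0, 0.65 * 2.2)    # 1.43
  expect_equal(res$z0M, 0.125 * 2.2)  # 0.275
  k <- 0.41
  expect_equal(res$u_star, k * 2 / log((5 - 1.43) / 0.275), tolerance = 1e-9)
  expect_equal(res$R_a, log((5 - 1.43) / 0.275) / (k * res$u_star),
               tolerance = 1e-9)

  # neutral R_a halves when wind doubles
  res2 <- aero_resistances(4, 5, 5, 2.2, 1.5)
  expect_equal(res2$R_a, res$R_a / 2, tolerance = 1e-9)

  # large |L| converges to the neutral form
  resL <- aero_resistances(2, 5, 5, 2.2, 1.5, L_MO = 1e9)
  expect_equal(resL$R_a, res$R_a, tolerance = 1e-6)

  low <- aero_resistances(0.2, 5, 5, 2.2, 1.5)
  expect_equal(low$flag, "wind_floored")
  expect_error(aero_resistances(2, 2, 2, 2.2, 1.5), "exceed")
})

test_that("zero thermal gradient yields zero sensible heat", {
  fs <- solve_fluxes(25, 25, 25, u = 2, S = 600, ea = 1.4, p = 101.3,
                     LAI = 2, h_c = 2.2)
  expect_equal(fs$H, 0, tolerance = 1e-9)
  expect_equal(fs$LE, fs$Rn - fs$G, tolerance = 1e-9)
  expect_true(fs$converged)
})

test_that("component energy balances close exactly by construction", {
  fs <- solve_fluxes(42.5, 33.75, 30, u = 2, S = 800, ea = 1.5,
                     p = 101.3, LAI = 1.5, h_c = 2.2)
  expect_true(fs$converged)
  expect_lt(fs$iterations, 100)
  expect_gt(fs$H, 0)
  expect_lt(abs(fs$Rn_s - fs$G - fs$H_s - fs$LE_s), 1e-6)
  expect_lt(abs(fs$Rn_c - fs$H_c - fs$LE_c), 1e-6)
  expect_equal(fs$H, fs$H_c + fs$H_s)
  expect_equal(fs$LE, fs$LE_c + fs$LE_s)
})

test_that("vanishing canopy degenerates to a one-source soil balance", {
  fs <- solve_fluxes(45, 30, 30, u = 2, S = 800, ea = 1.5, p = 101.3,
                     LAI = 0, h_c = 2.2)
  expect_equal(fs$H_c, 0)
  expect_equal(fs$LE_c, 0, tolerance = 1e-9)
  expect_equal(fs$Rn_c, 0, tolerance = 1e-9)
  expect_equal(fs$Rn, fs$Rn_s)
})

test_that("soil sensible heat grows with soil-air contrast at fixed resistances", {
  # fixed-resistance inner step: T_AC and H_s from the series network
  R_a <- 30; R_x <- 20; R_s <- 80
  Ta <- 30; Tc <- 33
  hs <- sapply(seq(0, 15, by = 3), function(dT) {
    Ts <- Ta + dT
    wa <- 1 / R_a; wc <- 1 / R_x; ws <- 1 / R_s
    T_AC <- (Ta * wa + Tc * wc + Ts * ws) / (wa + wc + ws)
    (Ts - T_AC) / R_s
  })
  expect_true(all(diff(hs) > 0))
})

test_that("the flux solution is deterministic", {
  a <- solve_fluxes(44, 31, 28, 3, 750, 1.2, 100.5, 2.1, 2.0)
  b <- solve_fluxes(44, 31, 28, 3, 750, 1.2, 100.5, 2.1, 2.0)
  expect_identical(unclass(a), unclass(b))
})
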