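test_that("scene generation is a pure function of config and seed", {
  g <- small_grid(2)
  cfg <- scene_config(seed = 5, gap_fraction = 0.2)
  s1 <- generate_scene(cfg, g)
  s2 <- generate_scene(cfg, g)
  expect_identical(s1$points, s2$points)
  expect_identical(s1$ground, s2$ground)
  expect_identical(s1$rasters$Tr$values, s2$rasters$Tr$values)
  expect_identical(s1$truth, s2$truth)

  s3 <- generate_scene(scene_config(seed = 6, gap_fraction = 0.2), g)
  expect_false(identical(s1$points, s3$points))
})

test_that("analytic truth follows box geometry", {
  # single 1.0 m strip fully crossing a 3.6 m cell: row spacing 7.2 puts
  # the k=0 row centre at 3.6, i.e. through the middle of cell [0,7.2)^2's
  # lower-left quadrant boundary; use a cell straddling it
  cfg <- scene_config(row_spacing = 7.2, canopy_width = 1, vine_height = 2.2,
                      cover_fraction = 0)
  layout <- scene_layout(cfg, c(0, 0, 7.2, 7.2))
  cell <- list(x0 = 0, y0 = 1.8, x1 = 3.6, y1 = 5.4)  # strip centred inside
  tr <- analytic_cell_truth(cfg, cell, layout)
  expect_equal(tr$Volume_vc, 1.0 * 3.6 * 2.2, tolerance = 1e-12)
  expect_equal(tr$Area_vc, 3.6, tolerance = 1e-12)
  expect_equal(tr$f_c, 3.6 / 12.96, tolerance = 1e-12)
  expect_equal(tr$h_vc, 2.2)

  # empty cell: all vine metrics zero
  cell0 <- list(x0 = 0, y0 = 4.5, x1 = 3.6, y1 = 5.4)
  tr0 <- analytic_cell_truth(cfg, cell0, layout)
  expect_equal(tr0$Volume_vc, 0)
  expect_equal(tr0$f_c, 0)

  # slope invariance: heights are relative, so truth is unchanged
  cfgS <- scene_config(row_spacing = 7.2, canopy_width = 1,
                       cover_fraction = 0, terrain_slope = 0.1)
  layoutS <- scene_layout(cfgS, c(0, 0, 7.2, 7.2))
  trS <- analytic_cell_truth(cfgS, cell, layoutS)
  expect_equal(trS$Volume_vc, tr$Volume_vc)
  expect_equal(trS$h_vc, tr$h_vc)
})

test_that("truth invariants hold across random configurations", {
  g <- small_grid()
  for (seed in 1:3) {
    cfg <- scene_config(seed = seed, gap_fraction = 0.3,
                        cover_fraction = 0.6)
    scn <- generate_scene(cfg, g)
    tr <- scn$truth
    expect_true(all(tr$Area_vc <= 12.96 + 1e-9))
    expect_true(all(tr$Area_v <= 12.96 + 1e-9))
    expect_true(all(tr$Volume_vc >= 0 & tr$Volume_v >= 0))
    expect_true(all(tr$f_c >= 0 & tr$f_c <= 1))
    expect_equal(tr$f_c, tr$Area_vc / 12.96, tolerance = 1e-12)
  }
})

test_that("generated rasters carry the expected NDVI endmembers", {
  scn <- small_scene()
  nd <- ndvi(as.vector(scn$rasters$N$values), as.vector(scn$rasters$R$values))
  # bimodal: soil ~0.11, vegetation ~0.82
  expect_gt(mean(nd > 0.6), 0.2)
  expect_gt(mean(nd < 0.3), 0.4)
  expect_equal(median(nd[nd > 0.6]), scene_ndvi_veg(), tolerance = 0.05)
  expect_equal(median(nd[nd < 0.3]), scene_ndvi_soil(), tolerance = 0.05)
  # thermal pixels span Tc..Ts
  trv <- as.vector(scn$rasters$Tr$values)
  expect_lt(min(trv), 33)
  expect_gt(max(trv), 43.5)
})

test_that("LiDAR ground points lie exactly on the terrain", {
  g <- small_grid(2)
  cfg <- scene_config(seed = 3, terrain_slope = 0.08, terrain_z0 = 50)
  scn <- generate_scene(cfg, g)
  expect_equal(scn$ground$z, 50 + 0.08 * scn$ground$x, tolerance = 1e-12)
})

test_that("forcing is plausible, clamped and reproducible", {
  f1 <- generate_forcing(48, seed = 4)
  f2 <- generate_forcing(48, seed = 4)
  expect_identical(f1, f2)
  expect_true(all(f1$u >= 0.5))
  expect_true(all(f1$S >= 0))
  expect_true(all(f1$Ta > -10 & f1$Ta < 45))
  expect_gt(f1$S[f1$hour == 12][1], 500)   # noon sun
  expect_equal(f1$S[f1$hour == 0][1], 0)   # midnight dark
})

test_that("simulated LAI observations recover their generating model", {
  # gaps + partial cover decouple vine volume from vegetation area
  # (in pure box truth Volume_vc is proportional to Area_vc)
  scn <- generate_scene(scene_config(seed = 31, gap_fraction = 0.3,
                                     cover_fraction = 0.6), small_grid())
  coefs <- c("(Intercept)" = 0.4, Volume_vc = 2.5, Area_v = 1.2)
  obs <- generate_lai_observations(scn$truth, coefs, noise_sd = 0,
                                   seed = 9)
  fit <- refit_linear(obs[c("Volume_vc", "Area_v")], obs$LAI,
                      c("Volume_vc", "Area_v"))
  expect_equal(unname(fit$coefficients), unname(coefs), tolerance = 1e-10)
  expect_true(all(!obs$censored))
})
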