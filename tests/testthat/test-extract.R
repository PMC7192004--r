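test_that("NDVI follows its definition with the undefined-denominator contract", {
  expect_equal(ndvi(0.3, 0.3), 0)
  expect_equal(ndvi(0.5, 0.1), 2 / 3, tolerance = 1e-12)
  expect_true(is.na(ndvi(0, 0)))
  expect_error(ndvi(-0.1, 0.2), "non-negative")
  expect_equal(ndvi(c(0.5, 0.25), c(0.05, 0.2)),
               c(0.45 / 0.55, 0.05 / 0.45), tolerance = 1e-12)
})

test_that("spectral attribution picks the containing pixel, with tie and nodata rules", {
  vals <- matrix(1:12, nrow = 3, ncol = 4, byrow = TRUE)  # row 1 = top
  r <- band_raster(vals, xll = 0, yll = 0, cellsize = 1)
  st <- structure(list(Tr = r), class = "raster_stack")

  # pixel centres: e.g. (0.5, 2.5) is row 1, col 1 -> value 1
  a <- attribute_point_spectra(data.frame(x = 0.5, y = 2.5), st)
  expect_equal(a$Tr, 1)
  a2 <- attribute_point_spectra(data.frame(x = 3.5, y = 0.5), st)
  expect_equal(a2$Tr, 12)

  # boundary point equidistant from two pixels: lower column index wins
  t1 <- attribute_point_spectra(data.frame(x = 1, y = 2.5), st)
  expect_equal(t1$Tr, 1)
  # equidistant rows: lower row index (upper pixel) wins
  t2 <- attribute_point_spectra(data.frame(x = 0.5, y = 2), st)
  expect_equal(t2$Tr, 1)

  # nodata pixel falls back to nearest valid neighbour within radius
  vals_na <- vals; vals_na[1, 1] <- NA
  rna <- band_raster(vals_na, 0, 0, 1)
  stna <- structure(list(Tr = rna), class = "raster_stack")
  f <- attribute_point_spectra(data.frame(x = 0.6, y = 2.6), stna,
                               search_radius = 1.5)
  expect_equal(f$Tr, 2)  # nearest valid is the pixel to the right
  f2 <- attribute_point_spectra(data.frame(x = 0.4, y = 2.6), stna,
                                search_radius = 0.2)
  expect_true(is.na(f2$Tr))
  expect_true(canopyflux:::has_flag(f2$flags, "no_Tr"))
})

test_that("coarse thermal pixels are shared by all points beneath them", {
  # 60 cm Tr over 10 cm optical: one Tr value for the ~36 points under it
  tr <- band_raster(matrix(c(30, 40, 50, 60), 2, 2, byrow = TRUE), 0, 0, 0.6)
  st <- structure(list(Tr = tr), class = "raster_stack")
  xs <- rep(seq(0.05, 0.55, by = 0.1), times = 6)
  ys <- rep(seq(0.65, 1.15, by = 0.1), each = 6)
  a <- attribute_point_spectra(data.frame(x = xs, y = ys), st)
  expect_equal(length(unique(a$Tr)), 1)
  expect_equal(unique(a$Tr), 30)
  expect_equal(nrow(a), 36)
})

test_that("ground reference mode I applies the NDVI-minimum rule with fallback", {
  cp <- data.frame(x = c(0, 1), y = c(0, 0), z = c(10.0, 12.1),
                   NDVI = c(0.2, 0.8))
  out <- assign_ground_reference(cp, mode = "I", ndvi_threshold = 0.6)
  expect_equal(out$rel_height, c(0, 2.1))
  expect_equal(attr(out, "cell_flag"), "")

  # all vegetation: fall back to min z over all points, flagged
  cp2 <- data.frame(x = c(0, 1), y = c(0, 0), z = c(11, 12),
                    NDVI = c(0.7, 0.9))
  out2 <- assign_ground_reference(cp2, mode = "I")
  expect_equal(out2$rel_height, c(0, 1))
  expect_equal(attr(out2, "cell_flag"), "ground_fallback")

  # no spectral data at all: same fallback
  cp3 <- data.frame(x = 0:1, y = c(0, 0), z = c(5, 7))
  out3 <- assign_ground_reference(cp3, mode = "I")
  expect_equal(out3$rel_height, c(0, 2))
  expect_equal(attr(out3, "cell_flag"), "ground_fallback")
})

test_that("mode II honours slope where mode I cannot", {
  # 10% slope; two canopy points at equal height above local ground
  gp <- data.frame(x = seq(0, 10, by = 0.25), y = 0)
  gp$z <- 100 + 0.1 * gp$x
  cp <- data.frame(x = c(1, 9), y = c(0.01, 0.01),
                   z = 100 + 0.1 * c(1, 9) + 2.2,
                   NDVI = c(0.8, 0.8))
  outII <- assign_ground_reference(cp, mode = "II", ground_points = gp)
  expect_equal(outII$rel_height, c(2.2, 2.2), tolerance = 1e-9)

  cpI <- rbind(cp, data.frame(x = 0, y = 0, z = 100, NDVI = 0.1))
  outI <- assign_ground_reference(cpI, mode = "I")
  expect_equal(outI$rel_height[1:2], c(2.3, 3.1), tolerance = 1e-9)

  expect_error(assign_ground_reference(cp, mode = "II"), "ground_points")
  expect_error(assign_ground_reference(cp[0, ], mode = "I"), "empty")
})

test_that("below-ground artifacts are floored at zero and flagged", {
  gp <- data.frame(x = 0:10, y = 0, z = 100)
  cp <- data.frame(x = c(1, 2), y = c(0, 0), z = c(99.9, 100.005))
  out <- assign_ground_reference(cp, mode = "II", ground_points = gp)
  expect_equal(out$rel_height, c(0, 0.005))
  expect_true(canopyflux:::has_flag(out$flags[1], "below_ground"))
  expect_false(canopyflux:::has_flag(out$flags[2], "below_ground"))
})

test_that("classification thresholds split ground, cover crop and vine as documented", {
  rec <- data.frame(NDVI = c(0.8, 0.8, 0.55, 0.8, NA),
                    rel_height = c(0.49, 0.50, 3.0, 2.0, 1.0))
  cls <- classify_points(rec, extraction_config())$class
  expect_equal(as.character(cls),
               c("cover_crop", "vine", "ground", "vine", "ground"))
})

test_that("vine-only cells give identical vegetation and vine metrics", {
  set.seed(21)
  n <- 80
  rec <- data.frame(x = runif(n, 0, 2), y = runif(n, 0, 2),
                    z = 102.2, rel_height = 2.2,
                    NDVI = 0.8, N = 0.5, R = 0.05, Tr = 32)
  rec <- classify_points(rec, extraction_config())
  s <- summarize_cell(rec, cell_area = 4, cell_id = 1L)
  expect_equal(s$Volume_v, s$Volume_vc, tolerance = 1e-9)
  expect_equal(s$SArea_v, s$SArea_vc, tolerance = 1e-9)
  expect_equal(s$Area_v, s$Area_vc, tolerance = 1e-9)
  expect_equal(s$h_v, s$h_vc)
  expect_equal(s$n_veg, s$n_vine)
})

test_that("adding pure-ground points never changes vine-class metrics", {
  set.seed(31)
  n <- 60
  vine <- data.frame(x = runif(n, 0, 2), y = runif(n, 0, 2),
                     z = 102.2, rel_height = 2.2, NDVI = 0.8)
  ground <- data.frame(x = runif(40, 0, 2), y = runif(40, 0, 2),
                       z = 100, rel_height = 0, NDVI = 0.1)
  s1 <- summarize_cell(classify_points(vine, extraction_config()),
                       cell_area = 4, cell_id = 1L)
  s2 <- summarize_cell(classify_points(rbind(vine, ground), extraction_config()),
                       cell_area = 4, cell_id = 1L)
  expect_equal(s2$Volume_vc, s1$Volume_vc)
  expect_equal(s2$SArea_vc, s1$SArea_vc)
  expect_equal(s2$Area_vc, s1$Area_vc)
  expect_equal(s2$h_vc, s1$h_vc)
})

test_that("run_extraction preserves the grid shape and flags empty cells", {
  scn <- small_scene()
  g <- small_grid()
  cells <- run_extraction(scn$points, scn$rasters, g,
                          fixed_thresh_config(mode = "II"),
                          ground = scn$ground)
  expect_equal(nrow(cells), 9)
  expect_equal(cells$id, 1:9)
  expect_true(all(cells$f_c >= 0 & cells$f_c <= 1))
  expect_equal(cells$w_c, 3.35 * cells$f_c, tolerance = 1e-12)
  expect_true(all(cells$SArea_v >= cells$Area_v - 1e-9))
  expect_true(all(cells$SArea_vc >= cells$Area_vc - 1e-9))

  # a cloud that misses one cell entirely still yields a row for it
  keep <- scn$points$x >= 3.6 | scn$points$y >= 3.6
  cells2 <- run_extraction(scn$points[keep, ], scn$rasters, g,
                           fixed_thresh_config(mode = "II"),
                           ground = scn$ground)
  expect_equal(nrow(cells2), 9)
  expect_true(canopyflux:::has_flag(cells2$flags[1], "empty_cell"))
  expect_error(run_extraction(scn$points, scn$rasters, g,
                              fixed_thresh_config(mode = "II")),
               "ground")
})
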