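# Shared fixture builders.  Small scenes are built on demand and cached
# for the session so several test files can reuse them cheaply.

.scene_cache <- new.env(parent = emptyenv())

small_grid <- function(n = 3, cell = 3.6) {
  make_grid(c(0, 0, n * cell, n * cell), cell)
}

cached_scene <- function(key, cfg, grid) {
  if (is.null(.scene_cache[[key]])) {
    .scene_cache[[key]] <- generate_scene(cfg, grid)
  }
  .scene_cache[[key]]
}

# default small flat scene, bare inter-row (mowed cover crop)
small_scene <- function() {
  cached_scene("small", scene_config(seed = 42, cover_fraction = 0),
               small_grid())
}

fixed_thresh_config <- function(...) {
  extraction_config(temp_method = "fixed", ndvi_s = 0.111, ndvi_c = 0.818, ...)
}

# NDVI endmembers implied by the default scene reflectances
scene_ndvi_soil <- function(cfg = scene_config()) {
  (cfg$soil_refl[["N"]] - cfg$soil_refl[["R"]]) /
    (cfg$soil_refl[["N"]] + cfg$soil_refl[["R"]])
}
scene_ndvi_veg <- function(cfg = scene_config()) {
  (cfg$veg_refl[["N"]] - cfg$veg_refl[["R"]]) /
    (cfg$veg_refl[["N"]] + cfg$veg_refl[["R"]])
}

# midpoint-rule double integral of f(x, y) over c(x0, y0, x1, y1)
integrate_plane_rect <- function(rect, f, n = 200) {
  xs <- seq(rect[1], rect[3], length.out = n + 1)
  ys <- seq(rect[2], rect[4], length.out = n + 1)
  mx <- (xs[-1] + xs[-(n + 1)]) / 2
  my <- (ys[-1] + ys[-(n + 1)]) / 2
  dx <- diff(xs)[1]; dy <- diff(ys)[1]
  sum(outer(mx, my, f)) * dx * dy
}
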