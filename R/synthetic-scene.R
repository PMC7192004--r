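#' Parametric synthetic vineyard scene description
#'
#' Describes a trellised vineyard the way the emulated acquisition looks
#' from above: parallel canopy strips (box cross-section) along east-west
#' rows 3.35 m apart, vine tops near 2.2 m with an open trellis space
#' below ~0.7 m, an optional inter-row cover crop under 0.5 m, and a
#' photogrammetric point density of order 40-120 points/m^2.  Soil is
#' warmer than the canopy, and vegetation/soil reflectances give the
#' familiar bimodal NDVI field (~0.82 vs ~0.11).
#'
#' The configuration plus a seed fully determine a scene: vine presence
#' along each row is drawn per 1.5 m vine slot (so `gap_fraction` > 0
#' punches missing-vine gaps into the strips), and the cover crop is
#' drawn per 0.5 m patch with probability `cover_fraction`.
#'
#' @param row_spacing distance between vine rows (m).
#' @param vine_height canopy top height above local ground (m).
#' @param canopy_base height of the open space under the canopy crown (m);
#'   kept for the ellipsoid option and scene documentation (the sampled
#'   envelope is the canopy top, which nadir photogrammetry sees).
#' @param canopy_width across-row width of the canopy strip (m).
#' @param row_orientation degrees from east-west; only 0 (rows along x)
#'   is generated, other values are rejected for now.
#' @param cover_height cover crop height (m), must stay below the 0.5 m
#'   vine/cover classification threshold.
#' @param cover_fraction probability a 0.5 m inter-row patch carries
#'   cover crop.
#' @param gap_fraction probability a 1.5 m vine slot is missing.
#' @param gap_cover whether missing-vine gaps carry cover crop (light
#'   reaching the gap floor favours regrowth there even when the
#'   inter-row is mowed bare).
#' @param point_density photogrammetric points per m^2.
#' @param lidar_density ground (LiDAR-like) points per m^2.
#' @param terrain_slope ground slope (rise per metre, along +x).
#' @param terrain_z0 ground elevation at x = 0 (m).
#' @param sd_z vertical noise of photogrammetric points (m).
#' @param veg_refl,soil_refl named reflectance means for `R`,`G`,`B`,`N`.
#' @param sd_refl reflectance noise sd per band.
#' @param Ts_mean,Tc_mean soil and canopy radiometric temperature (deg C);
#'   `Ts_mean >= Tc_mean`.
#' @param sd_tr thermal noise sd (deg C).
#' @param optical_res,thermal_res raster resolutions (m).
#' @param seed integer; scene generation is a pure function of
#'   (config, seed).
#' @return a `scene_config` list.
#' @export
scene_config <- function(row_spacing = 3.35,
                         vine_height = 2.2,
                         canopy_base = 0.7,
                         canopy_width = 1.0,
                         row_orientation = 0,
                         cover_height = 0.15,
                         cover_fraction = 1.0,
                         gap_fraction = 0,
                         gap_cover = TRUE,
                         point_density = 100,
                         lidar_density = 4,
                         terrain_slope = 0,
                         terrain_z0 = 100,
                         sd_z = 0.01,
                         veg_refl = c(R = 0.05, G = 0.08, B = 0.04, N = 0.5),
                         soil_refl = c(R = 0.2, G = 0.18, B = 0.15, N = 0.25),
                         sd_refl = 0.01,
                         Ts_mean = 45,
                         Tc_mean = 32,
                         sd_tr = 0.3,
                         optical_res = 0.1,
                         thermal_res = 0.6,
                         seed = 1L) {
  stopifnot(cover_height < 0.5, vine_height > 0.5,
            point_density > 0, lidar_density > 0,
            Ts_mean >= Tc_mean, canopy_width > 0,
            row_spacing > canopy_width)
  if (row_orientation != 0) {
    stop("only east-west rows (row_orientation = 0) are generated")
  }
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  class(cfg) <- "scene_config"
  cfg
}

VINE_SLOT_LEN <- 1.5   # vine spacing along the row (m)
COVER_PATCH <- 0.5     # cover-crop patch pitch (m)

terrain_z <- function(cfg, x) cfg$terrain_z0 + cfg$terrain_slope * x

#' Deterministic scene layout (rows, vine slots, cover patches)
#'
#' Row centre lines sit at `(k + 0.5) * row_spacing`; vine slots are
#' 1.5 m bins along x, cover patches 0.5 m bins in x and y.  Presence
#' draws are made once, in index order, from the scene seed, so the
#' layout is a pure function of (config, bounds).
#'
#' @param cfg a [scene_config()].
#' @param bounds `c(xmin, ymin, xmax, ymax)` of the scene.
#' @return list with row positions, slot presence matrix, cover patch
#'   presence matrix and the index offsets needed to query them.
#' @export
scene_layout <- function(cfg, bounds) {
  rs <- cfg$row_spacing
  k0 <- floor(bounds[2] / rs - 0.5); k1 <- ceiling(bounds[4] / rs)
  ks <- k0:k1
  y_rows <- (ks + 0.5) * rs
  inb <- y_rows + cfg$canopy_width / 2 > bounds[2] &
         y_rows - cfg$canopy_width / 2 < bounds[4]
  ks <- ks[inb]; y_rows <- y_rows[inb]

  s0 <- floor(bounds[1] / VINE_SLOT_LEN); s1 <- ceiling(bounds[3] / VINE_SLOT_LEN)
  ss <- s0:(s1 - 1L)

  p0 <- floor(bounds[1] / COVER_PATCH); p1 <- ceiling(bounds[3] / COVER_PATCH)
  q0 <- floor(bounds[2] / COVER_PATCH); q1 <- ceiling(bounds[4] / COVER_PATCH)

  withr_seed <- function(s, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(s)
    expr
  }
  slot_present <- withr_seed(cfg$seed + 101L,
    matrix(stats::runif(length(ks) * length(ss)) >= cfg$gap_fraction,
           nrow = length(ks), ncol = length(ss)))
  cover_present <- withr_seed(cfg$seed + 202L,
    matrix(stats::runif((p1 - p0) * (q1 - q0)) < cfg$cover_fraction,
           nrow = q1 - q0, ncol = p1 - p0))

  list(bounds = bounds, ks = ks, y_rows = y_rows,
       slot_s0 = ss[1], slot_present = slot_present,
       patch_p0 = p0, patch_q0 = q0, cover_present = cover_present)
}

# vine-canopy membership of planimetric positions
in_canopy <- function(layout, cfg, x, y) {
  out <- logical(length(x))
  si <- floor(x / VINE_SLOT_LEN) - layout$slot_s0 + 1L
  ok_s <- si >= 1L & si <= ncol(layout$slot_present)
  for (r in seq_along(layout$y_rows)) {
    near <- abs(y - layout$y_rows[r]) <= cfg$canopy_width / 2
    idx <- which(near & ok_s)
    if (length(idx)) out[idx] <- out[idx] | layout$slot_present[r, si[idx]]
  }
  out
}

# gap membership: inside a strip's y-band but over an absent vine slot
in_gap <- function(layout, cfg, x, y) {
  out <- logical(length(x))
  si <- floor(x / VINE_SLOT_LEN) - layout$slot_s0 + 1L
  ok_s <- si >= 1L & si <= ncol(layout$slot_present)
  for (r in seq_along(layout$y_rows)) {
    near <- abs(y - layout$y_rows[r]) <= cfg$canopy_width / 2
    idx <- which(near & ok_s)
    if (length(idx)) out[idx] <- out[idx] | !layout$slot_present[r, si[idx]]
  }
  out
}

in_cover <- function(layout, x, y) {
  pi <- floor(x / COVER_PATCH) - layout$patch_p0 + 1L
  qi <- floor(y / COVER_PATCH) - layout$patch_q0 + 1L
  ok <- pi >= 1L & pi <= ncol(layout$cover_present) &
        qi >= 1L & qi <= nrow(layout$cover_present)
  out <- logical(length(x))
  out[ok] <- layout$cover_present[cbind(qi[ok], pi[ok])]
  out
}

#' Analytic per-cell truth for a box-canopy scene
#'
#' Closed-form footprint area, top-surface area, volume and mean height
#' of the vine canopy in one grid cell, from the rectangle geometry of
#' the present vine slots.  Heights are relative to local ground, so the
#' truth is invariant to terrain slope.  Vegetation-class truth adds the
#' idealized cover-crop contribution (no transition walls), which is the
#' zero-wall limit the TIN approaches as point density grows.
#'
#' @param cfg a [scene_config()].
#' @param cell one row of a [make_grid()] grid (list/data.frame with
#'   `x0`, `y0`, `x1`, `y1`).
#' @param layout a [scene_layout()]; must cover the cell.
#' @return list of class `cell_truth`.
#' @export
analytic_cell_truth <- function(cfg, cell, layout) {
  cell_area <- (cell$x1 - cell$x0) * (cell$y1 - cell$y0)
  hw <- cfg$canopy_width / 2

  area_vc <- 0
  for (r in seq_along(layout$y_rows)) {
    wy <- min(cell$y1, layout$y_rows[r] + hw) -
          max(cell$y0, layout$y_rows[r] - hw)
    if (wy <= 0) next
    si_lo <- floor(cell$x0 / VINE_SLOT_LEN)
    si_hi <- ceiling(cell$x1 / VINE_SLOT_LEN) - 1L
    for (s in si_lo:si_hi) {
      ci <- s - layout$slot_s0 + 1L
      if (ci < 1L || ci > ncol(layout$slot_present)) next
      if (!layout$slot_present[r, ci]) next
      lx <- min(cell$x1, (s + 1) * VINE_SLOT_LEN) -
            max(cell$x0, s * VINE_SLOT_LEN)
      if (lx > 0) area_vc <- area_vc + wy * lx
    }
  }

  # cover-crop area: patches outside the canopy strips
  area_cover <- 0
  pi_lo <- floor(cell$x0 / COVER_PATCH); pi_hi <- ceiling(cell$x1 / COVER_PATCH) - 1L
  qi_lo <- floor(cell$y0 / COVER_PATCH); qi_hi <- ceiling(cell$y1 / COVER_PATCH) - 1L
  for (q in qi_lo:qi_hi) {
    py0 <- max(cell$y0, q * COVER_PATCH); py1 <- min(cell$y1, (q + 1) * COVER_PATCH)
    if (py1 <= py0) next
    # fraction of this patch's y-range not under a canopy strip
    ylen <- py1 - py0
    strip_olap <- 0
    for (r in seq_along(layout$y_rows)) {
      o <- min(py1, layout$y_rows[r] + hw) - max(py0, layout$y_rows[r] - hw)
      if (o > 0) strip_olap <- strip_olap + o
    }
    open_frac <- max(0, (ylen - strip_olap) / ylen)
    for (p in pi_lo:pi_hi) {
      ci <- p - layout$patch_p0 + 1L; ri <- q - layout$patch_q0 + 1L
      if (ci < 1L || ci > ncol(layout$cover_present) ||
          ri < 1L || ri > nrow(layout$cover_present)) next
      if (!layout$cover_present[ri, ci]) next
      px0 <- max(cell$x0, p * COVER_PATCH); px1 <- min(cell$x1, (p + 1) * COVER_PATCH)
      if (px1 > px0) area_cover <- area_cover + (px1 - px0) * ylen * open_frac
    }
  }

  area_v <- area_vc + area_cover
  vol_vc <- area_vc * cfg$vine_height
  vol_v <- vol_vc + area_cover * cfg$cover_height
  h_v <- if (area_v > 0) {
    (area_vc * cfg$vine_height + area_cover * cfg$cover_height) / area_v
  } else 0

  structure(list(
    Volume_v = vol_v, SArea_v = area_v, Area_v = area_v, h_v = h_v,
    Volume_vc = vol_vc, SArea_vc = area_vc, Area_vc = area_vc,
    h_vc = if (area_vc > 0) cfg$vine_height else 0,
    f_c = area_vc / cell_area,
    Ts = cfg$Ts_mean, Tc = cfg$Tc_mean
  ), class = "cell_truth")
}

#' Generate a synthetic vineyard scene
#'
#' Samples the upper canopy envelope (nadir photogrammetry cannot see
#' beneath the canopy) at the configured density, densifies the canopy
#' boundary with breakline points (structure-from-motion clouds resolve
#' the sharp canopy edge), fills inter-rows with cover-crop/ground
#' points, lays LiDAR-like ground points on the true terrain, and
#' rasterizes reflectance and radiometric temperature at their native
#' resolutions.  The thermal band mixes soil and canopy temperature
#' linearly by the vegetated fraction seen at the optical subgrid of each
#' thermal pixel.
#'
#' @param cfg a [scene_config()].
#' @param grid a [make_grid()] grid defining the scene extent.
#' @return list with `points` (photogrammetric cloud, data.frame
#'   x/y/z), `ground` (LiDAR-like ground points), `rasters` (a
#'   `raster_stack` with bands R,G,B,N,Tr), `truth` (data.frame of
#'   per-cell analytic truth keyed by cell id), and `layout`.
#' @export
generate_scene <- function(cfg, grid) {
  bounds <- c(attr(grid, "origin"),
              attr(grid, "origin") + c(attr(grid, "nx"), attr(grid, "ny")) *
                attr(grid, "cell_size"))
  layout <- scene_layout(cfg, bounds)
  area <- (bounds[3] - bounds[1]) * (bounds[4] - bounds[2])

  set.seed(cfg$seed + 303L)
  n <- round(cfg$point_density * area)
  px <- stats::runif(n, bounds[1], bounds[3])
  py <- stats::runif(n, bounds[2], bounds[4])
  canopy <- in_canopy(layout, cfg, px, py)
  gapc <- cfg$gap_cover & !canopy & in_gap(layout, cfg, px, py)
  cover <- !canopy & (in_cover(layout, px, py) | gapc)
  hsurf <- ifelse(canopy, cfg$vine_height, ifelse(cover, cfg$cover_height, 0))
  pz <- terrain_z(cfg, px) + hsurf + stats::rnorm(n, 0, cfg$sd_z)

  bl <- canopy_breaklines(cfg, layout, bounds)
  if (nrow(bl)) {
    # +-2 mm planimetric jitter keeps the edge pinned while avoiding the
    # exactly-collinear vertex runs that degrade the triangulation
    bl$x <- bl$x + stats::runif(nrow(bl), -0.002, 0.002)
    bl$y <- bl$y + stats::runif(nrow(bl), -0.002, 0.002)
    bl$z <- terrain_z(cfg, bl$x) + cfg$vine_height +
      stats::rnorm(nrow(bl), 0, cfg$sd_z)
  }
  pts <- rbind(data.frame(x = px, y = py, z = pz),
               bl[, c("x", "y", "z")])

  set.seed(cfg$seed + 404L)
  ng <- round(cfg$lidar_density * area)
  gx <- stats::runif(ng, bounds[1], bounds[3])
  gy <- stats::runif(ng, bounds[2], bounds[4])
  ground <- data.frame(x = gx, y = gy, z = terrain_z(cfg, gx))

  rasters <- rasterize_scene(cfg, layout, bounds)

  truth <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    tr <- analytic_cell_truth(cfg, grid[i, ], layout)
    data.frame(id = grid$id[i], as.data.frame(unclass(tr)))
  }))

  list(points = pts, ground = ground, rasters = rasters,
       truth = truth, layout = layout)
}

# breakline points along canopy strip edges at ~half the mean ground
# sample spacing, pinning the canopy footprint boundary in the TIN
canopy_breaklines <- function(cfg, layout, bounds) {
  sp <- 0.5 / sqrt(cfg$point_density)
  hw <- cfg$canopy_width / 2
  xs <- list(); ys <- list()
  for (r in seq_along(layout$y_rows)) {
    yr <- layout$y_rows[r]
    present <- layout$slot_present[r, ]
    for (ci in which(present)) {
      s <- layout$slot_s0 + ci - 1L
      x0 <- max(bounds[1], s * VINE_SLOT_LEN)
      x1 <- min(bounds[3], (s + 1) * VINE_SLOT_LEN)
      if (x1 <= x0) next
      ex <- seq(x0, x1, by = sp)
      for (side in c(-1, 1)) {
        ye <- yr + side * hw
        if (ye >= bounds[2] && ye <= bounds[4]) {
          xs[[length(xs) + 1L]] <- ex
          ys[[length(ys) + 1L]] <- rep(ye, length(ex))
        }
      }
      # cross edges where the neighbouring slot is absent or off-scene
      for (end in c(0L, 1L)) {
        ni <- ci + if (end == 0L) -1L else 1L
        open_end <- ni < 1L || ni > length(present) || !present[ni]
        if (open_end) {
          xe <- if (end == 0L) x0 else x1
          ey <- seq(max(bounds[2], yr - hw), min(bounds[4], yr + hw), by = sp)
          xs[[length(xs) + 1L]] <- rep(xe, length(ey))
          ys[[length(ys) + 1L]] <- ey
        }
      }
    }
  }
  if (!length(xs)) return(data.frame(x = numeric(), y = numeric(),
                                     z = numeric()))
  data.frame(x = unlist(xs), y = unlist(ys), z = NA_real_)
}

rasterize_scene <- function(cfg, layout, bounds) {
  set.seed(cfg$seed + 505L)
  ores <- cfg$optical_res
  nxo <- round((bounds[3] - bounds[1]) / ores)
  nyo <- round((bounds[4] - bounds[2]) / ores)
  cx <- bounds[1] + (seq_len(nxo) - 0.5) * ores
  cy <- bounds[2] + (seq_len(nyo) - 0.5) * ores
  gx <- rep(cx, times = nyo)
  gy <- rep(cy, each = nxo)
  # canopy mask dilated by half a pixel: orthomosaic edge pixels are
  # vegetation-dominated (canopy overhang), so the spectral footprint is
  # never narrower than the geometric one
  dil <- ores / 2
  veg_canopy <- in_canopy(layout, cfg, gx, gy) |
    in_canopy(layout, cfg, gx, gy - dil) |
    in_canopy(layout, cfg, gx, gy + dil) |
    in_canopy(layout, cfg, gx - dil, gy) |
    in_canopy(layout, cfg, gx + dil, gy)
  gapc <- cfg$gap_cover & !veg_canopy & in_gap(layout, cfg, gx, gy)
  veg <- veg_canopy | in_cover(layout, gx, gy) | gapc

  stack <- list()
  for (b in c("R", "G", "B", "N")) {
    mu <- ifelse(veg, cfg$veg_refl[[b]], cfg$soil_refl[[b]])
    v <- pmin(1, pmax(0, mu + stats::rnorm(length(mu), 0, cfg$sd_refl)))
    m <- matrix(v, nrow = nyo, ncol = nxo, byrow = TRUE)   # row 1 = ymin
    m <- m[nyo:1, , drop = FALSE]                          # flip: row 1 = top
    stack[[b]] <- band_raster(m, bounds[1], bounds[2], ores)
  }

  # thermal: vegetated fraction of each coarse pixel from the optical
  # subgrid, mixed linearly between Ts and Tc
  tres <- cfg$thermal_res
  nxt <- round((bounds[3] - bounds[1]) / tres)
  nyt <- round((bounds[4] - bounds[2]) / tres)
  ti <- floor((gx - bounds[1]) / tres) + 1L
  tj <- floor((gy - bounds[2]) / tres) + 1L
  ti <- pmin(ti, nxt); tj <- pmin(tj, nyt)
  cellidx <- (tj - 1L) * nxt + ti
  fveg <- tapply(as.numeric(veg), cellidx, mean)
  fmap <- numeric(nxt * nyt)
  fmap[as.integer(names(fveg))] <- fveg
  trv <- cfg$Ts_mean + (cfg$Tc_mean - cfg$Ts_mean) * fmap +
    stats::rnorm(length(fmap), 0, cfg$sd_tr)
  mt <- matrix(trv, nrow = nyt, ncol = nxt, byrow = TRUE)
  mt <- mt[nyt:1, , drop = FALSE]
  stack$Tr <- band_raster(mt, bounds[1], bounds[2], tres)

  structure(stack, class = "raster_stack")
}

#' Generate hourly meteorological forcing
#'
#' Physically plausible clear-sky diurnal forcing: sinusoidal solar
#' radiation peaking near 900 W/m^2 at noon, air temperature lagging the
#' sun between ~12 and ~32 deg C, wind speed floored at 0.5 m/s, vapour
#' pressure around 1.4 kPa and near-sea-level pressure.
#'
#' @param n_hours number of hourly records (starting at hour 0).
#' @param seed RNG seed.
#' @return data.frame with `hour`, `Ta` (deg C), `u` (m/s), `S` (W/m^2),
#'   `ea` (kPa), `p` (kPa).
#' @export
generate_forcing <- function(n_hours, seed = 1L) {
  stopifnot(n_hours >= 1)
  set.seed(seed)
  hour <- (seq_len(n_hours) - 1L) %% 24L
  S <- pmax(0, 900 * sin(pi * (hour - 6) / 12)) *
    (hour >= 6 & hour <= 18)
  S <- pmax(0, S + stats::rnorm(n_hours, 0, 15) * (S > 0))
  Ta <- 22 + 10 * sin(pi * (hour - 9) / 12) + stats::rnorm(n_hours, 0, 0.5)
  Ta <- pmin(45, pmax(-10, Ta))
  u <- pmax(0.5, 2 + stats::rnorm(n_hours, 0, 0.8))
  ea <- pmax(0.4, 1.4 + stats::rnorm(n_hours, 0, 0.15))
  p <- 101.3 + stats::rnorm(n_hours, 0, 0.2)
  data.frame(hour = hour, Ta = Ta, u = u, S = S, ea = ea, p = p)
}

#' Simulate LAI observations over cells with a known linear model
#'
#' Builds LAI as a linear combination of area-normalized structural
#' metrics plus Gaussian noise; used to test coefficient recovery of
#' [refit_linear()].  Truth coefficients are attached as an attribute.
#'
#' @param cell_truths data.frame from [generate_scene()]`$truth` (or any
#'   table carrying the term columns).
#' @param coefficients named vector: intercept plus term names matching
#'   columns of the normalized inputs.
#' @param noise_sd Gaussian noise sd on LAI.
#' @param cell_area grid-cell area used for normalization (m^2).
#' @param seed RNG seed.
#' @return data.frame of normalized inputs plus `LAI`; negative simulated
#'   LAI values are kept but flagged in the `censored` column.
#' @export
generate_lai_observations <- function(cell_truths, coefficients,
                                      noise_sd = 0, cell_area = 12.96,
                                      seed = 1L) {
  terms <- setdiff(names(coefficients), "(Intercept)")
  stopifnot(all(terms %in% names(cell_truths)))
  X <- as.data.frame(lapply(cell_truths[terms], function(v) v / cell_area))
  set.seed(seed)
  lai <- coefficients[["(Intercept)"]] +
    as.matrix(X) %*% coefficients[terms] +
    stats::rnorm(nrow(X), 0, noise_sd)
  out <- cbind(X, LAI = as.numeric(lai))
  out$censored <- out$LAI < 0
  attr(out, "truth_coefficients") <- coefficients
  out
}
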