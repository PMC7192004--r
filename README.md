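# canopyflux

Per-cell canopy structure from photogrammetric point clouds of trellised
vineyards, and the two-source energy balance those metrics feed.

## The problem

Remote-sensing evapotranspiration models over vineyards need more than
spectral imagery: the two-source energy balance (TSEB) wants leaf area
index (LAI), fractional cover, canopy height and width per model cell,
and a vineyard with an inter-row cover crop defeats purely spectral
estimates because vine and grass look alike in NDVI. Structure-from-motion
point clouds from UAV flights carry that missing 3D information.
`canopyflux` implements the full chain for users working at the
3.6 m grid scale typical of tall-trellis vineyards:

1. **Structural/spectral extraction** — clip the cloud per grid cell,
   attribute each point with the nearest pixel of co-registered R, G, B,
   NIR and thermal rasters, normalize heights against a ground reference
   (mode I: per-cell minimum z of NDVI-classified ground points; mode II:
   nearest LiDAR ground point, slope-aware), classify ground / cover
   crop / vine at NDVI > 0.6 and a 0.5 m relative-height split, and
   integrate a TIN (Delaunay) surface per class into volume
   (Σ triangle area × mean vertex height), 3D surface area and projected
   area, plus fractional cover `f_c = Area_vc / cell area` and canopy
   width `w_c = 3.35 · f_c`.
2. **Component temperatures** — per cell, an ordinary least-squares line
   through the (NDVI, Tr) scatter of the thermal pixels; substituting a
   pure-soil and a pure-canopy NDVI threshold into the line gives soil
   and canopy temperatures (`Ts`, `Tc`), with the warmer endpoint
   assigned to soil.
3. **LAI models** — three published regression forms over the
   area-normalized metrics (spectral-only, structural-only, combined),
   held as configurable expressions, plus an OLS refit utility.
4. **TSEB-2T** — longwave partitioning
   `Ln_c = (1 − e^{−k_L Ω LAI})(L_sky + L_s − 2 L_c)`, Campbell–Norman
   beam transmittance, `Rn_c`/`Rn_s`, `G = 0.3 Rn_s`, series-resistance
   sensible heat (`R_a`, `R_x = (C/LAI)√(l_w/U)`, `R_s`) with
   Monin–Obukhov iteration to |ΔL| < 1e-5, and latent heat as the
   residual of each component balance.
5. **Evaluation** — Bowen-ratio energy-balance closure forcing
   (`H_BR = H/(H+LE)·(Rn−G−H−LE)+H`) and fit statistics (R², MAE, RMSE,
   RRMSE with the excellent/good/fair/poor rating scale).

A parametric synthetic-scene generator (vine rows 3.35 m apart, 2.2 m
box canopies, cover crop below 0.5 m, ~100 points/m², 10 cm optical /
60 cm thermal rasters, warm soil vs cool canopy) provides analytic
per-cell truth so the whole pipeline is testable without any field data.

## Worked example

```r
library(canopyflux)

grid  <- make_grid(c(0, 0, 36, 36), cell_size = 3.6)       # 10 x 10 cells
scene <- generate_scene(scene_config(seed = 17, cover_fraction = 0), grid)

cfg   <- extraction_config(mode = "II", max_tin_edge = 0.5,
                       temp_method = "fixed", ndvi_s = 0.11, ndvi_c = 0.82)
cells <- run_extraction(scene$points, scene$rasters, grid, cfg,
                        ground = scene$ground)

cells[1, c("Volume_vc", "Area_vc", "h_vc", "f_c", "Ts", "Tc")]
#>   Volume_vc  Area_vc     h_vc      f_c       Ts       Tc
#> 1  7.938889 3.609347 2.200008 0.278499 45.02644 31.84598
```

The first cell holds one full-width canopy strip: 3.6 m² of projected
vine area (fractional cover 0.278), 7.92 m³ of canopy volume, a 2.2 m
mean canopy height, and component temperatures within a few tenths of a
degree of the scene's 45 °C soil / 32 °C canopy truth. Feeding the cell
into the energy balance at a clear noon:

```r
fs <- solve_fluxes(Ts = cells$Ts[1], Tc = cells$Tc[1], Ta = 30, u = 2,
                   S = 800, ea = 1.5, p = 101.3,
                   LAI = 1.5, h_c = cells$h_vc[1])
round(unlist(fs[c("Rn", "G", "H", "LE", "iterations")]), 1)
#>         Rn          G          H         LE iterations
#>      545.4       57.7      137.6      350.0       16.0
```

Net radiation splits into soil and canopy parts, soil heat flux is 30%
of the soil's share, the Monin–Obukhov iteration converges in 16 passes,
and latent heat is the residual — both component balances close to
machine precision.

The end-to-end orchestration (simulate → extract → partition → lai →
tseb → evaluate) is `run_pipeline(run_config(...))`; a thin command-line
front end lives at `inst/cli/canopyflux.R`.

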