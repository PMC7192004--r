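#' Structural metrics from a triangulated irregular network
#'
#' Builds a 2D Delaunay triangulation over the point positions and treats
#' the (relative) heights as elevations of a piecewise-linear surface.
#' Three metrics are integrated over that surface:
#'
#' * **volume** between the TIN and the zero-height plane, computed per
#'   triangle as planimetric area times the mean of the three vertex
#'   heights — exact for a piecewise-linear surface;
#' * **surface_area**, the sum of 3D triangle areas;
#' * **projected_area**, the sum of planimetric triangle areas (the
#'   nadir-projected canopy footprint, basis of fractional cover).
#'
#' Duplicate planimetric positions are collapsed to the highest point
#' (photogrammetric clouds stack returns); triangles with any planimetric
#' edge longer than `max_edge` can be discarded to stop the triangulation
#' bridging real canopy gaps (off by default).  Fewer than `min_points`
#' points, or a degenerate (collinear) configuration, yields zero metrics
#' and an explanatory flag rather than an error.
#'
#' @param x,y planimetric coordinates (m).
#' @param h heights above the reference surface (m), same length.
#' When `clip_rect` is given, the TIN is built from all supplied points
#' (typically the cell plus a buffer) and each triangle is clipped to the
#' rectangle before integration; because the surface is linear per
#' triangle this is exact and removes the convex-hull undershoot that a
#' hard clip at the cell boundary would cause.
#'
#' @param max_edge optional maximum planimetric edge length (m).
#' @param min_points minimum number of points for a triangulation
#'   (default 3; cell-level callers usually impose a stricter limit).
#' @param clip_rect optional `c(x0, y0, x1, y1)` integration window (m).
#' @return list with `volume` (m^3), `surface_area` (m^2),
#'   `projected_area` (m^2), `n_triangles`, and `flag` (`""` if clean).
#' @export
tin_metrics <- function(x, y, h, max_edge = NULL, min_points = 3L,
                        clip_rect = NULL) {
  stopifnot(length(x) == length(y), length(y) == length(h))
  flag <- ""
  keep <- is.finite(x) & is.finite(y) & is.finite(h)
  x <- x[keep]; y <- y[keep]; h <- h[keep]

  # collapse duplicate planimetric positions, keeping the highest return
  key <- paste(x, y)
  if (anyDuplicated(key)) {
    ord <- order(key, -h)
    first <- !duplicated(key[ord])
    sel <- ord[first]
    x <- x[sel]; y <- y[sel]; h <- h[sel]
    flag <- add_flag(flag, "duplicate_xy")
  }

  empty <- list(volume = 0, surface_area = 0, projected_area = 0,
                n_triangles = 0L)
  if (length(x) < max(3L, min_points)) {
    return(c(empty, list(flag = add_flag(flag, "insufficient_points"))))
  }

  # centre coordinates before triangulating: projected CRS offsets are
  # ~1e5-1e6 m and would otherwise eat the double precision budget
  mx <- mean(x); my <- mean(y)
  tri <- tryCatch(
    interp::triangles(interp::tri.mesh(x - mx, y - my, duplicate = "error")),
    error = function(e) NULL)
  if (is.null(tri) || nrow(tri) == 0) {
    return(c(empty, list(flag = add_flag(flag, "degenerate_geometry"))))
  }
  i <- tri[, "node1"]; j <- tri[, "node2"]; k <- tri[, "node3"]

  ax <- x[i]; ay <- y[i]; az <- h[i]
  bx <- x[j]; by <- y[j]; bz <- h[j]
  cx <- x[k]; cy <- y[k]; cz <- h[k]

  if (!is.null(max_edge) && is.finite(max_edge)) {
    e1 <- (ax - bx)^2 + (ay - by)^2
    e2 <- (bx - cx)^2 + (by - cy)^2
    e3 <- (cx - ax)^2 + (cy - ay)^2
    ok <- pmax(e1, e2, e3) <= max_edge^2
    if (!all(ok)) {
      ax <- ax[ok]; ay <- ay[ok]; az <- az[ok]
      bx <- bx[ok]; by <- by[ok]; bz <- bz[ok]
      cx <- cx[ok]; cy <- cy[ok]; cz <- cz[ok]
    }
    if (length(ax) == 0) {
      return(c(empty, list(flag = add_flag(flag, "all_triangles_filtered"))))
    }
  }

  area2d <- 0.5 * abs((bx - ax) * (cy - ay) - (cx - ax) * (by - ay))
  # 3D area via the cross product of the two edge vectors
  ux <- bx - ax; uy <- by - ay; uz <- bz - az
  vx <- cx - ax; vy <- cy - ay; vz <- cz - az
  nx <- uy * vz - uz * vy
  ny <- uz * vx - ux * vz
  nz <- ux * vy - uy * vx
  area3d <- 0.5 * sqrt(nx^2 + ny^2 + nz^2)

  if (is.null(clip_rect)) {
    return(list(volume = sum(area2d * (az + bz + cz) / 3),
                surface_area = sum(area3d),
                projected_area = sum(area2d),
                n_triangles = length(ax),
                flag = flag))
  }

  rx0 <- clip_rect[1]; ry0 <- clip_rect[2]
  rx1 <- clip_rect[3]; ry1 <- clip_rect[4]
  ins <- function(px, py) px >= rx0 & px < rx1 & py >= ry0 & py < ry1
  all_in <- ins(ax, ay) & ins(bx, by) & ins(cx, cy)
  disjoint <- (pmax(ax, bx, cx) < rx0) | (pmin(ax, bx, cx) > rx1) |
              (pmax(ay, by, cy) < ry0) | (pmin(ay, by, cy) > ry1)
  partial <- which(!all_in & !disjoint)

  vol <- sum(area2d[all_in] * (az[all_in] + bz[all_in] + cz[all_in]) / 3)
  sa <- sum(area3d[all_in])
  pa <- sum(area2d[all_in])
  slope_fac <- ifelse(area2d > 0, area3d / area2d, 1)

  for (t in partial) {
    poly <- clip_triangle_rect(c(ax[t], bx[t], cx[t]),
                               c(ay[t], by[t], cy[t]),
                               rx0, ry0, rx1, ry1)
    if (is.null(poly)) next
    a2 <- polygon_area(poly$x, poly$y)
    if (a2 <= 0) next
    cxp <- mean_centroid(poly$x, poly$y)
    zc <- interp_plane(cxp[1], cxp[2],
                       ax[t], ay[t], az[t], bx[t], by[t], bz[t],
                       cx[t], cy[t], cz[t])
    vol <- vol + a2 * zc
    sa <- sa + a2 * slope_fac[t]
    pa <- pa + a2
  }

  list(volume = vol, surface_area = sa, projected_area = pa,
       n_triangles = length(ax), flag = flag)
}

# Sutherland-Hodgman clip of a triangle against an axis-aligned rectangle
clip_triangle_rect <- function(px, py, rx0, ry0, rx1, ry1) {
  clip_edge <- function(px, py, keep, cross_at) {
    n <- length(px)
    if (n == 0) return(list(x = numeric(), y = numeric()))
    ox <- numeric(0); oy <- numeric(0)
    kp <- keep(px, py)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      if (kp[i]) { ox <- c(ox, px[i]); oy <- c(oy, py[i]) }
      if (xor(kp[i], kp[j])) {
        cr <- cross_at(px[i], py[i], px[j], py[j])
        ox <- c(ox, cr[1]); oy <- c(oy, cr[2])
      }
    }
    list(x = ox, y = oy)
  }
  p <- list(x = px, y = py)
  p <- clip_edge(p$x, p$y, function(x, y) x >= rx0, function(x1, y1, x2, y2) {
    t <- (rx0 - x1) / (x2 - x1); c(rx0, y1 + t * (y2 - y1)) })
  p <- clip_edge(p$x, p$y, function(x, y) x <= rx1, function(x1, y1, x2, y2) {
    t <- (rx1 - x1) / (x2 - x1); c(rx1, y1 + t * (y2 - y1)) })
  p <- clip_edge(p$x, p$y, function(x, y) y >= ry0, function(x1, y1, x2, y2) {
    t <- (ry0 - y1) / (y2 - y1); c(x1 + t * (x2 - x1), ry0) })
  p <- clip_edge(p$x, p$y, function(x, y) y <= ry1, function(x1, y1, x2, y2) {
    t <- (ry1 - y1) / (y2 - y1); c(x1 + t * (x2 - x1), ry1) })
  if (length(p$x) < 3) NULL else p
}

polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

mean_centroid <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  cr <- x[j] * y - x * y[j]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  c(sum((x[j] + x) * cr) / (6 * a), sum((y[j] + y) * cr) / (6 * a))
}

interp_plane <- function(qx, qy, x1, y1, z1, x2, y2, z2, x3, y3, z3) {
  d <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
  l1 <- ((y2 - y3) * (qx - x3) + (x3 - x2) * (qy - y3)) / d
  l2 <- ((y3 - y1) * (qx - x3) + (x1 - x3) * (qy - y3)) / d
  l1 * z1 + l2 * z2 + (1 - l1 - l2) * z3
}

#' Monte-Carlo volume under a TIN surface
#'
#' Independent cross-check for [tin_metrics()]: samples uniform planimetric
#' positions in the bounding box, linearly interpolates the TIN height at
#' each (via barycentric coordinates of the containing triangle), and
#' integrates.  Points outside the triangulated hull contribute zero.
#'
#' @param x,y,h TIN vertices as in [tin_metrics()].
#' @param n_samples number of Monte-Carlo draws.
#' @return estimated volume (m^3).
#' @export
tin_volume_mc <- function(x, y, h, n_samples = 1e5) {
  mx <- mean(x); my <- mean(y)
  tri <- interp::triangles(interp::tri.mesh(x - mx, y - my))
  px <- stats::runif(n_samples, min(x), max(x))
  py <- stats::runif(n_samples, min(y), max(y))
  hs <- numeric(n_samples)          # zero outside the hull
  unresolved <- rep(TRUE, n_samples)
  for (t in seq_len(nrow(tri))) {
    if (!any(unresolved)) break
    i <- tri[t, "node1"]; j <- tri[t, "node2"]; k <- tri[t, "node3"]
    d <- (y[j] - y[k]) * (x[i] - x[k]) + (x[k] - x[j]) * (y[i] - y[k])
    idx <- which(unresolved)
    l1 <- ((y[j] - y[k]) * (px[idx] - x[k]) +
           (x[k] - x[j]) * (py[idx] - y[k])) / d
    l2 <- ((y[k] - y[i]) * (px[idx] - x[k]) +
           (x[i] - x[k]) * (py[idx] - y[k])) / d
    l3 <- 1 - l1 - l2
    eps <- -1e-12
    inside <- l1 >= eps & l2 >= eps & l3 >= eps
    if (any(inside)) {
      sel <- idx[inside]
      hs[sel] <- l1[inside] * h[i] + l2[inside] * h[j] + l3[inside] * h[k]
      unresolved[sel] <- FALSE
    }
  }
  mean(hs) * diff(range(x)) * diff(range(y))
}
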