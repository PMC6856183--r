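## Synthetic phantom: co-registered OCTA flow + structural OCT volumes with a
## layered retina, two vascular plexuses, microaneurysms of three shape
## classes with known vessel attachments, intraretinal cysts, depth-decaying
## projection tails, and a complete ground-truth ledger.

#' Default phantom scan geometry
#'
#' A 256 (axial) x 128 x 128 voxel grid: the full 3-mm scan depth sampled
#' with 256 voxels (11.72 um axial pitch) and a ~1.3 mm lateral crop at the
#' 10 um lateral pitch of a 3 x 3 mm / 300 A-scan acquisition. The fovea sits
#' near the nasal edge so the 1-mm temporal analysis ROI fits in the grid.
#' @return a [volume_geometry()].
#' @export
default_phantom_geometry <- function()
  volume_geometry(256, 128, 128, axial_pitch_um = 3000 / 256,
                  lateral_pitch_um = 10,
                  fovea_xy = c(14, 64), temporal_direction = "+x")

#' Phantom configuration
#'
#' Forward-model parameters for [generate_phantom()]. The categorical mixes
#' default to the proportions observed in diabetic cohorts: most MAs attach to
#' two vessels, originate in the deep vascular complex, and are saccular.
#' Focal bulges are drawn below the 50 um smallness cutoff; saccular and
#' fusiform lesions at or above 60 um, within the 30-150 um overall range.
#'
#' @param geometry scan geometry, default [default_phantom_geometry()].
#' @param rng_seed integer seed fixing all randomness.
#' @param n_scp_vessels,n_dvc_vessels background capillaries per plexus.
#' @param vessel_radius_um capillary radius range (um).
#' @param n_mas number of microaneurysms, all placed inside the analysis ROI.
#' @param ma_size_um lesion size (long axis) range in um.
#' @param shape_mix,orientation_mix,vessels_per_ma_mix,origin_mix probability
#'   vectors over shape classes, orientation classes, branch counts 1-4 and
#'   plexus-origin classes; each must sum to 1.
#' @param n_cysts intraretinal cysts; the first is centered on the last MA so
#'   that cyst exclusion has a positive case.
#' @param tail_beta,tail_lambda_um projection-tail amplitude and axial decay
#'   length (see [add_projection_tails()]).
#' @param noise_sigma additive Gaussian noise scale (8-bit intensity units),
#'   applied to both volumes after tails.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(geometry = default_phantom_geometry(),
                           rng_seed = 1L,
                           n_scp_vessels = 8L, n_dvc_vessels = 12L,
                           vessel_radius_um = c(3.5, 6),
                           n_mas = 10L, ma_size_um = c(30, 150),
                           shape_mix = c(saccular = 0.596, fusiform = 0.154,
                                         focal_bulge = 0.250),
                           orientation_mix = c(parallel = 0.327,
                                               oblique = 0.673),
                           vessels_per_ma_mix = c(`1` = 0.308, `2` = 0.596,
                                                  `3` = 0.077, `4` = 0.019),
                           origin_mix = c(SCP_only = 0.384, DVC_only = 0.500,
                                          both = 0.116),
                           n_cysts = 2L,
                           tail_beta = 0.15, tail_lambda_um = 60,
                           noise_sigma = 2) {
  stopifnot(inherits(geometry, "volume_geometry"))
  for (mx in list(shape_mix, orientation_mix, vessels_per_ma_mix, origin_mix))
    if (abs(sum(mx) - 1) > 1e-9) stop("probability mixes must sum to 1")
  if (any(vessel_radius_um <= 0) || any(ma_size_um <= 0))
    stop("ranges must be positive")
  structure(list(
    geometry = geometry, rng_seed = as.integer(rng_seed),
    n_scp_vessels = as.integer(n_scp_vessels),
    n_dvc_vessels = as.integer(n_dvc_vessels),
    vessel_radius_um = vessel_radius_um, n_mas = as.integer(n_mas),
    ma_size_um = ma_size_um, shape_mix = shape_mix,
    orientation_mix = orientation_mix,
    vessels_per_ma_mix = vessels_per_ma_mix, origin_mix = origin_mix,
    n_cysts = as.integer(n_cysts), tail_beta = tail_beta,
    tail_lambda_um = tail_lambda_um, noise_sigma = noise_sigma
  ), class = "phantom_config")
}

## ---- surfaces ---------------------------------------------------------

## Smooth layered retina: flat boundary planes with a common low-frequency
## undulation plus a foveal depression of the inner boundaries. Depths in um,
## returned in fractional voxel units.
make_phantom_surfaces <- function(geometry) {
  g <- geometry
  base_um <- c(ILM = 400, GCC_INL = 490, INL_OPL = 530, OPL_ONL = 565,
               ONL_outer = 635, RPE = 695, BM = 703)
  dip_um <- c(ILM = 50, GCC_INL = 35, INL_OPL = 15, OPL_ONL = 5,
              ONL_outer = 0, RPE = 0, BM = 0)
  xs <- lateral_um(seq_len(g$n_x), g)
  ys <- lateral_um(seq_len(g$n_y), g)
  ph <- runif(4, 0, 2 * pi)
  und <- 4 * outer(sin(2 * pi * xs / 900 + ph[1]),
                   sin(2 * pi * ys / 700 + ph[2])) +
         3 * outer(sin(2 * pi * xs / 1500 + ph[3]),
                   sin(2 * pi * ys / 1100 + ph[4]))
  fx <- lateral_um(g$fovea_xy[1], g); fy <- lateral_um(g$fovea_xy[2], g)
  r2 <- outer((xs - fx)^2, rep(1, g$n_y)) + outer(rep(1, g$n_x), (ys - fy)^2)
  pit <- exp(-r2 / (2 * 150^2))
  surfaces <- lapply(BOUNDARY_NAMES, function(nm) {
    (base_um[[nm]] + und + dip_um[[nm]] * pit) / g$axial_pitch_um
  })
  names(surfaces) <- BOUNDARY_NAMES
  layer_surfaces(surfaces, g)
}

## surface depth in um at a lateral physical position (nearest voxel)
surf_um_at <- function(surfs, name, x_um, y_um) {
  g <- surfs$geometry
  i <- pmin(pmax(round(x_um / g$lateral_pitch_um + 0.5), 1), g$n_x)
  j <- pmin(pmax(round(y_um / g$lateral_pitch_um + 0.5), 1), g$n_y)
  surfs$surfaces[[name]][cbind(i, j)] * g$axial_pitch_um
}

## depth band (um) of a plexus at a lateral position
plexus_band_um <- function(surfs, plexus, x_um, y_um) {
  if (plexus == "SCP")
    c(surf_um_at(surfs, "ILM", x_um, y_um) + 5,
      surf_um_at(surfs, "GCC_INL", x_um, y_um) - 3)
  else
    c(surf_um_at(surfs, "GCC_INL", x_um, y_um) + 3,
      surf_um_at(surfs, "OPL_ONL", x_um, y_um) + 10)
}

## ---- rasterization primitives -----------------------------------------

## A box is a local sub-array with physical voxel-center coordinate vectors.
## Soft (partial-volume) edges: weight 1 at >= half a lateral pitch inside
## the surface, 0 at half a pitch outside.
soft_w <- function(dist_outside, s) pmin(1, pmax(0, (s - dist_outside) / (2 * s)))

## Rendered tube radius: capillaries thinner than the device's lateral point
## spread function (~14 um FWHM) appear at the PSF width, which also keeps
## sub-voxel tubes connected on the grid.
PSF_RADIUS_UM <- 7
render_radius <- function(r_um) pmax(r_um, PSF_RADIUS_UM)

make_box <- function(center_um, half_um, geometry) {
  g <- geometry
  zr <- max(1L, floor((center_um[1] - half_um) / g$axial_pitch_um + 0.5)):
        min(g$n_axial, ceiling((center_um[1] + half_um) / g$axial_pitch_um + 0.5))
  xr <- max(1L, floor((center_um[2] - half_um) / g$lateral_pitch_um + 0.5)):
        min(g$n_x, ceiling((center_um[2] + half_um) / g$lateral_pitch_um + 0.5))
  yr <- max(1L, floor((center_um[3] - half_um) / g$lateral_pitch_um + 0.5)):
        min(g$n_y, ceiling((center_um[3] + half_um) / g$lateral_pitch_um + 0.5))
  list(zr = zr, xr = xr, yr = yr,
       zc = axial_um(zr, g), xc = lateral_um(xr, g), yc = lateral_um(yr, g),
       arr = array(0, dim = c(length(zr), length(xr), length(yr))))
}

box_global_idx <- function(box, geometry) {
  d <- geom_dim(geometry)
  zz <- box$zr; xx <- box$xr; yy <- box$yr
  outer(outer(zz, d[1] * (xx - 1L), "+"), d[1] * d[2] * (yy - 1L), "+")
}

stamp_ball_box <- function(box, center_um, r_um, s) {
  d2 <- outer(outer((box$zc - center_um[1])^2, (box$xc - center_um[2])^2, "+"),
              (box$yc - center_um[3])^2, "+")
  box$arr <- pmax(box$arr, soft_w(sqrt(d2) - r_um, s))
  box
}

stamp_ellipsoid_box <- function(box, center_um, u, a_um, b_um, s) {
  dz <- box$zc - center_um[1]; dx <- box$xc - center_um[2]
  dy <- box$yc - center_um[3]
  t <- outer(outer(dz * u[1], dx * u[2], "+"), dy * u[3], "+")
  d2 <- outer(outer(dz^2, dx^2, "+"), dy^2, "+")
  q2 <- pmax(d2 - t^2, 0)
  rho <- sqrt((t / a_um)^2 + q2 / b_um^2)
  box$arr <- pmax(box$arr, soft_w((rho - 1) * b_um, s))
  box
}

stamp_segment_box <- function(box, p1, p2, r_um, s, step = 2) {
  len <- sqrt(sum((p2 - p1)^2))
  ts <- seq(0, 1, length.out = max(2, ceiling(len / step) + 1))
  for (t in ts)
    box <- stamp_ball_box(box, p1 + t * (p2 - p1), r_um, s)
  box
}

## Stamp a ball directly into the full flow array (returns updated voxels).
## Used for vessel tubes where a bounding box per tube would span the volume.
stamp_ball_global <- function(flow, center_um, r_um, value, s, geometry) {
  g <- geometry
  half <- r_um + 2 * s
  if (center_um[1] < -half || center_um[2] < -half || center_um[3] < -half)
    return(flow)
  box <- make_box(center_um, half, g)
  if (!length(box$zr) || !length(box$xr) || !length(box$yr)) return(flow)
  box <- stamp_ball_box(box, center_um, r_um, s)
  idx <- box_global_idx(box, g)
  sel <- box$arr > 0
  if (any(sel))
    flow[idx[sel]] <- pmax(flow[idx[sel]], value * box$arr[sel])
  flow
}

## ---- vessel tracing ---------------------------------------------------

unit3 <- function(v) v / sqrt(sum(v^2))

## direction (z,x,y) with given elevation (deg, positive = deeper) and
## lateral azimuth (rad)
dir_from_angles <- function(elev_deg, azim) {
  e <- elev_deg * pi / 180
  c(sin(e), cos(e) * cos(azim), cos(e) * sin(azim))
}

rot_azim <- function(v, dazim) {
  h <- sqrt(v[2]^2 + v[3]^2)
  a <- atan2(v[3], v[2]) + dazim
  c(v[1], h * cos(a), h * sin(a))
}

## Trace an attached-vessel stub: straight along `dir` until `exit_um` beyond
## the anchor, then steered toward a horizontal course inside the target
## plexus band. Returns a matrix of centerline points (um).
trace_stub <- function(anchor_um, dir, exit_um, plexus, surfs,
                       total_um = 240, step = 2) {
  g <- surfs$geometry
  lim_x <- g$n_x * g$lateral_pitch_um; lim_y <- g$n_y * g$lateral_pitch_um
  p <- anchor_um; d <- unit3(dir)
  n <- ceiling(total_um / step)
  pts <- matrix(NA_real_, n + 1, 3)
  pts[1, ] <- p
  for (k in seq_len(n)) {
    t <- k * step
    if (t > exit_um) {
      band <- plexus_band_um(surfs, plexus, p[2], p[3])
      tz <- if (p[1] < band[1]) 0.8 else if (p[1] > band[2]) -0.8 else 0
      h <- c(tz, d[2], d[3])
      if (sqrt(h[2]^2 + h[3]^2) < 0.2) h[2:3] <- c(cos(0.7), sin(0.7))
      d <- unit3(d + 0.4 * (unit3(h) - d))
    }
    p <- p + step * d
    if (p[2] < 2 || p[2] > lim_x - 2 || p[3] < 2 || p[3] > lim_y - 2) {
      pts <- pts[seq_len(k), , drop = FALSE]
      return(pts)
    }
    pts[k + 1, ] <- p
  }
  pts
}

## Background plexus capillary: a gently wiggling path across the whole
## lateral field at the plexus depth.
trace_background <- function(surfs, plexus, depth_offset_um, step = 2.5) {
  g <- surfs$geometry
  lim_x <- g$n_x * g$lateral_pitch_um; lim_y <- g$n_y * g$lateral_pitch_um
  diag_len <- sqrt(lim_x^2 + lim_y^2)
  azim <- runif(1, 0, 2 * pi)
  mid <- c(runif(1, 0.15, 0.85) * lim_x, runif(1, 0.15, 0.85) * lim_y)
  amp <- runif(1, 15, 40); per <- runif(1, 280, 650); ph <- runif(1, 0, 2 * pi)
  ts <- seq(-diag_len / 2, diag_len / 2, by = step)
  ux <- cos(azim); uy <- sin(azim)
  px <- mid[1] + ts * ux - sin(2 * pi * ts / per + ph) * amp * uy
  py <- mid[2] + ts * uy + sin(2 * pi * ts / per + ph) * amp * ux
  keep <- px > 2 & px < lim_x - 2 & py > 2 & py < lim_y - 2
  px <- px[keep]; py <- py[keep]
  if (!length(px)) return(matrix(numeric(0), 0, 3))
  dname <- if (plexus == "SCP") NA else sample(c("INL_OPL", "OPL_ONL"), 1)
  pz <- if (plexus == "SCP") {
    (surf_um_at(surfs, "ILM", px, py) +
       surf_um_at(surfs, "GCC_INL", px, py)) / 2 + depth_offset_um
  } else {
    surf_um_at(surfs, dname, px, py) + depth_offset_um
  }
  cbind(pz, px, py)
}

## rasterize a centerline into flow; returns list(flow, voxel_idx)
rasterize_tube <- function(flow, pts, r_um, value, s, geometry,
                           avoid_centers = NULL, avoid_radius = NULL) {
  if (!nrow(pts)) return(list(flow = flow, idx = integer(0)))
  keep <- rep(TRUE, nrow(pts))
  if (!is.null(avoid_centers) && nrow(avoid_centers)) {
    for (m in seq_len(nrow(avoid_centers))) {
      d2 <- (pts[, 1] - avoid_centers[m, 1])^2 +
            (pts[, 2] - avoid_centers[m, 2])^2 +
            (pts[, 3] - avoid_centers[m, 3])^2
      keep <- keep & d2 > avoid_radius[m]^2
    }
  }
  idx_all <- vector("list", sum(keep))
  ii <- 0
  for (k in which(keep)) {
    box <- make_box(pts[k, ], r_um + 2 * s, geometry)
    if (!length(box$zr) || !length(box$xr) || !length(box$yr)) next
    box <- stamp_ball_box(box, pts[k, ], r_um, s)
    gidx <- box_global_idx(box, geometry)
    sel <- box$arr > 0
    if (any(sel)) {
      flow[gidx[sel]] <- pmax(flow[gidx[sel]], value * box$arr[sel])
      ii <- ii + 1
      idx_all[[ii]] <- gidx[box$arr >= 0.5]
    }
  }
  list(flow = flow, idx = unique(unlist(idx_all[seq_len(ii)])))
}
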