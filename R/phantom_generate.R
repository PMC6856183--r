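## Phantom assembly: draw lesion specifications, rasterize bodies and
## attached vessels, add background capillaries, cysts, structural bands,
## projection tails and noise, and emit the ground-truth ledger.

cross3 <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

## Draw one MA specification at a lateral position (um). Axial placement and
## tilt are constrained so lesions stay inside the retina and span at most
## three of the four graded layers.
draw_ma_spec <- function(cfg, id, pos_xy_um, surfs) {
  shape <- sample(names(cfg$shape_mix), 1, prob = cfg$shape_mix)
  orientation <- sample(names(cfg$orientation_mix), 1,
                        prob = cfg$orientation_mix)
  origin <- sample(names(cfg$origin_mix), 1, prob = cfg$origin_mix)
  n_br <- as.integer(sample(names(cfg$vessels_per_ma_mix), 1,
                            prob = cfg$vessels_per_ma_mix))
  if (origin == "both" && n_br < 2L) n_br <- 2L
  lo <- cfg$ma_size_um[1]; hi <- cfg$ma_size_um[2]
  size <- if (shape == "focal_bulge") runif(1, max(lo, 34), min(48, hi))
          else if (shape == "fusiform") runif(1, max(lo, 70), hi)
          else runif(1, max(lo, 60), hi)
  if (origin == "SCP_only") size <- min(size, 110)
  if (origin == "both") size <- min(size, 100)
  tilt <- if (orientation == "parallel") runif(1, 0, 10) else runif(1, 30, 60)
  ## cap axial extent so multi-layer span stays physical
  ext_cap <- switch(shape, fusiform = 85, saccular = 75, focal_bulge = Inf)
  if (size * sin(tilt * pi / 180) > ext_cap)
    tilt <- asin(ext_cap / size) * 180 / pi

  x <- pos_xy_um[1]; y <- pos_xy_um[2]
  ilm <- surf_um_at(surfs, "ILM", x, y)
  gcc_inl <- surf_um_at(surfs, "GCC_INL", x, y)
  inl_opl <- surf_um_at(surfs, "INL_OPL", x, y)
  opl_onl <- surf_um_at(surfs, "OPL_ONL", x, y)

  tr <- tilt * pi / 180
  a <- size / 2
  b <- max(15, 0.28 * a)
  ax_half <- switch(shape,
    fusiform = a * sin(tr) + b * cos(tr) + 2,
    saccular = a * (1 + 0.5 * abs(sin(tr))),
    focal_bulge = 0.80 * a + 2)
  z <- switch(origin,
    SCP_only = {
      zlo <- ilm + ax_half + 2
      zhi <- max(zlo, min(gcc_inl + 6, inl_opl - 6 - ax_half))
      min(max((ilm + gcc_inl) / 2 + runif(1, -8, 8), zlo), zhi)
    },
    DVC_only = {
      zlo <- max(gcc_inl + 0.25 * ax_half, ilm + ax_half + 2)
      zhi <- opl_onl - 0.68 * ax_half
      if (zlo >= zhi) (zlo + zhi) / 2 else runif(1, zlo, zhi)
    },
    both = gcc_inl + 8 + runif(1, 0, 8))

  ## vessel geometry: w = local vessel axis (near-horizontal), u = lesion
  ## long axis, v = perpendicular offset direction for saccular lesions
  azim <- runif(1, 0, 2 * pi)
  sgn <- sample(c(-1, 1), 1)
  u <- dir_from_angles(sgn * tilt, azim)
  w <- dir_from_angles(runif(1, -4, 4), azim)
  h <- unit3(c(0, -w[3], w[2]))
  vv <- cross3(w, h); if (vv[1] < 0) vv <- -vv
  sphi <- min(1, sin(tr) / max(vv[1], 1e-6))
  phi <- asin(sphi)
  v <- sgn * (cos(phi) * sample(c(-1, 1), 1) * h + sin(phi) * vv)

  list(id = id, shape_class = shape, orientation_class = orientation,
       origin_class = origin, n_vessels = n_br, size_draw_um = size,
       tilt_deg = tilt, center_um = c(z, x, y), u = u, w = w, v = v,
       a = a, b = b, R = size / 2)
}

## rasterize one MA body; returns list(flow, mask_idx)
raster_ma_body <- function(flow, spec, geometry, s, value = 235) {
  ctr <- spec$center_um
  box <- switch(spec$shape_class,
    fusiform = {
      bx <- make_box(ctr, spec$a + 3 * s, geometry)
      stamp_ellipsoid_box(bx, ctr, spec$u, spec$a, spec$b, s)
    },
    saccular = {
      bx <- make_box(ctr, 2 * spec$R + 3 * s, geometry)
      bx <- stamp_ball_box(bx, ctr, spec$R, s)
      anchor <- ctr - spec$R * spec$v
      stamp_segment_box(bx, ctr, anchor, max(8, 0.4 * spec$R), s)
    },
    focal_bulge = {
      rm <- 0.75 * spec$R
      bx <- make_box(ctr, 2 * rm + 3 * s, geometry)
      bx <- stamp_ball_box(bx, ctr, rm, s)
      for (k in 1:3) {
        off <- unit3(rnorm(3)) * 0.5 * rm
        bx <- stamp_ball_box(bx, ctr + off, 0.5 * rm, s)
      }
      bx
    })
  gidx <- box_global_idx(box, geometry)
  sel <- box$arr > 0
  flow[gidx[sel]] <- pmax(flow[gidx[sel]], value * box$arr[sel])
  list(flow = flow, mask_idx = sort(gidx[box$arr >= 0.5]))
}

## Branch plan: list of (dir, plexus, anchor) realizing the drawn branch
## count and origin class. A through-vessel is two opposite branches.
## Branch anchors are spread over the lesion surface so distinct branches
## leave the dilated lesion at separated contact points and stay distinct
## connected components in the perivascular shell.
plan_branches <- function(spec) {
  n <- spec$n_vessels
  ctr <- spec$center_um
  sacc_A <- ctr - spec$R * spec$v   # vessel-axis point of a saccular lesion
  if (spec$origin_class != "both") {
    plx <- if (spec$origin_class == "SCP_only") "SCP" else "DVC"
    if (spec$shape_class == "saccular") {
      ## secondary vessel offset from the sphere center along the same
      ## perpendicular as the main one, so the lesion stays asymmetric
      ## about every attached vessel axis
      w2 <- rot_azim(spec$w, 1.35)
      A2 <- ctr - 0.55 * spec$R * spec$v
      plans <- list(
        list(dir = spec$w, plexus = plx, anchor = sacc_A),
        list(dir = -spec$w, plexus = plx, anchor = sacc_A),
        list(dir = w2, plexus = plx, anchor = A2),
        list(dir = -w2, plexus = plx, anchor = A2))
    } else {
      axis <- if (spec$shape_class == "fusiform") spec$u else spec$w
      plans <- list(
        list(dir = axis, plexus = plx, anchor = ctr),
        list(dir = -axis, plexus = plx, anchor = ctr),
        list(dir = rot_azim(axis, 1.15), plexus = plx, anchor = ctr),
        list(dir = -rot_azim(axis, 1.15), plexus = plx, anchor = ctr))
    }
    plans[seq_len(n)]
  } else {
    up <- function(d) if (d[1] > 0) -d else d
    if (spec$shape_class == "fusiform") {
      uu <- up(spec$u)
      plans <- list(
        list(dir = uu, plexus = "SCP", anchor = ctr),
        list(dir = -uu, plexus = "DVC", anchor = ctr),
        list(dir = rot_azim(-uu, 1.2), plexus = "DVC", anchor = ctr),
        list(dir = rot_azim(uu, 1.2), plexus = "SCP", anchor = ctr))
    } else {
      a1 <- runif(1, 0, 2 * pi)
      R <- spec$R
      top <- ctr - c(if (spec$shape_class == "saccular") R else 0.75 * R, 0, 0)
      dvc_anchor <- if (spec$shape_class == "saccular") sacc_A else ctr
      plans <- list(
        list(dir = dir_from_angles(-55, a1), plexus = "SCP", anchor = top),
        list(dir = dir_from_angles(10, a1 + pi), plexus = "DVC",
             anchor = dvc_anchor),
        list(dir = dir_from_angles(12, a1 + 2.2), plexus = "DVC",
             anchor = dvc_anchor),
        list(dir = dir_from_angles(-55, a1 + 2.4), plexus = "SCP",
             anchor = ctr))
    }
    plans[seq_len(n)]
  }
}

## Structural reflectance bands per layer, from the surfaces
make_struct_bands <- function(surfs, geometry) {
  g <- geometry
  s <- lapply(surfs$surfaces, identity)
  arr <- array(20, dim = geom_dim(g))
  bands <- list(
    list(s$ILM, s$GCC_INL, 150), list(s$GCC_INL, s$INL_OPL, 90),
    list(s$INL_OPL, s$OPL_ONL, 150), list(s$OPL_ONL, s$ONL_outer, 55),
    list(s$ONL_outer, s$RPE, 120), list(s$RPE, s$BM, 235))
  below <- s$BM
  for (z in seq_len(g$n_axial)) {
    zc <- z - 0.5
    slice <- matrix(20, g$n_x, g$n_y)
    for (bd in bands) {
      sel <- zc >= bd[[1]] & zc < bd[[2]]
      slice[sel] <- bd[[3]]
    }
    slice[zc >= below] <- 60
    arr[z, , ] <- slice
  }
  arr
}

#' Add depth-decaying projection tails beneath flow voxels
#'
#' Forward model for OCTA projection artifacts: every flow voxel casts a tail
#' onto deeper voxels, with amplitude `beta`, exponential axial decay length
#' `lambda_um`, and modulation by the local structural reflectance
#' (`S/255`) -- flow projects onto reflective tissue, not onto dark spaces.
#' The tail added at depth z is
#' `round(beta * sum_{z' < z} F(z') * exp(-(z - z') * pitch / lambda) * S(z) / 255)`
#' and the result is clipped to 255. Output is voxelwise >= input.
#'
#' @param flow a [flow_volume()] (the artifact-free flow).
#' @param struct the co-registered [struct_volume()].
#' @param beta tail amplitude coefficient (dimensionless).
#' @param lambda_um axial decay length in micrometers.
#' @return list with `flow` (tailed [flow_volume()]) and `artifact_mask`
#'   (logical array marking voxels whose added tail is >= 1 intensity unit
#'   and whose true flow is zero).
#' @export
add_projection_tails <- function(flow, struct, beta = 0.15, lambda_um = 60) {
  stopifnot(inherits(flow, "flow_volume"), inherits(struct, "struct_volume"))
  if (!geom_equal(flow$geometry, struct$geometry))
    stop("flow and struct geometries differ")
  g <- flow$geometry
  F <- flow$voxels; S <- struct$voxels
  decay <- exp(-g$axial_pitch_um / lambda_um)
  out <- F
  mask <- array(FALSE, dim = dim(F))
  A <- matrix(0, g$n_x, g$n_y)
  for (z in seq_len(g$n_axial)) {
    if (z > 1) A <- decay * (A + F[z - 1, , ])
    tl <- round(beta * A * S[z, , ] / 255)
    out[z, , ] <- pmin(F[z, , ] + tl, 255)
    mask[z, , ] <- tl >= 1 & F[z, , ] == 0
  }
  list(flow = flow_volume(out, g), artifact_mask = mask)
}

#' Generate a synthetic OCTA/OCT phantom with ground truth
#'
#' Builds co-registered flow and structural volumes over a layered retina:
#' superficial (SCP) capillaries between ILM and the GCC/INL boundary, deep
#' vascular complex (DVC) capillaries flanking the INL, microaneurysms of the
#' drawn shape/orientation/origin classes attached to the drawn number of
#' vessel branches, intraretinal cysts, projection tails and additive noise.
#' Every generated object is recorded in the returned truth ledger.
#'
#' @param cfg a [phantom_config()].
#' @return list with elements `flow` ([flow_volume()]), `struct`
#'   ([struct_volume()]), `surfaces` ([layer_surfaces()]) and `truth`
#'   (class `phantom_truth`: per-MA records with mask voxel indices and all
#'   graded quantities, per-vessel records, artifact mask, cyst footprints,
#'   and the noiseless true-flow voxel set).
#' @export
generate_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  g <- cfg$geometry
  set.seed(cfg$rng_seed)
  s_edge <- 0.5 * g$lateral_pitch_um
  surfs <- make_phantom_surfaces(g)
  roi <- roi_bounds(roi_spec(), g)

  ## --- lateral MA placement inside the ROI, minimum 200 um separation
  centers_xy <- matrix(numeric(0), 0, 2)
  if (cfg$n_mas > 0) {
    margin <- 80
    tries <- 0
    while (nrow(centers_xy) < cfg$n_mas) {
      tries <- tries + 1
      if (tries > 4000)
        stop("infeasible packing: too many MAs for the ROI; lower n_mas")
      p <- c(runif(1, roi$x_um[1] + margin, roi$x_um[2] - margin),
             runif(1, roi$y_um[1] + margin, roi$y_um[2] - margin))
      if (nrow(centers_xy) == 0 ||
          min(sqrt(rowSums(sweep(centers_xy, 2, p)^2))) > 200)
        centers_xy <- rbind(centers_xy, p)
    }
  }
  specs <- lapply(seq_len(cfg$n_mas), function(i)
    draw_ma_spec(cfg, i, centers_xy[i, ], surfs))

  ## --- rasterize MA bodies
  flow <- array(0, dim = geom_dim(g))
  for (i in seq_along(specs)) {
    r <- raster_ma_body(flow, specs[[i]], g, s_edge)
    flow <- r$flow
    specs[[i]]$mask_idx <- r$mask_idx
    mum <- idx_to_um(r$mask_idx, g)
    specs[[i]]$r_mask_um <- sqrt(max(rowSums(
      sweep(mum, 2, specs[[i]]$center_um)^2)))
  }

  ## --- attached vessel branches (a through-vessel is two branches)
  vessels <- list()
  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    branches <- plan_branches(spec)
    vids <- integer(0)
    plxs <- character(0)
    for (bi in seq_along(branches)) {
      br <- branches[[bi]]
      rv <- runif(1, cfg$vessel_radius_um[1], cfg$vessel_radius_um[2])
      pts <- trace_stub(br$anchor, br$dir,
                        exit_um = spec$size_draw_um / 2 + 22,
                        plexus = br$plexus, surfs = surfs,
                        total_um = if (bi <= 2) 240 else 150)
      ## truncate the stub before it strays into another lesion's
      ## perivascular neighbourhood
      if (length(specs) > 1 && nrow(pts) > 1) {
        cut <- nrow(pts)
        for (j in seq_along(specs)) {
          if (j == i) next
          oc <- specs[[j]]$center_um
          d2 <- (pts[, 1] - oc[1])^2 + (pts[, 2] - oc[2])^2 +
                (pts[, 3] - oc[3])^2
          inside <- which(d2 < (specs[[j]]$r_mask_um + 50)^2)
          if (length(inside)) cut <- min(cut, inside[1] - 1L)
        }
        pts <- pts[seq_len(max(cut, 1L)), , drop = FALSE]
      }
      rt <- rasterize_tube(flow, pts, render_radius(rv), 205, s_edge, g)
      flow <- rt$flow
      vid <- length(vessels) + 1L
      vessels[[vid]] <- list(id = vid, plexus = br$plexus, ma_id = spec$id,
                             centerline = pts, radius_um = rv,
                             voxel_idx = rt$idx)
      vids <- c(vids, vid)
      plxs <- c(plxs, br$plexus)
    }
    specs[[i]]$vessel_ids <- vids
    specs[[i]]$branch_plexus <- plxs
  }

  ## --- background plexus capillaries, carved clear of the lesions
  avoid_ctr <- if (length(specs))
    do.call(rbind, lapply(specs, function(sp) sp$center_um)) else NULL
  avoid_rad <- if (length(specs))
    vapply(specs, function(sp) sp$r_mask_um + 65, 0) else NULL
  bg_plan <- c(rep("SCP", cfg$n_scp_vessels), rep("DVC", cfg$n_dvc_vessels))
  for (plx in bg_plan) {
    rv <- runif(1, cfg$vessel_radius_um[1], cfg$vessel_radius_um[2])
    off <- if (plx == "SCP") runif(1, -10, 10) else runif(1, -6, 6)
    pts <- trace_background(surfs, plx, off)
    rt <- rasterize_tube(flow, pts, render_radius(rv), 205, s_edge, g,
                         avoid_centers = avoid_ctr, avoid_radius = avoid_rad)
    flow <- rt$flow
    vid <- length(vessels) + 1L
    vessels[[vid]] <- list(id = vid, plexus = plx, ma_id = NA_integer_,
                           centerline = pts, radius_um = rv,
                           voxel_idx = rt$idx)
  }

  ## --- cysts: first one centered on the last MA (positive exclusion case)
  cysts <- list()
  if (cfg$n_cysts > 0) {
    k <- 1L
    if (cfg$n_mas > 0) {
      last <- specs[[cfg$n_mas]]
      rl <- max(60, last$size_draw_um / 2 + 15)
      cysts[[k]] <- list(center_xy_um = last$center_um[2:3], radius_um = rl,
                         depth_um = surf_um_at(surfs, "INL_OPL",
                                               last$center_um[2],
                                               last$center_um[3]))
      k <- k + 1L
    }
    tries <- 0
    while (length(cysts) < cfg$n_cysts && tries < 2000) {
      tries <- tries + 1
      rl <- runif(1, 60, 110)
      p <- c(runif(1, roi$x_um[1] + rl, roi$x_um[2] - rl),
             runif(1, roi$y_um[1] + rl, roi$y_um[2] - rl))
      clear <- !length(specs) || all(sqrt(rowSums(
        sweep(centers_xy, 2, p)^2)) > rl + 90)
      if (clear)
        cysts[[length(cysts) + 1L]] <-
          list(center_xy_um = p, radius_um = rl,
               depth_um = surf_um_at(surfs, "INL_OPL", p[1], p[2]))
    }
    cysts <- lapply(cysts, function(cy) {
      th <- seq(0, 2 * pi, length.out = 25)[-25]
      cy$polygon_um <- cbind(cy$center_xy_um[1] + cy$radius_um * cos(th),
                             cy$center_xy_um[2] + cy$radius_um * sin(th))
      cy
    })
  }

  ## --- structural volume: layer bands + hyporeflective cysts
  struct <- make_struct_bands(surfs, g)
  for (cy in cysts) {
    ctr <- c(cy$depth_um, cy$center_xy_um)
    ra <- 25
    box <- make_box(ctr, cy$radius_um + 10, g)
    rho <- sqrt(outer(outer(((box$zc - ctr[1]) / ra)^2,
                            ((box$xc - ctr[2]) / cy$radius_um)^2, "+"),
                      ((box$yc - ctr[3]) / cy$radius_um)^2, "+"))
    gidx <- box_global_idx(box, g)
    struct[gidx[rho < 1]] <- 15
  }
  struct_int <- array(as.integer(pmin(pmax(round(struct), 0), 255)),
                      dim = geom_dim(g))

  ## --- finalize flow: quantize, add projection tails, then noise
  flow_true_int <- array(as.integer(pmin(pmax(round(flow), 0), 255)),
                         dim = geom_dim(g))
  true_flow_idx <- which(flow_true_int > 0L)
  tl <- add_projection_tails(flow_volume(flow_true_int, g),
                             struct_volume(struct_int, g),
                             beta = cfg$tail_beta,
                             lambda_um = cfg$tail_lambda_um)
  fvox <- tl$flow$voxels
  svox <- struct_int
  if (cfg$noise_sigma > 0) {
    fvox <- round(fvox + rnorm(length(fvox), 0, cfg$noise_sigma))
    svox <- round(svox + rnorm(length(svox), 0, cfg$noise_sigma))
    fvox <- array(as.integer(pmin(pmax(fvox, 0), 255)), dim = geom_dim(g))
    svox <- array(as.integer(pmin(pmax(svox, 0), 255)), dim = geom_dim(g))
  }

  ## --- truth ledger: graded quantities recomputed from the emitted masks
  mas <- lapply(specs, function(sp) {
    over <- FALSE
    for (cy in cysts)
      if (sqrt(sum((sp$center_um[2:3] - cy$center_xy_um)^2)) <= cy$radius_um)
        over <- TRUE
    list(id = sp$id,
         center_um = sp$center_um,
         center_vox = c(
           pmin(pmax(round(sp$center_um[1] / g$axial_pitch_um + 0.5), 1),
                g$n_axial),
           pmin(pmax(round(sp$center_um[2] / g$lateral_pitch_um + 0.5), 1),
                g$n_x),
           pmin(pmax(round(sp$center_um[3] / g$lateral_pitch_um + 0.5), 1),
                g$n_y)),
         shape_class = sp$shape_class,
         orientation_class = sp$orientation_class,
         tilt_deg = sp$tilt_deg,
         size_um = measure_size(sp$mask_idx, g),
         vessel_ids = sp$vessel_ids,
         branch_plexus = sp$branch_plexus,
         n_vessels = sp$n_vessels,
         origin_class = sp$origin_class,
         layers_occupied = layer_occupancy(sp$mask_idx, surfs),
         over_cyst = over,
         mask_idx = sp$mask_idx)
  })
  scp_idx <- unique(unlist(lapply(vessels, function(v)
    if (v$plexus == "SCP") v$voxel_idx)))
  dvc_idx <- unique(unlist(lapply(vessels, function(v)
    if (v$plexus == "DVC") v$voxel_idx)))
  truth <- structure(list(
    mas = mas, vessels = vessels, cysts = cysts,
    artifact_mask = tl$artifact_mask,
    true_flow_idx = true_flow_idx,
    scp_vessel_idx = scp_idx, dvc_vessel_idx = dvc_idx,
    config = cfg
  ), class = "phantom_truth")

  list(flow = flow_volume(fvox, g), struct = struct_volume(svox, g),
       surfaces = surfs, truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("phantom_truth: %d MAs, %d vessel branches, %d cysts\n",
              length(x$mas), length(x$vessels), length(x$cysts)))
  invisible(x)
}
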