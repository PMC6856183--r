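## 3D grading of microaneurysm candidates: lesion segmentation, connected
## vessel-branch counting with plexus labels, plexus-origin class, retinal
## layer occupancy, shape class, orientation relative to the RPE, and size
## (maximum Feret diameter).

#' Grading thresholds
#'
#' The numeric cutoffs that make the qualitative grading criteria
#' operational. All live in one record so alternative values can be
#' re-validated against phantom ground truth.
#'
#' @param asymmetry_thresh saccular vs fusiform cutoff on the asymmetry
#'   index (centroid offset from the vessel axis / volume-equivalent radius).
#' @param parallel_deg maximum tilt (degrees, to the RPE tangent plane) still
#'   graded parallel.
#' @param bulge_um lesions smaller than this (long axis, um) are focal
#'   bulges.
#' @param occupancy_frac,occupancy_min_vox a layer counts as occupied when at
#'   least this fraction (and this many) of mask voxels fall inside it.
#' @param seg_radius_um region-growing confinement radius around the seed.
#' @param seed_floor_frac region-growing threshold floor as a fraction of the
#'   seed intensity.
#' @param shell_um radius of the perivascular shell searched for connected
#'   vessel branches.
#' @param shell_thresh_frac shell binarization threshold as a fraction of the
#'   segmentation threshold (more permissive, so thin perfused capillaries
#'   stay contiguous).
#' @param min_branch_vox minimum voxels for a connected component to count as
#'   a vessel branch (rejects partial-volume shards at the lesion rim).
#' @param aniso_min principal-axis anisotropy ratio below which a lesion is
#'   near-isotropic and orientation is degenerate (graded parallel, flagged).
#' @param dedup_tol_um lateral tolerance for cross-slab deduplication.
#' @return an object of class `grading_config`.
#' @export
grading_config <- function(asymmetry_thresh = 0.3, parallel_deg = 15,
                           bulge_um = 50, occupancy_frac = 0.05,
                           occupancy_min_vox = 2L, seg_radius_um = 250,
                           seed_floor_frac = 0.3, shell_um = 150,
                           shell_thresh_frac = 0.5, min_branch_vox = 8L,
                           aniso_min = 1.2, dedup_tol_um = 25) {
  structure(as.list(environment()), class = "grading_config")
}

## local sub-box around a seed; returns index ranges and local arrays
seed_box <- function(seed, half_um, geometry) {
  g <- geometry
  hz <- ceiling(half_um / g$axial_pitch_um)
  hl <- ceiling(half_um / g$lateral_pitch_um)
  list(zr = max(1L, seed[1] - hz):min(g$n_axial, seed[1] + hz),
       xr = max(1L, seed[2] - hl):min(g$n_x, seed[2] + hl),
       yr = max(1L, seed[3] - hl):min(g$n_y, seed[3] + hl))
}

box_dist2 <- function(box, center_um, geometry) {
  g <- geometry
  outer(outer((axial_um(box$zr, g) - center_um[1])^2,
              (lateral_um(box$xr, g) - center_um[2])^2, "+"),
        (lateral_um(box$yr, g) - center_um[3])^2, "+")
}

box_to_global <- function(box, local_idx, geometry) {
  d <- c(length(box$zr), length(box$xr), length(box$yr))
  zxy <- idx_to_zxy(local_idx, d)
  glob <- cbind(box$zr[zxy[, 1]], box$xr[zxy[, 2]], box$yr[zxy[, 3]])
  zxy_to_idx(glob, geom_dim(geometry))
}

global_to_box <- function(box, global_idx, geometry) {
  zxy <- idx_to_zxy(global_idx, geom_dim(geometry))
  keep <- zxy[, 1] >= box$zr[1] & zxy[, 1] <= box$zr[length(box$zr)] &
          zxy[, 2] >= box$xr[1] & zxy[, 2] <= box$xr[length(box$xr)] &
          zxy[, 3] >= box$yr[1] & zxy[, 3] <= box$yr[length(box$yr)]
  loc <- cbind(zxy[keep, 1] - box$zr[1] + 1L, zxy[keep, 2] - box$xr[1] + 1L,
               zxy[keep, 3] - box$yr[1] + 1L)
  zxy_to_idx(loc, c(length(box$zr), length(box$xr), length(box$yr)))
}

#' Segment a microaneurysm in 3D from a seed
#'
#' Region growing from the seed over voxels at or above
#' `max(local Otsu, seed_floor_frac * seed intensity)`, confined to a ball of
#' `seg_radius_um` around the seed, followed by a morphological opening
#' (6-neighbour cross) that detaches thin feeding vessels; the seed's
#' connected component is kept.
#'
#' @param flow a [flow_volume()].
#' @param seed integer (z, x, y) voxel indices of the candidate seed.
#' @param cfg a [grading_config()].
#' @return list with `mask_idx` (linear voxel indices into the volume),
#'   `threshold` used, and `status` (`"ok"` or `"aborted"` when nothing
#'   remains after opening).
#' @export
segment_ma <- function(flow, seed, cfg = grading_config()) {
  stopifnot(inherits(flow, "flow_volume"))
  g <- flow$geometry
  seed <- as.integer(seed)
  if (any(seed < 1L) || any(seed > geom_dim(g)))
    stop("seed outside the voxel grid")
  seed_int <- flow$voxels[seed[1], seed[2], seed[3]]
  box <- seed_box(seed, cfg$seg_radius_um, g)
  vals <- flow$voxels[box$zr, box$xr, box$yr, drop = FALSE]
  seed_um <- c(axial_um(seed[1], g), lateral_um(seed[2], g),
               lateral_um(seed[3], g))
  ball <- box_dist2(box, seed_um, g) <= cfg$seg_radius_um^2
  thr <- max(otsu_threshold(vals[ball]), cfg$seed_floor_frac * seed_int)
  bin <- (vals >= thr) & ball
  seed_loc <- zxy_to_idx(cbind(seed[1] - box$zr[1] + 1L,
                               seed[2] - box$xr[1] + 1L,
                               seed[3] - box$yr[1] + 1L), dim(bin))
  if (!bin[seed_loc])
    return(list(mask_idx = integer(0), threshold = thr, status = "aborted"))
  lab <- label3d(bin, 26L)
  comp <- lab == lab[seed_loc]
  opened <- open_lat(comp)
  if (!any(opened))
    return(list(mask_idx = integer(0), threshold = thr, status = "aborted"))
  ## reconstruction: one lateral step restores the 1-px rim clipped by the
  ## opening without re-attaching detached (laterally adjacent) vessels;
  ## axial steps then regrow thin axial lesion tips, which no horizontal
  ## capillary can mimic
  opened <- dilate_lat(opened) & comp
  for (k in 1:3)
    opened <- (opened | shift3d(opened, 1) | shift3d(opened, -1)) & comp
  lab2 <- label3d(opened, 26L)
  keep_lab <- if (opened[seed_loc]) {
    lab2[seed_loc]
  } else {
    ## seed eroded by the opening: take the component nearest the seed
    oidx <- which(opened)
    zxy <- idx_to_zxy(oidx, dim(opened))
    d2 <- (axial_um(box$zr[zxy[, 1]], g) - seed_um[1])^2 +
          (lateral_um(box$xr[zxy[, 2]], g) - seed_um[2])^2 +
          (lateral_um(box$yr[zxy[, 3]], g) - seed_um[3])^2
    lab2[oidx[which.min(d2)]]
  }
  final <- which(lab2 == keep_lab)
  list(mask_idx = sort(box_to_global(box, final, g)), threshold = thr,
       status = "ok")
}

#' Count vessel branches connected to a lesion and label their plexus
#'
#' The flow volume is binarized (a permissive fraction of the segmentation
#' threshold, so thin capillaries stay contiguous) in a perivascular shell
#' around the lesion, and the lesion plus a corridor of about one capillary
#' diameter around it is removed. Each connected component of the remaining
#' vasculature's contact region on that corridor is one vessel branch -- a
#' through-vessel therefore counts as two branches (entry and exit), even if
#' its two ends reconnect through the capillary network far from the lesion.
#' Each branch is assigned SCP if the median depth of its local course lies
#' above the GCC/INL boundary at its median lateral position, DVC if within
#' the deep vascular complex band (down to 15 um below the OPL/ONL
#' boundary), and `other` below that.
#'
#' @param flow a [flow_volume()].
#' @param mask_idx lesion voxel indices from [segment_ma()].
#' @param surfs a [layer_surfaces()].
#' @param threshold binarization threshold (use the one from [segment_ma()]).
#' @param cfg a [grading_config()].
#' @return list with `n_vessels`, `plexus` (character per branch), `status`
#'   (`"ok"` or `"no_vessels"`), and `branches` (per branch: contact-point
#'   centroid `entry_um`, principal direction `dir`, voxel count).
#' @export
count_vessels <- function(flow, mask_idx, surfs, threshold,
                          cfg = grading_config()) {
  stopifnot(length(mask_idx) > 0)
  g <- flow$geometry
  mum <- idx_to_um(mask_idx, g)
  ctr <- colMeans(mum)
  rmax <- sqrt(max(rowSums(sweep(mum, 2, ctr)^2)))
  half <- rmax + cfg$shell_um + 15
  ctr_vox <- c(pmin(pmax(round(ctr[1] / g$axial_pitch_um + 0.5), 1), g$n_axial),
               pmin(pmax(round(ctr[2] / g$lateral_pitch_um + 0.5), 1), g$n_x),
               pmin(pmax(round(ctr[3] / g$lateral_pitch_um + 0.5), 1), g$n_y))
  box <- seed_box(as.integer(ctr_vox), half, g)
  vals <- flow$voxels[box$zr, box$xr, box$yr, drop = FALSE]
  shell_ball <- box_dist2(box, ctr, g) <= (rmax + cfg$shell_um)^2
  bin <- (vals >= cfg$shell_thresh_frac * threshold) & shell_ball
  mask_loc <- array(FALSE, dim = dim(bin))
  mask_loc[global_to_box(box, mask_idx, g)] <- TRUE
  ## the removed corridor spans ~one capillary diameter so a through-vessel
  ## is properly severed into entry and exit branches even for small lesions
  dil1 <- dilate6(dilate6(mask_loc))
  body <- bin & !dil1
  lab <- label3d(body, 26L)
  ring <- dilate6(dil1) & !dil1
  ## A branch is a distinct place where perfused vasculature touches the
  ## (dilated) lesion: connected components of the contact region. Counting
  ## contact zones rather than shell components keeps a through-vessel at
  ## two branches even when its two ends reconnect through the surrounding
  ## capillary network far from the lesion.
  contact <- ring & body
  clab <- label3d(contact, 26L)
  nz <- max(clab)
  branches <- list()
  if (nz > 0) {
    pc1 <- function(pts) {
      if (nrow(pts) < 3) return(c(0, 1, 0))
      ev <- eigen(stats::cov(pts), symmetric = TRUE)
      ev$vectors[, 1]
    }
    for (zid in seq_len(nz)) {
      zvox <- which(clab == zid)
      blab <- lab[zvox[1]]
      bvox <- which(lab == blab)
      if (length(bvox) < cfg$min_branch_vox) next
      entry <- colMeans(idx_to_um(box_to_global(box, zvox, g), g))
      gum <- idx_to_um(box_to_global(box, bvox, g), g)
      ## local course: the part of the vessel next to this contact zone,
      ## long enough to reach the branch's plexus-band course
      d2e <- rowSums(sweep(gum, 2, entry)^2)
      loc <- gum[d2e <= 180^2, , drop = FALSE]
      near <- gum[d2e <= 35^2, , drop = FALSE]
      zmed <- median(loc[, 1]); xmed <- median(loc[, 2])
      ymed <- median(loc[, 3])
      gcc_inl <- surf_um_at(surfs, "GCC_INL", xmed, ymed)
      opl_onl <- surf_um_at(surfs, "OPL_ONL", xmed, ymed)
      plexus <- if (zmed < gcc_inl) "SCP"
                else if (zmed <= opl_onl + 15) "DVC" else "other"
      branches[[length(branches) + 1]] <-
        list(plexus = plexus, entry_um = entry, dir = unit3(pc1(gum)),
             prox_dir = unit3(pc1(if (nrow(near) >= 3) near else loc)),
             n_vox = length(bvox))
    }
  }
  if (!length(branches))
    return(list(n_vessels = 0L, plexus = character(0), status = "no_vessels",
                branches = list()))
  list(n_vessels = length(branches),
       plexus = vapply(branches, function(b) b$plexus, ""),
       status = "ok", branches = branches)
}

#' Plexus origin class from per-branch labels
#'
#' SCP_only if all labeled branches arise from the superficial plexus,
#' DVC_only if all from the deep vascular complex, otherwise both. Branches
#' labeled `other` are ignored when at least one SCP/DVC label exists;
#' with no SCP/DVC labels at all the origin is undetermined.
#'
#' @param plexus character vector of branch labels from [count_vessels()].
#' @return one of `"SCP_only"`, `"DVC_only"`, `"both"`, `"undetermined"`.
#' @export
classify_origin <- function(plexus) {
  lab <- plexus[plexus %in% c("SCP", "DVC")]
  if (!length(lab)) return("undetermined")
  if (all(lab == "SCP")) "SCP_only"
  else if (all(lab == "DVC")) "DVC_only"
  else "both"
}

#' Retinal layers occupied by a lesion
#'
#' A layer (GCC, INL, OPL, ONL; half-open depth intervals between the
#' corresponding boundary surfaces at each lateral position) is occupied when
#' at least `occupancy_frac` of the mask voxels, and at least
#' `occupancy_min_vox` voxels, fall inside it.
#'
#' @param mask_idx lesion voxel indices.
#' @param surfs a [layer_surfaces()].
#' @param cfg a [grading_config()].
#' @return character vector, subset of [LAYER_NAMES].
#' @export
layer_occupancy <- function(mask_idx, surfs, cfg = grading_config()) {
  stopifnot(length(mask_idx) > 0, inherits(surfs, "layer_surfaces"))
  g <- surfs$geometry
  zxy <- idx_to_zxy(mask_idx, geom_dim(g))
  zc <- zxy[, 1] - 0.5
  lat <- cbind(zxy[, 2], zxy[, 3])
  n <- length(mask_idx)
  counts <- vapply(LAYER_NAMES, function(L) {
    iv <- layer_interval(surfs, L)
    sum(zc >= iv$inner[lat] & zc < iv$outer[lat])
  }, 0)
  if (sum(counts) == 0)
    stop("lesion mask lies entirely outside the graded retinal layers")
  occ <- counts >= max(cfg$occupancy_min_vox, cfg$occupancy_frac * n)
  LAYER_NAMES[occ]
}

#' Shape class from mask symmetry about the vessel axis
#'
#' Lesions below `bulge_um` on their long axis are focal bulges. Otherwise
#' the vessel axis is the least-squares line through the contact points of
#' the connected branches (or the single branch's direction), and the
#' asymmetry index is the perpendicular distance of the mask centroid from
#' that axis divided by the volume-equivalent sphere radius: fusiform
#' (symmetric dilation) when small, saccular (asymmetric outpouching)
#' otherwise. With no branches the axis is undefined and shape falls back to
#' size alone (focal bulge if small, else saccular).
#'
#' @param mask_idx lesion voxel indices.
#' @param branches branch list from [count_vessels()].
#' @param geometry a [volume_geometry()].
#' @param size_um lesion size from [measure_size()].
#' @param cfg a [grading_config()].
#' @return list with `shape_class` and `asymmetry_index`.
#' @export
classify_shape <- function(mask_idx, branches, geometry, size_um,
                           cfg = grading_config()) {
  stopifnot(length(mask_idx) > 0)
  g <- geometry
  if (size_um < cfg$bulge_um)
    return(list(shape_class = "focal_bulge", asymmetry_index = NA_real_))
  if (!length(branches))
    return(list(shape_class = "saccular", asymmetry_index = NA_real_))
  entries <- do.call(rbind, lapply(branches, function(b) b$entry_um))
  ctr <- colMeans(idx_to_um(mask_idx, g))
  ## A through-vessel shows as two branches with contact points on opposite
  ## sides of the lesion and antiparallel proximal courses; its chord is the
  ## vessel axis. Without such a pair, the largest branch's proximal course
  ## through its contact point serves as the axis.
  best <- NULL; best_vox <- -1
  if (nrow(entries) >= 2) {
    for (i in seq_len(nrow(entries) - 1)) for (j in (i + 1):nrow(entries)) {
      ei <- entries[i, ] - ctr; ej <- entries[j, ] - ctr
      if (sum(unit3(ei) * unit3(ej)) < -0.3 &&
          abs(sum(branches[[i]]$prox_dir * branches[[j]]$prox_dir)) > 0.6) {
        nv <- branches[[i]]$n_vox + branches[[j]]$n_vox
        if (nv > best_vox) { best <- c(i, j); best_vox <- nv }
      }
    }
  }
  if (!is.null(best)) {
    anchor <- (entries[best[1], ] + entries[best[2], ]) / 2
    u <- unit3(entries[best[2], ] - entries[best[1], ])
  } else {
    big <- which.max(vapply(branches, function(b) b$n_vox, 0))
    anchor <- entries[big, ]
    u <- branches[[big]]$prox_dir
  }
  dvec <- ctr - anchor
  d_perp <- sqrt(max(sum(dvec^2) - sum(dvec * u)^2, 0))
  vol_um3 <- length(mask_idx) * g$axial_pitch_um * g$lateral_pitch_um^2
  r_eq <- (3 * vol_um3 / (4 * pi))^(1 / 3)
  a <- d_perp / r_eq
  list(shape_class = if (a <= cfg$asymmetry_thresh) "fusiform" else "saccular",
       asymmetry_index = a)
}

#' Orientation of the lesion long axis relative to the RPE
#'
#' The long axis is the principal eigenvector of the mask's second-moment
#' matrix in physical units; the RPE tangent plane is fitted by least squares
#' over the mask's lateral footprint dilated by 50 um. Lesions tilted at most
#' `parallel_deg` from the plane are parallel, the rest oblique.
#' Near-isotropic lesions (axis anisotropy ratio below `aniso_min`) are
#' graded parallel with `degenerate = TRUE`.
#'
#' @param mask_idx lesion voxel indices.
#' @param surfs a [layer_surfaces()].
#' @param cfg a [grading_config()].
#' @return list with `orientation_class`, `tilt_deg`, `degenerate`.
#' @export
classify_orientation <- function(mask_idx, surfs, cfg = grading_config()) {
  stopifnot(length(mask_idx) > 0)
  g <- surfs$geometry
  pts <- idx_to_um(mask_idx, g)
  if (nrow(pts) < 4)
    return(list(orientation_class = "parallel", tilt_deg = 0,
                degenerate = TRUE))
  ev <- eigen(stats::cov(pts), symmetric = TRUE)
  axis <- unit3(ev$vectors[, 1])
  aniso <- sqrt(max(ev$values[1], 0) / max(ev$values[2], 1e-9))
  zxy <- idx_to_zxy(mask_idx, geom_dim(g))
  pad <- ceiling(50 / g$lateral_pitch_um)
  xr <- max(1L, min(zxy[, 2]) - pad):min(g$n_x, max(zxy[, 2]) + pad)
  yr <- max(1L, min(zxy[, 3]) - pad):min(g$n_y, max(zxy[, 3]) + pad)
  grid <- expand.grid(x = xr, y = yr)
  zs <- surfs$surfaces$RPE[cbind(grid$x, grid$y)] * g$axial_pitch_um
  X <- cbind(1, lateral_um(grid$x, g), lateral_um(grid$y, g))
  cf <- solve(crossprod(X), crossprod(X, zs))
  nrm <- unit3(c(1, -cf[2], -cf[3]))
  tilt <- 90 - acos(min(abs(sum(axis * nrm)), 1)) * 180 / pi
  if (aniso < cfg$aniso_min)
    return(list(orientation_class = "parallel", tilt_deg = tilt,
                degenerate = TRUE))
  list(orientation_class = if (tilt <= cfg$parallel_deg) "parallel"
                           else "oblique",
       tilt_deg = tilt, degenerate = FALSE)
}

#' Lesion size: maximum Feret diameter
#'
#' Maximum pairwise distance between mask voxel centers in physical units.
#' Exact; for large masks the search is restricted to surface voxels (which
#' preserves the maximum).
#'
#' @param mask_idx lesion voxel indices.
#' @param geometry a [volume_geometry()].
#' @return size in um.
#' @export
measure_size <- function(mask_idx, geometry) {
  stopifnot(length(mask_idx) > 0)
  g <- geometry
  if (length(mask_idx) > 800) {
    ## surface voxels: those missing at least one 6-neighbour in the mask
    d <- geom_dim(g)
    nb <- c(1L, -1L, d[1], -d[1], d[1] * d[2], -d[1] * d[2])
    interior <- rep(TRUE, length(mask_idx))
    for (o in nb)
      interior <- interior & ((mask_idx + o) %in% mask_idx)
    keep <- mask_idx[!interior]
    if (length(keep) >= 2) mask_idx <- keep
  }
  pts <- idx_to_um(mask_idx, g)
  n <- nrow(pts)
  if (n == 1) return(voxel_diag_um(g) / 2)
  if (n <= 2500) return(max(stats::dist(pts)))
  best <- 0
  for (i0 in seq(1, n, by = 500)) {
    i1 <- min(i0 + 499, n)
    blk <- pts[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), rowSums(pts^2), "+") - 2 * blk %*% t(pts)
    best <- max(best, max(d2))
  }
  sqrt(best)
}

#' Grade one candidate in 3D
#'
#' Runs segmentation, vessel-branch counting, origin, layer occupancy, size,
#' shape and orientation for a single seed, returning a full grading record.
#'
#' @param flow a [flow_volume()] (after artifact removal).
#' @param surfs a [layer_surfaces()].
#' @param seed integer (z, x, y) seed voxel.
#' @param id record identifier.
#' @param cfg a [grading_config()].
#' @return an `ma_record` list; `status` is `"ok"` or `"aborted"`.
#' @export
grade_ma <- function(flow, surfs, seed, id = 1L, cfg = grading_config()) {
  seg <- segment_ma(flow, seed, cfg)
  if (seg$status != "ok")
    return(structure(list(id = id, seed = seed, status = "aborted"),
                     class = "ma_record"))
  g <- flow$geometry
  cv <- count_vessels(flow, seg$mask_idx, surfs, seg$threshold, cfg)
  size <- measure_size(seg$mask_idx, g)
  shp <- classify_shape(seg$mask_idx, cv$branches, g, size, cfg)
  ori <- classify_orientation(seg$mask_idx, surfs, cfg)
  layers <- layer_occupancy(seg$mask_idx, surfs, cfg)
  structure(list(
    id = id, seed = seed, status = "ok", mask_idx = seg$mask_idx,
    threshold = seg$threshold,
    n_vessels = cv$n_vessels, branch_plexus = cv$plexus,
    origin_class = classify_origin(cv$plexus),
    layers_occupied = layers,
    shape_class = shp$shape_class, asymmetry_index = shp$asymmetry_index,
    orientation_class = ori$orientation_class, tilt_deg = ori$tilt_deg,
    orientation_degenerate = ori$degenerate,
    size_um = size
  ), class = "ma_record")
}

#' @export
print.ma_record <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("ma_record %s: %s\n", x$id, x$status))
    return(invisible(x))
  }
  cat(sprintf(
    "ma_record %s: %s, %s, %d vessel(s) [%s], layers {%s}, %.1f um\n",
    x$id, x$shape_class, x$orientation_class, x$n_vessels,
    x$origin_class, paste(x$layers_occupied, collapse = ","), x$size_um))
  invisible(x)
}

#' Flatten grading records to a data.frame
#'
#' @param records list of `ma_record`s.
#' @return data.frame with one row per record; `layers_occupied` is a
#'   comma-separated string, `n_layers` its cardinality.
#' @export
records_df <- function(records) {
  rows <- lapply(records, function(r) {
    if (r$status != "ok")
      return(data.frame(id = r$id, status = r$status, n_vessels = NA_integer_,
                        origin_class = NA_character_, layers = NA_character_,
                        n_layers = NA_integer_, shape_class = NA_character_,
                        orientation_class = NA_character_,
                        size_um = NA_real_, stringsAsFactors = FALSE))
    data.frame(id = r$id, status = "ok", n_vessels = r$n_vessels,
               origin_class = r$origin_class,
               layers = paste(r$layers_occupied, collapse = ","),
               n_layers = length(r$layers_occupied),
               shape_class = r$shape_class,
               orientation_class = r$orientation_class,
               size_um = r$size_um, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
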