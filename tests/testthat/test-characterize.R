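# 3D grading operators on constructed scenes with known geometry. The small
# test grid is isotropic (10 um voxels); flat surfaces put the INL at
# 170-260 um and the DVC band at 170-365 um depth.

scene_geometry <- function(n_x = 48, n_y = 24) small_geometry(n_x = n_x,
                                                              n_y = n_y)

# ellipsoid mask voxel indices (axes in um, u = long-axis direction)
ellipsoid_idx <- function(geometry, center_um, u, a_um, b_um) {
  g <- geometry
  zs <- (seq_len(g$n_axial) - 0.5) * g$axial_pitch_um
  xs <- (seq_len(g$n_x) - 0.5) * g$lateral_pitch_um
  ys <- (seq_len(g$n_y) - 0.5) * g$lateral_pitch_um
  grid <- expand.grid(z = zs, x = xs, y = ys)
  rel <- cbind(grid$z - center_um[1], grid$x - center_um[2],
               grid$y - center_um[3])
  t <- rel %*% u
  q2 <- rowSums(rel^2) - t^2
  which((t / a_um)^2 + q2 / b_um^2 <= 1)
}

# flow volume: an ellipsoid lesion plus an optional tube along +-x
lesion_scene <- function(geometry, center_um, u = c(0, 1, 0), a_um = 55,
                         b_um = 25, tube = c("through", "stub", "none"),
                         tube_r = 10) {
  tube <- match.arg(tube)
  g <- geometry
  vox <- array(0L, dim = c(g$n_axial, g$n_x, g$n_y))
  vox[ellipsoid_idx(g, center_um, u, a_um, b_um)] <- 235L
  if (tube != "none") {
    zs <- (seq_len(g$n_axial) - 0.5) * g$axial_pitch_um
    xs <- (seq_len(g$n_x) - 0.5) * g$lateral_pitch_um
    ys <- (seq_len(g$n_y) - 0.5) * g$lateral_pitch_um
    d2 <- outer(outer((zs - center_um[1])^2, rep(0, g$n_x), "+"),
                (ys - center_um[3])^2, "+")
    tube_vox <- d2 <= tube_r^2
    if (tube == "stub") {
      keep_x <- xs >= center_um[2]
      tube_vox[, !keep_x, ] <- FALSE
    }
    vox[tube_vox & vox == 0L] <- 205L
  }
  flow_volume(vox, g)
}

test_that("segmentation recovers an isolated sphere and respects connectivity", {
  g <- scene_geometry()
  ctr <- c(215, 160, 120)
  fl <- ball_flow(g, rbind(ctr), 40)
  seed <- um_to_vox(ctr, g)
  seg <- segment_ma(fl, seed)
  expect_equal(seg$status, "ok")
  truth_idx <- which(fl$voxels > 0)
  dice <- 2 * length(intersect(seg$mask_idx, truth_idx)) /
    (length(seg$mask_idx) + length(truth_idx))
  expect_gte(dice, 0.9)

  # seed on an empty background aborts with a status, not an error
  seg0 <- segment_ma(fl, c(5L, 5L, 5L))
  expect_equal(seg0$status, "aborted")
  expect_length(seg0$mask_idx, 0)

  # a second sphere 300 um away stays out of the first sphere's mask
  fl2 <- ball_flow(g, rbind(ctr, ctr + c(0, 300, 0)), c(40, 40))
  seg2 <- segment_ma(fl2, seed)
  far <- which(fl2$voxels > 0)
  far <- far[!(far %in% which(fl$voxels > 0))]
  expect_length(intersect(seg2$mask_idx, far), 0)
})

test_that("a through-vessel counts as two branches, a stub as one", {
  g <- scene_geometry()
  surfs <- flat_surfaces(g)
  ctr <- c(215, 240, 120)
  for (mode in c("through", "stub")) {
    fl <- lesion_scene(g, ctr, u = c(0, 1, 0), tube = mode)
    seg <- segment_ma(fl, um_to_vox(ctr, g))
    cv <- count_vessels(fl, seg$mask_idx, surfs, seg$threshold)
    expect_equal(cv$n_vessels, if (mode == "through") 2L else 1L,
                 label = mode)
    expect_true(all(cv$plexus == "DVC"))
  }
})

test_that("origin classification follows the branch labels", {
  expect_equal(classify_origin(c("SCP", "SCP")), "SCP_only")
  expect_equal(classify_origin(c("DVC", "DVC", "DVC")), "DVC_only")
  expect_equal(classify_origin(c("SCP", "DVC")), "both")
  expect_equal(classify_origin(c("SCP", "other")), "SCP_only")
  expect_equal(classify_origin(c("other")), "undetermined")
  expect_equal(classify_origin(character(0)), "undetermined")
})

test_that("layer occupancy uses half-open intervals and the 5% rule", {
  g <- scene_geometry()
  surfs <- flat_surfaces(g)
  # sphere strictly inside the INL (170-260 um)
  inl_ball <- ellipsoid_idx(g, c(215, 160, 120), c(1, 0, 0), 30, 30)
  expect_setequal(layer_occupancy(inl_ball, surfs), "INL")
  # ellipsoid straddling INL/OPL with a ~50/50 split
  strad <- ellipsoid_idx(g, c(260, 160, 120), c(1, 0, 0), 40, 40)
  expect_setequal(layer_occupancy(strad, surfs), c("INL", "OPL"))
  # mask entirely above the ILM is a geometry inconsistency
  vitreous <- ellipsoid_idx(g, c(40, 160, 120), c(1, 0, 0), 25, 25)
  expect_error(layer_occupancy(vitreous, surfs), "outside the graded")
})

test_that("shape classification separates fusiform, saccular and focal bulge", {
  g <- scene_geometry()
  surfs <- flat_surfaces(g)
  ctr <- c(215, 240, 120)
  # ellipsoid centered on its through-vessel: symmetric, fusiform
  fl <- lesion_scene(g, ctr, u = c(0, 1, 0), tube = "through")
  seg <- segment_ma(fl, um_to_vox(ctr, g))
  cv <- count_vessels(fl, seg$mask_idx, surfs, seg$threshold)
  sz <- measure_size(seg$mask_idx, g)
  shp <- classify_shape(seg$mask_idx, cv$branches, g, sz)
  expect_equal(shp$shape_class, "fusiform")
  expect_lte(shp$asymmetry_index, 0.15)

  # sphere offset from the vessel axis by its own radius: saccular
  R <- 40
  vox <- ball_flow(g, rbind(ctr + c(-R, 0, 0)), R)$voxels
  zs <- (seq_len(g$n_axial) - 0.5) * 10
  ys <- (seq_len(g$n_y) - 0.5) * 10
  d2 <- outer(outer((zs - ctr[1])^2, rep(0, g$n_x), "+"), (ys - ctr[3])^2, "+")
  vox[d2 <= 10^2 & vox == 0L] <- 205L
  fl2 <- flow_volume(vox, g)
  seg2 <- segment_ma(fl2, um_to_vox(ctr + c(-R, 0, 0), g))
  cv2 <- count_vessels(fl2, seg2$mask_idx, surfs, seg2$threshold)
  sz2 <- measure_size(seg2$mask_idx, g)
  shp2 <- classify_shape(seg2$mask_idx, cv2$branches, g, sz2)
  expect_equal(shp2$shape_class, "saccular")
  expect_gt(shp2$asymmetry_index, 0.3)

  # small lesions are focal bulges regardless of symmetry
  shp3 <- classify_shape(seg$mask_idx, cv$branches, g, size_um = 45)
  expect_equal(shp3$shape_class, "focal_bulge")
  # with no branches at all, large lesions fall back to saccular
  expect_equal(classify_shape(seg$mask_idx, list(), g, 80)$shape_class,
               "saccular")
})

test_that("orientation grading measures tilt to the RPE tangent plane", {
  g <- scene_geometry()
  surfs <- flat_surfaces(g)
  # prolate ellipsoid lying along the (flat) RPE: parallel, tilt ~ 0
  flat <- ellipsoid_idx(g, c(215, 240, 120), c(0, 1, 0), 70, 22)
  o1 <- classify_orientation(flat, surfs)
  expect_equal(o1$orientation_class, "parallel")
  expect_false(o1$degenerate)
  expect_lt(o1$tilt_deg, 8)

  # prolate ellipsoid tilted 45 degrees: oblique, tilt 45 +- 3
  u45 <- c(sin(pi / 4), cos(pi / 4), 0)
  tilted <- ellipsoid_idx(g, c(260, 240, 120), u45, 70, 22)
  o2 <- classify_orientation(tilted, surfs)
  expect_equal(o2$orientation_class, "oblique")
  expect_lt(abs(o2$tilt_deg - 45), 3)

  # a sphere has no meaningful axis: degenerate, graded parallel
  o3 <- classify_orientation(ellipsoid_idx(g, c(215, 160, 120),
                                           c(1, 0, 0), 30, 30), surfs)
  expect_true(o3$degenerate)
  expect_equal(o3$orientation_class, "parallel")
})

test_that("size is the maximum Feret diameter in physical units", {
  g <- scene_geometry()
  d <- c(g$n_axial, g$n_x, g$n_y)
  two <- octama3d:::zxy_to_idx(rbind(c(10L, 10L, 10L), c(10L, 13L, 10L)), d)
  expect_equal(measure_size(two, g), 30)

  sphere <- ellipsoid_idx(g, c(215, 160, 120), c(1, 0, 0), 50, 50)
  diag_um <- sqrt(sum(c(10, 10, 10)^2))
  expect_lt(abs(measure_size(sphere, g) - 100), diag_um)
  # the surface-voxel shortcut agrees with the exact small-mask path
  expect_equal(measure_size(sphere, g),
               max(stats::dist(octama3d:::idx_to_um(sphere, g))))
})

test_that("grading is invariant to intensity rescaling and lateral shifts", {
  g <- scene_geometry()
  surfs <- flat_surfaces(g)
  ctr <- c(215, 200, 120)
  fl <- lesion_scene(g, ctr, u = c(0, 1, 0), tube = "through")
  r1 <- grade_ma(fl, surfs, um_to_vox(ctr, g))

  dim_fl <- flow_volume(array(as.integer(round(fl$voxels * 0.55)),
                              dim = dim(fl$voxels)), g)
  r2 <- grade_ma(dim_fl, surfs, um_to_vox(ctr, g))
  expect_equal(r2$shape_class, r1$shape_class)
  expect_lt(abs(r2$asymmetry_index - r1$asymmetry_index), 0.05)

  # shift the whole scene by 3 voxels in x and 2 in y
  shifted <- array(0L, dim = dim(fl$voxels))
  shifted[, 4:g$n_x, 3:g$n_y] <- fl$voxels[, 1:(g$n_x - 3), 1:(g$n_y - 2)]
  r3 <- grade_ma(flow_volume(shifted, g), surfs,
                 um_to_vox(ctr, g) + c(0L, 3L, 2L))
  expect_equal(r3$n_vessels, r1$n_vessels)
  expect_equal(r3$shape_class, r1$shape_class)
  expect_equal(r3$layers_occupied, r1$layers_occupied)
  expect_equal(r3$size_um, r1$size_um, tolerance = 1e-8)
})
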