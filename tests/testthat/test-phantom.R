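test_that("phantom generation is deterministic under a fixed seed", {
  cfg <- phantom_config(rng_seed = 42, n_mas = 3L, n_scp_vessels = 3L,
                        n_dvc_vessels = 4L, n_cysts = 1L)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$flow$voxels, b$flow$voxels)
  expect_identical(a$struct$voxels, b$struct$voxels)
  expect_identical(a$surfaces$surfaces, b$surfaces$surfaces)
  expect_identical(lapply(a$truth$mas, `[[`, "mask_idx"),
                   lapply(b$truth$mas, `[[`, "mask_idx"))
})

test_that("with no lesions, noise or tails, all flow is ledgered vasculature", {
  cfg <- phantom_config(rng_seed = 5, n_mas = 0L, n_cysts = 0L,
                        noise_sigma = 0, tail_beta = 0)
  ph <- generate_phantom(cfg)
  nz <- which(ph$flow$voxels > 0L)
  expect_identical(nz, ph$truth$true_flow_idx)
  vessel_idx <- sort(unique(c(ph$truth$scp_vessel_idx,
                              ph$truth$dvc_vessel_idx)))
  # every ledgered vessel voxel carries flow; the remaining nonzero voxels
  # are sub-half-maximum partial-volume fringe of the same tubes
  expect_true(all(vessel_idx %in% nz))
  expect_false(any(ph$truth$artifact_mask))
})

test_that("artifact mask marks exactly the pure-tail voxels", {
  cfg <- phantom_config(rng_seed = 5, n_mas = 0L, n_cysts = 0L,
                        noise_sigma = 0)
  ph <- generate_phantom(cfg)
  amask <- which(ph$truth$artifact_mask)
  expect_gt(length(amask), 0)
  # artifact voxels have zero true flow but nonzero flow in the volume
  expect_true(all(ph$flow$voxels[amask] >= 1L))
  expect_length(intersect(amask, ph$truth$true_flow_idx), 0)
})

test_that("a pure-fusiform mix yields lesions symmetric about the vessel axis", {
  # brute-force reflection oracle: reflect every mask voxel through the
  # lesion's vessel-axis line and require >= 90% of the reflections to land
  # on (or one voxel from, allowing grid quantization) the original mask.
  # Saccular lesions from the same generator fail this, so the oracle
  # discriminates the two shape families.
  reflection_overlap <- function(m, truth, g) {
    v1 <- truth$vessels[[m$vessel_ids[1]]]
    k <- min(12, nrow(v1$centerline))
    u <- v1$centerline[k, ] - v1$centerline[1, ]
    u <- u / sqrt(sum(u^2))
    # a point on the axis: the attached vessel's anchor
    c0 <- v1$centerline[1, ]
    pts <- octama3d:::idx_to_um(m$mask_idx, g)
    rel <- sweep(pts, 2, c0)
    t <- rel %*% u
    refl <- sweep(2 * (t %*% t(u)) - rel, 2, c0, "+")
    ridx <- octama3d:::zxy_to_idx(cbind(
      pmin(pmax(round(refl[, 1] / g$axial_pitch_um + 0.5), 1), g$n_axial),
      pmin(pmax(round(refl[, 2] / g$lateral_pitch_um + 0.5), 1), g$n_x),
      pmin(pmax(round(refl[, 3] / g$lateral_pitch_um + 0.5), 1), g$n_y)),
      c(g$n_axial, g$n_x, g$n_y))
    near <- array(FALSE, dim = c(g$n_axial, g$n_x, g$n_y))
    near[m$mask_idx] <- TRUE
    near <- octama3d:::dilate6(near)
    mean(near[ridx])
  }
  cfg <- phantom_config(rng_seed = 9, n_mas = 5L,
                        shape_mix = c(saccular = 0, fusiform = 1,
                                      focal_bulge = 0))
  ph <- generate_phantom(cfg)
  g <- ph$flow$geometry
  expect_true(all(vapply(ph$truth$mas, `[[`, "", "shape_class") == "fusiform"))
  for (m in ph$truth$mas)
    expect_gte(reflection_overlap(m, ph$truth, g), 0.9)

  sac <- generate_phantom(phantom_config(
    rng_seed = 9, n_mas = 5L,
    shape_mix = c(saccular = 1, fusiform = 0, focal_bulge = 0)))
  sac_overlap <- vapply(sac$truth$mas, reflection_overlap, 0,
                        truth = sac$truth, g = sac$flow$geometry)
  expect_true(mean(sac_overlap < 0.9) >= 0.8)
})

test_that("lesions span between one and three retinal layers", {
  for (seed in c(3, 11)) {
    ph <- generate_phantom(phantom_config(rng_seed = seed))
    n_layers <- vapply(ph$truth$mas,
                       function(m) length(m$layers_occupied), 0L)
    expect_true(all(n_layers >= 1 & n_layers <= 3))
    # ledger layers are recomputable from the emitted mask and surfaces
    for (m in ph$truth$mas)
      expect_setequal(layer_occupancy(m$mask_idx, ph$surfaces),
                      m$layers_occupied)
  }
})

test_that("infeasible lesion packing is reported", {
  expect_error(generate_phantom(phantom_config(n_mas = 60L)),
               "lower n_mas")
})

test_that("shape frequencies follow the configured mix across seeds", {
  shapes <- character(0)
  for (seed in 21:26) {
    ph <- generate_phantom(phantom_config(
      rng_seed = seed, n_mas = 8L, n_scp_vessels = 2L, n_dvc_vessels = 2L,
      n_cysts = 0L, tail_beta = 0, noise_sigma = 0))
    shapes <- c(shapes, vapply(ph$truth$mas, `[[`, "", "shape_class"))
  }
  # binomial check at ~3 sigma around the default saccular share (0.596)
  p <- mean(shapes == "saccular")
  se <- sqrt(0.596 * (1 - 0.596) / length(shapes))
  expect_lt(abs(p - 0.596), 3.5 * se)
})
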