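# Slab projection, ROI placement, candidate detection, cyst exclusion and
# cross-slab deduplication.

test_that("slab projection honours half-open depth intervals", {
  g <- small_geometry()
  surfs <- flat_surfaces(g)
  vox <- array(0L, dim = c(64, 24, 24))
  vox[9:16, , ] <- 100L  # inside [ILM=8, GCC_INL=17): voxel centers 8.5-16.5
  fl <- flow_volume(vox, g)
  scp_max <- make_enface(fl, surfs, slab_spec("SCP", "ILM", 0, "GCC_INL", 0,
                                              "max"))
  expect_true(all(scp_max == 100))
  expect_equal(attr(scp_max, "slab"), "SCP")

  # mean of a 4-voxel slab holding {0, 0, 100, 100}
  g2 <- small_geometry(n_axial = 16)
  s2 <- flat_surfaces(g2, depths = c(ILM = 2, GCC_INL = 6, INL_OPL = 8,
                                     OPL_ONL = 10, ONL_outer = 12, RPE = 14,
                                     BM = 15))
  v2 <- array(0L, dim = c(16, 24, 24))
  v2[5:6, , ] <- 100L  # slab [2,6) = voxels 3,4,5,6; two of four at 100
  m <- make_enface(flow_volume(v2, g2), s2,
                   slab_spec("SCP", "ILM", 0, "GCC_INL", 0, "mean"))
  expect_true(all(m == 50))

  # inverted interval (offsets crossing) errors with the pixel
  expect_error(make_enface(fl, surfs,
                           slab_spec("SCP", "ILM", 100, "GCC_INL", -100)),
               "inverted slab interval")
})

test_that("SCP slab image peaks at every superficial lesion position", {
  b <- default_phantom_bundle()
  ph <- b$phantom
  enf <- make_enface(b$cleaned, ph$surfaces, scp_slab_spec())
  g <- ph$flow$geometry
  for (m in ph$truth$mas) {
    if (!"GCC" %in% m$layers_occupied) next
    ix <- round(m$center_um[2] / g$lateral_pitch_um + 0.5)
    iy <- round(m$center_um[3] / g$lateral_pitch_um + 0.5)
    win <- enf[max(1, ix - 3):min(g$n_x, ix + 3),
               max(1, iy - 3):min(g$n_y, iy + 3)]
    ring <- enf[max(1, ix - 8):min(g$n_x, ix + 8),
                max(1, iy - 8):min(g$n_y, iy + 8)]
    expect_gt(max(win), stats::median(ring))
  }
})

test_that("ROI is temporal and tangential to the fovea and fits the grid", {
  g <- default_phantom_geometry()
  rb <- roi_bounds(roi_spec(), g)
  fovea_x_um <- (g$fovea_xy[1] - 0.5) * g$lateral_pitch_um
  expect_equal(rb$x_um[1], fovea_x_um)        # edge touches the fovea line
  expect_equal(diff(rb$x_um), 1000)
  expect_equal(mean(rb$y_um), (g$fovea_xy[2] - 0.5) * g$lateral_pitch_um)
  # a nasal fovea with -x temporal direction has no room
  g2 <- volume_geometry(64, 128, 128, 4, 10, fovea_xy = c(14, 64),
                        temporal_direction = "-x")
  expect_error(roi_bounds(roi_spec(), g2), "does not fit")
})

test_that("an isolated Gaussian blob is detected once, at its position", {
  g <- volume_geometry(64, 128, 128, 10, 10, fovea_xy = c(14, 64))
  rb <- roi_bounds(roi_spec(), g)
  cx <- mean(rb$x_vox); cy <- mean(rb$y_vox)
  xs <- seq_len(128); sigma <- 34 / g$lateral_pitch_um  # 80 um FWHM
  img <- 200 * exp(-(outer((xs - cx)^2, (xs - cy)^2, "+")) / (2 * sigma^2))
  cands <- detect_candidates(img, roi_spec(), g, slab = "SCP")
  cands <- cands[cands$excluded_reason == "none", ]
  expect_equal(nrow(cands), 1)
  expect_lt(abs(cands$x_vox - cx), 1)
  expect_lt(abs(cands$y_vox - cy), 1)

  blank <- matrix(0, 128, 128)
  expect_equal(nrow(detect_candidates(blank, roi_spec(), g)), 0)
})

test_that("detection is translation-equivariant with the ROI", {
  g <- volume_geometry(64, 128, 128, 10, 10, fovea_xy = c(14, 54))
  g_shift <- volume_geometry(64, 128, 128, 10, 10, fovea_xy = c(14, 66))
  rb <- roi_bounds(roi_spec(), g)
  cx <- 60; cy <- 50
  xs <- seq_len(128); sigma <- 4
  blob <- function(cx, cy)
    200 * exp(-(outer((xs - cx)^2, (xs - cy)^2, "+")) / (2 * sigma^2))
  a <- detect_candidates(blob(cx, cy), roi_spec(), g)
  b <- detect_candidates(blob(cx, cy + 12), roi_spec(), g_shift)
  a <- a[a$excluded_reason == "none", ]; b <- b[b$excluded_reason == "none", ]
  expect_equal(nrow(a), 1); expect_equal(nrow(b), 1)
  expect_equal(b$x_vox, a$x_vox, tolerance = 1e-6)
  expect_equal(b$y_vox, a$y_vox + 12, tolerance = 1e-6)
})

test_that("cyst exclusion flags exactly the overlying candidates", {
  cands <- data.frame(id = 1:3, slab = "DVC", x_vox = c(5, 10, 20),
                      y_vox = c(5, 10, 20),
                      x_um = c(50, 100, 200), y_um = c(50, 100, 200),
                      excluded_reason = "none", stringsAsFactors = FALSE)
  expect_identical(exclude_over_cysts(cands, list()), cands)
  cysts <- list(list(center_xy_um = c(100, 40), radius_um = 60))
  out <- exclude_over_cysts(cands, cysts)
  # candidate 1 at distance exactly 50+... inside; candidate 2 at exactly 60
  # on the closed boundary is excluded too
  d <- sqrt((cands$x_um - 100)^2 + (cands$y_um - 40)^2)
  expect_identical(out$excluded_reason == "over_cyst", d <= 60)

  # phantom: precisely the ledger's over-cyst lesions lose their candidates
  b <- default_phantom_bundle()
  ph <- b$phantom
  det <- detect_both_slabs(b$cleaned, ph$surfaces, cysts = ph$truth$cysts)
  for (m in ph$truth$mas) {
    near <- sqrt((det$merged$x_um - m$center_um[2])^2 +
                 (det$merged$y_um - m$center_um[3])^2) < 60
    if (m$over_cyst) expect_false(any(near))
  }
})

test_that("cross-slab deduplication merges pairs and keeps the count identity", {
  set.seed(7)
  mk <- function(n, slab, xr) data.frame(
    id = seq_len(n), slab = slab,
    x_vox = 0, y_vox = 0,
    x_um = runif(n, xr[1], xr[2]), y_um = runif(n, 100, 900),
    excluded_reason = "none", stringsAsFactors = FALSE)
  # 22 SCP + 41 DVC with exactly 11 cross-slab pairs within tolerance
  scp <- mk(22, "SCP", c(100, 900))
  dvc <- mk(41, "DVC", c(1200, 2000))  # far from all SCP
  dvc$x_um[1:11] <- scp$x_um[1:11] + 10  # 11 true pairs, 10 um apart
  dvc$y_um[1:11] <- scp$y_um[1:11]
  merged <- dedup_candidates(scp, dvc, tol_um = 25)
  expect_equal(nrow(merged), 52)
  expect_equal(sum(merged$sources == "SCP+DVC"), 11)
  expect_equal(nrow(merged), nrow(scp) + nrow(dvc) - 11)

  expect_identical(nrow(dedup_candidates(scp, dvc[0, ], 25)), nrow(scp))

  # two DVC candidates within tolerance of one SCP candidate: only the
  # nearer merges (brute-force three-point configuration)
  scp1 <- mk(1, "SCP", c(500, 500))
  dvc2 <- mk(2, "DVC", c(500, 500))
  dvc2$y_um <- scp1$y_um + c(20, 8)
  m <- dedup_candidates(scp1, dvc2, tol_um = 25)
  expect_equal(nrow(m), 2)
  expect_equal(m$id_dvc[m$sources == "SCP+DVC"], 2L)

  # property: |merged| = |SCP| + |DVC| - |pairs| on random configurations
  for (k in 1:5) {
    s <- mk(sample(3:12, 1), "SCP", c(100, 900))
    d <- mk(sample(3:12, 1), "DVC", c(100, 900))
    m <- dedup_candidates(s, d, tol_um = 40)
    expect_equal(nrow(m), nrow(s) + nrow(d) - sum(m$sources == "SCP+DVC"))
  }
})
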