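## En face slab construction, ROI placement temporal/tangential to the
## fovea, blob-based MA candidate detection, cyst exclusion, and cross-slab
## deduplication.

#' En face slab specification
#'
#' A slab is the volume between two boundary surfaces (plus offsets); flow
#' within it is projected to a 2D en face image. The standard slabs are
#' provided by [scp_slab_spec()] (ILM to GCC/INL boundary) and
#' [dvc_slab_spec()] (GCC/INL to 15 um below OPL/ONL, covering the middle and
#' deep plexuses flanking the INL).
#'
#' @param name slab name, `"SCP"` or `"DVC"`.
#' @param inner,outer boundary names from [BOUNDARY_NAMES].
#' @param inner_offset_um,outer_offset_um offsets added to the boundaries
#'   (positive = deeper), in um.
#' @param projection `"max"` or `"mean"`.
#' @return an object of class `slab_spec`.
#' @export
slab_spec <- function(name, inner, inner_offset_um = 0,
                      outer, outer_offset_um = 0,
                      projection = c("max", "mean")) {
  projection <- match.arg(projection)
  stopifnot(inner %in% BOUNDARY_NAMES, outer %in% BOUNDARY_NAMES)
  structure(list(name = name, inner = inner,
                 inner_offset_um = inner_offset_um, outer = outer,
                 outer_offset_um = outer_offset_um, projection = projection),
            class = "slab_spec")
}

#' @rdname slab_spec
#' @export
scp_slab_spec <- function(projection = "mean")
  slab_spec("SCP", "ILM", 0, "GCC_INL", 0, projection)

#' @rdname slab_spec
#' @export
dvc_slab_spec <- function(projection = "mean")
  slab_spec("DVC", "GCC_INL", 0, "OPL_ONL", 15, projection)

#' Analysis region of interest
#'
#' A square ROI placed temporally and tangentially to the foveal center: the
#' nearest vertical edge touches the fovea's x position (gap `gap_um`), and
#' the square is vertically centered on the fovea.
#'
#' @param side_um side length in um (default 1 mm).
#' @param gap_um gap between the foveal center and the near ROI edge.
#' @return an object of class `roi_spec`.
#' @export
roi_spec <- function(side_um = 1000, gap_um = 0)
  structure(list(side_um = side_um, gap_um = gap_um), class = "roi_spec")

#' Resolve ROI bounds on a given grid
#'
#' @param roi a [roi_spec()].
#' @param geometry a [volume_geometry()].
#' @return list with `x_um`, `y_um` (physical bounds) and `x_vox`, `y_vox`
#'   (1-based voxel index ranges of voxels whose centers fall inside).
#' @export
roi_bounds <- function(roi, geometry) {
  g <- geometry
  fx <- lateral_um(g$fovea_xy[1], g); fy <- lateral_um(g$fovea_xy[2], g)
  x_um <- if (g$temporal_direction == "+x")
    c(fx + roi$gap_um, fx + roi$gap_um + roi$side_um)
  else
    c(fx - roi$gap_um - roi$side_um, fx - roi$gap_um)
  y_um <- c(fy - roi$side_um / 2, fy + roi$side_um / 2)
  lp <- g$lateral_pitch_um
  x_vox <- c(ceiling(x_um[1] / lp + 0.5), floor(x_um[2] / lp + 0.5))
  y_vox <- c(ceiling(y_um[1] / lp + 0.5), floor(y_um[2] / lp + 0.5))
  if (x_vox[1] < 1 || x_vox[2] > g$n_x || y_vox[1] < 1 || y_vox[2] > g$n_y)
    stop("ROI does not fit inside the lateral grid")
  list(x_um = x_um, y_um = y_um, x_vox = x_vox, y_vox = y_vox)
}

#' Project a flow volume to an en face slab image
#'
#' Pixel (x, y) is the max or mean of flow over the half-open depth interval
#' `[inner + inner_offset, outer + outer_offset)` at that position, with
#' voxel centers at depth `i - 0.5`.
#'
#' @param flow a [flow_volume()].
#' @param surfs a [layer_surfaces()].
#' @param spec a [slab_spec()].
#' @return numeric `n_x` by `n_y` matrix (intensity 0-255), with the slab
#'   name attached as attribute `"slab"`.
#' @export
make_enface <- function(flow, surfs, spec) {
  stopifnot(inherits(flow, "flow_volume"), inherits(surfs, "layer_surfaces"),
            inherits(spec, "slab_spec"))
  g <- flow$geometry
  inner <- surfs$surfaces[[spec$inner]] + spec$inner_offset_um / g$axial_pitch_um
  outer <- surfs$surfaces[[spec$outer]] + spec$outer_offset_um / g$axial_pitch_um
  if (any(inner >= outer)) {
    bad <- which(inner >= outer, arr.ind = TRUE)[1, ]
    stop(sprintf("inverted slab interval at (x=%d, y=%d)", bad[1], bad[2]))
  }
  acc <- matrix(0, g$n_x, g$n_y)
  cnt <- matrix(0, g$n_x, g$n_y)
  for (z in seq_len(g$n_axial)) {
    zc <- z - 0.5
    inslab <- zc >= inner & zc < outer
    if (!any(inslab)) next
    slice <- flow$voxels[z, , ]
    if (spec$projection == "max") {
      acc[inslab] <- pmax(acc[inslab], slice[inslab])
    } else {
      acc[inslab] <- acc[inslab] + slice[inslab]
      cnt[inslab] <- cnt[inslab] + 1
    }
  }
  if (spec$projection == "mean") acc <- acc / pmax(cnt, 1)
  attr(acc, "slab") <- spec$name
  acc
}

#' Depth of peak flow within a slab at a lateral position
#'
#' Used to seed 3D lesion segmentation from an en face candidate.
#'
#' @param flow a [flow_volume()].
#' @param surfs a [layer_surfaces()].
#' @param spec a [slab_spec()].
#' @param x,y 1-based lateral voxel indices.
#' @return 1-based axial voxel index of the maximum flow inside the slab.
#' @export
slab_seed_depth <- function(flow, surfs, spec, x, y) {
  g <- flow$geometry
  inner <- surfs$surfaces[[spec$inner]][x, y] +
    spec$inner_offset_um / g$axial_pitch_um
  outer <- surfs$surfaces[[spec$outer]][x, y] +
    spec$outer_offset_um / g$axial_pitch_um
  zr <- seq_len(g$n_axial)
  zr <- zr[(zr - 0.5) >= inner & (zr - 0.5) < outer]
  if (!length(zr)) return(NA_integer_)
  zr[which.max(flow$voxels[cbind(zr, x, y)])]
}

#' Detect microaneurysm candidates on an en face slab image
#'
#' Blob detection standing in for a human grader: the image background is
#' removed with a running median (radius `bg_radius_um`), thin linear vessels
#' are suppressed with a grayscale morphological opening (3x3 cross), the
#' result is thresholded by Otsu's method computed within the ROI, and
#' connected bright regions with equivalent diameter in
#' `[min_diam_um, max_diam_um]` and circularity >= `min_circ` are kept.
#' Candidates whose center falls outside the ROI are returned with
#' `excluded_reason = "outside_roi"`.
#'
#' @param enface matrix from [make_enface()].
#' @param roi a [roi_spec()].
#' @param geometry a [volume_geometry()].
#' @param slab slab name recorded on the candidates (defaults to the
#'   `"slab"` attribute of `enface`).
#' @param min_diam_um,max_diam_um equivalent-diameter gate, um.
#' @param min_circ minimum circularity `4*pi*area/perimeter^2`.
#' @param bg_radius_um radius of the median background filter, um.
#' @param min_contrast minimum lesion contrast over background (0-1 scale)
#'   accepted as a threshold. Guards the degenerate case of a lesion-free
#'   ROI, where Otsu would otherwise split background from the capillary
#'   mesh: a mean-projected capillary (2-5 of ~23 slab voxels) stays below
#'   ~0.17 while the dimmest lesions exceed ~0.24.
#' @return data.frame of candidates: `id`, `slab`, `x_vox`, `y_vox`
#'   (centroid, fractional), `x_um`, `y_um`, `excluded_reason`
#'   (`"none"` or `"outside_roi"`).
#' @export
detect_candidates <- function(enface, roi, geometry,
                              slab = attr(enface, "slab"),
                              min_diam_um = 20, max_diam_um = 200,
                              min_circ = 0.5, bg_radius_um = 100,
                              min_contrast = 0.18) {
  g <- geometry
  rb <- roi_bounds(roi, g)
  img <- enface / 255
  bg <- EBImage::medianFilter(img, max(1L, round(bg_radius_um /
                                                   g$lateral_pitch_um)))
  sub <- pmax(img - bg, 0)
  roi_vals <- sub[rb$x_vox[1]:rb$x_vox[2], rb$y_vox[1]:rb$y_vox[2]]
  thr <- if (max(roi_vals) > min(roi_vals))
    EBImage::otsu(roi_vals, range = c(0, 1)) else Inf
  thr <- max(thr, min_contrast)
  ## binary opening (3x3 cross) detaches and deletes sub-resolution
  ## capillary lines, leaving compact lesion blobs
  bw <- EBImage::opening(sub > thr, EBImage::makeBrush(3, "diamond"))
  empty <- data.frame(id = integer(0), slab = character(0),
                      x_vox = numeric(0), y_vox = numeric(0),
                      x_um = numeric(0), y_um = numeric(0),
                      excluded_reason = character(0),
                      stringsAsFactors = FALSE)
  if (!any(bw)) return(empty)
  lab <- EBImage::bwlabel(bw)
  shp <- EBImage::computeFeatures.shape(lab)
  mom <- EBImage::computeFeatures.moment(lab)
  if (is.null(shp) || nrow(shp) == 0) return(empty)
  eq_diam <- 2 * sqrt(shp[, "s.area"] / pi) * g$lateral_pitch_um
  circ <- 4 * pi * shp[, "s.area"] / pmax(shp[, "s.perimeter"], 1)^2
  keep <- eq_diam >= min_diam_um & eq_diam <= max_diam_um & circ >= min_circ
  if (!any(keep)) return(empty)
  cx <- mom[keep, "m.cx"]; cy <- mom[keep, "m.cy"]
  x_um <- (cx - 0.5) * g$lateral_pitch_um
  y_um <- (cy - 0.5) * g$lateral_pitch_um
  inside <- x_um >= rb$x_um[1] & x_um <= rb$x_um[2] &
            y_um >= rb$y_um[1] & y_um <= rb$y_um[2]
  data.frame(id = seq_along(cx),
             slab = if (is.null(slab)) NA_character_ else slab,
             x_vox = cx, y_vox = cy, x_um = x_um, y_um = y_um,
             excluded_reason = ifelse(inside, "none", "outside_roi"),
             stringsAsFactors = FALSE)
}

#' Exclude candidates lying over intraretinal cysts
#'
#' OCTA can display pseudoflow within cysts and cysts distort the layered
#' architecture, so candidates topographically over a cyst are flagged.
#' Footprints are closed: a candidate exactly on the boundary is excluded.
#'
#' @param cands candidate data.frame from [detect_candidates()] or
#'   [dedup_candidates()].
#' @param cysts either the `cysts` element of a `phantom_truth` (list of
#'   `center_xy_um` + `radius_um`) or a logical `n_x` by `n_y` footprint
#'   matrix.
#' @param geometry a [volume_geometry()] (needed for the matrix form).
#' @return `cands` with `excluded_reason = "over_cyst"` where applicable.
#' @export
exclude_over_cysts <- function(cands, cysts, geometry = NULL) {
  if (!nrow(cands)) return(cands)
  over <- rep(FALSE, nrow(cands))
  if (is.matrix(cysts)) {
    stopifnot(!is.null(geometry))
    ix <- pmin(pmax(round(cands$x_um / geometry$lateral_pitch_um + 0.5), 1),
               geometry$n_x)
    iy <- pmin(pmax(round(cands$y_um / geometry$lateral_pitch_um + 0.5), 1),
               geometry$n_y)
    over <- cysts[cbind(ix, iy)]
  } else {
    for (cy in cysts) {
      d <- sqrt((cands$x_um - cy$center_xy_um[1])^2 +
                (cands$y_um - cy$center_xy_um[2])^2)
      over <- over | d <= cy$radius_um
    }
  }
  cands$excluded_reason[over & cands$excluded_reason == "none"] <- "over_cyst"
  cands
}

#' Merge candidates seen on both SCP and DVC slabs
#'
#' Lesions detected on both en face images are included once and considered
#' visualized on both. Greedy nearest-pair matching within `tol_um` lateral
#' distance; ties are broken by the smaller candidate id.
#'
#' @param scp_cands,dvc_cands candidate data.frames (typically already
#'   filtered to `excluded_reason == "none"`).
#' @param tol_um lateral merge tolerance (default 25 um, about twice the
#'   device's lateral resolution step).
#' @return data.frame with one row per merged lesion: `sources` is
#'   `"SCP"`, `"DVC"` or `"SCP+DVC"`; `id_scp`/`id_dvc` reference the input
#'   candidates; `x_um`, `y_um` is the (mean) center.
#' @export
dedup_candidates <- function(scp_cands, dvc_cands, tol_um = 25) {
  stopifnot(tol_um >= 0)
  n1 <- nrow(scp_cands); n2 <- nrow(dvc_cands)
  pairs <- NULL
  if (n1 > 0 && n2 > 0) {
    d <- outer(scp_cands$x_um, dvc_cands$x_um, "-")^2 +
         outer(scp_cands$y_um, dvc_cands$y_um, "-")^2
    cand <- which(d <= tol_um^2, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(d[cand], scp_cands$id[cand[, 1]], dvc_cands$id[cand[, 2]])
      cand <- cand[ord, , drop = FALSE]
      used1 <- logical(n1); used2 <- logical(n2)
      keep <- logical(nrow(cand))
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used1[i] && !used2[j]) {
          used1[i] <- TRUE; used2[j] <- TRUE; keep[k] <- TRUE
        }
      }
      pairs <- cand[keep, , drop = FALSE]
    }
  }
  rows <- list()
  matched1 <- if (!is.null(pairs)) pairs[, 1] else integer(0)
  matched2 <- if (!is.null(pairs)) pairs[, 2] else integer(0)
  if (!is.null(pairs) && nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      rows[[length(rows) + 1]] <- data.frame(
        sources = "SCP+DVC", id_scp = scp_cands$id[i],
        id_dvc = dvc_cands$id[j],
        x_um = (scp_cands$x_um[i] + dvc_cands$x_um[j]) / 2,
        y_um = (scp_cands$y_um[i] + dvc_cands$y_um[j]) / 2,
        stringsAsFactors = FALSE)
    }
  }
  for (i in setdiff(seq_len(n1), matched1))
    rows[[length(rows) + 1]] <- data.frame(
      sources = "SCP", id_scp = scp_cands$id[i], id_dvc = NA_integer_,
      x_um = scp_cands$x_um[i], y_um = scp_cands$y_um[i],
      stringsAsFactors = FALSE)
  for (j in setdiff(seq_len(n2), matched2))
    rows[[length(rows) + 1]] <- data.frame(
      sources = "DVC", id_scp = NA_integer_, id_dvc = dvc_cands$id[j],
      x_um = dvc_cands$x_um[j], y_um = dvc_cands$y_um[j],
      stringsAsFactors = FALSE)
  if (!length(rows))
    return(data.frame(sources = character(0), id_scp = integer(0),
                      id_dvc = integer(0), x_um = numeric(0),
                      y_um = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$merged_id <- seq_len(nrow(out))
  out
}
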