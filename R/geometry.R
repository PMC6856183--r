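## Core containers: scan geometry, flow/structural volumes, layer surfaces.
## Arrays are indexed (axial, x, y), 1-based, with depth increasing with the
## axial index. Continuous depth coordinates (layer surfaces, slab limits)
## live on the [0, n_axial) scale where voxel i occupies [i-1, i), so the
## center of voxel i is at depth i - 0.5 voxels.

#' Boundary surface names, innermost to outermost
#'
#' The seven retinal boundary surfaces used throughout the package, ordered
#' from the inner limiting membrane (ILM) to Bruch's membrane (BM). GCC_INL is
#' the boundary between the ganglion cell complex and the inner nuclear layer.
#' @export
BOUNDARY_NAMES <- c("ILM", "GCC_INL", "INL_OPL", "OPL_ONL",
                    "ONL_outer", "RPE", "BM")

#' Retinal layer names graded for occupancy
#' @export
LAYER_NAMES <- c("GCC", "INL", "OPL", "ONL")

#' Construct scan geometry
#'
#' Describes the voxel grid of a co-registered OCTA/OCT acquisition: axial
#' voxel count first (depth increases with index), then the two lateral axes.
#' Defaults mirror a 3 x 3 mm macular scan sampled at 300 A-scans per B-scan
#' (10 um lateral pitch).
#'
#' @param n_axial,n_x,n_y voxel counts; axial is the first array axis.
#' @param axial_pitch_um,lateral_pitch_um physical voxel size in micrometers.
#' @param fovea_xy integer (x, y) voxel coordinates (1-based) of the foveal
#'   center.
#' @param temporal_direction which lateral direction points temporally,
#'   `"+x"` or `"-x"`; the analysis ROI is placed on this side of the fovea.
#' @return an object of class `volume_geometry`.
#' @export
volume_geometry <- function(n_axial, n_x, n_y,
                            axial_pitch_um, lateral_pitch_um = 10,
                            fovea_xy = c(round(n_x / 2), round(n_y / 2)),
                            temporal_direction = c("+x", "-x")) {
  temporal_direction <- match.arg(temporal_direction)
  counts <- c(n_axial = n_axial, n_x = n_x, n_y = n_y)
  if (any(counts < 8))
    stop("all voxel counts must be >= 8, got ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  if (axial_pitch_um <= 0 || lateral_pitch_um <= 0)
    stop("voxel pitches must be positive")
  fovea_xy <- as.numeric(fovea_xy)
  if (length(fovea_xy) != 2 ||
      fovea_xy[1] < 1 || fovea_xy[1] > n_x ||
      fovea_xy[2] < 1 || fovea_xy[2] > n_y)
    stop("fovea_xy must lie inside the lateral grid")
  structure(list(
    n_axial = as.integer(n_axial), n_x = as.integer(n_x),
    n_y = as.integer(n_y),
    axial_pitch_um = as.numeric(axial_pitch_um),
    lateral_pitch_um = as.numeric(lateral_pitch_um),
    fovea_xy = fovea_xy,
    temporal_direction = temporal_direction
  ), class = "volume_geometry")
}

#' @export
print.volume_geometry <- function(x, ...) {
  cat(sprintf(
    "volume_geometry: %d (axial) x %d x %d voxels, %.3g x %.3g um pitch\n",
    x$n_axial, x$n_x, x$n_y, x$axial_pitch_um, x$lateral_pitch_um))
  cat(sprintf("  fovea at (%g, %g), temporal = %s\n",
              x$fovea_xy[1], x$fovea_xy[2], x$temporal_direction))
  invisible(x)
}

geom_dim <- function(geometry) c(geometry$n_axial, geometry$n_x, geometry$n_y)

geom_equal <- function(a, b) {
  identical(geom_dim(a), geom_dim(b)) &&
    isTRUE(all.equal(a$axial_pitch_um, b$axial_pitch_um)) &&
    isTRUE(all.equal(a$lateral_pitch_um, b$lateral_pitch_um))
}

new_volume <- function(voxels, geometry, kind) {
  stopifnot(inherits(geometry, "volume_geometry"))
  voxels <- as.array(voxels)
  if (!identical(dim(voxels), geom_dim(geometry)))
    stop("voxel array shape (", paste(dim(voxels), collapse = "x"),
         ") does not match geometry (",
         paste(geom_dim(geometry), collapse = "x"), ")")
  if (anyNA(voxels) || min(voxels) < 0 || max(voxels) > 255)
    stop("voxel values must be integers in [0, 255]")
  storage.mode(voxels) <- "integer"
  structure(list(voxels = voxels, geometry = geometry),
            class = c(paste0(kind, "_volume"), "octa_volume"))
}

#' OCTA flow volume
#'
#' An 8-bit flow-intensity volume indexed `(axial, x, y)` with depth
#' increasing along the first axis.
#'
#' @param voxels integer array, values 0-255, dimensions matching `geometry`.
#' @param geometry a [volume_geometry()].
#' @return an object of class `flow_volume`.
#' @export
flow_volume <- function(voxels, geometry) new_volume(voxels, geometry, "flow")

#' Structural OCT volume
#'
#' An 8-bit reflectance volume co-registered with a [flow_volume()].
#' @inheritParams flow_volume
#' @return an object of class `struct_volume`.
#' @export
struct_volume <- function(voxels, geometry) new_volume(voxels, geometry, "struct")

#' @export
print.octa_volume <- function(x, ...) {
  cat(sprintf("%s: %s voxels, intensity range [%d, %d]\n",
              class(x)[1], paste(dim(x$voxels), collapse = " x "),
              min(x$voxels), max(x$voxels)))
  print(x$geometry)
  invisible(x)
}

#' Retinal layer boundary surfaces
#'
#' Per-(x, y) axial depth maps for the seven boundary surfaces in
#' [BOUNDARY_NAMES], in fractional voxel units on `[0, n_axial)` (voxel `i`
#' occupies depth `[i-1, i)`). Depths must strictly increase from ILM to BM at
#' every lateral position.
#'
#' @param surfaces named list of `n_x` by `n_y` numeric matrices, one per
#'   boundary in [BOUNDARY_NAMES].
#' @param geometry a [volume_geometry()].
#' @return an object of class `layer_surfaces`.
#' @export
layer_surfaces <- function(surfaces, geometry) {
  stopifnot(inherits(geometry, "volume_geometry"))
  missing <- setdiff(BOUNDARY_NAMES, names(surfaces))
  if (length(missing))
    stop("missing boundary surface(s): ", paste(missing, collapse = ", "))
  surfaces <- surfaces[BOUNDARY_NAMES]
  for (nm in BOUNDARY_NAMES) {
    m <- surfaces[[nm]]
    if (!is.matrix(m) || !identical(dim(m), c(geometry$n_x, geometry$n_y)))
      stop("surface ", nm, " must be an n_x by n_y matrix")
    if (anyNA(m) || min(m) < 0 || max(m) >= geometry$n_axial)
      stop("surface ", nm, " has depths outside [0, n_axial)")
  }
  for (k in seq_len(length(BOUNDARY_NAMES) - 1)) {
    d <- surfaces[[BOUNDARY_NAMES[k + 1]]] - surfaces[[BOUNDARY_NAMES[k]]]
    if (any(d <= 0)) {
      bad <- which(d <= 0, arr.ind = TRUE)[1, ]
      stop(sprintf(
        "boundary order violation: %s not above %s at (x=%d, y=%d)",
        BOUNDARY_NAMES[k], BOUNDARY_NAMES[k + 1], bad[1], bad[2]))
    }
  }
  structure(list(surfaces = surfaces, geometry = geometry),
            class = "layer_surfaces")
}

#' @export
print.layer_surfaces <- function(x, ...) {
  rng <- vapply(x$surfaces, function(m) mean(m), numeric(1))
  cat("layer_surfaces (mean depth, voxels):\n")
  for (nm in BOUNDARY_NAMES) cat(sprintf("  %-9s %7.2f\n", nm, rng[[nm]]))
  invisible(x)
}

## Half-open depth intervals (in fractional voxel units) of the four graded
## retinal layers, as matrices over the lateral grid.
layer_interval <- function(surfs, layer) {
  s <- surfs$surfaces
  switch(layer,
    GCC = list(inner = s$ILM,     outer = s$GCC_INL),
    INL = list(inner = s$GCC_INL, outer = s$INL_OPL),
    OPL = list(inner = s$INL_OPL, outer = s$OPL_ONL),
    ONL = list(inner = s$OPL_ONL, outer = s$ONL_outer),
    stop("unknown layer: ", layer))
}

## physical coordinates (um) of voxel centers; i is 1-based index vector
axial_um <- function(i, geometry) (i - 0.5) * geometry$axial_pitch_um
lateral_um <- function(i, geometry) (i - 0.5) * geometry$lateral_pitch_um
voxel_diag_um <- function(geometry)
  sqrt(geometry$axial_pitch_um^2 + 2 * geometry$lateral_pitch_um^2)
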