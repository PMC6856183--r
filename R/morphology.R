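## Internal 3D array utilities: connected components (Rcpp BFS), cross-shaped
## (6-neighbour) erosion/dilation via array shifts, index conversions, and
## physical-unit ball offsets. Arrays are (axial, x, y).

label3d <- function(mask, connectivity = 26L) {
  stopifnot(length(dim(mask)) == 3)
  m <- mask
  m[is.na(m)] <- FALSE
  .label3d_cpp(as.logical(m), dim(mask), as.integer(connectivity))
}

shift3d <- function(arr, dz = 0L, dx = 0L, dy = 0L, fill = FALSE) {
  d <- dim(arr)
  out <- array(fill, dim = d)
  src_z <- seq_len(d[1]) - dz; src_x <- seq_len(d[2]) - dx
  src_y <- seq_len(d[3]) - dy
  okz <- src_z >= 1 & src_z <= d[1]
  okx <- src_x >= 1 & src_x <= d[2]
  oky <- src_y >= 1 & src_y <= d[3]
  out[okz, okx, oky] <- arr[src_z[okz], src_x[okx], src_y[oky]]
  out
}

dilate6 <- function(mask) {
  mask | shift3d(mask, 1) | shift3d(mask, -1) |
    shift3d(mask, 0, 1) | shift3d(mask, 0, -1) |
    shift3d(mask, 0, 0, 1) | shift3d(mask, 0, 0, -1)
}

erode6 <- function(mask) {
  mask & shift3d(mask, 1) & shift3d(mask, -1) &
    shift3d(mask, 0, 1) & shift3d(mask, 0, -1) &
    shift3d(mask, 0, 0, 1) & shift3d(mask, 0, 0, -1)
}

## morphological opening with the 6-neighbour cross element
open6 <- function(mask) dilate6(erode6(mask))

## lateral-only (x,y 4-neighbour) erosion/dilation: removes structures that
## are thin in the en face plane (capillaries) without clipping lesions that
## are only a couple of voxels thick axially
erode_lat <- function(mask) {
  mask & shift3d(mask, 0, 1) & shift3d(mask, 0, -1) &
    shift3d(mask, 0, 0, 1) & shift3d(mask, 0, 0, -1)
}
dilate_lat <- function(mask) {
  mask | shift3d(mask, 0, 1) | shift3d(mask, 0, -1) |
    shift3d(mask, 0, 0, 1) | shift3d(mask, 0, 0, -1)
}
open_lat <- function(mask) dilate_lat(erode_lat(mask))

idx_to_zxy <- function(idx, dims) {
  idx0 <- idx - 1L
  z <- idx0 %% dims[1]
  x <- (idx0 %/% dims[1]) %% dims[2]
  y <- idx0 %/% (dims[1] * dims[2])
  cbind(z = z + 1L, x = x + 1L, y = y + 1L)
}

zxy_to_idx <- function(zxy, dims) {
  (zxy[, 1]) + dims[1] * (zxy[, 2] - 1L) + dims[1] * dims[2] * (zxy[, 3] - 1L)
}

## physical coordinates (um) of voxels given by linear indices
idx_to_um <- function(idx, geometry) {
  zxy <- idx_to_zxy(idx, geom_dim(geometry))
  cbind(z = (zxy[, 1] - 0.5) * geometry$axial_pitch_um,
        x = (zxy[, 2] - 0.5) * geometry$lateral_pitch_um,
        y = (zxy[, 3] - 0.5) * geometry$lateral_pitch_um)
}

## Otsu threshold on arbitrary non-negative values scaled to [0, 1]
otsu_threshold <- function(values, levels = 256L) {
  values <- values[is.finite(values)]
  if (!length(values) || max(values) <= min(values)) return(Inf)
  lo <- min(values); hi <- max(values)
  scaled <- matrix((values - lo) / (hi - lo), nrow = 1)
  thr <- EBImage::otsu(scaled, range = c(0, 1), levels = levels)
  lo + thr * (hi - lo)
}
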