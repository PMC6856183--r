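## Readers/writers for the interchange formats the pipeline touches:
## uncompressed 8-bit raw volumes with a JSON geometry sidecar, multi-page
## grayscale TIFF stacks, and layer surfaces as long-format CSV.

AXIS_TOKENS <- c("axial", "x", "y")

geometry_to_list <- function(geometry, shape, axis_order) {
  list(shape = as.integer(shape),
       axis_order = axis_order,
       axial_pitch_um = geometry$axial_pitch_um,
       lateral_pitch_um = geometry$lateral_pitch_um,
       fovea_xy = geometry$fovea_xy,
       temporal_direction = geometry$temporal_direction)
}

geometry_from_list <- function(lst) {
  ord <- match(AXIS_TOKENS, lst$axis_order)
  shape_axial_first <- as.integer(lst$shape)[ord]
  volume_geometry(
    n_axial = shape_axial_first[1], n_x = shape_axial_first[2],
    n_y = shape_axial_first[3],
    axial_pitch_um = lst$axial_pitch_um,
    lateral_pitch_um = lst$lateral_pitch_um,
    fovea_xy = unlist(lst$fovea_xy),
    temporal_direction = lst$temporal_direction)
}

#' Read an uncompressed 8-bit raw volume with its geometry sidecar
#'
#' The sidecar is a JSON file declaring the on-disk array `shape`, the
#' `axis_order` (a permutation of `"axial"`, `"x"`, `"y"`; fastest-varying
#' axis first, i.e. column-major), voxel pitches, foveal position and temporal
#' direction. The returned volume is always axial-first regardless of the
#' on-disk order.
#'
#' @param path raw data file, one unsigned byte per voxel.
#' @param sidecar path to the JSON geometry descriptor.
#' @param kind `"flow"` or `"struct"`.
#' @return a [flow_volume()] or [struct_volume()].
#' @export
read_raw_volume <- function(path, sidecar, kind = c("flow", "struct")) {
  kind <- match.arg(kind)
  lst <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(lst$axis_order) ||
      !setequal(lst$axis_order, AXIS_TOKENS) ||
      length(lst$axis_order) != 3)
    stop("sidecar axis_order must be a permutation of ",
         paste(AXIS_TOKENS, collapse = ", "), "; got: ",
         paste(lst$axis_order, collapse = ", "))
  shape <- as.integer(lst$shape)
  expected <- prod(shape)
  actual <- file.size(path)
  if (is.na(actual) || actual != expected)
    stop(sprintf("raw file size mismatch: expected %d bytes (%s), found %s",
                 expected, paste(shape, collapse = "x"),
                 ifelse(is.na(actual), "missing file", actual)))
  bytes <- readBin(path, what = "integer", n = expected, size = 1,
                   signed = FALSE)
  arr <- array(bytes, dim = shape)
  perm <- match(AXIS_TOKENS, lst$axis_order)
  arr <- aperm(arr, perm)
  new_volume(arr, geometry_from_list(lst), kind)
}

#' Write a volume as uncompressed 8-bit raw data plus JSON sidecar
#'
#' Bytes are written axial-first (axial fastest-varying); the sidecar records
#' the full geometry so the pair round-trips through [read_raw_volume()].
#'
#' @param vol a [flow_volume()] or [struct_volume()].
#' @param path,sidecar_path output paths for the raw bytes and JSON sidecar.
#' @export
write_raw_volume <- function(vol, path, sidecar_path) {
  stopifnot(inherits(vol, "octa_volume"))
  writeBin(as.raw(as.integer(vol$voxels)), path)
  jsonlite::write_json(
    geometry_to_list(vol$geometry, dim(vol$voxels), AXIS_TOKENS),
    sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Read a multi-page 8-bit grayscale TIFF as a volume
#'
#' Page `k` of the stack becomes axial slice `k`; each page is an `n_x` by
#' `n_y` matrix. TIFF files carry no physical geometry, so a
#' [volume_geometry()] may be supplied; otherwise the device-style defaults
#' of [default_phantom_geometry()] pitches (11.72 um axial, 10 um lateral)
#' are assumed.
#'
#' @param path TIFF file.
#' @param geometry optional [volume_geometry()] consistent with the stack.
#' @param kind `"flow"` or `"struct"`.
#' @return a [flow_volume()] or [struct_volume()].
#' @export
read_tiff_stack <- function(path, geometry = NULL, kind = c("flow", "struct")) {
  kind <- match.arg(kind)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- lapply(pages, dim)
  if (any(vapply(dims, length, 1L) != 2))
    stop("expected single-channel 8-bit pages; found multi-channel page")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    stop("ragged TIFF stack: pages have differing dimensions")
  if (max(vapply(pages, max, 0)) > 255 || min(vapply(pages, min, 0)) < 0)
    stop("expected single-channel 8-bit pages; values outside [0, 255]")
  arr <- array(0L, dim = c(length(pages), dims[[1]][1], dims[[1]][2]))
  for (k in seq_along(pages)) arr[k, , ] <- pages[[k]]
  if (is.null(geometry))
    geometry <- volume_geometry(dim(arr)[1], dim(arr)[2], dim(arr)[3],
                                axial_pitch_um = 3000 / 256,
                                lateral_pitch_um = 10)
  new_volume(arr, geometry, kind)
}

#' Write a volume as a multi-page 8-bit grayscale TIFF
#'
#' @param vol a [flow_volume()] or [struct_volume()].
#' @param path output TIFF path.
#' @export
write_tiff_stack <- function(vol, path) {
  stopifnot(inherits(vol, "octa_volume"))
  pages <- lapply(seq_len(dim(vol$voxels)[1]),
                  function(k) vol$voxels[k, , ] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8, compression = "none")
  invisible(NULL)
}

#' Read layer boundary surfaces from long-format CSV
#'
#' Columns `x, y, boundary, depth`: 1-based lateral voxel indices, boundary
#' name from [BOUNDARY_NAMES], and fractional axial depth in voxel units. All
#' seven boundaries must be present at every lateral position; the strict
#' inner-to-outer ordering is validated on load.
#'
#' @param path CSV file.
#' @param geometry a [volume_geometry()] describing the grid.
#' @return a [layer_surfaces()].
#' @export
read_surfaces <- function(path, geometry) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "boundary", "depth")
  if (!all(need %in% names(df)))
    stop("surfaces CSV must have columns: ", paste(need, collapse = ", "))
  missing <- setdiff(BOUNDARY_NAMES, unique(df$boundary))
  if (length(missing))
    stop("missing boundary surface(s): ", paste(missing, collapse = ", "))
  surfaces <- lapply(BOUNDARY_NAMES, function(nm) {
    sub <- df[df$boundary == nm, ]
    m <- matrix(NA_real_, geometry$n_x, geometry$n_y)
    m[cbind(sub$x, sub$y)] <- sub$depth
    if (anyNA(m)) stop("surface ", nm, " does not cover the lateral grid")
    m
  })
  names(surfaces) <- BOUNDARY_NAMES
  layer_surfaces(surfaces, geometry)
}

#' Write layer boundary surfaces as long-format CSV
#'
#' @param surfs a [layer_surfaces()].
#' @param path output CSV path.
#' @export
write_surfaces <- function(surfs, path) {
  stopifnot(inherits(surfs, "layer_surfaces"))
  g <- surfs$geometry
  grid <- expand.grid(x = seq_len(g$n_x), y = seq_len(g$n_y))
  df <- do.call(rbind, lapply(BOUNDARY_NAMES, function(nm) {
    data.frame(x = grid$x, y = grid$y, boundary = nm,
               depth = surfs$surfaces[[nm]][cbind(grid$x, grid$y)])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(NULL)
}
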