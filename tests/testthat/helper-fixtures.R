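# Shared fixtures: small geometries, flat layer stacks, and a lazily cached
# default phantom (generation plus artifact removal is the expensive part of
# the suite, so the seed-1 bundle is built once and reused).

small_geometry <- function(n_axial = 64, n_x = 24, n_y = 24,
                           axial_pitch_um = 10, lateral_pitch_um = 10)
  volume_geometry(n_axial, n_x, n_y, axial_pitch_um, lateral_pitch_um)

# flat boundary stack at the given depths (fractional voxel units)
flat_surfaces <- function(geometry,
                          depths = c(ILM = 8, GCC_INL = 17, INL_OPL = 26,
                                     OPL_ONL = 35, ONL_outer = 44, RPE = 53,
                                     BM = 56)) {
  surfaces <- lapply(depths, function(d)
    matrix(d, geometry$n_x, geometry$n_y))
  names(surfaces) <- names(depths)
  layer_surfaces(surfaces, geometry)
}

# a flow volume containing one or more digitized balls (value 235)
ball_flow <- function(geometry, centers_um, radii_um, value = 235L) {
  vox <- array(0L, dim = c(geometry$n_axial, geometry$n_x, geometry$n_y))
  zs <- (seq_len(geometry$n_axial) - 0.5) * geometry$axial_pitch_um
  xs <- (seq_len(geometry$n_x) - 0.5) * geometry$lateral_pitch_um
  ys <- (seq_len(geometry$n_y) - 0.5) * geometry$lateral_pitch_um
  for (k in seq_len(nrow(centers_um))) {
    d2 <- outer(outer((zs - centers_um[k, 1])^2, (xs - centers_um[k, 2])^2,
                      "+"), (ys - centers_um[k, 3])^2, "+")
    vox[d2 <= radii_um[k]^2] <- value
  }
  flow_volume(vox, geometry)
}

um_to_vox <- function(p_um, geometry)
  c(round(p_um[1] / geometry$axial_pitch_um + 0.5),
    round(p_um[2] / geometry$lateral_pitch_um + 0.5),
    round(p_um[3] / geometry$lateral_pitch_um + 0.5))

# cached seed-1 default phantom with its cleaned volume
.phantom_cache <- new.env(parent = emptyenv())
default_phantom_bundle <- function() {
  if (is.null(.phantom_cache$bundle)) {
    ph <- generate_phantom(phantom_config(rng_seed = 1))
    cleaned <- remove_projection(ph$flow, ph$struct, removal_config())
    .phantom_cache$bundle <- list(phantom = ph, cleaned = cleaned)
  }
  .phantom_cache$bundle
}
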