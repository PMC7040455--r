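#' Fractional coordinates within the interpolation cube
#'
#' For a photon at `pos` (voxel coordinates, centroids at half-integers), the
#' fraction along each axis is `coord - round(coord) + 0.5` with round =
#' half-away-from-zero, so a query at a voxel centroid gives fraction 0 (its
#' own voxel's vertex) and a query on a voxel face gives 0.5.
#'
#' @param pos position triple in voxel coordinates.
#' @return Numeric triple `(xd, yd, zd)` in `[0, 1]`.
#' @export
fractional_coords <- function(pos) {
  cpp_frac_coords(as.numeric(pos))
}

#' Build the same-medium interpolation cube at a position
#'
#' The eight vertices are the centroids of the voxels bracketing `pos` (lower
#' corner index `round(coord) - 1` per axis). A vertex's mask bit is set iff
#' its voxel's refractive index equals that of the photon's current voxel;
#' vertices outside the grid are masked out.
#'
#' @param pos position in voxel coordinates.
#' @param voxel the photon's current (pre-crossing) voxel index, 0-based triple.
#' @param volume a [labeled_volume()].
#' @param media a [medium_table()].
#' @param normal_map a `normal_map` from [compute_normal_map()].
#' @return List with `vertices` (8 x 3, vertex order x-fastest), `mask`
#'   (8 logicals), `fractions` and `lower_corner`.
#' @export
build_interp_cube <- function(pos, voxel, volume, media, normal_map) {
  check_media_cover(volume, media)
  n_of <- rep(NA_real_, max(media$label) + 1L)
  n_of[media$label + 1L] <- media$n
  cpp_build_cube(as.numeric(pos), as.integer(voxel), volume$labels,
                 as.integer(volume$shape), n_of,
                 as.numeric(normal_map$gx), as.numeric(normal_map$gy),
                 as.numeric(normal_map$gz))
}

#' Masked trilinear interpolation of vertex normals
#'
#' Applies the masked trilinear blend componentwise (masked vertices
#' contribute zero; the blend is not re-weighted by the active mask sum), then
#' normalizes to unit length. A (near-)zero blend returns the zero vector and
#' the caller falls back to the stored voxel normal, then the facet normal.
#'
#' @param cube a cube from [build_interp_cube()], or any list with
#'   `vertices`, `mask`, `fractions`.
#' @return Unit vector, or the zero vector.
#' @export
interpolate_normal <- function(cube) {
  cpp_interp_normal(cube$vertices, cube$mask, cube$fractions)
}
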