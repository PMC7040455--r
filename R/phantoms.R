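#' Labeled voxel volume
#'
#' A 3-D grid of small non-negative integer labels with cubic voxels of edge
#' `dx` (cm). Voxel `(i, j, k)` (0-based) spans world coordinates
#' `[i*dx, (i+1)*dx)` per axis and has its centroid at `(i + 0.5) * dx`.
#' All containment tests in the phantom generators use voxel centroids.
#'
#' @param labels integer 3-D array of medium labels.
#' @param dx voxel edge length in cm.
#' @return An object of class `labeled_volume` with fields `labels`, `shape`
#'   and `dx`.
#' @export
labeled_volume <- function(labels, dx) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3-D array")
  if (!is.numeric(dx) || length(dx) != 1L || dx <= 0)
    stop("`dx` must be a single positive voxel edge length (cm)")
  if (any(dim(labels) < 3L))
    stop("each grid dimension must be at least 3 voxels")
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || any(labels < 0L))
    stop("labels must be non-negative integers")
  structure(list(labels = labels, shape = dim(labels), dx = dx),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat("Labeled voxel volume:", paste(x$shape, collapse = " x "),
      sprintf("voxels, dx = %g cm (%.3g x %.3g x %.3g cm)\n", x$dx,
              x$shape[1] * x$dx, x$shape[2] * x$dx, x$shape[3] * x$dx))
  tab <- table(x$labels)
  cat("Labels:", paste(sprintf("%s (%d voxels)", names(tab), as.integer(tab)),
                       collapse = ", "), "\n")
  invisible(x)
}

#' Medium (tissue) property table
#'
#' Maps each voxel label to the optical properties used by the transport loop:
#' refractive index `n`, absorption coefficient `mua` (1/cm), scattering
#' coefficient `mus` (1/cm) and scattering anisotropy `g`.
#'
#' @param label integer vector of unique labels.
#' @param n refractive indices (>= 1).
#' @param mua absorption coefficients, 1/cm (>= 0).
#' @param mus scattering coefficients, 1/cm (>= 0).
#' @param g Henyey-Greenstein anisotropy factors, each in (-1, 1).
#' @return A `medium_table` data frame.
#' @export
medium_table <- function(label, n, mua, mus, g) {
  if (anyDuplicated(label)) stop("medium labels must be unique")
  if (any(n < 1)) stop("refractive indices must be >= 1")
  if (any(mua < 0) || any(mus < 0)) stop("mua and mus must be non-negative")
  if (any(abs(g) >= 1)) stop("anisotropy g must satisfy |g| < 1")
  out <- data.frame(label = as.integer(label), n = as.numeric(n),
                    mua = as.numeric(mua), mus = as.numeric(mus),
                    g = as.numeric(g))
  class(out) <- c("medium_table", "data.frame")
  out
}

# check that every label present in the volume has a media entry
check_media_cover <- function(volume, media) {
  present <- sort(unique(as.vector(volume$labels)))
  missing <- setdiff(present, media$label)
  if (length(missing))
    stop("labels missing from the medium table: ",
         paste(missing, collapse = ", "))
  invisible(present)
}

# centroid coordinate grids (cm) for a given shape/dx, per axis
centroids <- function(shape, dx) {
  lapply(shape, function(n) (seq_len(n) - 0.5) * dx)
}

#' Two-layer slab phantom
#'
#' Splits the grid at the plane `z = z_interface`: voxels whose centroid lies
#' at or above the interface (centroid z <= `z_interface`) get `label_top`,
#' the rest `label_bottom`.
#'
#' @param shape integer vector `(Nx, Ny, Nz)`.
#' @param dx voxel edge length, cm.
#' @param z_interface interface depth, cm; must lie strictly inside the grid.
#' @param label_top,label_bottom labels for the two layers.
#' @return A [labeled_volume()].
#' @export
make_slab <- function(shape, dx, z_interface, label_top = 1L, label_bottom = 2L) {
  if (z_interface <= 0 || z_interface >= shape[3] * dx)
    stop("z_interface must lie strictly inside the grid (0, Nz*dx)")
  zc <- (seq_len(shape[3]) - 0.5) * dx
  lab <- array(label_bottom, dim = shape)
  lab[, , zc <= z_interface] <- label_top
  labeled_volume(lab, dx)
}

#' Sphere phantom
#'
#' Labels a voxel `label_in` iff its centroid lies strictly inside the sphere.
#'
#' @param shape integer vector `(Nx, Ny, Nz)`.
#' @param dx voxel edge length, cm.
#' @param center sphere center, cm triple.
#' @param radius sphere radius, cm (must exceed `dx`).
#' @param label_in,label_out labels inside/outside the sphere.
#' @return A [labeled_volume()].
#' @export
make_sphere <- function(shape, dx, center, radius, label_in = 2L,
                        label_out = 1L) {
  if (radius <= dx) stop("radius must exceed the voxel size dx")
  cc <- centroids(shape, dx)
  dx2 <- outer((cc[[1]] - center[1])^2, (cc[[2]] - center[2])^2, `+`)
  lab <- array(label_out, dim = shape)
  r2 <- radius^2
  for (k in seq_len(shape[3])) {
    inside <- dx2 + (cc[[3]][k] - center[3])^2 < r2
    sl <- lab[, , k]
    sl[inside] <- label_in
    lab[, , k] <- sl
  }
  labeled_volume(lab, dx)
}

#' Biconvex lens phantom
#'
#' The lens is the intersection of two balls whose spherical caps form the two
#' lens surfaces, optionally clipped to an aperture cylinder. The lens axis is
#' z; `center` is the mid-plane point on the axis. Surface 1 (radius `R1`)
#' faces -z, surface 2 (radius `R2`) faces +z, and the center thickness along
#' the axis is `thickness`.
#'
#' @param shape integer vector `(Nx, Ny, Nz)`.
#' @param dx voxel edge length, cm.
#' @param center lens center (mid-plane on axis), cm triple.
#' @param R1,R2 surface radii of curvature, cm.
#' @param thickness center thickness, cm.
#' @param aperture full aperture diameter, cm.
#' @param label_lens,label_ambient labels for lens and surround.
#' @return A [labeled_volume()].
#' @export
make_biconvex_lens <- function(shape, dx, center, R1, R2, thickness, aperture,
                               label_lens = 2L, label_ambient = 1L) {
  a <- aperture / 2
  if (R1 < a || R2 < a)
    stop("surface radii R1, R2 must be at least half the aperture")
  if (thickness <= 0) stop("thickness must be positive")
  # sphere centers on the axis: vertex 1 at z0 - t/2, center 1 below it, etc.
  z0 <- center[3]
  c1 <- z0 - thickness / 2 + R1
  c2 <- z0 + thickness / 2 - R2
  cc <- centroids(shape, dx)
  rho2 <- outer((cc[[1]] - center[1])^2, (cc[[2]] - center[2])^2, `+`)
  lab <- array(label_ambient, dim = shape)
  for (k in seq_len(shape[3])) {
    z <- cc[[3]][k]
    inside <- rho2 < a^2 &
      rho2 + (z - c1)^2 < R1^2 &
      rho2 + (z - c2)^2 < R2^2
    if (any(inside)) {
      sl <- lab[, , k]
      sl[inside] <- label_lens
      lab[, , k] <- sl
    }
  }
  labeled_volume(lab, dx)
}

#' Analytic volume of the biconvex lens
#'
#' Closed-form volume of the intersection of the two lens balls clipped to the
#' aperture cylinder, by integrating the z-extent over the aperture disk.
#' Used as an independent check of the voxelized lens.
#'
#' @inheritParams make_biconvex_lens
#' @return Volume in cm^3.
#' @export
lens_volume_analytic <- function(R1, R2, thickness, aperture) {
  a <- aperture / 2
  # z-extent at radius rho: from sphere 2 cap to sphere 1 cap
  # integral of 2*pi*rho*(sqrt(R^2-rho^2) - (R - t/2)) for each cap half
  cap <- function(R) {
    amax <- sqrt(R^2 - (R - thickness / 2)^2)  # natural cap edge radius
    aa <- min(a, amax)
    2 * pi * ((R^3 - (R^2 - aa^2)^1.5) / 3 - (R - thickness / 2) * aa^2 / 2)
  }
  cap(R1) + cap(R2)
}
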