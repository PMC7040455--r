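#' Unique refractive indices present in a volume
#'
#' @param volume a [labeled_volume()].
#' @param media a [medium_table()] covering every label in `volume`.
#' @return Strictly increasing vector of the distinct refractive indices of
#'   the media actually present in the volume.
#' @export
unique_refractive_indices <- function(volume, media) {
  present <- check_media_cover(volume, media)
  sort(unique(media$n[match(present, media$label)]))
}

#' Binary occupancy map of one refractive index
#'
#' @inheritParams unique_refractive_indices
#' @param n_value one refractive index value.
#' @return 3-D 0/1 array, 1 where the voxel's medium has index `n_value`.
#' @export
binary_map <- function(volume, media, n_value) {
  check_media_cover(volume, media)
  n_of <- rep(NA_real_, max(media$label) + 1L)
  n_of[media$label + 1L] <- media$n
  out <- array(0, dim = volume$shape)
  out[n_of[volume$labels + 1L] == n_value] <- 1
  out
}

# shift-based separable convolution pass with replicate padding.
# kernel index m in -1:1 applies to the sample at i + m.
conv_axis <- function(a, kernel, axis) {
  d <- dim(a)
  n <- d[axis]
  im1 <- c(1L, seq_len(n - 1L))      # sample at i - 1
  ip1 <- c(seq_len(n - 1L) + 1L, n)  # sample at i + 1
  pick <- function(idx) {
    switch(axis, `1` = a[idx, , , drop = FALSE],
           `2` = a[, idx, , drop = FALSE],
           `3` = a[, , idx, drop = FALSE])
  }
  out <- kernel[2] * a
  if (kernel[1] != 0) out <- out + kernel[1] * pick(im1)
  if (kernel[3] != 0) out <- out + kernel[3] * pick(ip1)
  dim(out) <- d
  out
}

#' 3x3x3 Sobel-Feldman gradient of a binary map
#'
#' Separable operator: derivative kernel `(-1, 0, 1)` along the gradient axis,
#' smoothing kernel `(1, 2, 1)` along the two orthogonal axes; replicate
#' padding at the grid faces. The gradient points from the 0-region into the
#' 1-region, i.e. away from the boundary into the region interior.
#'
#' @param binary 3-D array containing only 0 and 1.
#' @return List with components `gx`, `gy`, `gz` (raw, unnormalized).
#' @export
sobel3d <- function(binary) {
  if (!is.array(binary) || length(dim(binary)) != 3L)
    stop("`binary` must be a 3-D array")
  if (!all(binary %in% c(0, 1)))
    stop("`binary` must contain only 0 and 1")
  deriv <- c(-1, 0, 1)
  sm <- c(1, 2, 1)
  gx <- conv_axis(conv_axis(conv_axis(binary, deriv, 1L), sm, 2L), sm, 3L)
  gy <- conv_axis(conv_axis(conv_axis(binary, sm, 1L), deriv, 2L), sm, 3L)
  gz <- conv_axis(conv_axis(conv_axis(binary, sm, 1L), sm, 2L), deriv, 3L)
  list(gx = gx, gy = gy, gz = gz)
}

#' Smooth a gradient field componentwise
#'
#' Each component is smoothed independently by the DCT penalized
#' least-squares smoother with global smoothing factor `s` (see
#' `smoothn_dct`); `s = 0` returns the field unchanged and constants are
#' always reproduced exactly.
#'
#' @param field list with `gx`, `gy`, `gz` arrays of equal shape.
#' @param s smoothing factor, >= 0.
#' @return List with smoothed `gx`, `gy`, `gz`.
#' @export
smooth_field <- function(field, s = 2) {
  if (s < 0) stop("smoothing factor s must be >= 0")
  if (s == 0) return(field)
  d <- dim(field$gx)
  Cs <- lapply(d, dct_matrix)
  Gamma <- 1 / (1 + s * laplacian_eigenvalues(d)^2)
  list(gx = smoothn_dct(field$gx, s, Cs, Gamma),
       gy = smoothn_dct(field$gy, s, Cs, Gamma),
       gz = smoothn_dct(field$gz, s, Cs, Gamma))
}

#' Aggregate per-medium smoothed fields into one normal map
#'
#' Each smoothed field is masked by its own binary map (so opposite sides of
#' a boundary never mix or cancel), the masked fields are summed, vectors with
#' negligible magnitude are zeroed, and the rest are normalized to unit
#' length.
#'
#' @param fields list of smoothed gradient fields (one per refractive index).
#' @param masks list of the matching binary maps.
#' @param dx voxel edge length, cm (carried for downstream use).
#' @param mag_floor relative magnitude floor: vectors whose pre-normalization
#'   magnitude falls below `mag_floor * max(magnitude)` are stored as zero,
#'   confining nonzero normals to a shell around the mismatched boundaries.
#' @return A `normal_map` object with unit (or zero) vectors `gx`, `gy`, `gz`.
#' @export
aggregate_normals <- function(fields, masks, dx, mag_floor = 1e-3) {
  if (length(fields) != length(masks))
    stop("fields and masks must pair up")
  d <- dim(masks[[1]])
  gx <- array(0, d); gy <- array(0, d); gz <- array(0, d)
  for (i in seq_along(fields)) {
    if (!identical(dim(fields[[i]]$gx), d))
      stop("field/mask shape mismatch")
    m <- masks[[i]]
    gx <- gx + fields[[i]]$gx * m
    gy <- gy + fields[[i]]$gy * m
    gz <- gz + fields[[i]]$gz * m
  }
  mag <- sqrt(gx^2 + gy^2 + gz^2)
  floor_abs <- mag_floor * max(mag)
  zero <- mag <= max(floor_abs, 1e-9)
  mag[zero] <- 1
  gx <- gx / mag; gy <- gy / mag; gz <- gz / mag
  gx[zero] <- 0; gy[zero] <- 0; gz[zero] <- 0
  structure(list(gx = gx, gy = gy, gz = gz, shape = d, dx = dx),
            class = "normal_map")
}

#' Compute the smoothed boundary-normal field of a labeled volume
#'
#' Full pipeline: for each unique refractive index, build the binary map,
#' apply the 3x3x3 Sobel-Feldman operator, smooth each gradient component
#' with the DCT penalized least-squares smoother (factor `s`), mask by the
#' medium's own binary map, sum, and normalize per voxel to unit length.
#'
#' @inheritParams unique_refractive_indices
#' @param s smoothing factor (default 2).
#' @param mag_floor see [aggregate_normals()].
#' @return A `normal_map` object.
#' @export
compute_normal_map <- function(volume, media, s = 2, mag_floor = 1e-3) {
  nvals <- unique_refractive_indices(volume, media)
  if (length(nvals) < 2) {
    z <- array(0, volume$shape)
    return(structure(list(gx = z, gy = z, gz = z, shape = volume$shape,
                          dx = volume$dx), class = "normal_map"))
  }
  d <- volume$shape
  Cs <- if (s > 0) lapply(d, dct_matrix) else NULL
  Gamma <- if (s > 0) 1 / (1 + s * laplacian_eigenvalues(d)^2) else NULL
  fields <- vector("list", length(nvals))
  masks <- vector("list", length(nvals))
  for (i in seq_along(nvals)) {
    b <- binary_map(volume, media, nvals[i])
    gset <- sobel3d(b)
    if (s > 0)
      gset <- list(gx = smoothn_dct(gset$gx, s, Cs, Gamma),
                   gy = smoothn_dct(gset$gy, s, Cs, Gamma),
                   gz = smoothn_dct(gset$gz, s, Cs, Gamma))
    fields[[i]] <- gset
    masks[[i]] <- b
  }
  aggregate_normals(fields, masks, volume$dx, mag_floor = mag_floor)
}

#' @export
print.normal_map <- function(x, ...) {
  nz <- sum(x$gx != 0 | x$gy != 0 | x$gz != 0)
  cat("Boundary normal map:", paste(x$shape, collapse = " x "),
      sprintf("voxels, dx = %g cm; %d voxels carry a unit normal\n", x$dx, nz))
  invisible(x)
}
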