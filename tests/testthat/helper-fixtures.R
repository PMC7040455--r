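# Shared fixtures, built once per test run. The small sphere (r = 0.3 cm at
# dx = 0.01) keeps unit tests fast; the full-scale experiments live in the
# acceptance tests.

.fixtures <- new.env(parent = emptyenv())

small_sphere_fixture <- function() {
  if (is.null(.fixtures$sphere)) {
    dx <- 0.01
    center <- c(0.35, 0.35, 0.35)
    vol <- make_sphere(c(70, 70, 70), dx, center, 0.3, label_in = 2L,
                       label_out = 1L)
    med <- medium_table(c(1L, 2L), n = c(1.00, 1.33), mua = c(0, 0),
                        mus = c(0, 0), g = c(0, 0))
    .fixtures$sphere <- list(
      volume = vol, media = med, center = center, radius = 0.3, dx = dx,
      normal_map = compute_normal_map(vol, med, s = 2))
  }
  .fixtures$sphere
}

slab_fixture <- function() {
  if (is.null(.fixtures$slab)) {
    vol <- make_slab(c(20, 20, 20), 0.01, 0.1, label_top = 1L,
                     label_bottom = 2L)
    med <- medium_table(c(1L, 2L), n = c(1.00, 1.33), mua = c(0.1, 0.1),
                        mus = c(10, 10), g = c(0.5, 0.5))
    .fixtures$slab <- list(volume = vol, media = med,
                           normal_map = compute_normal_map(vol, med, s = 2))
  }
  .fixtures$slab
}

# angular error (degrees) between rows of two unit-vector matrices
angle_between_deg <- function(a, b) {
  a <- a / sqrt(rowSums(a^2))
  b <- b / sqrt(rowSums(b^2))
  acos(pmin(1, pmax(-1, rowSums(a * b)))) * 180 / pi
}

# angular error of stored normals against the analytic radial field of a
# sphere fixture, restricted to voxels of `label` within `band` cm of the
# surface
sphere_normal_errors <- function(fx, nm = fx$normal_map, label = 2L,
                                 band = 1.5 * fx$dx) {
  idx <- which(nm$gx != 0 | nm$gy != 0 | nm$gz != 0, arr.ind = TRUE)
  cent <- sweep((idx - 0.5) * fx$dx, 2, fx$center)
  rr <- sqrt(rowSums(cent^2))
  sel <- fx$volume$labels[idx] == label & abs(rr - fx$radius) < band
  radial <- cent[sel, , drop = FALSE] / rr[sel]
  # stored vectors point away from the boundary into their own region:
  # -radial inside the sphere, +radial outside
  if (label == 2L) radial <- -radial
  vn <- cbind(nm$gx[idx], nm$gy[idx], nm$gz[idx])[sel, , drop = FALSE]
  angle_between_deg(vn, radial)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
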