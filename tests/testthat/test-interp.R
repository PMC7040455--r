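test_that("fractional coordinates follow the centroid convention", {
  # voxel centroid: fraction 0 (round is half-away-from-zero)
  expect_equal(fractional_coords(c(0.5, 0.5, 0.5)), c(0, 0, 0))
  # direct evaluation off-centroid
  expect_equal(fractional_coords(c(0.4, 0.6, 1.0)), c(0.9, 0.1, 0.5))
  # a voxel face is midway between the adjacent centroids
  expect_equal(fractional_coords(c(1.0, 2.0, 3.0)), c(0.5, 0.5, 0.5))
})

test_that("interpolation collapses to the voxel normal at its centroid", {
  fx <- small_sphere_fixture()
  nm <- fx$normal_map
  # pick a boundary voxel with a stored normal, query its centroid
  idx <- which(nm$gx != 0 | nm$gy != 0 | nm$gz != 0, arr.ind = TRUE)
  v <- idx[100, ] - 1L  # 0-based voxel index
  cube <- build_interp_cube(v + 0.5, v, fx$volume, fx$media, nm)
  expect_equal(cube$fractions, c(0, 0, 0))
  got <- interpolate_normal(cube)
  expect_equal(got, c(nm$gx[idx[100, , drop = FALSE]],
                      nm$gy[idx[100, , drop = FALSE]],
                      nm$gz[idx[100, , drop = FALSE]]), tolerance = 1e-9)
})

test_that("equal vertex vectors interpolate to themselves", {
  u <- c(1, 2, 2) / 3
  cube <- list(vertices = matrix(rep(u, each = 8), 8, 3),
               mask = rep(TRUE, 8),
               fractions = c(0.3, 0.7, 0.1))
  expect_equal(interpolate_normal(cube), u, tolerance = 1e-12)
})

test_that("fully masked cubes yield the zero vector", {
  cube <- list(vertices = matrix(rnorm(24), 8, 3), mask = rep(FALSE, 8),
               fractions = c(0.5, 0.5, 0.5))
  expect_equal(interpolate_normal(cube), c(0, 0, 0))
})

test_that("vertex masks restrict to the photon's own medium", {
  fx <- slab_fixture()
  # photon in the top medium (k <= 9, 0-based), on the interface face z = 10
  pos <- c(10.3, 10.3, 10.0)
  cube <- build_interp_cube(pos, c(10L, 10L, 9L), fx$volume, fx$media,
                            fx$normal_map)
  # exactly the 4 lower-plane vertices (same medium as the photon) are active
  expect_equal(sum(cube$mask), 4L)
  expect_true(all(cube$mask[1:4]) && !any(cube$mask[5:8]))
  # masked interpolation only mixes same-side vectors: result is the slab
  # top-side normal exactly
  expect_equal(interpolate_normal(cube), c(0, 0, -1))
  # deep inside one medium every vertex matches
  cube2 <- build_interp_cube(c(5.5, 5.5, 5.5), c(5L, 5L, 5L), fx$volume,
                             fx$media, fx$normal_map)
  expect_true(all(cube2$mask))
})

test_that("grid-corner queries clip outside vertices from the mask", {
  fx <- slab_fixture()
  cube <- build_interp_cube(c(19.5, 19.5, 19.5), c(19L, 19L, 19L),
                            fx$volume, fx$media, fx$normal_map)
  expect_equal(sum(cube$mask), 1L)
  # at the low corner the cube still fits: all same-medium vertices active
  cube0 <- build_interp_cube(c(0.5, 0.5, 0.5), c(0L, 0L, 0L), fx$volume,
                             fx$media, fx$normal_map)
  expect_equal(sum(cube0$mask), 8L)
  expect_error(build_interp_cube(c(-1, 5, 5), c(0L, 5L, 5L), fx$volume,
                                 fx$media, fx$normal_map), "outside")
})

test_that("interpolated normals vary more smoothly than stored normals", {
  fx <- small_sphere_fixture()
  nm <- fx$normal_map
  dxv <- fx$dx
  # walk along x at fixed y over the sphere's top: at each sample find the
  # z-face where the label changes and evaluate both normal estimates there
  jy <- 35L
  xs <- seq(20, 50, by = 0.25)
  stored <- NULL; interp <- NULL
  for (x in xs) {
    ix <- floor(x)
    col <- fx$volume$labels[ix + 1L, jy + 1L, ]
    kz <- which(col == 2L)
    if (!length(kz)) next
    k_in <- min(kz)               # first sphere voxel from the top
    pos <- c(x, jy + 0.5, k_in - 1L)  # on the face above it, voxel coords
    vox <- c(ix, jy, k_in - 2L)   # photon approaching from outside (0-based)
    if (vox[3] < 0) next
    cube <- build_interp_cube(pos, as.integer(vox), fx$volume, fx$media, nm)
    iv <- interpolate_normal(cube)
    sv <- c(nm$gx[vox[1] + 1, vox[2] + 1, vox[3] + 1],
            nm$gy[vox[1] + 1, vox[2] + 1, vox[3] + 1],
            nm$gz[vox[1] + 1, vox[2] + 1, vox[3] + 1])
    if (sum(iv^2) == 0 || sum(sv^2) == 0) next
    stored <- rbind(stored, sv); interp <- rbind(interp, iv)
  }
  expect_gt(nrow(stored), 50)
  jump <- function(m) angle_between_deg(m[-1, , drop = FALSE],
                                        m[-nrow(m), , drop = FALSE])
  expect_lt(max(jump(interp)), max(jump(stored)))
  expect_lte(mean(jump(interp)), mean(jump(stored)) + 1e-3)
})
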