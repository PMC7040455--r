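test_that("unique refractive indices are deduplicated and sorted", {
  vol <- labeled_volume(array(c(1L, 2L, 3L), c(3, 3, 3)), 0.01)
  med <- medium_table(c(1L, 2L, 3L), n = c(1.42, 1.00, 1.33),
                      mua = c(0, 0, 0), mus = c(0, 0, 0), g = c(0, 0, 0))
  expect_equal(unique_refractive_indices(vol, med), c(1.00, 1.33, 1.42))
  med2 <- medium_table(c(1L, 2L, 3L), n = c(1.33, 1.33, 1.00),
                       mua = c(0, 0, 0), mus = c(0, 0, 0), g = c(0, 0, 0))
  expect_equal(unique_refractive_indices(vol, med2), c(1.00, 1.33))
  med3 <- medium_table(c(1L, 2L), n = c(1, 1.33), mua = c(0, 0),
                       mus = c(0, 0), g = c(0, 0))
  expect_error(unique_refractive_indices(vol, med3), "3")
})

test_that("binary maps partition the volume across unique indices", {
  fx <- slab_fixture()
  nv <- unique_refractive_indices(fx$volume, fx$media)
  maps <- lapply(nv, function(n) binary_map(fx$volume, fx$media, n))
  total <- Reduce(`+`, maps)
  expect_true(all(total == 1))
  # top layer count matches construction (z < 0.1 cm of a 0.2 cm slab)
  expect_equal(sum(maps[[1]]), 20L * 20L * 10L)
})

test_that("Sobel gradient of a slab is exactly axis-aligned and inward", {
  fx <- slab_fixture()
  b <- binary_map(fx$volume, fx$media, 1.00)  # top region, small z
  g <- sobel3d(b)
  # at the last 1-layer (k = 10), the gradient must point to -z (into region)
  expect_true(all(g$gx[, , 10] == 0))
  expect_true(all(g$gy[, , 10] == 0))
  expect_true(all(g$gz[, , 10] < 0))
  # and on the facing side of the bottom region, to +z
  b2 <- binary_map(fx$volume, fx$media, 1.33)
  g2 <- sobel3d(b2)
  expect_true(all(g2$gz[, , 11] > 0))
  # constant map has zero gradient everywhere (replicate padding)
  gc <- sobel3d(array(1, c(5, 5, 5)))
  expect_true(all(gc$gx == 0 & gc$gy == 0 & gc$gz == 0))
  expect_error(sobel3d(array(0.5, c(5, 5, 5))), "0 and 1")
})

test_that("DCT smoother is the identity at s = 0 and preserves constants", {
  f <- list(gx = array(rnorm(125), c(5, 5, 5)),
            gy = array(rnorm(125), c(5, 5, 5)),
            gz = array(rnorm(125), c(5, 5, 5)))
  expect_identical(smooth_field(f, s = 0), f)
  const <- list(gx = array(3, c(6, 5, 4)), gy = array(-1, c(6, 5, 4)),
                gz = array(0.5, c(6, 5, 4)))
  sm <- smooth_field(const, s = 7)
  expect_equal(sm$gx, const$gx, tolerance = 1e-12)
  expect_equal(sm$gy, const$gy, tolerance = 1e-12)
  expect_equal(sm$gz, const$gz, tolerance = 1e-12)
  expect_error(smooth_field(f, s = -1), ">= 0")
})

test_that("smoothing with s = 2 reduces the sphere-normal angular error", {
  fx <- small_sphere_fixture()
  nm_raw <- compute_normal_map(fx$volume, fx$media, s = 0)
  err_raw <- sphere_normal_errors(fx, nm_raw)
  err_smooth <- sphere_normal_errors(fx)
  expect_lt(mean(err_smooth), mean(err_raw))
})

test_that("sphere pipeline normals track the analytic radial field", {
  # note: this fixture (r = 0.3 cm) has 3.3x the voxel-level curvature of
  # the full-scale validation sphere; the full-scale accuracy check lives
  # with the validation experiments
  fx <- small_sphere_fixture()
  err <- sphere_normal_errors(fx)
  expect_lt(mean(err), 2.5)
  expect_lte(unname(quantile(err, 0.99)), 6.5)
})

test_that("stored vectors are unit length or exactly zero", {
  fx <- small_sphere_fixture()
  nm <- fx$normal_map
  mag <- sqrt(nm$gx^2 + nm$gy^2 + nm$gz^2)
  expect_true(all(mag < 1e-6 | abs(mag - 1) < 1e-6))
})

test_that("nonzero normals are confined to a shell around the boundary", {
  fx <- small_sphere_fixture()
  nm <- fx$normal_map
  idx <- which(nm$gx != 0 | nm$gy != 0 | nm$gz != 0, arr.ind = TRUE)
  rr <- sqrt(rowSums(sweep((idx - 0.5) * fx$dx, 2, fx$center)^2))
  # the magnitude floor confines nonzero vectors to the smoother's support
  # around the boundary (about a dozen voxels at s = 2), not the whole grid
  expect_lt(max(abs(rr - fx$radius)), 15 * fx$dx)
})

test_that("slab normals mirror exactly across the interface", {
  fx <- slab_fixture()
  nm <- fx$normal_map
  # interface between layers k = 10 and k = 11
  expect_true(all(nm$gz[, , 10] == -1))
  expect_true(all(nm$gz[, , 11] == 1))
  expect_true(all(nm$gx[, , 10:11] == 0))
  expect_true(all(nm$gy[, , 10:11] == 0))
})

test_that("single-medium volumes produce an all-zero normal map", {
  vol <- labeled_volume(array(1L, c(6, 6, 6)), 0.01)
  med <- medium_table(1L, 1.4, 0, 0, 0)
  nm <- compute_normal_map(vol, med)
  expect_true(all(nm$gx == 0 & nm$gy == 0 & nm$gz == 0))
})

test_that("masked aggregation rejects mismatched shapes", {
  f1 <- list(gx = array(1, c(4, 4, 4)), gy = array(0, c(4, 4, 4)),
             gz = array(0, c(4, 4, 4)))
  f2 <- list(gx = array(1, c(5, 4, 4)), gy = array(0, c(5, 4, 4)),
             gz = array(0, c(5, 4, 4)))
  expect_error(aggregate_normals(list(f1, f2),
                                 list(array(1, c(4, 4, 4)),
                                      array(1, c(4, 4, 4))), 0.01),
               "mismatch")
})

test_that("halving dx does not worsen the typical sphere-normal error", {
  build <- function(dx) {
    n <- round(0.7 / dx)
    vol <- make_sphere(rep(n, 3), dx, rep(0.35, 3), 0.25, 2L, 1L)
    med <- medium_table(c(1L, 2L), n = c(1.00, 1.33), mua = c(0, 0),
                        mus = c(0, 0), g = c(0, 0))
    fx <- list(volume = vol, media = med, center = rep(0.35, 3),
               radius = 0.25, dx = dx)
    fx$normal_map <- compute_normal_map(vol, med, s = 2)
    fx
  }
  coarse <- build(0.02)
  fine <- build(0.01)
  # the median and mean error shrink with resolution; the extreme tail does
  # not (the smoothing factor acts in voxel units, so its physical support
  # shrinks with dx) -- see the methods vignette
  expect_lt(median(sphere_normal_errors(fine)),
            median(sphere_normal_errors(coarse)))
  expect_lt(mean(sphere_normal_errors(fine)),
            mean(sphere_normal_errors(coarse)))
})
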