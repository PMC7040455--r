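# homogeneous non-mismatched box used by several transport tests
homog_run <- function(n_photons, mua, mus, g, mode = "matched", seed = 1,
                      radius = 0, shape = c(30, 30, 60), origin = NULL) {
  vol <- labeled_volume(array(1L, shape), 0.01)
  med <- medium_table(1L, n = 1.33, mua = mua, mus = mus, g = g)
  if (is.null(origin)) origin <- c(shape[1] / 2, shape[2] / 2, 0.1) * 0.01
  cfg <- sim_config(n_photons, mode = mode,
                    source = source_spec(origin, c(0, 0, 1), radius),
                    seed = seed)
  simulate_photons(vol, med, cfg)
}

test_that("launch places photons on the source disk with unit weight", {
  res <- homog_run(200, mua = 0, mus = 0, g = 0, radius = 0)
  # pencil beam: every photon starts exactly at the origin
  expect_true(all(res$launch$x == res$launch$x[1]))
  expect_true(all(abs(res$launch$x - 0.15) < 1e-12))
  # and with unit weight: in an empty box all escape with weight 1
  expect_true(all(res$escape$weight == 1))

  res2 <- homog_run(1e5, mua = 0, mus = 0, g = 0, radius = 0.05,
                    shape = c(40, 40, 20),
                    origin = c(0.2, 0.2, 0.01))
  r <- sqrt((res2$launch$x - 0.2)^2 + (res2$launch$y - 0.2)^2)
  expect_lte(max(r), 0.05)
  # uniform disk: half the photons fall within radius/sqrt(2)
  p <- mean(r <= 0.05 / sqrt(2))
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 1e5))
})

test_that("free paths in a homogeneous medium are exponential", {
  # absorbing-only medium: each photon deposits its full weight at the end
  # of its first hop, so the depth profile of absorbed weight is exp(-mut z)
  mua <- 8
  res <- homog_run(2e5, mua = mua, mus = 0, g = 0, shape = c(20, 20, 100))
  prof <- apply(res$fluence$deposit, 3, sum)
  z <- (seq_len(100) - 0.5) * 0.01
  sel <- 5:60  # central range, away from launch face and far-end truncation
  fit <- lm(log(prof[sel]) ~ z[sel])
  expect_equal(unname(coef(fit)[2]), -mua, tolerance = 0.03)
})

test_that("absorbed, escaped and roulette weight balance to 1e-6", {
  for (seed in 1:3) {
    res <- homog_run(2000, mua = 0.5, mus = 30, g = 0.8, seed = seed)
    expect_lt(abs(conservation_residual(res)), 1e-6)
  }
  # with refractive mismatch and all four modes
  fx <- slab_fixture()
  for (mode in c("matched", "facet", "surface", "interp")) {
    cfg <- sim_config(1000, mode = mode,
                      source = source_spec(c(0.1, 0.1, 0.005), c(0, 0, 1),
                                           0.02), seed = 4)
    res <- simulate_photons(fx$volume, fx$media, cfg, fx$normal_map)
    expect_lt(abs(conservation_residual(res)), 1e-6)
  }
})

test_that("a fully absorbing slab captures all weight that enters", {
  vol <- labeled_volume(array(1L, c(20, 20, 3)), 0.01)
  med <- medium_table(1L, n = 1.33, mua = 1e4, mus = 0, g = 0)
  cfg <- sim_config(2000, mode = "matched",
                    source = source_spec(c(0.1, 0.1, 0.001), c(0, 0, 1), 0),
                    seed = 2)
  res <- simulate_photons(vol, med, cfg)
  absorbed <- sum(res$fluence$values * med$mua * 0.01^3)
  expect_equal(absorbed, 1, tolerance = 1e-3)
})

test_that("Henyey-Greenstein sampling has the right moments", {
  set.seed(31)
  # isotropic limit: cos(theta) uniform on [-1, 1]
  u <- hg_sample(1e5, 0)
  ks <- suppressWarnings(stats::ks.test(u, "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
  # anisotropic: E[cos theta] = g
  g <- 0.9
  cth <- hg_sample(1e6, g)
  se <- sd(cth) / sqrt(length(cth))
  expect_lt(abs(mean(cth) - g), 3 * se)
  expect_error(hg_sample(10, 1), "\\|g\\| < 1")
})

test_that("spin preserves unit length and the HG polar angle", {
  set.seed(7)
  d0 <- c(1, 2, -2) / 3
  dirs <- spin_direction(d0, 0.9, 1e5)
  expect_lt(max(abs(rowSums(dirs^2) - 1)), 1e-9)
  # the polar cosines relative to the incoming direction average to g
  cth <- dirs %*% d0
  expect_lt(abs(mean(cth) - 0.9), 3 * sd(cth) / sqrt(length(cth)))
})

test_that("Russian roulette is unbiased and leaves heavy photons alone", {
  set.seed(9)
  w <- rep(1e-5, 1e6)
  out <- roulette(w, threshold = 1e-4, survival = 10)
  expect_true(all(out %in% c(0, 1e-4)))
  expect_lt(abs(mean(out) - 1e-5), 3 * sd(out) / sqrt(length(out)))
  expect_identical(roulette(c(0.5, 1e-3), threshold = 1e-4, survival = 10),
                   c(0.5, 1e-3))
})

test_that("boundary crossings reflect with the Fresnel probability", {
  # pencil beam at normal incidence onto an n 1.00 -> 1.33 slab face
  vol <- make_slab(c(10, 10, 40), 0.01, 0.2, 1L, 2L)
  med <- medium_table(c(1L, 2L), n = c(1.00, 1.33), mua = c(0, 0),
                      mus = c(0, 0), g = c(0, 0))
  cfg <- sim_config(2e5, mode = "facet",
                    source = source_spec(c(0.05, 0.05, 0.005), c(0, 0, 1),
                                         0), seed = 13)
  res <- simulate_photons(vol, med, cfg)
  frac_reflected <- mean(res$escape$n_reflections == 1)
  R0 <- ((1 - 1.33) / (1 + 1.33))^2
  expect_lt(abs(frac_reflected - R0), 3 * sqrt(R0 * (1 - R0) / 2e5))
})

test_that("escape positions lie exactly on the outer grid faces", {
  res <- homog_run(2000, mua = 0.1, mus = 20, g = 0.7, seed = 21)
  on_face <- function(v, n) abs(v) < 1e-9 | abs(v - n * 0.01) < 1e-9
  ok <- on_face(res$escape$x, 30) | on_face(res$escape$y, 30) |
    on_face(res$escape$z, 60)
  expect_true(all(ok))
})

test_that("identical seeds reproduce runs bitwise", {
  a <- homog_run(500, mua = 0.3, mus = 40, g = 0.85, seed = 77)
  b <- homog_run(500, mua = 0.3, mus = 40, g = 0.85, seed = 77)
  expect_identical(a$fluence$values, b$fluence$values)
  expect_identical(a$escape, b$escape)
  expect_identical(a$launch, b$launch)
})

test_that("all four boundary modes coincide when indices are matched", {
  vol <- make_slab(c(16, 16, 16), 0.01, 0.08, 1L, 2L)
  med <- medium_table(c(1L, 2L), n = c(1.4, 1.4), mua = c(0.2, 0.3),
                      mus = c(20, 30), g = c(0.6, 0.8))
  nm <- compute_normal_map(vol, med, s = 2)
  runs <- lapply(c("matched", "facet", "surface", "interp"), function(m) {
    cfg <- sim_config(400, mode = m,
                      source = source_spec(c(0.08, 0.08, 0.005),
                                           c(0, 0, 1), 0.03), seed = 5)
    simulate_photons(vol, med, cfg, nm)
  })
  for (i in 2:4) {
    expect_identical(runs[[i]]$fluence$values, runs[[1]]$fluence$values)
    expect_identical(runs[[i]]$escape, runs[[1]]$escape)
  }
})

test_that("facet, surface and interp agree on an axis-aligned slab", {
  fx <- slab_fixture()
  runs <- lapply(c("facet", "surface", "interp"), function(m) {
    cfg <- sim_config(800, mode = m,
                      source = source_spec(c(0.1, 0.1, 0.005), c(0, 0, 1),
                                           0.03), seed = 19)
    simulate_photons(fx$volume, fx$media, cfg, fx$normal_map)
  })
  for (i in 2:3) {
    expect_identical(runs[[i]]$fluence$values, runs[[1]]$fluence$values)
    expect_identical(runs[[i]]$escape, runs[[1]]$escape)
  }
})

test_that("surface and interp modes demand a normal map", {
  vol <- make_slab(c(10, 10, 10), 0.01, 0.05)
  med <- medium_table(c(1L, 2L), n = c(1, 1.33), mua = c(0, 0),
                      mus = c(0, 0), g = c(0, 0))
  cfg <- sim_config(10, mode = "surface",
                    source = source_spec(c(0.05, 0.05, 0.005), c(0, 0, 1),
                                         0))
  expect_error(simulate_photons(vol, med, cfg), "normal_map")
})
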