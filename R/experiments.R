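# Canned validation experiments: a collimated beam striking the side of a
# refractive sphere (reflected-beam geometry against the analytic oracle) and
# a beam focused through a biconvex lens into a scattering aqueous medium
# (facet-normal vs interpolated-surface-normal fluence discrepancy). Both are
# used by the test suite and the acceptance script; the defaults are the
# package's documented study conditions.

#' Set up the sphere reflection experiment
#'
#' A sphere of radius `radius` (default 1 cm, refractive index 1.33) in air
#' (n = 1.00) voxelized at `dx` = 0.01 cm, with a collimated beam traveling
#' +z, offset from the sphere center by `beam_offset` so it strikes the
#' sphere's side. Absorption and scattering are zero, so every photon path is
#' ballistic apart from Fresnel events. The beam geometry (offset 0.6 cm,
#' radius 0.15 cm) spans impact parameters 0.45--0.75 cm, i.e. incidence
#' angles of roughly 27--49 degrees on the side of the sphere.
#'
#' @param shape,dx grid size and voxel edge (cm).
#' @param radius sphere radius, cm.
#' @param n_inside,n_ambient refractive indices.
#' @param s smoothing factor for the normal map.
#' @param beam_offset lateral offset of the beam axis from the sphere center,
#'   cm.
#' @param beam_radius source disk radius, cm.
#' @return List with `volume`, `media`, `normal_map`, `scene` (the analytic
#'   sphere), and `source`.
#' @export
setup_sphere_experiment <- function(shape = c(208, 208, 208), dx = 0.01,
                                    radius = 1.0, n_inside = 1.33,
                                    n_ambient = 1.00, s = 2,
                                    beam_offset = 0.6, beam_radius = 0.15) {
  center <- shape * dx / 2
  volume <- make_sphere(shape, dx, center, radius, label_in = 2L,
                        label_out = 1L)
  media <- medium_table(label = c(1L, 2L), n = c(n_ambient, n_inside),
                        mua = c(0, 0), mus = c(0, 0), g = c(0, 0))
  normal_map <- compute_normal_map(volume, media, s = s)
  list(volume = volume, media = media, normal_map = normal_map,
       scene = sphere_scene(center, radius, n_inside, n_ambient),
       source = source_spec(c(center[1] + beam_offset, center[2], 2 * dx),
                            c(0, 0, 1), beam_radius))
}

#' Run the sphere reflection experiment
#'
#' @param setup a list from [setup_sphere_experiment()].
#' @param n_photons photons to launch.
#' @param mode boundary mode (`"surface"` or `"interp"` for the validation).
#' @param seed RNG seed.
#' @return List with the `mc_result`, the per-photon reflected-direction
#'   errors (degrees) and the beam-edge errors from [beam_edge_error()].
#' @export
run_sphere_experiment <- function(setup, n_photons = 20000,
                                  mode = "surface", seed = 1) {
  cfg <- sim_config(n_photons, mode = mode, source = setup$source,
                    seed = seed)
  result <- simulate_photons(setup$volume, setup$media, cfg,
                             setup$normal_map)
  list(result = result,
       photon_errors = reflected_angle_error(result, setup$scene),
       edge_errors = beam_edge_error(result, setup$scene))
}

#' Set up the lens focusing experiment
#'
#' A biconvex lens (n = 1.52) immersed in water (n = 1.33), the lower part of
#' the grid filled with a scattering aqueous solution (n = 1.33,
#' mus = 100/cm, g = 0.90) starting at `scatter_z`. Absorption is negligible
#' (`mua`, default 0.01/cm, is five orders below mus) but nonzero so fluence
#' is recorded everywhere. A collimated beam enters along +z through the
#' lens. The default lens (R1 = R2 = 0.2 cm, center thickness 0.15 cm,
#' aperture 0.3 cm, mid-plane at z = 0.35 cm) has a thin-lens focal length of
#' 0.7 cm in water, so the focus falls inside the default 1.28 cm grid.
#'
#' @param shape,dx grid size and voxel edge (cm).
#' @param center lens mid-plane center, cm triple.
#' @param R1,R2,thickness,aperture lens geometry, cm (see
#'   [make_biconvex_lens()]).
#' @param n_lens,n_ambient refractive indices.
#' @param mua,mus,g optical properties of the scattering solution (1/cm,
#'   1/cm, dimensionless); `mua` is also used for the water and lens so
#'   absorbed weight is recorded there.
#' @param s smoothing factor for the normal map.
#' @param beam_radius source disk radius, cm.
#' @param scatter_z depth (cm) where the scattering solution begins.
#' @return List with `volume`, `media`, `normal_map`, `source`, `scene`, and
#'   the `region` mask (voxels below and lateral to the lens).
#' @export
setup_lens_experiment <- function(shape = c(128, 128, 128), dx = 0.01,
                                  center = c(0.64, 0.64, 0.35), R1 = 0.2,
                                  R2 = 0.2, thickness = 0.15, aperture = 0.3,
                                  n_lens = 1.52, n_ambient = 1.33,
                                  mua = 0.01, mus = 100, g = 0.90, s = 2,
                                  beam_radius = 0.10, scatter_z = 0.5) {
  volume <- make_biconvex_lens(shape, dx, center, R1, R2, thickness,
                               aperture, label_lens = 2L, label_ambient = 1L)
  lab <- volume$labels
  zc <- (seq_len(shape[3]) - 0.5) * dx
  for (k in which(zc >= scatter_z)) {
    sl <- lab[, , k]
    sl[sl == 1L] <- 3L
    lab[, , k] <- sl
  }
  volume <- labeled_volume(lab, dx)
  media <- medium_table(label = c(1L, 2L, 3L),
                        n = c(n_ambient, n_lens, n_ambient),
                        mua = c(mua, mua, mua), mus = c(0, 0, mus),
                        g = c(0, 0, g))
  normal_map <- compute_normal_map(volume, media, s = s)
  # region below and lateral to the lens
  xs <- (seq_len(shape[1]) - 0.5) * dx
  ys <- (seq_len(shape[2]) - 0.5) * dx
  rho <- sqrt(outer((xs - center[1])^2, (ys - center[2])^2, `+`))
  region <- array(FALSE, dim = shape)
  z_top <- center[3] - thickness / 2
  z_bot <- center[3] + thickness / 2
  for (k in seq_len(shape[3])) {
    z <- zc[k]
    region[, , k] <- (z > z_bot) | (z > z_top & rho > aperture / 2)
  }
  list(volume = volume, media = media, normal_map = normal_map,
       source = source_spec(c(center[1], center[2], dx), c(0, 0, 1),
                            beam_radius),
       scene = lens_scene(center, R1, R2, thickness, aperture, n_lens,
                          n_ambient),
       region = region)
}

#' Run the lens facet-vs-interpolated comparison
#'
#' Runs the lens experiment in facet-normal (FN) and
#' interpolated-surface-normal (ISN) modes with the same seed and returns the
#' voxel-wise percent-change map `100 (phi_FN - phi_ISN) / phi_ISN` together
#' with its maximum over the region below and lateral to the lens.
#'
#' @param setup a list from [setup_lens_experiment()].
#' @param n_photons photons per run.
#' @param seed RNG seed (used for both runs).
#' @param floor low-fluence floor for the percent-change map.
#' @return List with both `mc_result`s (`fn`, `isn`), the percent-change map
#'   `pc`, and `max_region_pc`.
#' @export
run_lens_comparison <- function(setup, n_photons = 1e5, seed = 1,
                                floor = 1e-8) {
  run1 <- function(mode) {
    cfg <- sim_config(n_photons, mode = mode, source = setup$source,
                      seed = seed)
    simulate_photons(setup$volume, setup$media, cfg, setup$normal_map)
  }
  fn <- run1("facet")
  isn <- run1("interp")
  pc <- percent_change_map(fn$fluence, isn$fluence, floor = floor)
  sel <- setup$region & !is.na(pc)
  list(fn = fn, isn = isn, pc = pc, max_region_pc = max(pc[sel]))
}
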