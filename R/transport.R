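#' Collimated disk source
#'
#' Photons launch from points sampled uniformly on a disk of radius `radius`
#' (cm) centered at `origin` (cm), perpendicular to `direction`, all traveling
#' along `direction` with weight 1. `radius = 0` gives a pencil beam.
#'
#' @param origin cm triple, on or inside the grid.
#' @param direction beam direction (normalized internally).
#' @param radius disk radius, cm.
#' @return A `source_spec` list.
#' @export
source_spec <- function(origin, direction, radius = 0) {
  if (radius < 0) stop("source radius must be >= 0")
  d <- as.numeric(direction)
  m <- sqrt(sum(d^2))
  if (m <= 0) stop("source direction must be nonzero")
  structure(list(kind = "collimated_disk", origin = as.numeric(origin),
                 direction = d / m, radius = radius), class = "source_spec")
}

#' Simulation configuration
#'
#' @param n_photons number of photons to launch (>= 1).
#' @param mode boundary handling: `"matched"` (ignore index mismatches),
#'   `"facet"` (axis-aligned face normal), `"surface"` (stored smoothed
#'   normal of the pre-crossing voxel), or `"interp"` (same-medium-masked
#'   trilinear interpolation of neighboring normals).
#' @param source a [source_spec()].
#' @param seed RNG seed, or `NULL` to use the current RNG state.
#' @param roulette_threshold weight below which Russian roulette triggers.
#' @param roulette_survival survival multiplier (kill with probability
#'   `1 - 1/survival`, else multiply the weight by `survival`).
#' @param max_events per-photon event cap (loop safety; reached events are
#'   reported in the result totals).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_photons, mode = c("interp", "surface", "facet",
                                           "matched"),
                       source, seed = NULL, roulette_threshold = 1e-4,
                       roulette_survival = 10, max_events = 1e6) {
  mode <- match.arg(mode)
  if (n_photons < 1) stop("n_photons must be >= 1")
  if (roulette_threshold <= 0 || roulette_threshold >= 1)
    stop("roulette_threshold must lie in (0, 1)")
  if (roulette_survival <= 1) stop("roulette_survival must exceed 1")
  if (!inherits(source, "source_spec")) stop("`source` must be a source_spec")
  structure(list(n_photons = as.integer(n_photons), mode = mode,
                 source = source, seed = seed,
                 roulette_threshold = roulette_threshold,
                 roulette_survival = roulette_survival,
                 max_events = max_events), class = "sim_config")
}

mode_code <- function(mode) {
  match(mode, c("matched", "facet", "surface", "interp")) - 1L
}

# label-indexed property lookup vectors (position label+1)
media_lookup <- function(volume, media) {
  check_media_cover(volume, media)
  L <- max(media$label) + 1L
  out <- list(n = rep(1, L), mua = rep(0, L), mus = rep(0, L), g = rep(0, L))
  i <- media$label + 1L
  out$n[i] <- media$n; out$mua[i] <- media$mua
  out$mus[i] <- media$mus; out$g[i] <- media$g
  out
}

#' Run a Monte Carlo photon transport simulation
#'
#' Executes the hop/drop/spin loop with Fresnel handling at
#' refractive-index-mismatched voxel faces under the configured boundary
#' mode. The dimensionless step `s = -log(xi)` is consumed across voxels as
#' `mu_t * path`; voxels with `mu_t = 0` are traversed ballistically. At a
#' mismatched face the photon reflects with the unpolarized Fresnel
#' probability (single draw, no weight splitting), else refracts by Snell's
#' law. Photons exiting the outer grid faces escape and are recorded; no
#' Fresnel step is applied at the grid boundary itself.
#'
#' @param volume a [labeled_volume()].
#' @param media a [medium_table()].
#' @param cfg a [sim_config()].
#' @param normal_map a `normal_map`, required for `surface` and `interp`
#'   modes.
#' @return An `mc_result` list: `fluence` (a `fluence_grid`: absorbed weight
#'   per voxel normalized to W/cm^2 per W delivered), `escape` (data frame of
#'   escaping photons: photon id, exit face 1..6 (x-,x+,y-,y+,z-,z+),
#'   position cm, direction, weight, Fresnel reflection/transmission counts),
#'   `launch` (launch positions and directions), `totals` (weight
#'   bookkeeping) and the echoed configuration.
#' @export
simulate_photons <- function(volume, media, cfg, normal_map = NULL) {
  if (cfg$mode %in% c("surface", "interp") && is.null(normal_map))
    stop("surface and interp modes require a normal_map")
  if (!is.null(normal_map) && !identical(normal_map$shape, volume$shape))
    stop("normal map shape does not match the volume")
  lk <- media_lookup(volume, media)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  src <- cfg$source
  origin_vox <- src$origin / volume$dx
  if (any(origin_vox < 0) || any(origin_vox > volume$shape))
    stop("source origin lies outside the grid")
  empty <- numeric(0)
  res <- cpp_run(volume$labels, as.integer(volume$shape), volume$dx,
                 lk$n, lk$mua, lk$mus, lk$g,
                 if (is.null(normal_map)) empty else as.numeric(normal_map$gx),
                 if (is.null(normal_map)) empty else as.numeric(normal_map$gy),
                 if (is.null(normal_map)) empty else as.numeric(normal_map$gz),
                 mode_code(cfg$mode), cfg$n_photons,
                 src$origin, src$direction, src$radius,
                 cfg$roulette_threshold, cfg$roulette_survival,
                 cfg$max_events)
  deposit <- array(res$deposit, dim = volume$shape)
  # phi = deposited / (mua * dx^3 * N); voxels of mua = 0 media keep 0
  mua_vox <- array(lk$mua[volume$labels + 1L], dim = volume$shape)
  phi <- array(0, dim = volume$shape)
  pos <- mua_vox > 0
  phi[pos] <- deposit[pos] / (mua_vox[pos] * volume$dx^3 * cfg$n_photons)
  esc <- as.data.frame(res$escape)
  names(esc) <- c("id", "face", "x", "y", "z", "ux", "uy", "uz", "weight",
                  "n_reflections", "n_transmissions")
  launch <- as.data.frame(res$launch)
  names(launch) <- c("x", "y", "z", "ux", "uy", "uz")
  structure(list(
    fluence = structure(list(values = phi, deposit = deposit,
                             dx = volume$dx, n_photons = cfg$n_photons,
                             seed = cfg$seed, mode = cfg$mode),
                        class = "fluence_grid"),
    escape = esc, launch = launch,
    totals = c(res$totals, launched = as.numeric(cfg$n_photons)),
    n_truncated = res$n_truncated, config = cfg), class = "mc_result")
}

#' Weight-conservation residual of a run
#'
#' `launched - deposited - escaped - roulette_killed + roulette_gained
#'  - truncated`, relative to the launched weight. Zero up to floating-point
#' rounding for every run.
#'
#' @param result an `mc_result`.
#' @return Relative residual (dimensionless).
#' @export
conservation_residual <- function(result) {
  t <- result$totals
  (t[["launched"]] - t[["deposited"]] - t[["escaped"]] -
     t[["roulette_killed"]] + t[["roulette_gained"]] -
     t[["truncated_weight"]]) / t[["launched"]]
}

#' @export
print.mc_result <- function(x, ...) {
  t <- x$totals
  cat(sprintf("Monte Carlo run: %d photons, mode '%s'%s\n",
              x$config$n_photons, x$config$mode,
              if (is.null(x$config$seed)) "" else
                sprintf(", seed %d", x$config$seed)))
  cat(sprintf("  deposited %.4f | escaped %.4f | roulette net %.4f (of %g launched)\n",
              t[["deposited"]], t[["escaped"]],
              t[["roulette_killed"]] - t[["roulette_gained"]],
              t[["launched"]]))
  cat(sprintf("  %d escape records; conservation residual %.2e\n",
              nrow(x$escape), conservation_residual(x)))
  invisible(x)
}

#' @export
print.fluence_grid <- function(x, ...) {
  cat(sprintf("Fluence grid %s, dx = %g cm, %d photons, mode '%s'\n",
              paste(dim(x$values), collapse = " x "), x$dx, x$n_photons,
              x$mode))
  cat(sprintf("  phi range [0, %.4g] W/cm^2/W\n", max(x$values)))
  invisible(x)
}

#' Sample Henyey-Greenstein scattering angle cosines
#'
#' Inverse-CDF sampling of `cos(theta)` for anisotropy `g`; uniform on
#' `[-1, 1]` for `g = 0`. Mean of the distribution equals `g`.
#'
#' @param n number of draws.
#' @param g anisotropy, `|g| < 1`.
#' @return Numeric vector of cosines.
#' @export
hg_sample <- function(n, g) cpp_hg_sample(as.integer(n), g)

#' Scatter a direction by Henyey-Greenstein draws
#'
#' @param direction unit incoming direction.
#' @param g anisotropy.
#' @param n number of independent scattered directions to draw.
#' @return `n x 3` matrix of unit directions.
#' @export
spin_direction <- function(direction, g, n = 1) {
  cpp_spin(as.numeric(direction), g, as.integer(n))
}

#' Russian roulette on photon weights
#'
#' Weights below `threshold` survive with probability `1/survival` (and are
#' multiplied by `survival`) or are set to zero; the expected weight is
#' preserved. Weights at or above the threshold pass through untouched.
#'
#' @param w numeric weights.
#' @param threshold roulette trigger weight.
#' @param survival survival multiplier (> 1).
#' @return Post-roulette weights.
#' @export
roulette <- function(w, threshold = 1e-4, survival = 10) {
  if (survival <= 1) stop("survival multiplier must exceed 1")
  cpp_roulette(as.numeric(w), threshold, survival)
}
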