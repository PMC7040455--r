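# Analytic ray tracer for spheres and spherical lens surfaces. Serves as
# geometry ground truth for the Monte Carlo boundary handling: exact
# ray-sphere intersections, Snell/Fresnel applied analytically at each hit,
# deterministic branch (transmit unless total internal reflection).

#' Analytic sphere scene
#'
#' @param center sphere center, cm triple.
#' @param radius sphere radius, cm.
#' @param n_inside,n_ambient refractive indices inside and outside.
#' @return An `analytic_scene`.
#' @export
sphere_scene <- function(center, radius, n_inside, n_ambient = 1) {
  if (radius <= 0) stop("radius must be positive")
  structure(list(kind = "sphere",
                 spheres = list(list(center = as.numeric(center),
                                     radius = radius)),
                 n_inside = n_inside, n_ambient = n_ambient,
                 n_at = function(p) {
                   if (sum((p - center)^2) < radius^2) n_inside else n_ambient
                 }), class = "analytic_scene")
}

#' Analytic biconvex lens scene
#'
#' Same parameterization as [make_biconvex_lens()]: the lens medium is the
#' intersection of the two surface balls, clipped to the aperture cylinder
#' around the z axis.
#'
#' @inheritParams make_biconvex_lens
#' @param n_lens,n_ambient refractive indices of lens and surround.
#' @return An `analytic_scene`.
#' @export
lens_scene <- function(center, R1, R2, thickness, aperture, n_lens,
                       n_ambient) {
  a <- aperture / 2
  c1 <- c(center[1], center[2], center[3] - thickness / 2 + R1)
  c2 <- c(center[1], center[2], center[3] + thickness / 2 - R2)
  structure(list(kind = "lens",
                 spheres = list(list(center = c1, radius = R1),
                                list(center = c2, radius = R2)),
                 n_inside = n_lens, n_ambient = n_ambient,
                 n_at = function(p) {
                   rho2 <- (p[1] - center[1])^2 + (p[2] - center[2])^2
                   if (rho2 < a^2 &&
                       sum((p - c1)^2) < R1^2 && sum((p - c2)^2) < R2^2)
                     n_lens else n_ambient
                 }), class = "analytic_scene")
}

# smallest positive root of |o + t d - c|^2 = r^2 beyond t > eps, and the next
ray_sphere_ts <- function(origin, dir, center, radius, eps = 1e-9) {
  oc <- origin - center
  b <- sum(oc * dir)
  disc <- b^2 - (sum(oc^2) - radius^2)
  if (disc <= 0) return(numeric(0))
  s <- sqrt(disc)
  ts <- c(-b - s, -b + s)
  ts[ts > eps]
}

#' Trace a ray through an analytic scene
#'
#' Follows the deterministic branch: at each surface hit with a refractive
#' mismatch the ray transmits by Snell's law (recording the Fresnel
#' reflectance), except under total internal reflection, where it reflects.
#' Rays that miss every surface run straight to the scene bound.
#'
#' @param origin,direction launch ray (direction normalized internally).
#' @param scene an `analytic_scene`.
#' @param max_events cap on surface interactions.
#' @param t_max path length bound, cm.
#' @return List with `polyline` (matrix of vertices), `events` (data frame
#'   with position, incidence/transmission angles in degrees, and Fresnel
#'   reflectance per hit), and `final_dir`.
#' @export
trace_ray <- function(origin, direction, scene, max_events = 20, t_max = 50) {
  p <- as.numeric(origin)
  d <- as.numeric(direction)
  d <- d / sqrt(sum(d^2))
  poly <- matrix(p, 1, 3)
  ev <- list()
  eps <- 1e-9
  for (k in seq_len(max_events)) {
    ts <- sort(unlist(lapply(scene$spheres, function(s)
      ray_sphere_ts(p, d, s$center, s$radius, eps = 1e-7))))
    hit <- FALSE
    for (t in ts) {
      q <- p + t * d
      n1 <- scene$n_at(q - 1e-6 * d)
      n2 <- scene$n_at(q + 1e-6 * d)
      if (n1 == n2) next
      # surface normal from whichever sphere this hit lies on
      nrm <- NULL
      for (s in scene$spheres) {
        if (abs(sqrt(sum((q - s$center)^2)) - s$radius) < 1e-6) {
          nrm <- (q - s$center) / s$radius
          break
        }
      }
      if (is.null(nrm)) next
      nrm <- orient_normal(nrm, d)
      ci <- -sum(d * nrm)
      R <- fresnel_reflectance(d, nrm, n1, n2)
      theta_i <- acos(pmin(1, ci)) * 180 / pi
      if (R >= 1) {  # TIR: follow the reflected ray
        d_new <- specular_reflect(d, nrm)
        theta_t <- NA_real_
      } else {
        d_new <- snell_refract(d, nrm, n1, n2)
        theta_t <- asin(pmin(1, n1 / n2 * sin(theta_i * pi / 180))) * 180 / pi
      }
      ev[[length(ev) + 1]] <- data.frame(
        x = q[1], y = q[2], z = q[3], theta_i_deg = theta_i,
        theta_t_deg = theta_t, R = R, n1 = n1, n2 = n2)
      p <- q + 1e-9 * d_new
      d <- d_new
      poly <- rbind(poly, q)
      hit <- TRUE
      break
    }
    if (!hit) break
  }
  poly <- rbind(poly, p + t_max * d)
  list(polyline = poly,
       events = if (length(ev)) do.call(rbind, ev) else
         data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                    theta_i_deg = numeric(0), theta_t_deg = numeric(0),
                    R = numeric(0), n1 = numeric(0), n2 = numeric(0)),
       final_dir = d)
}

#' Analytic specular reflection off the first sphere hit
#'
#' @param origin,direction launch ray.
#' @param scene an `analytic_scene` (the first sphere is used).
#' @return Unit reflected direction, or `NULL` if the ray misses.
#' @export
specular_reflection <- function(origin, direction, scene) {
  d <- as.numeric(direction)
  d <- d / sqrt(sum(d^2))
  s <- scene$spheres[[1]]
  ts <- ray_sphere_ts(as.numeric(origin), d, s$center, s$radius)
  if (!length(ts)) return(NULL)
  q <- as.numeric(origin) + min(ts) * d
  nrm <- (q - s$center) / s$radius
  specular_reflect(d, nrm)
}

#' Angular error of Monte Carlo reflected photons against the oracle
#'
#' For each escaping photon that underwent exactly one Fresnel reflection and
#' no transmission (i.e. bounced off the first surface), computes the angle
#' between its escape direction and the analytic specular reflection of the
#' same launch ray. Photons whose launch ray misses the analytic surface are
#' excluded and counted.
#'
#' @param result an `mc_result` from [simulate_photons()] with scattering off.
#' @param scene the matching `analytic_scene`.
#' @return Numeric vector of per-photon errors in degrees, with attributes
#'   `n_excluded` (no analytic hit) and `ids`.
#' @export
reflected_angle_error <- function(result, scene) {
  esc <- result$escape
  sel <- esc$n_reflections == 1 & esc$n_transmissions == 0
  esc <- esc[sel, , drop = FALSE]
  errs <- numeric(0)
  ids <- integer(0)
  n_excluded <- 0L
  for (r in seq_len(nrow(esc))) {
    id <- esc$id[r]
    lr <- result$launch[id, ]
    ref <- specular_reflection(c(lr$x, lr$y, lr$z), c(lr$ux, lr$uy, lr$uz),
                               scene)
    if (is.null(ref)) { n_excluded <- n_excluded + 1L; next }
    mc <- c(esc$ux[r], esc$uy[r], esc$uz[r])
    cosang <- sum(mc * ref) / sqrt(sum(mc^2))
    errs <- c(errs, acos(pmin(1, pmax(-1, cosang))) * 180 / pi)
    ids <- c(ids, id)
  }
  attr(errs, "n_excluded") <- n_excluded
  attr(errs, "ids") <- ids
  errs
}

#' Paraxial focal length of a thin lens immersed in a medium
#'
#' Lensmaker's equation in a medium:
#' `1/f = (n_lens/n_ambient - 1) (1/R1 + 1/R2)` for a biconvex lens.
#'
#' @inheritParams lens_scene
#' @return Focal length, cm (from the lens mid-plane, thin-lens limit).
#' @export
lensmaker_focal <- function(R1, R2, n_lens, n_ambient) {
  1 / ((n_lens / n_ambient - 1) * (1 / R1 + 1 / R2))
}

#' Axis crossings of rays focused by an analytic lens
#'
#' Traces axis-parallel rays at the given heights through the lens scene and
#' returns the z at which each exit ray crosses the lens axis.
#'
#' @param scene a lens `analytic_scene` centered on the z axis.
#' @param heights launch heights (cm) off the axis.
#' @param z_start launch plane, cm.
#' @return Numeric vector of axis-crossing z values, cm.
#' @export
lens_axis_crossings <- function(scene, heights, z_start = 0) {
  cx <- scene$spheres[[1]]$center[1]
  cy <- scene$spheres[[1]]$center[2]
  vapply(heights, function(h) {
    tr <- trace_ray(c(cx + h, cy, z_start), c(0, 0, 1), scene)
    p <- tr$polyline[nrow(tr$polyline) - 1, ]
    d <- tr$final_dir
    if (abs(d[1]) < 1e-12) return(NA_real_)
    t <- (cx - p[1]) / d[1]
    p[3] + t * d[3]
  }, 0)
}

#' Beam-edge angular error of the reflected beam
#'
#' Compares the *edges* of the Monte Carlo reflected beam with the analytic
#' reflected beam. The beam edge is the rim of the source disk: reflected
#' photons (one Fresnel reflection, no transmission) launched within the
#' outer `edge_frac` annulus of the disk form the edge set, split into the
#' near-side and far-side edges by launch impact parameter relative to the
#' beam axis. For each edge the mean Monte Carlo reflected direction is
#' compared against the mean analytic specular reflection of the same launch
#' rays; the angle between the two mean directions is that edge's error.
#'
#' @param result an `mc_result` with scattering off.
#' @param scene the matching sphere `analytic_scene`.
#' @param edge_frac fraction of the source-disk radius forming the rim
#'   annulus.
#' @return Named numeric vector `c(edge_inner, edge_outer)` of angular errors
#'   in degrees, with attribute `n_band` (photons per edge).
#' @export
beam_edge_error <- function(result, scene, edge_frac = 0.1) {
  esc <- result$escape
  sel <- esc$n_reflections == 1 & esc$n_transmissions == 0
  esc <- esc[sel, , drop = FALSE]
  s <- scene$spheres[[1]]
  lau <- result$launch
  src <- result$config$source
  # impact parameter of every launch ray w.r.t. the sphere
  rel <- cbind(lau$x - s$center[1], lau$y - s$center[2], lau$z - s$center[3])
  dirs <- cbind(lau$ux, lau$uy, lau$uz)
  proj <- rowSums(rel * dirs)
  b_all <- sqrt(pmax(0, rowSums(rel^2) - proj^2))
  # distance from the beam axis within the source disk
  rel_s <- cbind(lau$x - src$origin[1], lau$y - src$origin[2],
                 lau$z - src$origin[3])
  proj_s <- rowSums(rel_s * dirs)
  r_disk <- sqrt(pmax(0, rowSums(rel_s^2) - proj_s^2))
  rim <- r_disk >= (1 - edge_frac) * max(r_disk)
  # impact parameter of the beam axis ray
  rel_ax <- src$origin - s$center
  b_axis <- sqrt(max(0, sum(rel_ax^2) - sum(rel_ax * src$direction)^2))
  out <- c(edge_inner = NA_real_, edge_outer = NA_real_)
  n_band <- c(0L, 0L)
  for (side in 1:2) {
    in_band <- rim & (if (side == 1) b_all < b_axis else b_all >= b_axis)
    ids <- esc$id[in_band[esc$id]]
    if (!length(ids)) next
    rows <- esc[match(ids, esc$id), , drop = FALSE]
    mc_mean <- colSums(cbind(rows$ux, rows$uy, rows$uz))
    an <- t(vapply(ids, function(id) {
      lr <- lau[id, ]
      r <- specular_reflection(c(lr$x, lr$y, lr$z), c(lr$ux, lr$uy, lr$uz),
                               scene)
      if (is.null(r)) c(NA_real_, NA_real_, NA_real_) else r
    }, numeric(3)))
    an <- an[stats::complete.cases(an), , drop = FALSE]
    if (!nrow(an)) next
    an_mean <- colSums(an)
    cosang <- sum(mc_mean * an_mean) /
      sqrt(sum(mc_mean^2) * sum(an_mean^2))
    out[side] <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    n_band[side] <- nrow(an)
  }
  attr(out, "n_band") <- n_band
  out
}
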