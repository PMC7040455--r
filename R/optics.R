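#' Orient a boundary normal against the incident direction
#'
#' Returns the normal or its negation such that it faces the incoming photon
#' (`dot(normal, incident) <= 0`).
#'
#' @param normal nonzero normal vector (normalized internally).
#' @param incident unit incident direction.
#' @return Oriented unit normal.
#' @export
orient_normal <- function(normal, incident) {
  cpp_orient_normal(as.numeric(normal), as.numeric(incident))
}

#' Unpolarized Fresnel reflectance
#'
#' Average of the s- and p-polarized intensity reflectances for light crossing
#' from index `n1` into `n2` at the given boundary normal. Returns 1 at or
#' beyond the critical angle (total internal reflection).
#'
#' @param incident unit incident direction.
#' @param normal boundary normal (any orientation; oriented internally).
#' @param n1,n2 refractive indices on the incident and far side.
#' @return Reflection probability in `[0, 1]`.
#' @export
fresnel_reflectance <- function(incident, normal, n1, n2) {
  cpp_fresnel_reflectance(as.numeric(incident), as.numeric(normal), n1, n2)
}

#' Specular reflection of a direction at a boundary
#'
#' @inheritParams fresnel_reflectance
#' @return Unit reflected direction `d - 2 (d . n) n`.
#' @export
specular_reflect <- function(incident, normal) {
  cpp_reflect(as.numeric(incident), as.numeric(normal))
}

#' Snell refraction of a direction at a boundary
#'
#' Vector form of Snell's law. Errors under total internal reflection; the
#' caller must branch on [fresnel_reflectance()] first.
#'
#' @inheritParams fresnel_reflectance
#' @return Unit transmitted direction, coplanar with `incident` and `normal`.
#' @export
snell_refract <- function(incident, normal, n1, n2) {
  cpp_refract(as.numeric(incident), as.numeric(normal), n1, n2)
}
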