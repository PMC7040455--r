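# 2-D straight-edge orientation sweeps quantifying the worst-case direction
# error of the facet-normal convention versus the 3x3 Sobel gradient estimate.
#
# Edge model: an ideal step edge with normal at angle phi. Rasterization uses
# the exact area fraction of the half-plane over each pixel square (the ideal
# sampled step edge); a hard binary threshold of the same half-plane is also
# available for comparison, but its staircase corners dominate the error and
# do not measure the operator itself.

# exact area of the unit pixel square (center origin) on the positive side of
# the line c1*x + s1*y + D = 0, via polygon clipping
pixel_coverage <- function(D, c1, s1) {
  if (D >= 0.5 * (abs(c1) + abs(s1))) return(1)
  if (D <= -0.5 * (abs(c1) + abs(s1))) return(0)
  px <- c(-0.5, 0.5, 0.5, -0.5); py <- c(-0.5, -0.5, 0.5, 0.5)
  f <- c1 * px + s1 * py + D
  ox <- numeric(0); oy <- numeric(0)
  for (i in 1:4) {
    j <- i %% 4 + 1
    if (f[i] >= 0) { ox <- c(ox, px[i]); oy <- c(oy, py[i]) }
    if ((f[i] > 0 && f[j] < 0) || (f[i] < 0 && f[j] > 0)) {
      t <- f[i] / (f[i] - f[j])
      ox <- c(ox, px[i] + t * (px[j] - px[i]))
      oy <- c(oy, py[i] + t * (py[j] - py[i]))
    }
  }
  if (length(ox) < 3) return(0)
  abs(sum(ox * c(oy[-1], oy[1]) - c(ox[-1], ox[1]) * oy)) / 2
}

#' Rasterize a 2-D half-plane edge
#'
#' Pixel centers sit at integer coordinates of an `n x n` grid centered on the
#' origin. The half-plane has unit normal `(cos(phi), sin(phi))` (phi in
#' degrees) and signed offset `offset` (pixels) from the origin.
#'
#' @param phi_deg edge-normal orientation, degrees.
#' @param offset signed sub-pixel offset of the edge line, pixels.
#' @param n image size (odd recommended).
#' @param model `"coverage"` for exact area sampling of the ideal step edge,
#'   `"binary"` for hard thresholding of pixel centers.
#' @return `n x n` matrix of pixel values in `[0, 1]`.
#' @export
half_plane_image <- function(phi_deg, offset = 0, n = 25,
                             model = c("coverage", "binary")) {
  model <- match.arg(model)
  phi <- phi_deg * pi / 180
  c1 <- cos(phi); s1 <- sin(phi)
  if (abs(c1) < 1e-12) c1 <- 0  # snap axis-aligned edges exactly
  if (abs(s1) < 1e-12) s1 <- 0
  xs <- seq_len(n) - (n + 1) / 2
  D <- outer(xs * c1, xs * s1, `+`) - offset
  if (model == "binary") return((D > 0) * 1)
  matrix(vapply(D, pixel_coverage, 0, c1 = c1, s1 = s1), n, n)
}

#' 2-D 3x3 Sobel gradient
#'
#' Derivative kernel `(-1, 0, 1)` crossed with smoothing kernel `(1, 2, 1)`,
#' replicate padding. `gx` differentiates along rows (the first index).
#'
#' @param img numeric matrix.
#' @return List with `gx`, `gy` matrices.
#' @export
sobel2d <- function(img) {
  n <- nrow(img); m <- ncol(img)
  p <- img[c(1, seq_len(n), n), c(1, seq_len(m), m)]
  deriv <- c(-1, 0, 1); sm <- c(1, 2, 1)
  gx <- matrix(0, n, m); gy <- matrix(0, n, m)
  for (di in -1:1) for (dj in -1:1) {
    sub <- p[(2 + di):(n + 1 + di), (2 + dj):(m + 1 + dj)]
    gx <- gx + deriv[di + 2] * sm[dj + 2] * sub
    gy <- gy + sm[di + 2] * deriv[dj + 2] * sub
  }
  list(gx = gx, gy = gy)
}

angdiff_deg <- function(a, b) {
  d <- (a - b + pi) %% (2 * pi) - pi
  abs(d) * 180 / pi
}

#' Worst-case facet-normal direction error over an edge-orientation sweep
#'
#' The facet normal of a boundary pixel is axis-aligned by construction, so
#' its direction error against an edge with normal at angle `phi` is the
#' angle to the nearest coordinate axis.
#'
#' @param phis_deg edge orientations to sweep, degrees (default 0..45).
#' @return List with `max_error_deg` and the per-orientation `errors`.
#' @export
facet_edge_error_sweep <- function(phis_deg = seq(0, 45, by = 0.05)) {
  err <- pmin(phis_deg %% 90, 90 - phis_deg %% 90)
  list(max_error_deg = max(err), errors = err, phis_deg = phis_deg)
}

#' Worst-case Sobel direction error over an edge sweep
#'
#' Rasterizes ideal step edges over a sweep of orientations and sub-pixel
#' offsets, applies the 3x3 Sobel operator, and measures the gradient
#' direction error at pixels whose center lies on the edge line (within
#' `adjacency` pixels), where the operator's estimate is defined.
#'
#' @param phis_deg orientations to sweep, degrees.
#' @param offsets sub-pixel edge offsets to sweep, pixels.
#' @param adjacency max pixel-center distance to the line, pixels.
#' @param n image size.
#' @param model edge model passed to [half_plane_image()].
#' @return List with `max_error_deg`, and the error matrix over the sweep.
#' @export
sobel_edge_error_sweep <- function(phis_deg = seq(0, 45, by = 0.05),
                                   offsets = 0, adjacency = 0.05, n = 15,
                                   model = "coverage") {
  xs <- seq_len(n) - (n + 1) / 2
  interior <- 2  # keep the 3x3 support away from the replicate-padded rim
  E <- matrix(NA_real_, length(phis_deg), length(offsets))
  for (i in seq_along(phis_deg)) {
    phi <- phis_deg[i] * pi / 180
    c1 <- cos(phi); s1 <- sin(phi)
    for (j in seq_along(offsets)) {
      img <- half_plane_image(phis_deg[i], offsets[j], n, model)
      D <- outer(xs * c1, xs * s1, `+`) - offsets[j]
      g <- sobel2d(img)
      sel <- abs(D) <= adjacency &
        row(D) > interior & row(D) <= n - interior &
        col(D) > interior & col(D) <= n - interior &
        (g$gx^2 + g$gy^2) > 1e-12
      if (!any(sel)) next
      ang <- atan2(g$gy[sel], g$gx[sel])
      E[i, j] <- max(angdiff_deg(ang, phi))
    }
  }
  list(max_error_deg = max(E, na.rm = TRUE), errors = E,
       phis_deg = phis_deg, offsets = offsets)
}
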