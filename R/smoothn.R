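# Penalized least-squares smoothing of gridded data via the discrete cosine
# transform (Garcia 2010 / Buckley 1994). The smoothed field is
#   y_hat = IDCT( Gamma * DCT(y) ),  Gamma = 1 / (1 + s * Lambda^2),
# where Lambda is the DCT eigenvalue field of the discrete Laplacian,
#   Lambda(k1,k2,k3) = sum_d ( -2 + 2 cos((k_d - 1) pi / n_d ) ),
# and s >= 0 is the scalar smoothing factor. DCT-II implies reflective
# (Neumann) boundary handling, so constants are reproduced exactly and no
# spurious gradients appear at the grid faces.

# orthonormal DCT-II matrix of order n (C %*% x transforms, t(C) inverts)
dct_matrix <- function(n) {
  k <- 0:(n - 1)
  j <- 0:(n - 1)
  C <- sqrt(2 / n) * cos(pi * outer(k, 2 * j + 1) / (2 * n))
  C[1, ] <- C[1, ] / sqrt(2)
  C
}

# multiply a 3-D array by M along one axis
apply_axis <- function(a, M, axis) {
  d <- dim(a)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  if (axis != 1) a <- aperm(a, perm)
  dd <- dim(a)
  a <- M %*% matrix(a, dd[1], dd[2] * dd[3])
  dim(a) <- dd
  if (axis != 1) a <- aperm(a, order(perm))
  a
}

dct3 <- function(a, Cs) {
  for (ax in 1:3) a <- apply_axis(a, Cs[[ax]], ax)
  a
}

idct3 <- function(a, Cs) {
  for (ax in 1:3) a <- apply_axis(a, t(Cs[[ax]]), ax)
  a
}

# DCT eigenvalues of the 3-D discrete Laplacian, as a full array
laplacian_eigenvalues <- function(shape) {
  lam <- lapply(shape, function(n) -2 + 2 * cos((0:(n - 1)) * pi / n))
  l12 <- outer(lam[[1]], lam[[2]], `+`)
  out <- array(0, dim = shape)
  for (k in seq_len(shape[3])) out[, , k] <- l12 + lam[[3]][k]
  out
}

# smooth one 3-D array with smoothing factor s (s = 0 returns the input)
smoothn_dct <- function(a, s, Cs = NULL, Gamma = NULL) {
  if (s == 0) return(a)
  d <- dim(a)
  if (is.null(Cs)) Cs <- lapply(d, dct_matrix)
  if (is.null(Gamma)) Gamma <- 1 / (1 + s * laplacian_eigenvalues(d)^2)
  idct3(dct3(a, Cs) * Gamma, Cs)
}
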