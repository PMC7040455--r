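# Native on-disk formats: raw little-endian binaries (uint8 labels, float32
# normals/fluence, x-fastest ordering) plus a JSON sidecar carrying shape,
# voxel size, the medium table and enough run metadata to reproduce a
# simulation. CSV for the escape record.

FORMAT_VERSION <- 1L

sidecar_path <- function(prefix) paste0(prefix, ".json")

write_sidecar <- function(prefix, payload) {
  payload$format_version <- FORMAT_VERSION
  jsonlite::write_json(payload, sidecar_path(prefix), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

read_sidecar <- function(prefix) {
  sc <- jsonlite::read_json(sidecar_path(prefix), simplifyVector = TRUE)
  if (is.null(sc$format_version) || sc$format_version != FORMAT_VERSION)
    stop("unknown or missing sidecar format version in ", sidecar_path(prefix))
  if (is.null(sc$dx) || sc$dx <= 0)
    stop("sidecar dx must be positive in ", sidecar_path(prefix))
  sc
}

read_raw_array <- function(path, shape, what, size) {
  n_expect <- prod(shape)
  info <- file.info(path)
  if (is.na(info$size)) stop("missing binary file ", path)
  n_bytes <- n_expect * size
  if (info$size != n_bytes)
    stop(sprintf("%s: expected %d bytes (%d voxels x %d), found %d",
                 path, n_bytes, n_expect, size, info$size))
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, what = what, n = n_expect, size = size,
               endian = "little")
  array(v, dim = shape)
}

#' Write / read a labeled volume with its medium table
#'
#' `<prefix>.vol.bin` holds the labels as uint8 (x-fastest ordering);
#' `<prefix>.json` carries shape, dx and the medium table.
#'
#' @param volume a [labeled_volume()].
#' @param media a [medium_table()].
#' @param prefix file path prefix.
#' @return `write_volume` returns `prefix` invisibly; `read_volume` returns
#'   `list(volume, media)`.
#' @export
write_volume <- function(volume, media, prefix) {
  check_media_cover(volume, media)
  if (max(volume$labels) > 255L) stop("labels exceed uint8 range")
  con <- file(paste0(prefix, ".vol.bin"), "wb")
  writeBin(as.raw(as.vector(volume$labels)), con)
  close(con)
  write_sidecar(prefix, list(kind = "volume", shape = volume$shape,
                             dx = volume$dx,
                             media = as.data.frame(unclass(media))))
  invisible(prefix)
}

#' @rdname write_volume
#' @export
read_volume <- function(prefix) {
  sc <- read_sidecar(prefix)
  if (!identical(sc$kind, "volume")) stop("sidecar is not a volume sidecar")
  shape <- as.integer(sc$shape)
  raw <- read_raw_array(paste0(prefix, ".vol.bin"), shape, "raw", 1L)
  labels <- array(as.integer(raw), dim = shape)
  media <- do.call(medium_table, sc$media[c("label", "n", "mua", "mus", "g")])
  list(volume = labeled_volume(labels, sc$dx), media = media)
}

#' Write / read a normal map
#'
#' Three raw float32 binaries `<prefix>.gx.bin` etc. plus a JSON sidecar.
#' Values round-trip bit-exactly at float32 precision.
#'
#' @param nm a `normal_map`.
#' @param prefix file path prefix.
#' @export
write_normals <- function(nm, prefix) {
  for (comp in c("gx", "gy", "gz")) {
    con <- file(paste0(prefix, ".", comp, ".bin"), "wb")
    writeBin(as.vector(nm[[comp]]), con, size = 4, endian = "little")
    close(con)
  }
  write_sidecar(prefix, list(kind = "normals", shape = nm$shape, dx = nm$dx))
  invisible(prefix)
}

#' @rdname write_normals
#' @export
read_normals <- function(prefix) {
  sc <- read_sidecar(prefix)
  if (!identical(sc$kind, "normals")) stop("sidecar is not a normals sidecar")
  shape <- as.integer(sc$shape)
  out <- lapply(c("gx", "gy", "gz"), function(comp)
    read_raw_array(paste0(prefix, ".", comp, ".bin"), shape, "numeric", 4L))
  structure(list(gx = out[[1]], gy = out[[2]], gz = out[[3]], shape = shape,
                 dx = sc$dx), class = "normal_map")
}

#' Write / read a fluence grid
#'
#' `<prefix>.phi.bin` holds phi (W/cm^2 per W delivered) as float32; the
#' sidecar echoes dx, photon count, seed and boundary mode.
#'
#' @param fl a `fluence_grid` from [simulate_photons()].
#' @param prefix file path prefix.
#' @export
write_fluence <- function(fl, prefix) {
  con <- file(paste0(prefix, ".phi.bin"), "wb")
  writeBin(as.vector(fl$values), con, size = 4, endian = "little")
  close(con)
  write_sidecar(prefix, list(kind = "fluence", shape = dim(fl$values),
                             dx = fl$dx, n_photons = fl$n_photons,
                             seed = fl$seed, mode = fl$mode,
                             units = "W/cm^2/W"))
  invisible(prefix)
}

#' @rdname write_fluence
#' @export
read_fluence <- function(prefix) {
  sc <- read_sidecar(prefix)
  if (!identical(sc$kind, "fluence")) stop("sidecar is not a fluence sidecar")
  shape <- as.integer(sc$shape)
  values <- read_raw_array(paste0(prefix, ".phi.bin"), shape, "numeric", 4L)
  structure(list(values = values, dx = sc$dx, n_photons = sc$n_photons,
                 seed = sc$seed, mode = sc$mode), class = "fluence_grid")
}

#' Write / read an escape record as CSV
#'
#' @param escape the `escape` data frame of an `mc_result`.
#' @param path CSV file path.
#' @export
write_escape <- function(escape, path) {
  write.csv(escape, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_escape
#' @export
read_escape <- function(path) read.csv(path)

#' Voxel-wise percent change between two fluence grids
#'
#' `100 * (phi_a - phi_b) / phi_b` wherever `phi_b > floor`; other voxels are
#' `NA` (masked). The floor avoids division blow-ups in voxels the reference
#' run barely visited.
#'
#' @param phi_a,phi_b `fluence_grid` objects (or plain arrays) of equal shape.
#' @param floor minimum reference fluence for a valid voxel.
#' @return 3-D array of percent changes with `NA` outside the valid mask.
#' @export
percent_change_map <- function(phi_a, phi_b, floor = 1e-8) {
  a <- if (inherits(phi_a, "fluence_grid")) phi_a$values else phi_a
  b <- if (inherits(phi_b, "fluence_grid")) phi_b$values else phi_b
  if (!identical(dim(a), dim(b))) stop("fluence grids differ in shape")
  out <- array(NA_real_, dim = dim(a))
  ok <- b > floor
  out[ok] <- 100 * (a[ok] - b[ok]) / b[ok]
  out
}
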