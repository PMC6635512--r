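#' Construct a CT core volume
#'
#' Wraps a 3D grayscale voxel grid with its physical metadata.  Gray values
#' must lie within the stated bit depth (0-255 or 0-65535).
#'
#' @param voxels 3D integer array of gray values (x, y, z).
#' @param voxel_size isotropic voxel edge length in micrometers.
#' @param bit_depth 8 or 16; guessed from the data range if `NULL`.
#' @param core_id,system_label identifiers carried through the pipeline.
#' @return an object of class `zp_volume`.
#' @export
core_volume <- function(voxels, voxel_size, bit_depth = NULL,
                        core_id = "core", system_label = "") {
  .zp_stopifnot_dim3(voxels)
  if (length(voxels) == 0L) stop("volume grid is empty")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("voxel_size must be a single positive number (micrometers)")
  storage.mode(voxels) <- "integer"
  rng <- range(voxels)
  if (is.null(bit_depth)) bit_depth <- if (rng[2] > 255L) 16L else 8L
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (rng[1] < 0L || rng[2] > (2L^bit_depth - 1L))
    stop("gray values outside the ", bit_depth, "-bit range")
  structure(
    list(voxels = voxels, voxel_size = voxel_size,
         bit_depth = as.integer(bit_depth), core_id = core_id,
         system_label = system_label, border_trimmed = FALSE,
         excluded = NULL),
    class = "zp_volume")
}

#' @export
print.zp_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<zp_volume> %s: %d x %d x %d voxels @ %.4g um, %d-bit%s\n",
              x$core_id, d[1], d[2], d[3], x$voxel_size, x$bit_depth,
              if (x$border_trimmed) ", border trimmed" else ""))
  invisible(x)
}

# logical mask of voxels retained for analysis
.zp_included <- function(vol) {
  if (is.null(vol$excluded)) rep(TRUE, length(vol$voxels)) else !vol$excluded
}

#' Rescale a 16-bit volume to the 8-bit axis
#'
#' Min-max rescales gray values to 0-255 (rounded).  Histogram fitting and
#' thresholding operate on the 8-bit axis; applying this consistently to
#' fitting and segmentation keeps the threshold meaningful for 16-bit
#' acquisitions.  8-bit input is returned unchanged.
#'
#' @param vol a [core_volume()].
#' @return an 8-bit `zp_volume`.
#' @export
rescale_to_8bit <- function(vol) {
  stopifnot(inherits(vol, "zp_volume"))
  if (vol$bit_depth == 8L) return(vol)
  rng <- range(vol$voxels)
  span <- max(1L, rng[2] - rng[1])
  v <- vol$voxels
  v[] <- as.integer(round((as.numeric(v) - rng[1]) / span * 255))
  out <- vol
  out$voxels <- v
  out$bit_depth <- 8L
  out
}

#' Read / write a CT volume as multi-page TIFF
#'
#' `read_volume_tiff()` loads a z-stack (one page per slice) into a
#' [core_volume()]; `write_volume_tiff()` writes one.  Gray values are
#' stored at the volume's bit depth.
#'
#' @param path file path of a multi-page grayscale TIFF.
#' @param voxel_size voxel edge length in micrometers.
#' @param vol a `zp_volume`.
#' @param ... passed on to [core_volume()].
#' @return `read_volume_tiff()` returns a `zp_volume`;
#'   `write_volume_tiff()` returns `path` invisibly.
#' @export
read_volume_tiff <- function(path, voxel_size, ...) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(!vapply(pages, is.matrix, logical(1))))
    stop("expected single-channel grayscale pages in ", path)
  arr <- array(0L, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- as.integer(pages[[k]])
  core_volume(arr, voxel_size = voxel_size, ...)
}

#' @rdname read_volume_tiff
#' @export
write_volume_tiff <- function(vol, path) {
  stopifnot(inherits(vol, "zp_volume"))
  denom <- 2^vol$bit_depth - 1
  pages <- lapply(seq_len(dim(vol$voxels)[3]),
                  function(k) vol$voxels[, , k] / denom)
  tiff::writeTIFF(pages, path, bits.per.sample = vol$bit_depth)
  invisible(path)
}

#' Write a label or float map as TIFF
#'
#' Label maps (integer codes) are written as 8-bit pages.  Radius and
#' distance maps (micrometers) are written as 32-bit float pages divided
#' by `scale` (TIFF float samples live in `[0, 1]`); `NA` is stored as a
#' negative sentinel and restored on reading.  `read_float_tiff()` with
#' the same `scale` inverts the encoding.
#'
#' @param x 3D integer (labels) or numeric (float map) array.
#' @param path output file path.
#' @param scale micrometers mapped to 1.0 in the file (default 32768).
#' @return the writers return `path` invisibly; `read_float_tiff()`
#'   returns a numeric 3D array.
#' @export
write_label_tiff <- function(x, path) {
  .zp_stopifnot_dim3(x, "label map")
  pages <- lapply(seq_len(dim(x)[3]), function(k) x[, , k] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
write_float_tiff <- function(x, path, scale = 32768) {
  .zp_stopifnot_dim3(x, "float map")
  if (any(x > scale, na.rm = TRUE))
    stop("values exceed the encoding scale of ", scale)
  x[is.na(x)] <- -scale
  pages <- lapply(seq_len(dim(x)[3]), function(k) x[, , k] / scale)
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32))
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_float_tiff <- function(path, scale = 32768) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * scale
  arr[arr < 0] <- NA_real_
  arr
}
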