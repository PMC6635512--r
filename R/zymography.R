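#' Construct a zymogram
#'
#' A zymogram is a 2D grayscale image of enzyme activity: a membrane
#' soaked in a fluorogenic (MUF/AMC) substrate is laid on a freshly cut
#' soil face, the released fluorophore is photographed under UV, and
#' brighter gray means higher activity (an `invert` flag on
#' [standardize_zymogram()] handles negative-stain inputs).  The contact
#' mask marks pixels with good membrane-soil contact; only those are
#' usable.
#'
#' @param pixels numeric matrix of gray values.
#' @param mm_per_pixel pixel edge, millimeters.
#' @param enzyme enzyme name; one of the six mapped hydrolases/peptidases
#'   (see Details) or any other label. Enzyme identity is metadata only:
#'   all enzymes flow through identical operations.
#' @param core_id core identifier.
#' @param slice_index index of the cut face (0 = core top).
#' @param slice_depth_um depth of the cut face below the core top.
#' @param incubated was this slice incubated with fresh organic inputs
#'   before mapping?
#' @param contact_mask logical matrix, same shape as `pixels`; defaults
#'   to all-usable.
#' @param cell_truth optional generator bookkeeping (synthetic cores).
#' @details The canonical enzymes are beta-glucosidase,
#'   cellobiohydrolase, xylanase, N-acetyl-beta-glucosaminidase, leucine
#'   aminopeptidase and acid phosphatase.
#' @return an object of class `zp_zymogram`.
#' @export
zymogram <- function(pixels, mm_per_pixel, enzyme = "beta-glucosidase",
                     core_id = "core", slice_index = 0L,
                     slice_depth_um = 0, incubated = FALSE,
                     contact_mask = NULL, cell_truth = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (length(pixels) == 0L) stop("zero-size zymogram")
  if (!is.numeric(mm_per_pixel) || mm_per_pixel <= 0)
    stop("mm_per_pixel must be a positive number")
  if (is.null(contact_mask)) contact_mask <- matrix(TRUE, nrow(pixels),
                                                    ncol(pixels))
  if (!identical(dim(contact_mask), dim(pixels)))
    stop("contact_mask shape mismatch")
  structure(
    list(pixels = pixels, mm_per_pixel = mm_per_pixel, enzyme = enzyme,
         core_id = core_id, slice_index = as.integer(slice_index),
         slice_depth_um = slice_depth_um, incubated = isTRUE(incubated),
         contact_mask = contact_mask, cell_truth = cell_truth),
    class = "zp_zymogram")
}

#' @export
print.zp_zymogram <- function(x, ...) {
  cat(sprintf(paste0("<zp_zymogram> %s slice %d (%g um): %s, %d x %d px @ ",
                     "%g mm, %.0f%% usable%s\n"),
              x$core_id, x$slice_index, x$slice_depth_um, x$enzyme,
              nrow(x$pixels), ncol(x$pixels), x$mm_per_pixel,
              100 * mean(x$contact_mask),
              if (x$incubated) ", incubated" else ""))
  invisible(x)
}

#' Load / save a zymogram image
#'
#' Reads a grayscale TIFF or PNG into a [zymogram()].  RGB input is
#' converted to grayscale by channel averaging, with a warning.  The
#' pixel scale must be supplied (there is no reliable in-file scale for
#' membrane photographs).  `write_zymogram()` stores the pixels as
#' 16-bit grayscale TIFF plus a `.meta.csv` sidecar with the metadata;
#' integer-valued pixels in 0-65535 round-trip exactly.
#'
#' @param path image file (`.tif`/`.tiff`/`.png`).
#' @param mm_per_pixel pixel edge, millimeters (required).
#' @param ... further metadata passed to [zymogram()].
#' @param z a `zp_zymogram`.
#' @return `load_zymogram()` returns a `zp_zymogram`; `write_zymogram()`
#'   returns `path` invisibly.
#' @export
load_zymogram <- function(path, mm_per_pixel = NULL, ...) {
  if (is.null(mm_per_pixel))
    stop("mm_per_pixel metadata is required to place the zymogram on the ",
         "core")
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = ,
                tiff = tiff::readTIFF(path, as.is = TRUE),
                png = png::readPNG(path) * 65535,
                stop("unsupported image format: ", ext))
  if (length(dim(img)) == 3L) {
    warning("RGB input converted to grayscale by channel averaging")
    img <- apply(img, c(1, 2), mean)
  }
  meta_path <- paste0(path, ".meta.csv")
  meta <- list(...)
  if (file.exists(meta_path) && !length(meta)) {
    m <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
    meta <- list(enzyme = m$enzyme[1], core_id = m$core_id[1],
                 slice_index = m$slice_index[1],
                 slice_depth_um = m$slice_depth_um[1],
                 incubated = m$incubated[1])
  }
  do.call(zymogram, c(list(pixels = img, mm_per_pixel = mm_per_pixel),
                      meta))
}

#' @rdname load_zymogram
#' @export
write_zymogram <- function(z, path) {
  stopifnot(inherits(z, "zp_zymogram"))
  px <- z$pixels
  if (all(px == round(px)) && min(px) >= 0 && max(px) <= 65535) {
    img <- px / 65535
  } else {
    rng <- range(px)
    img <- (px - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  }
  tiff::writeTIFF(img, path, bits.per.sample = 16)
  utils::write.csv(
    data.frame(enzyme = z$enzyme, core_id = z$core_id,
               slice_index = z$slice_index,
               slice_depth_um = z$slice_depth_um,
               incubated = z$incubated,
               mm_per_pixel = z$mm_per_pixel),
    paste0(path, ".meta.csv"), row.names = FALSE)
  invisible(path)
}

#' Apply a membrane-contact mask
#'
#' Zymograms are only reliable where the membrane made good contact with
#' the soil face; contact quality is mapped by MUF staining of the
#' membrane.  Pixels whose stain intensity reaches `threshold` are
#' usable.  If the usable fraction falls below `min_usable` the slice is
#' flagged unusable (`usable = FALSE`), with a warning.
#'
#' @param z a [zymogram()].
#' @param mask_image numeric matrix co-registered with the zymogram
#'   (same shape): stain intensity.
#' @param threshold stain level at or above which contact counts as good.
#'   No instrument-independent default exists; calibrate per campaign.
#' @param min_usable minimum usable fraction before the slice is flagged
#'   (default 0.1).
#' @return the zymogram with updated `contact_mask`, `mask_fraction` and
#'   `usable` fields.
#' @export
apply_contact_mask <- function(z, mask_image, threshold,
                               min_usable = 0.1) {
  stopifnot(inherits(z, "zp_zymogram"))
  if (!identical(dim(mask_image), dim(z$pixels)))
    stop("mask image shape mismatch")
  z$contact_mask <- mask_image >= threshold
  z$mask_fraction <- mean(z$contact_mask)
  z$usable <- z$mask_fraction >= min_usable
  if (!z$usable)
    warning(sprintf("usable fraction %.1f%% below %.1f%%: slice flagged ",
                    100 * z$mask_fraction, 100 * min_usable),
            "unusable")
  z
}

#' Standardize a zymogram to z-scores
#'
#' Centers and scales the usable pixels by the mean and standard
#' deviation of the entire (usable part of the) zymogram, yielding
#' dimensionless activity z-scores.  Standardization is invariant under
#' positive affine gray transforms, so camera gain and exposure do not
#' affect downstream associations.  Masked pixels carry no value (`NA`).
#'
#' This is the pixel-scale utility; the co-registration step
#' ([build_grid()]) standardizes at the 1-mm aggregated scale, matching
#' the order of operations of the core pipeline.
#'
#' @param z a [zymogram()].
#' @param invert set `TRUE` for negative-stain input (darker = more
#'   active); z-scores are computed on the negated grays.
#' @return an object of class `zp_szymo` with `zscores` (matrix, `NA`
#'   where unusable), `mask_fraction` and the source metadata.
#' @export
standardize_zymogram <- function(z, invert = FALSE) {
  stopifnot(inherits(z, "zp_zymogram"))
  px <- if (invert) -z$pixels else z$pixels
  usable <- z$contact_mask
  vals <- px[usable]
  if (length(vals) < 2L) stop("need at least 2 usable pixels")
  m <- mean(vals)
  s <- sd(vals)
  if (s == 0) stop("zero variance over usable pixels: cannot standardize ",
                   "slice ", z$slice_index, " of ", z$core_id)
  zs <- (px - m) / s
  zs[!usable] <- NA_real_
  structure(
    list(zscores = zs, mask_fraction = mean(usable),
         enzyme = z$enzyme, core_id = z$core_id,
         slice_index = z$slice_index, slice_depth_um = z$slice_depth_um,
         incubated = z$incubated, mm_per_pixel = z$mm_per_pixel),
    class = "zp_szymo")
}

#' @export
print.zp_szymo <- function(x, ...) {
  cat(sprintf("<zp_szymo> %s slice %d: %s, %.0f%% usable, mean 0 / sd 1\n",
              x$core_id, x$slice_index, x$enzyme, 100 * x$mask_fraction))
  invisible(x)
}
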