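#' Distance from the soil matrix to the nearest sizeable pore
#'
#' Computes, for every voxel, the exact Euclidean distance (micrometers,
#' voxel center to voxel center) to the nearest qualifying pore voxel,
#' where a pore voxel qualifies when its inscribed-sphere radius is at
#' least `min_radius`.  Qualification is per voxel, so narrow throats of
#' large pores still qualify.  With no qualifying pores the map is all
#' infinite (with a warning).
#'
#' @param seg a [segment_volume()] result.
#' @param psm the matching [local_thickness()] map.
#' @param min_radius qualifying pore radius, micrometers (default 30).
#' @return an object of class `zp_distmap`: `distance_um` (numeric
#'   array; 0 on qualifying pore voxels), `min_radius`, `voxel_size`.
#' @export
distance_to_qualifying_pores <- function(seg, psm, min_radius = 30) {
  stopifnot(inherits(seg, "zp_segmented"), inherits(psm, "zp_psm"))
  d <- dim(seg$labels)
  qual <- seg$labels == .zp_lab[["pore"]] &
    !is.na(psm$radius_um) & psm$radius_um >= min_radius
  if (!any(qual)) {
    warning("no qualifying pores (radius >= ", min_radius,
            " um): distance map is infinite")
    dist <- array(Inf, d)
  } else {
    dist <- array(sqrt(edt_sq_cpp(qual, d)) * seg$voxel_size, d)
  }
  structure(list(distance_um = dist, min_radius = min_radius,
                 voxel_size = seg$voxel_size, core_id = seg$core_id),
            class = "zp_distmap")
}

#' Microbial spatial footprint of sizeable pores
#'
#' The footprint is the share of the soil matrix lying strictly within
#' `reach` micrometers of the nearest qualifying pore: the matrix volume
#' plausibly reached by decomposition products and microbial activity
#' hosted in those pores.  Only solid voxels count (POM and the excluded
#' border enter neither numerator nor denominator).
#'
#' @param dmap a [distance_to_qualifying_pores()] result.
#' @param seg the matching segmented volume.
#' @param reach distance, micrometers (default 180).
#' @return an object of class `zp_footprint`: logical `mask` (solid
#'   voxels within reach), `footprint_fraction` (percent of solid
#'   matrix), `reach_um`, `qualifying_pore_rule`, `method`, `core_id`.
#' @export
footprint_fraction <- function(dmap, seg, reach = 180) {
  stopifnot(inherits(dmap, "zp_distmap"), inherits(seg, "zp_segmented"))
  if (reach < 0) stop("reach must be >= 0")
  solid <- seg$labels == .zp_lab[["solid"]]
  n_solid <- sum(solid)
  if (n_solid == 0L) {
    warning("no solid voxels: footprint fraction undefined")
    frac <- NA_real_
    mask <- array(FALSE, dim(seg$labels))
  } else {
    mask <- solid & dmap$distance_um < reach
    frac <- 100 * sum(mask) / n_solid
  }
  structure(
    list(mask = mask, footprint_fraction = frac, reach_um = reach,
         qualifying_pore_rule = sprintf("pore voxels with radius >= %g um",
                                        dmap$min_radius),
         method = "euclidean", n_steps = NA_integer_,
         core_id = seg$core_id),
    class = "zp_footprint")
}

#' @export
print.zp_footprint <- function(x, ...) {
  cat(sprintf(paste0("<zp_footprint> %s: %.2f%% of matrix within %g um ",
                     "(%s, %s)\n"),
              x$core_id, x$footprint_fraction, x$reach_um,
              x$qualifying_pore_rule, x$method))
  invisible(x)
}

#' Footprint by iterated morphological dilation
#'
#' Morphological variant of [footprint_fraction()]: the qualifying pore
#' voxels are dilated `n_steps` times with a 6- or 26-connected
#' structuring element and the dilated set is intersected with the solid
#' matrix.  Dilation reach is chamfer-like (step count times voxel size
#' along axes for 6-connectivity, further along diagonals for 26), so
#' this bounds rather than equals the Euclidean shell; it exists to
#' mirror the classical image-toolbox procedure and quantify the
#' discrepancy against the metrically exact Euclidean version.
#'
#' @param seg a [segment_volume()] result.
#' @param psm the matching [local_thickness()] map.
#' @param n_steps number of dilation steps; default
#'   `ceiling(180 / voxel_size)`.
#' @param connectivity 6 or 26 (default 26).
#' @param min_radius qualifying pore radius, micrometers.
#' @return a `zp_footprint` with `method = "dilation"` and the step count
#'   recorded in `n_steps`.
#' @export
dilation_equivalent_footprint <- function(seg, psm, n_steps = NULL,
                                          connectivity = 26,
                                          min_radius = 30) {
  stopifnot(inherits(seg, "zp_segmented"), inherits(psm, "zp_psm"))
  if (is.null(n_steps)) n_steps <- as.integer(ceiling(180 / seg$voxel_size))
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("n_steps must be >= 1")
  if (!connectivity %in% c(6, 26)) stop("connectivity must be 6 or 26")
  d <- dim(seg$labels)
  qual <- seg$labels == .zp_lab[["pore"]] &
    !is.na(psm$radius_um) & psm$radius_um >= min_radius
  solid <- seg$labels == .zp_lab[["solid"]]
  n_solid <- sum(solid)
  dil <- array(dilate3d_cpp(qual, d, n_steps, as.integer(connectivity)), d)
  mask <- dil & solid
  frac <- if (n_solid == 0L) NA_real_ else 100 * sum(mask) / n_solid
  structure(
    list(mask = mask, footprint_fraction = frac,
         reach_um = n_steps * seg$voxel_size,
         qualifying_pore_rule = sprintf("pore voxels with radius >= %g um",
                                        min_radius),
         method = sprintf("dilation (%d steps, %d-connected)",
                          n_steps, as.integer(connectivity)),
         n_steps = n_steps, core_id = seg$core_id),
    class = "zp_footprint")
}
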