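#' Continuous pore-size map by maximal inscribed spheres
#'
#' Assigns each pore voxel the radius of the largest sphere that fits
#' entirely inside the pore phase and covers that voxel (local thickness).
#' The computation is an exact Euclidean distance transform to the
#' non-pore phase followed by sphere propagation: the maximal sphere
#' centered at `c` is the open ball whose radius is the distance from `c`
#' to the nearest non-pore voxel center, and every voxel it covers
#' inherits at least that radius.  On small grids this equals the
#' exhaustive search over all candidate sphere centers.
#'
#' Solid, POM and excluded-border voxels all delimit the pore phase.
#' Distances are voxel-center to voxel-center, so an isolated pore voxel
#' has radius one voxel and no reported radius can fall below half the
#' voxel size; pores much below one voxel radius are simply not resolved.
#'
#' @param seg a [segment_volume()] result.
#' @return an object of class `zp_psm` with `radius_um` (numeric array,
#'   `NA` off the pore phase) and `radius_sq_vox` (integer squared radii
#'   in voxel units, exact).
#' @export
local_thickness <- function(seg) {
  stopifnot(inherits(seg, "zp_segmented"))
  d <- dim(seg$labels)
  pore <- seg$labels == .zp_lab[["pore"]]
  radius <- array(NA_real_, d)
  if (!any(pore)) {
    warning("no pore voxels: empty pore-size map")
    return(structure(list(radius_um = radius,
                          radius_sq_vox = array(NA_real_, d),
                          voxel_size = seg$voxel_size,
                          core_id = seg$core_id),
                     class = "zp_psm"))
  }
  if (all(pore))
    warning("volume is entirely pore; radii are grid-bounded sentinels")
  dbg <- edt_sq_cpp(!pore, d)
  lt2 <- array(local_thickness_sq_cpp(pore, d, dbg), d)
  radius[pore] <- sqrt(lt2[pore]) * seg$voxel_size
  lt2[!pore] <- NA_real_
  structure(list(radius_um = radius, radius_sq_vox = lt2,
                 voxel_size = seg$voxel_size, core_id = seg$core_id),
            class = "zp_psm")
}

#' @export
print.zp_psm <- function(x, ...) {
  r <- x$radius_um[!is.na(x$radius_um)]
  if (length(r))
    cat(sprintf("<zp_psm> %s: %d pore voxels, radius %.1f-%.1f um\n",
                x$core_id, length(r), min(r), max(r)))
  else cat(sprintf("<zp_psm> %s: empty\n", x$core_id))
  invisible(x)
}

#' Classify voxels into pore size classes
#'
#' Bins pore voxels by their inscribed-sphere radius into the visible
#' size classes and assigns solid voxels to the sub-resolution proxy class
#' `unresolved_matrix`: porosity finer than the imaging limit resides in
#' the solid matrix, so matrix volume stands in for "<30 um" pore
#' prevalence.  POM and excluded voxels carry no class.
#'
#' Bins are closed on the left and open on the right except that the
#' first visible bin is closed at its upper bound: with the default
#' bounds `(30, 150, 180)` um, radius 150 belongs to `p30_150`, radii in
#' `(150, 180]` to `p150_180` and radii above 180 to `p180_plus`.  Pore
#' voxels below the first bound (possible only within a voxel of the
#' resolution floor) join the smallest visible class.
#'
#' @param psm a [local_thickness()] result.
#' @param seg the matching segmented volume.
#' @param bounds three increasing radii (um), default `c(30, 150, 180)`.
#' @return an object of class `zp_classmap` (integer array `class_map`
#'   with codes 0 none, 1-4 per [pore_classes()], plus `bounds`).
#' @export
classify_pores <- function(psm, seg, bounds = c(30, 150, 180)) {
  stopifnot(inherits(psm, "zp_psm"), inherits(seg, "zp_segmented"))
  if (length(bounds) != 3L || any(diff(bounds) <= 0))
    stop("bounds must be three increasing radii")
  d <- dim(seg$labels)
  if (!identical(dim(psm$radius_um), d))
    stop("pore-size map and segmentation shapes differ")
  cm <- array(.zp_cls[["none"]], d)
  cm[seg$labels == .zp_lab[["solid"]]] <- .zp_cls[["unresolved_matrix"]]
  pore <- which(seg$labels == .zp_lab[["pore"]])
  if (length(pore))
    cm[pore] <- .zp_radius_class(psm$radius_um[pore], bounds)
  structure(list(class_map = cm, bounds = bounds,
                 voxel_size = seg$voxel_size, core_id = seg$core_id),
            class = "zp_classmap")
}

#' Image-based porosity
#'
#' Fraction of the analyzed volume occupied by visible (segmented) pores:
#' pore voxels over pore + solid + POM voxels, with excluded-border voxels
#' omitted from both counts.
#'
#' @param seg a [segment_volume()] result.
#' @return porosity as a fraction in `[0, 1]`.
#' @export
image_porosity <- function(seg) {
  stopifnot(inherits(seg, "zp_segmented"))
  lab <- seg$labels
  n_incl <- sum(lab != .zp_lab[["excluded"]])
  if (n_incl == 0L) stop("no included voxels")
  sum(lab == .zp_lab[["pore"]]) / n_incl
}

#' Total porosity from gravimetric data
#'
#' `1 - bulk_density / particle_density` with bulk density
#' `dry_mass / bulk_volume`.  The default particle density of
#' 2.6 g cm^-3 is the standard assumption for mineral soil.
#'
#' @param dry_mass oven-dry soil mass, g.
#' @param bulk_volume core volume, cm^3 (e.g. from the CT image).
#' @param particle_density g cm^-3.
#' @return total porosity as a fraction in `(0, 1]`.
#' @export
#' @examples
#' total_porosity(130, 100)  # bulk density 1.3 -> porosity 0.5
total_porosity <- function(dry_mass, bulk_volume, particle_density = 2.6) {
  if (dry_mass < 0 || bulk_volume <= 0 || particle_density <= 0)
    stop("masses, volumes and densities must be positive")
  bd <- dry_mass / bulk_volume
  if (bd >= particle_density)
    stop(sprintf("bulk density %.3g >= particle density %.3g: nonphysical",
                 bd, particle_density))
  1 - bd / particle_density
}

#' Assemble a porosity report for one core
#'
#' Combines image-based porosity (visible pores), total porosity from
#' gravimetric data and their difference, the sub-resolution ("<30 um")
#' porosity.  A negative difference is physically inconsistent (it means
#' the image shows more pore space than the gravimetric total); it is
#' flagged, and reported both raw and clipped at zero.  Class volumes are
#' voxel counts times the voxel volume.
#'
#' @param seg a [segment_volume()] result.
#' @param classmap a [classify_pores()] result.
#' @param total_porosity total porosity fraction from [total_porosity()],
#'   or `NULL` if gravimetric data are unavailable.
#' @return an object of class `zp_porosity`: `core_id`,
#'   `image_porosity`, `total_porosity`, `sub30_porosity` (clipped),
#'   `sub30_porosity_raw`, `consistent` flag and `class_volumes_um3`.
#' @export
porosity_report <- function(seg, classmap, total_porosity = NULL) {
  stopifnot(inherits(seg, "zp_segmented"), inherits(classmap, "zp_classmap"))
  ip <- image_porosity(seg)
  vx3 <- seg$voxel_size^3
  vis <- c("p30_150", "p150_180", "p180_plus")
  cv <- vapply(vis, function(cl)
    sum(classmap$class_map == .zp_cls[[cl]]) * vx3, numeric(1))
  sub30_raw <- if (is.null(total_porosity)) NA_real_ else
    total_porosity - ip
  consistent <- is.na(sub30_raw) || sub30_raw >= 0
  if (!consistent)
    warning("image porosity exceeds total porosity; sub-30 um porosity ",
            "clipped at 0 (raw value reported alongside)")
  structure(
    list(core_id = seg$core_id, image_porosity = ip,
         total_porosity = if (is.null(total_porosity)) NA_real_ else
           total_porosity,
         sub30_porosity = if (is.na(sub30_raw)) NA_real_ else
           max(0, sub30_raw),
         sub30_porosity_raw = sub30_raw,
         consistent = consistent, class_volumes_um3 = cv),
    class = "zp_porosity")
}

#' @export
print.zp_porosity <- function(x, ...) {
  cat(sprintf("<zp_porosity> %s: image %.4f, total %.4f, <30um %.4f%s\n",
              x$core_id, x$image_porosity, x$total_porosity,
              x$sub30_porosity,
              if (!x$consistent) " [inconsistent]" else ""))
  invisible(x)
}

#' @export
as.data.frame.zp_porosity <- function(x, ...) {
  data.frame(core_id = x$core_id, image_porosity = x$image_porosity,
             total_porosity = x$total_porosity,
             sub30_porosity = x$sub30_porosity,
             sub30_porosity_raw = x$sub30_porosity_raw,
             consistent = x$consistent,
             vol_p30_150_um3 = x$class_volumes_um3[["p30_150"]],
             vol_p150_180_um3 = x$class_volumes_um3[["p150_180"]],
             vol_p180_plus_um3 = x$class_volumes_um3[["p180_plus"]],
             row.names = NULL)
}
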