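#' Run the CT side of the pipeline on one core
#'
#' Convenience wrapper chaining the standard per-core steps: 3D median
#' filtering, optional border trimming, two-Gaussian histogram fit and
#' minimum-error threshold, segmentation (with optional POM mask),
#' local thickness, pore classification, the distance map to sizeable
#' pores and the footprint fraction.
#'
#' @param vol a [core_volume()].
#' @param pom_mask optional logical POM mask.
#' @param filter_radius median-filter radius in voxels (0 to skip).
#' @param trim_margin lateral border trim, micrometers (0 to skip).
#' @param bounds pore-class radius bounds, micrometers.
#' @param min_radius qualifying pore radius for the footprint.
#' @param reach footprint distance, micrometers.
#' @param compute_distance set `FALSE` to skip the distance map and
#'   footprint (saves memory/time when only classes are needed).
#' @return list with `volume` (filtered/trimmed), `fit`, `threshold`,
#'   `seg`, `psm`, `classmap`, and (unless skipped) `dmap`, `footprint`.
#' @export
process_core <- function(vol, pom_mask = NULL, filter_radius = 2L,
                         trim_margin = 0, bounds = c(30, 150, 180),
                         min_radius = 30, reach = 180,
                         compute_distance = TRUE) {
  stopifnot(inherits(vol, "zp_volume"))
  if (filter_radius >= 1L) vol <- median_filter_3d(vol, filter_radius)
  if (trim_margin > 0) vol <- trim_border(vol, trim_margin)
  fit <- fit_two_gaussians(vol)
  thr <- minimum_error_threshold(fit)
  seg <- segment_volume(vol, thr, pom_mask = pom_mask)
  psm <- local_thickness(seg)
  classmap <- classify_pores(psm, seg, bounds = bounds)
  out <- list(volume = vol, fit = fit, threshold = thr, seg = seg,
              psm = psm, classmap = classmap)
  if (compute_distance) {
    out$dmap <- distance_to_qualifying_pores(seg, psm,
                                             min_radius = min_radius)
    out$footprint <- footprint_fraction(out$dmap, seg, reach = reach)
  }
  out
}

#' Prepare a synthetic core for an association study
#'
#' Generates a synthetic core, runs the full CT pipeline on its rendered
#' grayscale volume, and pre-aggregates the CT cell tables for the
#' requested cut faces.  Only the light-weight pieces needed to pair the
#' core with (replicate) zymograms are kept: the spec, the true class
#' map (for zymogram generation) and the per-slice cell tables; the
#' large voxel arrays are dropped.
#'
#' @param spec a [synthetic_spec()].
#' @param slice_indices cut faces to prepare (see [generate_zymogram()]).
#' @param filter_radius,min_radius,reach passed to [process_core()].
#' @param compute_distance whether cell footprint fractions are needed.
#' @return list with `spec`, `truth` (slim: `class_map` only),
#'   `threshold`, `fit`, `image_porosity`, and `ct_cells` (one table per
#'   slice index, named by index).
#' @export
prepare_core <- function(spec, slice_indices, filter_radius = 2L,
                         min_radius = 30, reach = 180,
                         compute_distance = FALSE) {
  stopifnot(inherits(spec, "zp_spec"))
  truth <- generate_phase_volume(spec, footprint = FALSE)
  vol <- render_grayscale(truth, spec)
  pom <- if (any(truth$phase == 2L)) truth$phase == 2L else NULL
  proc <- process_core(vol, pom_mask = pom, filter_radius = filter_radius,
                       bounds = spec$class_bounds, min_radius = min_radius,
                       reach = reach, compute_distance = compute_distance)
  cells <- lapply(slice_indices, function(k) {
    depth <- round(k * spec$slice_spacing / spec$voxel_size) *
      spec$voxel_size
    ct <- aggregate_ct_cells(proc$seg, proc$classmap,
                             slice_depth_um = depth,
                             dmap = proc$dmap,
                             cell_size_um = spec$cell_size_um,
                             reach = reach)
    attr(ct, "system_label") <- spec$system_label
    ct
  })
  names(cells) <- as.character(slice_indices)
  list(spec = spec,
       truth = list(class_map = truth$class_map, spec = spec),
       threshold = proc$threshold, fit = proc$fit,
       image_porosity = image_porosity(proc$seg),
       slice_indices = slice_indices, ct_cells = cells)
}

#' Build the cell records of a multi-core zymography study
#'
#' Pairs every prepared core and cut face with a generated zymogram
#' (fresh activity noise per call when `seed` varies) and row-binds the
#' [build_grid()] records, ready for [percentile_select()] and
#' [associate()].
#'
#' @param cores list of [prepare_core()] results.
#' @param enzyme enzyme to simulate.
#' @param seed study-level seed; per-zymogram seeds are derived from it,
#'   so different seeds give independent replicate noise realizations on
#'   the same cores.
#' @param incubated incubation flag passed to the zymograms.
#' @param min_coverage per-cell usable-pixel minimum.
#' @return data.frame of cell records across cores and slices.
#' @export
study_records <- function(cores, enzyme = "beta-glucosidase", seed = 1L,
                          incubated = FALSE, min_coverage = 0.5) {
  recs <- list()
  for (ci in seq_along(cores)) {
    core <- cores[[ci]]
    for (k in core$slice_indices) {
      zseed <- .zp_seed(seed, 7919L * ci + 104729L * k)
      zym <- generate_zymogram(core$truth, core$spec, slice_index = k,
                               enzyme = enzyme, incubated = incubated,
                               seed = zseed)
      recs[[length(recs) + 1L]] <-
        build_grid(zym, ct_cells = core$ct_cells[[as.character(k)]],
                   min_coverage = min_coverage)
    }
  }
  do.call(rbind, recs)
}
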