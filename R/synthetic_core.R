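#' Specify a synthetic soil core
#'
#' Bundles all parameters of the synthetic-core generator: grid geometry,
#' the pore population (spheres and axis-aligned tubes of known radius),
#' particulate organic matter (POM) inclusions, the grayscale model for
#' rendering, the slicing geometry for zymography, and the enzyme effect
#' sizes injected per pore class.  Defaults mirror the acquisition the
#' package targets: 29-um voxels and 2-mm slice spacing.
#'
#' Sphere and tube centers are placed by seeded uniform sampling such that
#' each shape fits entirely inside the grid (tubes span the full grid along
#' their axis); overlaps are allowed and resolved as the union of shapes,
#' with the true radius at a voxel the maximum over covering shapes.  The
#' slice spacing need not be an exact multiple of the voxel size: cut
#' planes are mapped to the nearest CT plane, as with a physical saw cut.
#'
#' @param grid_shape voxels per axis (length 3).
#' @param voxel_size voxel edge, micrometers.
#' @param pore_population list of entries `list(shape, radius, count)` with
#'   `shape` one of `"sphere"`, `"tube"`, `radius` in micrometers and
#'   `count` a non-negative integer.  Tubes are axis-aligned circular
#'   cylinders (axis drawn at random), a root-channel analogue.
#' @param pom_count,pom_radius number and radius (um) of spherical POM
#'   inclusions, rendered with solid-phase gray statistics.
#' @param gray_model named vector `mean_solid`, `sd_solid`, `mean_void`,
#'   `sd_void` on the 8-bit gray scale; void (air + liquid) must be darker
#'   than solid, as in attenuation images.
#' @param slice_spacing distance between successive cut faces, micrometers.
#' @param enzyme_effects named list/vector of activity shifts (in SD units)
#'   per pore class, e.g. `c(p30_150 = 1, unresolved_matrix = 0.3)`; names
#'   must be [pore_classes()].
#' @param activity_noise_sd SD of the cell-level activity noise (SD units).
#' @param pixel_noise_sd SD of additional per-pixel sensor noise.
#' @param activity_baseline baseline activity level.
#' @param zymo_mm_per_pixel zymogram pixel size, millimeters.
#' @param contact_fraction fraction of the membrane with good soil contact;
#'   below 1, a random rectangular region is marked unusable.
#' @param cell_size_um edge of the aggregation cell (default 1 mm).
#' @param min_pore_prevalence minimum visible-pore volume fraction for a
#'   cell to count as pore-dominated when assigning enzyme effects; cells
#'   below it are matrix-dominated (the sub-resolution pore micro-site).
#' @param class_bounds radius bounds (um) separating visible pore classes.
#' @param rng_seed integer seed; every generated artifact draws from a
#'   documented substream offset of this seed.
#' @param core_id,system_label identifiers.
#' @return an object of class `zp_spec`.
#' @seealso [generate_phase_volume()], [render_grayscale()],
#'   [generate_zymogram()]
#' @export
#' @examples
#' sp <- synthetic_spec(grid_shape = c(64, 64, 64),
#'                      pore_population = list(list(shape = "sphere",
#'                                                  radius = 150, count = 1)))
#' truth <- generate_phase_volume(sp)
#' truth$image_porosity
synthetic_spec <- function(grid_shape = c(128, 128, 128),
                           voxel_size = 29,
                           pore_population = list(),
                           pom_count = 0, pom_radius = 300,
                           gray_model = c(mean_solid = 160, sd_solid = 15,
                                          mean_void = 60, sd_void = 12),
                           slice_spacing = 2000,
                           enzyme_effects = list(),
                           activity_noise_sd = 1.0,
                           pixel_noise_sd = 0.1,
                           activity_baseline = 0,
                           zymo_mm_per_pixel = 0.1,
                           contact_fraction = 1.0,
                           cell_size_um = 1000,
                           min_pore_prevalence = 0.01,
                           class_bounds = c(30, 150, 180),
                           rng_seed = 1L,
                           core_id = "synthetic-core",
                           system_label = "synthetic") {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L))
  if (voxel_size <= 0) stop("voxel_size must be positive")
  for (p in pore_population) {
    if (!is.list(p) || is.null(p$shape) || is.null(p$radius) ||
        is.null(p$count))
      stop("each pore_population entry needs shape, radius, count")
    if (!p$shape %in% c("sphere", "tube"))
      stop("pore shape must be 'sphere' or 'tube'")
    if (p$radius <= 0) stop("pore radii must be positive")
    if (p$count < 0) stop("pore counts must be non-negative")
  }
  gm <- gray_model
  need <- c("mean_solid", "sd_solid", "mean_void", "sd_void")
  if (!all(need %in% names(gm))) stop("gray_model must name ", toString(need))
  if (any(gm[c("sd_solid", "sd_void")] < 0)) stop("gray sd must be >= 0")
  if (gm["mean_void"] >= gm["mean_solid"])
    stop("mean_void must be below mean_solid (air + liquid is darker)")
  if (slice_spacing <= 0) stop("slice_spacing must be positive")
  if (slice_spacing < voxel_size)
    stop("slice_spacing must be at least one voxel")
  if (pom_count < 0 || pom_radius <= 0) stop("invalid POM settings")
  if (activity_noise_sd < 0 || pixel_noise_sd < 0)
    stop("noise SDs must be >= 0")
  if (contact_fraction <= 0 || contact_fraction > 1)
    stop("contact_fraction must be in (0, 1]")
  if (min_pore_prevalence < 0 || min_pore_prevalence >= 1)
    stop("min_pore_prevalence must be in [0, 1)")
  if (length(class_bounds) != 3L || any(diff(class_bounds) <= 0))
    stop("class_bounds must be three increasing radii (um)")
  ee <- as.list(enzyme_effects)
  if (length(ee) && !all(names(ee) %in% .zp_classes))
    stop("enzyme_effects names must be pore_classes()")
  # the largest shape must fit inside the grid
  if (length(pore_population)) {
    rmax <- max(vapply(pore_population, `[[`, numeric(1), "radius"))
    if (2 * rmax > min(grid_shape) * voxel_size)
      stop(sprintf(paste0("grid too small: largest shape (diameter %g um) ",
                          "exceeds the smallest grid extent (%g um)"),
                   2 * rmax, min(grid_shape) * voxel_size))
  }
  structure(
    list(grid_shape = grid_shape, voxel_size = voxel_size,
         pore_population = pore_population, pom_count = as.integer(pom_count),
         pom_radius = pom_radius, gray_model = gm,
         slice_spacing = slice_spacing, enzyme_effects = ee,
         activity_noise_sd = activity_noise_sd,
         pixel_noise_sd = pixel_noise_sd,
         activity_baseline = activity_baseline,
         zymo_mm_per_pixel = zymo_mm_per_pixel,
         contact_fraction = contact_fraction, cell_size_um = cell_size_um,
         min_pore_prevalence = min_pore_prevalence,
         class_bounds = class_bounds, rng_seed = as.integer(rng_seed),
         core_id = core_id, system_label = system_label),
    class = "zp_spec")
}

#' @export
print.zp_spec <- function(x, ...) {
  cat(sprintf("<zp_spec> %s: %s voxels @ %g um, %d pore population(s), seed %d\n",
              x$core_id, paste(x$grid_shape, collapse = " x "),
              x$voxel_size, length(x$pore_population), x$rng_seed))
  invisible(x)
}

# uniform integer in [lo, hi], safe when lo == hi
.zp_sample1 <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

# radius (um) -> class code, using the package binning convention:
# [b1, b2] -> p30_150 (closed at b2), (b2, b3] -> p150_180, > b3 -> p180_plus.
# Visible pore voxels below b1 (possible only within ~1 voxel of the
# resolution floor) fall into the smallest visible class.
.zp_radius_class <- function(r, bounds) {
  cls <- integer(length(r))
  cls[r <= bounds[2]] <- .zp_cls[["p30_150"]]
  cls[r > bounds[2] & r <= bounds[3]] <- .zp_cls[["p150_180"]]
  cls[r > bounds[3]] <- .zp_cls[["p180_plus"]]
  cls
}

# voxel coordinate matrix (n x 3) of a voxelized ball around integer center,
# radius in voxels; clipped to the grid
.zp_ball_voxels <- function(center, r_vox, dims) {
  rr <- floor(r_vox)
  xs <- max(1L, center[1] - rr):min(dims[1], center[1] + rr)
  ys <- max(1L, center[2] - rr):min(dims[2], center[2] + rr)
  zs <- max(1L, center[3] - rr):min(dims[3], center[3] + rr)
  g <- expand.grid(x = xs, y = ys, z = zs, KEEP.OUT.ATTRS = FALSE)
  d2 <- (g$x - center[1])^2 + (g$y - center[2])^2 + (g$z - center[3])^2
  as.matrix(g[d2 <= r_vox^2, , drop = FALSE])
}

.zp_lin_index <- function(coords, dims) {
  (coords[, 3] - 1L) * (dims[1] * dims[2]) +
    (coords[, 2] - 1L) * dims[1] + coords[, 1]
}

#' Generate a phase volume with known ground truth
#'
#' Places the requested pore shapes and POM inclusions by seeded uniform
#' sampling and returns per-voxel phase labels together with the
#' analytically known radius map, class map, footprint mask and image
#' porosity.  For a voxel covered by several shapes the true radius is the
#' maximum over covering shapes, consistent with the maximal-inscribed-
#' sphere definition used downstream.
#'
#' The true footprint mask uses the same discrete semantics as the
#' pipeline: solid voxels whose center lies strictly within
#' `reach` (180 um) of the center of any void voxel belonging to a shape
#' of radius at least `min_radius` (30 um).
#'
#' @param spec a [synthetic_spec()].
#' @param reach,min_radius footprint ground-truth parameters, micrometers.
#' @param footprint if `FALSE`, skip the (comparatively slow) ground-truth
#'   footprint mask; all other truth fields are unaffected.
#' @return an object of class `zp_truth` with elements `phase` (integer
#'   array: 0 solid, 1 void, 2 POM), `radius_um` (true radius on void
#'   voxels, `NA` elsewhere), `class_map` (integer array, see
#'   [pore_classes()]), `footprint` (logical array), `image_porosity`,
#'   and the `spec`.
#' @export
generate_phase_volume <- function(spec, reach = 180, min_radius = 30,
                                  footprint = TRUE) {
  stopifnot(inherits(spec, "zp_spec"))
  dims <- spec$grid_shape
  vx <- spec$voxel_size
  n <- prod(dims)
  phase <- array(0L, dims)           # 0 solid, 1 void, 2 POM
  radius <- array(NA_real_, dims)

  set.seed(.zp_seed(spec$rng_seed, 0L))
  shapes <- list()
  for (p in spec$pore_population) {
    if (p$count == 0) next
    r_vox <- p$radius / vx
    for (k in seq_len(p$count)) {
      if (p$shape == "sphere") {
        lo <- rep(as.integer(ceiling(1 + r_vox)), 3L)
        hi <- as.integer(floor(dims - r_vox))
        if (any(hi < lo))
          stop("grid too small to contain a sphere of radius ", p$radius,
               " um")
        ctr <- c(.zp_sample1(lo[1], hi[1]), .zp_sample1(lo[2], hi[2]),
                 .zp_sample1(lo[3], hi[3]))
        vxl <- .zp_ball_voxels(ctr, r_vox, dims)
        shapes[[length(shapes) + 1L]] <-
          list(shape = "sphere", center = ctr, radius = p$radius)
      } else {
        axis <- sample.int(3L, 1L)
        perp <- setdiff(1:3, axis)
        lo <- as.integer(ceiling(1 + r_vox))
        hi <- as.integer(floor(dims[perp] - r_vox))
        if (any(hi < lo))
          stop("grid too small to contain a tube of radius ", p$radius,
               " um")
        c1 <- .zp_sample1(lo, hi[1])
        c2 <- .zp_sample1(lo, hi[2])
        ax <- seq_len(dims[axis])
        g <- expand.grid(u = (c1 - floor(r_vox)):(c1 + floor(r_vox)),
                         v = (c2 - floor(r_vox)):(c2 + floor(r_vox)),
                         KEEP.OUT.ATTRS = FALSE)
        g <- g[(g$u - c1)^2 + (g$v - c2)^2 <= r_vox^2, , drop = FALSE]
        coords <- cbind(rep(g$u, each = length(ax)),
                        rep(g$v, each = length(ax)),
                        rep(ax, times = nrow(g)))
        vxl <- matrix(0L, nrow(coords), 3L)
        vxl[, perp[1]] <- coords[, 1]
        vxl[, perp[2]] <- coords[, 2]
        vxl[, axis] <- coords[, 3]
        shapes[[length(shapes) + 1L]] <-
          list(shape = "tube", axis = axis, center = c(c1, c2),
               radius = p$radius)
      }
      if (nrow(vxl)) {
        idx <- .zp_lin_index(vxl, dims)
        phase[idx] <- 1L
        radius[idx] <- pmax(radius[idx], p$radius, na.rm = TRUE)
      }
    }
  }

  # POM: spherical inclusions in the solid phase (pores win on overlap)
  if (spec$pom_count > 0) {
    r_vox <- spec$pom_radius / vx
    lo <- rep(as.integer(ceiling(1 + r_vox)), 3L)
    hi <- as.integer(floor(dims - r_vox))
    if (any(hi < lo))
      stop("grid too small to contain POM of radius ", spec$pom_radius,
           " um")
    for (k in seq_len(spec$pom_count)) {
      ctr <- c(.zp_sample1(lo[1], hi[1]), .zp_sample1(lo[2], hi[2]),
               .zp_sample1(lo[3], hi[3]))
      vxl <- .zp_ball_voxels(ctr, r_vox, dims)
      idx <- .zp_lin_index(vxl, dims)
      idx <- idx[phase[idx] == 0L]
      phase[idx] <- 2L
    }
  }

  class_map <- array(.zp_cls[["none"]], dims)
  class_map[phase == 0L] <- .zp_cls[["unresolved_matrix"]]
  void <- which(phase == 1L)
  if (length(void))
    class_map[void] <- .zp_radius_class(radius[void], spec$class_bounds)

  fp <- if (footprint)
    .zp_truth_footprint(phase, radius, vx, reach, min_radius, dims)
  else NULL

  structure(
    list(phase = phase, radius_um = radius, class_map = class_map,
         footprint = fp,
         image_porosity = sum(phase == 1L) / n,
         shapes = shapes, spec = spec),
    class = "zp_truth")
}

# ground-truth footprint by direct offset dilation of qualifying void
# voxels (independent of the pipeline's distance transform)
.zp_truth_footprint <- function(phase, radius, vx, reach, min_radius,
                                dims) {
  footprint <- array(FALSE, dims)
  qual <- which(phase == 1L & !is.na(radius) & radius >= min_radius)
  if (!length(qual)) return(footprint)
  d2max <- floor((reach / vx)^2 - 1e-9)   # strict "< reach"
  rr <- floor(sqrt(d2max))
  qc <- arrayInd(qual, dims)
  reached <- array(FALSE, dims)
  for (dz in -rr:rr) for (dy in -rr:rr) for (dx in -rr:rr) {
    if (dx * dx + dy * dy + dz * dz > d2max) next
    x <- qc[, 1] + dx; y <- qc[, 2] + dy; z <- qc[, 3] + dz
    ok <- x >= 1L & x <= dims[1] & y >= 1L & y <= dims[2] &
      z >= 1L & z <= dims[3]
    if (!any(ok)) next
    reached[cbind(x[ok], y[ok], z[ok])] <- TRUE
  }
  footprint[phase == 0L & reached] <- TRUE
  footprint
}

#' @export
print.zp_truth <- function(x, ...) {
  d <- dim(x$phase)
  cat(sprintf(paste0("<zp_truth> %s: %d x %d x %d voxels, image porosity ",
                     "%.4f, %d shapes\n"),
              x$spec$core_id, d[1], d[2], d[3], x$image_porosity,
              length(x$shapes)))
  invisible(x)
}

#' Render a ground-truth phase volume to grayscale
#'
#' Draws each voxel's gray value from its phase's Gaussian gray model
#' (POM uses the solid statistics), clips to 0-255 and rounds.  Uses the
#' spec seed at substream offset 1, so the same spec always renders the
#' same volume.
#'
#' @param truth a [generate_phase_volume()] result.
#' @param spec the generating [synthetic_spec()]; defaults to `truth$spec`.
#' @return an 8-bit [core_volume()].
#' @export
render_grayscale <- function(truth, spec = truth$spec) {
  stopifnot(inherits(truth, "zp_truth"), inherits(spec, "zp_spec"))
  gm <- spec$gray_model
  n <- length(truth$phase)
  set.seed(.zp_seed(spec$rng_seed, 1L))
  g <- rnorm(n, mean = gm[["mean_solid"]], sd = gm[["sd_solid"]])
  void <- truth$phase == 1L
  nv <- sum(void)
  if (nv) g[void] <- rnorm(nv, mean = gm[["mean_void"]],
                           sd = gm[["sd_void"]])
  g <- array(as.integer(pmin(255, pmax(0, round(g)))), dim(truth$phase))
  core_volume(g, voxel_size = spec$voxel_size, bit_depth = 8L,
              core_id = spec$core_id, system_label = spec$system_label)
}

# dominant pore class of a cell: if the visible-pore volume fraction falls
# below the prevalence threshold the cell is matrix-dominated (its pore
# space is sub-resolution); otherwise the visible pore class with the
# largest voxel count, ties going to the larger class
.zp_dominant_class <- function(cls_counts, min_prevalence = 0.01) {
  vis <- cls_counts[c("p30_150", "p150_180", "p180_plus")]
  n_tot <- sum(cls_counts[c("unresolved_matrix", "p30_150", "p150_180",
                            "p180_plus")])
  if (n_tot == 0 || sum(vis) / n_tot < min_prevalence)
    return("unresolved_matrix")
  names(vis)[max(which(vis == max(vis)))]
}

#' Generate a zymogram for a cut plane of a synthetic core
#'
#' Emulates laying a substrate-saturated membrane on the face exposed by
#' cutting the core at `slice_index` times the slice spacing.  The activity
#' of each 1-mm aggregation cell below the plane is
#' `baseline + effect(dominant true pore class) + noise`; the map is then
#' rendered at the zymogram pixel scale with optional per-pixel sensor
#' noise.  Activity is emitted in dimensionless "standardizable" units.
#'
#' @param truth a [generate_phase_volume()] result (the `class_map` and
#'   spec are used, so a slimmed truth object suffices).
#' @param spec the generating spec; defaults to `truth$spec`.
#' @param slice_index which cut face, so the plane sits at
#'   `slice_index * slice_spacing` below the core top (0 = top face).
#' @param enzyme enzyme name (metadata only; all enzymes flow through the
#'   same operations).
#' @param incubated flag marking slices incubated with fresh organic
#'   inputs before mapping.
#' @param seed optional override of the derived substream seed, for
#'   replicate noise realizations on the same core.
#' @return a `zp_zymogram` whose `cell_truth` element records, per 1-mm
#'   cell, the dominant true class, the injected effect and the noiseless
#'   plus noisy activity.
#' @export
generate_zymogram <- function(truth, spec = truth$spec, slice_index,
                              enzyme = "beta-glucosidase",
                              incubated = FALSE, seed = NULL) {
  stopifnot(inherits(truth, "zp_truth") || is.list(truth),
            inherits(spec, "zp_spec"))
  dims <- spec$grid_shape
  vx <- spec$voxel_size
  cv <- max(1L, as.integer(round(spec$cell_size_um / vx)))
  z_plane <- as.integer(round(slice_index * spec$slice_spacing / vx))
  if (slice_index < 0 || z_plane + cv > dims[3])
    stop("slice_index ", slice_index,
         " addresses a cut plane outside the volume")
  ncx <- dims[1] %/% cv
  ncy <- dims[2] %/% cv
  if (ncx < 1 || ncy < 1) stop("grid cross-section smaller than one cell")

  if (is.null(seed)) {
    enz_i <- match(enzyme, .zp_enzymes, nomatch = 99L)
    seed <- .zp_seed(spec$rng_seed, 1000L + slice_index * 101L + enz_i)
  }
  set.seed(seed)

  cm <- truth$class_map
  zs <- (z_plane + 1L):(z_plane + cv)
  eff <- spec$enzyme_effects
  cell <- expand.grid(cell_x = seq_len(ncx), cell_y = seq_len(ncy),
                      KEEP.OUT.ATTRS = FALSE)
  dom <- character(nrow(cell))
  for (i in seq_len(nrow(cell))) {
    xs <- ((cell$cell_x[i] - 1L) * cv + 1L):(cell$cell_x[i] * cv)
    ys <- ((cell$cell_y[i] - 1L) * cv + 1L):(cell$cell_y[i] * cv)
    counts <- tabulate(cm[xs, ys, zs] + 1L, nbins = 5L)
    names(counts) <- c("none", .zp_classes)
    dom[i] <- .zp_dominant_class(counts, spec$min_pore_prevalence)
  }
  effect <- vapply(dom, function(d) {
    e <- eff[[d]]
    if (is.null(e)) 0 else as.numeric(e)
  }, numeric(1))
  noiseless <- spec$activity_baseline + effect
  value <- noiseless + rnorm(nrow(cell), 0, spec$activity_noise_sd)

  # render at the zymogram pixel scale (pixel value = value of the cell
  # containing the pixel center, plus sensor noise)
  px_um <- spec$zymo_mm_per_pixel * 1000
  npx <- floor(ncx * cv * vx / px_um)
  npy <- floor(ncy * cv * vx / px_um)
  cx_of_px <- pmin(ncx, floor(((seq_len(npx) - 0.5) * px_um) / (cv * vx)) + 1L)
  cy_of_px <- pmin(ncy, floor(((seq_len(npy) - 0.5) * px_um) / (cv * vx)) + 1L)
  vmat <- matrix(value, nrow = ncx, ncol = ncy)
  pix <- vmat[cx_of_px, cy_of_px, drop = FALSE]
  if (spec$pixel_noise_sd > 0)
    pix <- pix + matrix(rnorm(length(pix), 0, spec$pixel_noise_sd),
                        nrow(pix), ncol(pix))

  mask <- matrix(TRUE, npx, npy)
  if (spec$contact_fraction < 1) {
    # one random bad rectangle occupying (1 - contact_fraction) of the area
    bad <- 1 - spec$contact_fraction
    w <- max(1L, round(npx * sqrt(bad)))
    h <- max(1L, round(npy * bad / (w / npx)))
    h <- min(h, npy)
    x0 <- sample.int(npx - w + 1L, 1L)
    y0 <- sample.int(npy - h + 1L, 1L)
    mask[x0:(x0 + w - 1L), y0:(y0 + h - 1L)] <- FALSE
  }

  cell$dominant_class <- dom
  cell$effect <- effect
  cell$activity_noiseless <- noiseless
  cell$activity <- value

  zymogram(pixels = pix, mm_per_pixel = spec$zymo_mm_per_pixel,
           enzyme = enzyme, core_id = spec$core_id,
           slice_index = slice_index,
           slice_depth_um = z_plane * vx, incubated = incubated,
           contact_mask = mask, cell_truth = cell)
}

#' Matched-porosity scenario specs
#'
#' Builds a pair of synthetic-core specs with (approximately) equal image
#' porosity but contrasting architecture: `"few_large"` concentrates the
#' pore volume in a small number of large (> 180 um) spheres, while
#' `"many_small"` spreads the same volume over many 30-150 um spheres.
#' The pair is the synthetic analogue of contrasting cropping systems with
#' coarse- versus fine-pore dominated structure.
#'
#' @param type which member of the pair.
#' @param grid_shape,voxel_size grid geometry.
#' @param target_porosity requested image porosity (placement overlaps may
#'   reduce the realized value slightly).
#' @param seed RNG seed for the spec.
#' @param ... further arguments to [synthetic_spec()].
#' @return a `zp_spec`.
#' @export
scenario_spec <- function(type = c("few_large", "many_small"),
                          grid_shape = c(128, 128, 128), voxel_size = 29,
                          target_porosity = 0.03, seed = 1L, ...) {
  type <- match.arg(type)
  radius <- if (type == "few_large") 250 else 75
  r_vox <- radius / voxel_size
  # voxelized sphere volume in voxels
  rr <- floor(r_vox)
  off <- expand.grid(x = -rr:rr, y = -rr:rr, z = -rr:rr)
  vol_vox <- sum(off$x^2 + off$y^2 + off$z^2 <= r_vox^2)
  count <- max(1L, round(target_porosity * prod(grid_shape) / vol_vox))
  synthetic_spec(grid_shape = grid_shape, voxel_size = voxel_size,
                 pore_population = list(list(shape = "sphere",
                                             radius = radius,
                                             count = count)),
                 rng_seed = seed,
                 core_id = paste0(type, "-", seed),
                 system_label = type, ...)
}

.zp_enzymes <- c("beta-glucosidase", "cellobiohydrolase", "xylanase",
                 "N-acetyl-beta-glucosaminidase", "leucine aminopeptidase",
                 "acid phosphatase")

#' Treat ground-truth phases as a noiseless segmentation
#'
#' Converts a [generate_phase_volume()] result directly into a
#' `zp_segmented` object, bypassing grayscale rendering and thresholding.
#' Useful for isolating downstream geometry from segmentation noise.
#'
#' @param truth a `zp_truth`.
#' @return a `zp_segmented` volume.
#' @export
as_segmented <- function(truth) {
  stopifnot(inherits(truth, "zp_truth"))
  labels <- array(.zp_lab[["solid"]], dim(truth$phase))
  labels[truth$phase == 1L] <- .zp_lab[["pore"]]
  labels[truth$phase == 2L] <- .zp_lab[["pom"]]
  segmented_volume(labels, voxel_size = truth$spec$voxel_size,
                   core_id = truth$spec$core_id,
                   system_label = truth$spec$system_label,
                   provenance = "ground truth (noiseless)")
}

# voxel count of a digitized sphere of the given radius (um)
.zp_sphere_vox_count <- function(radius, voxel_size) {
  r_vox <- radius / voxel_size
  rr <- floor(r_vox)
  off <- expand.grid(x = -rr:rr, y = -rr:rr, z = -rr:rr)
  sum(off$x^2 + off$y^2 + off$z^2 <= r_vox^2)
}

#' Reference spec for the enzyme-effect recovery study
#'
#' One synthetic core of the validation scenario used to test end-to-end
#' recovery of injected pore-class effects: a realistic sparse macropore
#' system of 110-um spheres at ~2% image porosity (so each 1-mm cell
#' holds a Poisson-varying pore volume and the percentile rule can find
#' both pore-rich and matrix micro-sites), with activity shifted by
#' +1.0 SD in 30-150 um dominated cells and +0.3 SD in matrix-dominated
#' cells.  The default grid gives a 7 x 7 grid of 1-mm cells per slice
#' and ten 2-mm-spaced cut faces.
#'
#' @param rng_seed seed for this core.
#' @param core_id identifier.
#' @param grid_shape voxels per axis.
#' @param target_porosity image porosity of the sphere population.
#' @param ... overrides passed to [synthetic_spec()].
#' @return a `zp_spec`.
#' @export
association_study_spec <- function(rng_seed, core_id = paste0("study-",
                                                              rng_seed),
                                   grid_shape = c(238, 238, 690),
                                   target_porosity = 0.02, ...) {
  voxel_size <- 29
  count <- round(target_porosity * prod(grid_shape) /
                   .zp_sphere_vox_count(110, voxel_size))
  synthetic_spec(
    grid_shape = grid_shape, voxel_size = voxel_size,
    pore_population = list(list(shape = "sphere", radius = 110,
                                count = count)),
    enzyme_effects = list(unresolved_matrix = 0.3, p30_150 = 1.0),
    activity_noise_sd = 1.0, rng_seed = rng_seed, core_id = core_id,
    system_label = "study", ...)
}
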