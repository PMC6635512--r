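#' Aggregate CT quantities onto the 1-mm cell grid of a cut face
#'
#' For the cut plane at `slice_depth_um`, partitions the cross-section
#' into square cells of `cell_size_um` (cells extending beyond the
#' cross-section are cropped) and, for the 1-mm^3 voxel of material on
#' the uncut side below the new surface, computes per cell the volume
#' fraction of each pore class and, if a distance map is supplied, the
#' fraction of matrix within `reach` of a sizeable pore.
#' Excluded-border voxels count in no numerator or denominator.
#'
#' @param seg a [segment_volume()] result.
#' @param classmap the matching [classify_pores()] map.
#' @param slice_depth_um depth of the cut face below the core top; mapped
#'   to the nearest CT plane.
#' @param dmap optional [distance_to_qualifying_pores()] map.
#' @param cell_size_um aggregation cell edge (default 1000 = 1 mm).
#' @param reach footprint distance, micrometers.
#' @return data.frame with one row per cell: `cell_x`, `cell_y`,
#'   `n_vox`, abundances `ab_unresolved_matrix`, `ab_p30_150`,
#'   `ab_p150_180`, `ab_p180_plus`, and `footprint_fraction_cell`.
#' @export
aggregate_ct_cells <- function(seg, classmap, slice_depth_um, dmap = NULL,
                               cell_size_um = 1000, reach = 180) {
  stopifnot(inherits(seg, "zp_segmented"), inherits(classmap, "zp_classmap"))
  d <- dim(seg$labels)
  vx <- seg$voxel_size
  cv <- max(1L, as.integer(round(cell_size_um / vx)))
  z_plane <- as.integer(round(slice_depth_um / vx))
  if (z_plane < 0L || z_plane + cv > d[3])
    stop("cut plane at ", slice_depth_um, " um leaves no full cell below ",
         "it inside the volume")
  ncx <- d[1] %/% cv
  ncy <- d[2] %/% cv
  if (ncx < 1L || ncy < 1L) stop("cross-section smaller than one cell")

  zs <- (z_plane + 1L):(z_plane + cv)
  lab <- seg$labels[, , zs, drop = FALSE]
  cls <- classmap$class_map[, , zs, drop = FALSE]

  # cell id per voxel of the slab; NA outside full cells
  cx <- ifelse(seq_len(d[1]) <= ncx * cv, (seq_len(d[1]) - 1L) %/% cv + 1L,
               NA_integer_)
  cy <- ifelse(seq_len(d[2]) <= ncy * cv, (seq_len(d[2]) - 1L) %/% cv + 1L,
               NA_integer_)
  cell_id <- outer(cx, cy, function(a, b) a + (b - 1L) * ncx)
  cell_id <- array(rep(cell_id, length(zs)), dim(lab))

  keep <- !is.na(cell_id) & lab != .zp_lab[["excluded"]]
  id <- cell_id[keep]
  cl <- cls[keep]
  lb <- lab[keep]
  ncell <- ncx * ncy

  # rowsum drops absent ids; build a dense vector instead
  dense <- function(sel) {
    out <- numeric(ncell)
    t <- rowsum(as.numeric(sel), id)
    out[as.integer(rownames(t))] <- t[, 1]
    out
  }
  n_vox <- dense(rep(1, length(id)))
  ab <- sapply(.zp_classes, function(cn)
    ifelse(n_vox > 0, dense(cl == .zp_cls[[cn]]) / pmax(n_vox, 1), NA_real_))

  fp <- rep(NA_real_, ncell)
  if (!is.null(dmap)) {
    stopifnot(inherits(dmap, "zp_distmap"))
    dm <- dmap$distance_um[, , zs, drop = FALSE]
    solid <- lb == .zp_lab[["solid"]]
    n_solid <- dense(solid)
    n_in <- dense(solid & dm[keep] < reach)
    fp <- ifelse(n_solid > 0, n_in / pmax(n_solid, 1), NA_real_)
  }

  out <- data.frame(
    cell_x = rep(seq_len(ncx), times = ncy),
    cell_y = rep(seq_len(ncy), each = ncx),
    n_vox = n_vox)
  for (cn in .zp_classes) out[[paste0("ab_", cn)]] <- ab[, cn]
  out$footprint_fraction_cell <- fp
  attr(out, "cell_size_um") <- cv * vx
  attr(out, "cell_vox") <- cv
  out
}

#' Fuse a zymogram with CT pore data on the 1-mm grid
#'
#' Averages zymogram pixels into the cells of the cut-face grid, pairs
#' each cell with the CT quantities of the 1-mm^3 voxel below the
#' surface (the enzyme cell sits at the face center of that voxel), and
#' standardizes the cell means across the whole slice.  Cells whose
#' usable-pixel coverage falls below `min_coverage` get no activity
#' value (`NA`); they still carry pore data.
#'
#' The zymogram is assumed laterally registered with the CT
#' cross-section (the synthetic generator emits perfectly registered
#' pairs); `flip_x`, `flip_y` and `rotate90` apply a configured rigid
#' alignment for real acquisitions.
#'
#' @param z a [zymogram()] (raw grays; standardization happens here,
#'   after aggregation).
#' @param seg,classmap,dmap CT-side inputs, as in [aggregate_ct_cells()].
#' @param cell_size_um,reach grid geometry, as in [aggregate_ct_cells()].
#' @param min_coverage minimum usable-pixel fraction per cell.
#' @param standardize `"after"` (default: standardize the cell means
#'   across the slice) or `"before"` (standardize pixels first, then
#'   average; exposed for sensitivity analysis).
#' @param flip_x,flip_y,rotate90 lateral registration of the zymogram to
#'   the CT cross-section: flips are applied first, then `rotate90`
#'   quarter-turns.
#' @param slice_spacing_um if supplied, validates that the zymogram's
#'   depth sits on the slice lattice.
#' @param ct_cells precomputed [aggregate_ct_cells()] table (skips the
#'   CT aggregation; `seg`, `classmap`, `dmap` may then be `NULL`).
#' @return data.frame of cell records: identifiers, class abundances,
#'   cell footprint fraction, `coverage`, `n_pixels`, `mean_activity`
#'   (raw cell mean) and `mean_activity_z` (slice-standardized).
#' @export
build_grid <- function(z, seg = NULL, classmap = NULL, dmap = NULL,
                       cell_size_um = 1000, reach = 180,
                       min_coverage = 0.5,
                       standardize = c("after", "before"),
                       flip_x = FALSE, flip_y = FALSE, rotate90 = 0L,
                       slice_spacing_um = NULL, ct_cells = NULL) {
  stopifnot(inherits(z, "zp_zymogram"))
  standardize <- match.arg(standardize)
  if (!is.null(slice_spacing_um)) {
    k <- z$slice_depth_um / slice_spacing_um
    if (abs(k - round(k)) > 1e-6)
      stop("slice depth ", z$slice_depth_um, " um is not on the ",
           slice_spacing_um, " um slice lattice")
  }
  if (is.null(ct_cells)) {
    ct_cells <- aggregate_ct_cells(seg, classmap,
                                   slice_depth_um = z$slice_depth_um,
                                   dmap = dmap, cell_size_um = cell_size_um,
                                   reach = reach)
  }
  cell_um <- attr(ct_cells, "cell_size_um")
  ncx <- max(ct_cells$cell_x)
  ncy <- max(ct_cells$cell_y)

  px <- z$pixels
  usable <- z$contact_mask
  if (flip_x) {
    px <- px[nrow(px):1, , drop = FALSE]
    usable <- usable[nrow(usable):1, , drop = FALSE]
  }
  if (flip_y) {
    px <- px[, ncol(px):1, drop = FALSE]
    usable <- usable[, ncol(usable):1, drop = FALSE]
  }
  for (r in seq_len(rotate90 %% 4L)) {
    px <- t(px[nrow(px):1, , drop = FALSE])
    usable <- t(usable[nrow(usable):1, , drop = FALSE])
  }
  if (standardize == "before") {
    zz <- z
    zz$pixels <- px
    zz$contact_mask <- usable
    px <- standardize_zymogram(zz)$zscores
    px[is.na(px)] <- 0  # masked pixels are dropped via `usable` anyway
  }

  px_um <- z$mm_per_pixel * 1000
  cx_px <- floor(((seq_len(nrow(px)) - 0.5) * px_um) / cell_um) + 1L
  cy_px <- floor(((seq_len(ncol(px)) - 0.5) * px_um) / cell_um) + 1L
  cid <- outer(ifelse(cx_px <= ncx, cx_px, NA_integer_),
               ifelse(cy_px <= ncy, cy_px, NA_integer_),
               function(a, b) a + (b - 1L) * ncx)
  keep <- !is.na(cid)
  id <- cid[keep]
  ncell <- ncx * ncy
  dense <- function(v) {
    out <- numeric(ncell)
    t <- rowsum(v, id)
    out[as.integer(rownames(t))] <- t[, 1]
    out
  }
  n_px <- dense(rep(1, length(id)))
  n_use <- dense(as.numeric(usable[keep]))
  sum_use <- dense(ifelse(usable[keep], px[keep], 0))
  coverage <- ifelse(n_px > 0, n_use / pmax(n_px, 1), 0)
  mean_act <- ifelse(n_use > 0, sum_use / pmax(n_use, 1), NA_real_)
  mean_act[coverage < min_coverage] <- NA_real_

  if (standardize == "after") {
    ok <- !is.na(mean_act)
    if (sum(ok) >= 2L && sd(mean_act[ok]) > 0) {
      zscore <- (mean_act - mean(mean_act[ok])) / sd(mean_act[ok])
    } else {
      zscore <- rep(NA_real_, ncell)
    }
  } else {
    zscore <- mean_act  # pixel z-scores were averaged per cell
  }

  out <- ct_cells
  out$core_id <- z$core_id
  out$system_label <- if (!is.null(seg)) seg$system_label else
    attr(ct_cells, "system_label") %||% ""
  out$slice_index <- z$slice_index
  out$enzyme <- z$enzyme
  out$incubated <- z$incubated
  out$n_pixels <- n_px
  out$coverage <- coverage
  out$mean_activity <- mean_act
  out$mean_activity_z <- zscore
  out$selected_class <- NA_character_
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select pore-class-representative cells by the percentile rule
#'
#' Aggregation to the 1-mm grid smooths pore information, so the
#' association analysis keeps only cells that are highly representative
#' of one pore class: for each core and class, a cell is selected when
#' its class abundance strictly exceeds the class's `q`-quantile over
#' all of that core's cells (type-1, inverse-ECDF quantile; with
#' continuous abundances exactly `floor((1 - q) * n)` cells exceed it,
#' and ties at the threshold are excluded).  A cell exceeding the
#' percentile for several classes is grouped in the largest of them.
#'
#' @param records cell records from [build_grid()] (possibly several
#'   slices/cores row-bound together).
#' @param q quantile level (default 0.95).
#' @param classes classes entering the analysis; by default the three
#'   size groups `unresolved_matrix` (<30 um proxy), `p30_150` and
#'   `p180_plus` (the gap class `p150_180` is kept out of three-class
#'   comparisons).
#' @param min_records warn when a core has fewer records than this (the
#'   percentile becomes unstable).
#' @return `records` with `selected_class` filled in (`NA` for
#'   unselected cells).
#' @export
percentile_select <- function(records, q = 0.95,
                              classes = c("unresolved_matrix", "p30_150",
                                          "p180_plus"),
                              min_records = 20L) {
  stopifnot(is.data.frame(records))
  bad <- setdiff(classes, .zp_classes)
  if (length(bad)) stop("unknown classes: ", toString(bad))
  classes <- .zp_classes[.zp_classes %in% classes]  # size order
  records$selected_class <- NA_character_
  for (core in unique(records$core_id)) {
    rows <- which(records$core_id == core)
    if (length(rows) < min_records)
      warning("core ", core, " has only ", length(rows),
              " records; the ", q, "-quantile is unstable")
    for (cn in classes) {  # ascending size: larger classes overwrite
      ab <- records[[paste0("ab_", cn)]][rows]
      thr <- quantile(ab, q, type = 1, names = FALSE, na.rm = TRUE)
      sel <- !is.na(ab) & ab > thr
      records$selected_class[rows[sel]] <- cn
    }
  }
  records
}

#' Association table of enzyme activity by pore-class micro-site
#'
#' Summarizes slice-standardized activity over the selected,
#' class-representative cells: group means with standard errors and
#' counts, grouped by selected class and any further grouping columns
#' (e.g. `system_label`, `enzyme`, `incubated`).  Cells without an
#' activity value or without a selected class are dropped; empty groups
#' are omitted.  The s.e.m. is `sd/sqrt(n)` over cells (`NA` for
#' single-cell groups).
#'
#' @param records output of [percentile_select()].
#' @param group_by further grouping column names (default none).
#' @return data.frame with columns `pore_class`, the grouping columns,
#'   `mean_z`, `sem`, `n_cells`, `n_slices`, `n_cores`.
#' @export
associate <- function(records, group_by = character()) {
  stopifnot(is.data.frame(records))
  keep <- !is.na(records$selected_class) & !is.na(records$mean_activity_z)
  r <- records[keep, , drop = FALSE]
  if (!nrow(r)) stop("no selected records with activity values")
  missing_cols <- setdiff(group_by, names(r))
  if (length(missing_cols))
    stop("grouping columns not present: ", toString(missing_cols))
  key <- interaction(c(list(r$selected_class),
                       lapply(group_by, function(g) r[[g]])),
                     drop = TRUE, lex.order = TRUE)
  split_rows <- split(seq_len(nrow(r)), key)
  rows <- lapply(split_rows, function(ix) {
    zvals <- r$mean_activity_z[ix]
    out <- data.frame(pore_class = r$selected_class[ix[1]])
    for (g in group_by) out[[g]] <- r[[g]][ix[1]]
    out$mean_z <- mean(zvals)
    out$sem <- if (length(zvals) > 1L) sd(zvals) / sqrt(length(zvals))
               else NA_real_
    out$n_cells <- length(zvals)
    out$n_slices <- length(unique(paste(r$core_id[ix], r$slice_index[ix])))
    out$n_cores <- length(unique(r$core_id[ix]))
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$pore_class <- factor(out$pore_class,
                           levels = .zp_classes[.zp_classes %in%
                                                  out$pore_class])
  out[order(out$pore_class), , drop = FALSE]
}

#' Permutation contrast between two pore-class micro-site groups
#'
#' Seeded two-sided permutation test for the difference in mean
#' standardized activity between cells selected for `class_a` and
#' `class_b`.  Class labels are permuted within each core, respecting
#' the nesting of cells in cores.  This is a deliberately simple
#' stand-in for full mixed-effects inference (enzyme, system and depth
#' strata are not modeled); the record CSVs are designed so external
#' mixed-model tools can consume them.
#'
#' @param records output of [percentile_select()].
#' @param class_a,class_b class names to contrast (difference is
#'   `mean(class_a) - mean(class_b)`).
#' @param n_perm number of permutations (>= 999).
#' @param seed RNG seed.
#' @return list with `estimate` (observed difference, SD units),
#'   `p_value`, `n_a`, `n_b`, `n_perm`.
#' @export
permutation_contrast <- function(records, class_a, class_b,
                                 n_perm = 1999L, seed = 1L) {
  stopifnot(is.data.frame(records))
  if (n_perm < 999L) stop("n_perm must be >= 999")
  keep <- records$selected_class %in% c(class_a, class_b) &
    !is.na(records$mean_activity_z)
  r <- records[keep, , drop = FALSE]
  if (!any(r$selected_class == class_a))
    stop("class ", class_a, " absent from every core")
  if (!any(r$selected_class == class_b))
    stop("class ", class_b, " absent from every core")
  diff_of <- function(lab)
    mean(r$mean_activity_z[lab == class_a]) -
      mean(r$mean_activity_z[lab == class_b])
  obs <- diff_of(r$selected_class)
  cores <- split(seq_len(nrow(r)), r$core_id)
  restore <- .zp_local_rng(.zp_seed(seed, 0L))
  on.exit(restore(), add = TRUE)
  perm <- numeric(n_perm)
  lab <- r$selected_class
  for (b in seq_len(n_perm)) {
    pl <- lab
    for (ix in cores) pl[ix] <- pl[ix][sample.int(length(ix))]
    perm[b] <- diff_of(pl)
  }
  perm <- perm[is.finite(perm)]
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (length(perm) + 1)
  list(estimate = obs, p_value = p,
       n_a = sum(r$selected_class == class_a),
       n_b = sum(r$selected_class == class_b),
       n_perm = n_perm)
}
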