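#' 3D median filter with a spherical neighborhood
#'
#' Replaces each voxel by the median of the gray values within a spherical
#' neighborhood of the given radius (in voxels), the standard denoising
#' step before histogram segmentation of CT volumes.  Neighborhoods are
#' truncated at the grid boundary; with an even neighbor count the upper
#' median is taken (interior spherical neighborhoods always have an odd
#' count).
#'
#' @param vol a [core_volume()].
#' @param radius neighborhood radius in voxels (default 2).
#' @return a filtered `zp_volume` of the same shape and bit depth.
#' @export
median_filter_3d <- function(vol, radius = 2L) {
  stopifnot(inherits(vol, "zp_volume"))
  radius <- as.integer(radius)
  if (radius < 1L) stop("radius must be >= 1 voxel")
  if (radius > max(dim(vol$voxels)))
    stop("radius exceeds every grid dimension")
  out <- vol
  out$voxels <- array(
    median_filter3d_cpp(vol$voxels, dim(vol$voxels), radius),
    dim(vol$voxels))
  out
}

#' Exclude a border shell from analysis
#'
#' Marks voxels within `margin` micrometers of the lateral (x, y) grid
#' boundary as excluded, the standard guard against sample-wall artifacts
#' in cores scanned inside their rings.  Set `faces = "all"` to also trim
#' the top and bottom faces.  Excluded voxels keep their gray values but
#' are omitted from histograms, porosities and footprint statistics.
#' Re-trimming with the same margin is idempotent.
#'
#' @param vol a [core_volume()].
#' @param margin trim depth in micrometers (default 5000, i.e. 0.5 cm).
#' @param faces `"lateral"` (default) or `"all"`.
#' @return the volume with an updated exclusion mask and
#'   `border_trimmed = TRUE`.
#' @export
trim_border <- function(vol, margin = 5000, faces = c("lateral", "all")) {
  stopifnot(inherits(vol, "zp_volume"))
  faces <- match.arg(faces)
  if (margin < 0) stop("margin must be >= 0")
  d <- dim(vol$voxels)
  nvox <- as.integer(ceiling(margin / vol$voxel_size))
  if (2L * nvox >= d[1] || 2L * nvox >= d[2])
    stop("margin of ", margin, " um consumes the entire cross-section")
  out <- vol
  if (nvox > 0L) {
    excl <- if (is.null(vol$excluded)) array(FALSE, d) else vol$excluded
    ix <- c(seq_len(nvox), (d[1] - nvox + 1L):d[1])
    iy <- c(seq_len(nvox), (d[2] - nvox + 1L):d[2])
    excl[ix, , ] <- TRUE
    excl[, iy, ] <- TRUE
    if (faces == "all") {
      if (2L * nvox >= d[3])
        stop("margin of ", margin, " um consumes the entire depth")
      iz <- c(seq_len(nvox), (d[3] - nvox + 1L):d[3])
      excl[, , iz] <- TRUE
    }
    out$excluded <- excl
  }
  out$border_trimmed <- TRUE
  out
}

#' Fit a two-Gaussian model to a volume's gray histogram
#'
#' CT histograms of moist soil show two overlapping distributions, a dark
#' one from air + liquid filled pores and a bright one from solid.  This
#' fits their sum, `A1 exp(-(g - mu1)^2 / 2 s1^2) + A2 exp(-(g - mu2)^2 /
#' 2 s2^2)`, to the 256-bin 8-bit histogram of the non-excluded voxels by
#' nonlinear least squares (Levenberg-Marquardt, multi-start from the
#' modes of a smoothed histogram with a quantile-based fallback, sigma
#' bounded to \[0.5, 128\] gray levels).  16-bit input is min-max rescaled
#' to the 8-bit axis first.  The component with the smaller mean is
#' air + liquid.
#'
#' A histogram with (near) two-valued support cannot constrain the sigmas;
#' such fits are flagged `degenerate` and [minimum_error_threshold()] then
#' falls back to the midpoint between the two dominant gray levels.  A
#' component carrying less than 1% of the fitted mass triggers a
#' near-unimodal warning.
#'
#' @param vol a [core_volume()].
#' @param n_starts number of jittered restarts around each start point.
#' @return an object of class `zp_histfit` with fields `amp1`, `mu1`,
#'   `sigma1`, `amp2`, `mu2`, `sigma2`, `fit_residual` (sum of squared
#'   errors), `degenerate`, `fallback_threshold`, `counts`.
#' @export
fit_two_gaussians <- function(vol, n_starts = 4L) {
  stopifnot(inherits(vol, "zp_volume"))
  vol8 <- rescale_to_8bit(vol)
  gray <- vol8$voxels[.zp_included(vol8)]
  if (!length(gray)) stop("no included voxels to build a histogram from")
  counts <- tabulate(gray + 1L, nbins = 256L)
  g <- 0:255

  # degenerate (near two-valued) histogram: no sigma information
  nz <- which(counts > 0)
  top2 <- nz[order(counts[nz], decreasing = TRUE)][1:min(2, length(nz))]
  if (length(nz) <= 3L || sum(counts[top2]) / sum(counts) > 0.999) {
    top2 <- sort(top2)
    fallback <- as.integer(floor(mean(top2))) - 1L
    warning("degenerate (near two-valued) histogram; ",
            "falling back to the midpoint threshold")
    return(structure(
      list(amp1 = counts[top2[1]], mu1 = top2[1] - 1, sigma1 = NA_real_,
           amp2 = counts[top2[length(top2)]], mu2 = top2[length(top2)] - 1,
           sigma2 = NA_real_, fit_residual = NA_real_, degenerate = TRUE,
           fallback_threshold = fallback, counts = counts),
      class = "zp_histfit"))
  }

  # start points: the dominant mode of a smoothed histogram paired with
  # (a) the best-separated secondary mode, (b) low-tail quantiles (the
  # air+liquid component of a dense core may hold only a few percent of
  # the mass and hide from mode detection), (c) bulk quantiles
  sm <- stats::filter(counts, rep(1 / 9, 9), sides = 2)
  sm[is.na(sm)] <- 0
  locmax <- which(diff(sign(diff(sm))) == -2) + 1L
  locmax <- locmax[order(sm[locmax], decreasing = TRUE)]
  starts <- list()
  add_start <- function(a, b) {
    if (!is.na(a) && !is.na(b) && abs(b - a) >= 10)
      starts[[length(starts) + 1L]] <<- c(mu1 = min(a, b), mu2 = max(a, b))
  }
  main_mode <- if (length(locmax)) locmax[1] - 1L else
    which.max(counts) - 1L
  far <- locmax[abs(locmax - 1L - main_mode) >= 20][1]
  add_start(main_mode, far - 1L)
  for (q in c(0.005, 0.02, 0.1))
    add_start(quantile(gray, q, names = FALSE), main_mode)
  qs <- quantile(gray, c(0.25, 0.75), names = FALSE)
  add_start(qs[1], qs[2])
  if (!length(starts)) starts[[1]] <- c(mu1 = main_mode - 20,
                                        mu2 = main_mode + 20)

  fit_one <- function(st) {
    s0 <- max(2, (st["mu2"] - st["mu1"]) / 4)
    start <- list(A1 = max(counts[round(st["mu1"]) + 1], 1),
                  m1 = unname(st["mu1"]), s1 = unname(s0),
                  A2 = max(counts[round(st["mu2"]) + 1], 1),
                  m2 = unname(st["mu2"]), s2 = unname(s0))
    tryCatch(
      minpack.lm::nlsLM(
        counts ~ A1 * exp(-(g - m1)^2 / (2 * s1^2)) +
          A2 * exp(-(g - m2)^2 / (2 * s2^2)),
        start = start,
        lower = c(0, 0, 0.5, 0, 0, 0.5),
        upper = c(Inf, 255, 128, Inf, 255, 128),
        control = nls.control(maxiter = 200, warnOnly = TRUE)),
      error = function(e) NULL)
  }

  best <- NULL
  best_sse <- Inf
  jit <- .zp_local_rng(.zp_seed(sum(counts), 7L))  # deterministic jitter
  on.exit(jit(), add = TRUE)
  for (st in starts) {
    cand <- list(st)
    for (j in seq_len(max(0L, n_starts - 1L)))
      cand[[j + 1L]] <- st + stats::runif(2, -10, 10)
    for (cc in cand) {
      cc["mu1"] <- min(max(cc["mu1"], 0), 255)
      cc["mu2"] <- min(max(cc["mu2"], 0), 255)
      if (cc["mu2"] <= cc["mu1"]) next
      f <- fit_one(cc)
      if (is.null(f)) next
      sse <- sum(stats::residuals(f)^2)
      if (sse < best_sse) {
        best <- f
        best_sse <- sse
      }
    }
  }
  if (is.null(best))
    stop("two-Gaussian fit failed to converge from all start points; ",
         "histogram may not be bimodal")

  p <- coef(best)
  comp <- if (p["m1"] <= p["m2"]) c(1L, 2L) else c(2L, 1L)
  A <- unname(p[c("A1", "A2")][comp])
  m <- unname(p[c("m1", "m2")][comp])
  s <- unname(p[c("s1", "s2")][comp])
  w <- A * s / sum(A * s)
  if (any(w < 0.01))
    warning("near-unimodal histogram: one component carries <1% ",
            "of the fitted mass")
  structure(
    list(amp1 = A[1], mu1 = m[1], sigma1 = s[1],
         amp2 = A[2], mu2 = m[2], sigma2 = s[2],
         fit_residual = best_sse, degenerate = FALSE,
         fallback_threshold = NA_integer_, counts = counts),
    class = "zp_histfit")
}

#' @export
print.zp_histfit <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<zp_histfit> degenerate; fallback threshold %d\n",
                x$fallback_threshold))
  } else {
    cat(sprintf(paste0("<zp_histfit> air+liquid: mu %.2f sd %.2f | solid: ",
                       "mu %.2f sd %.2f | SSE %.3g\n"),
                x$mu1, x$sigma1, x$mu2, x$sigma2, x$fit_residual))
  }
  invisible(x)
}

#' Minimum-error threshold between two fitted Gaussians
#'
#' Scans all 256 gray levels for the threshold `t` that minimizes the
#' absolute difference between the two misclassified areas: the part of
#' the air + liquid component above `t` and the part of the solid
#' component below `t` (the level `t` itself is counted in neither tail).
#' Balancing the two misclassified areas conserves the voxel balance
#' between the segmented phases.  Ties are broken toward the lower gray
#' level.
#'
#' By default the areas are those of the fitted, amplitude-scaled
#' components; `scale = "density"` instead normalizes each component to
#' unit area before comparing tails.
#'
#' @param model a [fit_two_gaussians()] result.
#' @param scale `"fitted"` (amplitude-scaled components, default) or
#'   `"density"` (each component normalized to unit area).
#' @return integer gray level in `[mu1, mu2]`.
#' @export
minimum_error_threshold <- function(model, scale = c("fitted", "density")) {
  stopifnot(inherits(model, "zp_histfit"))
  scale <- match.arg(scale)
  if (model$degenerate) return(model$fallback_threshold)
  g <- 0:255
  g1 <- model$amp1 * exp(-(g - model$mu1)^2 / (2 * model$sigma1^2))
  g2 <- model$amp2 * exp(-(g - model$mu2)^2 / (2 * model$sigma2^2))
  if (scale == "density") {
    g1 <- g1 / sum(g1)
    g2 <- g2 / sum(g2)
  }
  crit <- vapply(g, function(t)
    abs(sum(g1[g > t]) - sum(g2[g < t])), numeric(1))
  t <- g[which.min(crit)]  # which.min takes the first (lowest) minimizer
  as.integer(t)
}

#' Construct a segmented volume
#'
#' Low-level constructor for per-voxel phase labels: 0 excluded, 1 pore,
#' 2 solid, 3 POM.  Most users will call [segment_volume()] instead.
#'
#' @param labels 3D integer array of label codes.
#' @param voxel_size voxel edge, micrometers.
#' @param core_id,system_label,provenance metadata.
#' @return an object of class `zp_segmented`.
#' @export
segmented_volume <- function(labels, voxel_size, core_id = "core",
                             system_label = "", provenance = "") {
  .zp_stopifnot_dim3(labels, "label map")
  storage.mode(labels) <- "integer"
  if (!all(labels %in% .zp_lab)) stop("unknown label codes present")
  structure(
    list(labels = labels, voxel_size = voxel_size, core_id = core_id,
         system_label = system_label, provenance = provenance),
    class = "zp_segmented")
}

#' @export
print.zp_segmented <- function(x, ...) {
  tab <- tabulate(x$labels + 1L, nbins = 4L)
  cat(sprintf(paste0("<zp_segmented> %s: %s voxels @ %g um | pore %d, ",
                     "solid %d, POM %d, excluded %d\n"),
              x$core_id, paste(dim(x$labels), collapse = " x "),
              x$voxel_size, tab[2], tab[3], tab[4], tab[1]))
  invisible(x)
}

#' Segment a volume into pore and solid phases
#'
#' Applies a gray threshold: values at or below the threshold become pore
#' (air + liquid), values above become solid.  An optional POM mask
#' overrides pore/solid labels (but not the excluded border).
#' Segmentation is a pure function of its inputs.  16-bit volumes are
#' min-max rescaled to the 8-bit axis first, matching
#' [fit_two_gaussians()].
#'
#' @param vol a [core_volume()].
#' @param threshold gray level from [minimum_error_threshold()].
#' @param pom_mask optional logical array (same shape) of particulate
#'   organic matter voxels, identified externally.
#' @return a `zp_segmented` volume with threshold provenance.
#' @export
segment_volume <- function(vol, threshold, pom_mask = NULL) {
  stopifnot(inherits(vol, "zp_volume"))
  vol8 <- rescale_to_8bit(vol)
  if (threshold < 0 || threshold > 255)
    stop("threshold outside the 8-bit gray range")
  d <- dim(vol8$voxels)
  if (!is.null(pom_mask)) {
    if (!identical(dim(pom_mask), d)) stop("pom_mask shape mismatch")
    if (!is.logical(pom_mask)) stop("pom_mask must be logical")
  }
  labels <- array(.zp_lab[["solid"]], d)
  labels[vol8$voxels <= threshold] <- .zp_lab[["pore"]]
  if (!is.null(pom_mask)) labels[pom_mask] <- .zp_lab[["pom"]]
  if (!is.null(vol8$excluded)) labels[vol8$excluded] <- .zp_lab[["excluded"]]
  segmented_volume(labels, voxel_size = vol8$voxel_size,
                   core_id = vol8$core_id,
                   system_label = vol8$system_label,
                   provenance = sprintf("threshold %d on %s", threshold,
                                        vol8$core_id))
}
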