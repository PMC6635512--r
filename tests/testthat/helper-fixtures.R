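# fixture builders used across test files

# segmented volume that is solid except for listed spheres (centers in
# voxel coords, radii in voxels)
make_sphere_seg <- function(dims, centers, radii_vox, voxel_size = 29,
                            core_id = "fixture") {
  lab <- array(2L, dims)  # solid
  for (s in seq_along(radii_vox)) {
    ctr <- centers[[s]]
    g <- as.matrix(expand.grid(1:dims[1], 1:dims[2], 1:dims[3]))
    d2 <- (g[, 1] - ctr[1])^2 + (g[, 2] - ctr[2])^2 + (g[, 3] - ctr[3])^2
    lab[d2 <= radii_vox[s]^2] <- 1L
  }
  segmented_volume(lab, voxel_size = voxel_size, core_id = core_id)
}

# random "blob" pore volume: union of small spheres, guaranteed background
make_blob_pore <- function(dims, n_spheres = 10, r_range = c(1.5, 4.5),
                           seed = 1) {
  set.seed(seed)
  pore <- array(FALSE, dims)
  g <- as.matrix(expand.grid(1:dims[1], 1:dims[2], 1:dims[3]))
  for (s in seq_len(n_spheres)) {
    r <- runif(1, r_range[1], r_range[2])
    ctr <- sapply(dims, function(n) sample.int(n, 1))
    d2 <- (g[, 1] - ctr[1])^2 + (g[, 2] - ctr[2])^2 + (g[, 3] - ctr[3])^2
    pore[d2 <= r^2] <- TRUE
  }
  # keep a solid shell so background always exists
  pore[1, , ] <- FALSE; pore[dims[1], , ] <- FALSE
  pore[, 1, ] <- FALSE; pore[, dims[2], ] <- FALSE
  pore[, , 1] <- FALSE; pore[, , dims[3]] <- FALSE
  pore
}

seg_from_pore <- function(pore, voxel_size = 29) {
  lab <- array(2L, dim(pore))
  lab[pore] <- 1L
  segmented_volume(lab, voxel_size = voxel_size)
}

# hand-built two-Gaussian histogram model object
make_histfit <- function(a1, m1, s1, a2, m2, s2) {
  structure(list(amp1 = a1, mu1 = m1, sigma1 = s1, amp2 = a2, mu2 = m2,
                 sigma2 = s2, fit_residual = 0, degenerate = FALSE,
                 fallback_threshold = NA_integer_, counts = NULL),
            class = "zp_histfit")
}
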