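# Independent brute-force oracles implementing the definitions directly.
# These deliberately avoid the package's distance-transform code paths.

# offsets sorted by squared distance, as a matrix (dx, dy, dz, d2)
.offset_table <- function(rmax) {
  off <- as.matrix(expand.grid(dx = -rmax:rmax, dy = -rmax:rmax,
                               dz = -rmax:rmax))
  d2 <- off[, 1]^2 + off[, 2]^2 + off[, 3]^2
  cbind(off, d2 = d2)[order(d2), , drop = FALSE]
}

# maximal-inscribed-sphere local thickness, squared voxel radii, by the
# definition: grow a candidate sphere at every pore center until it hits a
# non-pore voxel, then let every covered voxel inherit the largest radius.
oracle_local_thickness_sq <- function(pore) {
  d <- dim(pore)
  off <- .offset_table(max(d))
  n_off <- nrow(off)
  out <- array(0, d)
  centers <- which(pore)
  cc <- arrayInd(centers, d)
  chunk <- 600L
  for (i in seq_along(centers)) {
    cx <- cc[i, 1]; cy <- cc[i, 2]; cz <- cc[i, 3]
    # D2 = squared distance to the nearest in-grid non-pore voxel
    D2 <- NA_real_
    start <- 1L
    while (start <= n_off) {
      end <- min(start + chunk - 1L, n_off)
      ix <- start:end
      x <- cx + off[ix, 1]; y <- cy + off[ix, 2]; z <- cz + off[ix, 3]
      ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
      if (any(ok)) {
        lin <- x[ok] + (y[ok] - 1) * d[1] + (z[ok] - 1) * d[1] * d[2]
        bg <- !pore[lin]
        if (any(bg)) {
          D2 <- off[ix[ok][bg][1], 4]
          break
        }
      }
      start <- end + 1L
    }
    stopifnot(!is.na(D2))  # test volumes always contain background
    # paint the open ball of squared radius D2 (covers offsets d2 <= D2-1)
    m <- findInterval(D2 - 1, off[, 4])
    if (m >= 1) {
      ix <- 1:m
      x <- cx + off[ix, 1]; y <- cy + off[ix, 2]; z <- cz + off[ix, 3]
      ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
      lin <- x[ok] + (y[ok] - 1) * d[1] + (z[ok] - 1) * d[1] * d[2]
      out[lin] <- pmax(out[lin], D2)
    }
  }
  out[!pore] <- NA_real_
  out
}

# all-pairs nearest-distance scan (voxel centers), squared voxel units
oracle_nearest_sq <- function(target_mask) {
  d <- dim(target_mask)
  tc <- arrayInd(which(target_mask), d)
  out <- array(Inf, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3])
    out[i, j, k] <- min((tc[, 1] - i)^2 + (tc[, 2] - j)^2 +
                          (tc[, 3] - k)^2)
  out
}

# exhaustive 256-level minimum-error threshold scan on two Gaussian
# components (amplitude-scaled), level t in neither tail
oracle_min_error_scan <- function(a1, m1, s1, a2, m2, s2) {
  g <- 0:255
  c1 <- a1 * exp(-(g - m1)^2 / (2 * s1^2))
  c2 <- a2 * exp(-(g - m2)^2 / (2 * s2^2))
  crit <- sapply(g, function(t) abs(sum(c1[g > t]) - sum(c2[g < t])))
  g[which.min(crit)]
}

# per-voxel spherical-neighborhood median by direct enumeration (upper
# median, matching the filter's documented convention)
oracle_median_filter <- function(vol, radius) {
  d <- dim(vol)
  out <- array(0L, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    vals <- integer(0)
    for (dx in -radius:radius) for (dy in -radius:radius)
      for (dz in -radius:radius) {
        if (dx^2 + dy^2 + dz^2 > radius^2) next
        x <- i + dx; y <- j + dy; z <- k + dz
        if (x < 1 || x > d[1] || y < 1 || y > d[2] || z < 1 || z > d[3])
          next
        vals <- c(vals, vol[x, y, z])
      }
    out[i, j, k] <- sort(vals)[length(vals) %/% 2 + 1L]
  }
  out
}
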