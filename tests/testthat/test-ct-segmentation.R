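test_that("median filter leaves constants alone and removes speckle", {
  const <- core_volume(array(77L, c(9, 9, 9)), voxel_size = 29)
  expect_identical(median_filter_3d(const, 2)$voxels, const$voxels)

  speck <- array(10L, c(9, 9, 9))
  speck[5, 5, 5] <- 250L
  v <- median_filter_3d(core_volume(speck, 29), 2)
  expect_identical(v$voxels[5, 5, 5], 10L)
  expect_true(all(v$voxels == 10L))
})

test_that("median filter matches the exhaustive neighborhood scan", {
  set.seed(8)
  vol <- array(sample.int(256, 16^3, replace = TRUE) - 1L, c(16, 16, 16))
  got <- median_filter_3d(core_volume(vol, 29), 1)$voxels
  expect_identical(got, oracle_median_filter(vol, 1))
})

test_that("median filter validates its radius", {
  v <- core_volume(array(0L, c(5, 5, 5)), 29)
  expect_error(median_filter_3d(v, 0), ">= 1")
  expect_error(median_filter_3d(v, 9), "exceeds")
})

test_that("border trimming excludes the documented lateral shell", {
  v <- core_volume(array(100L, c(400, 400, 5)), voxel_size = 29)
  expect_null(trim_border(v, 0)$excluded)   # margin 0: nothing excluded

  tr <- trim_border(v, 5000)
  n <- as.integer(ceiling(5000 / 29))
  expect_identical(n, 173L)
  expect_true(all(tr$excluded[1:n, , ]))
  expect_true(all(tr$excluded[, 1:n, ]))
  expect_false(any(tr$excluded[(n + 1):(400 - n), (n + 1):(400 - n), ]))
  # idempotent
  tr2 <- trim_border(tr, 5000)
  expect_identical(tr2$excluded, tr$excluded)
  # excluded voxels leave the histogram
  expect_identical(sum(zymopore:::.zp_included(tr)), 14580L)
})

test_that("margins consuming the cross-section are rejected", {
  v <- core_volume(array(100L, c(40, 40, 5)), voxel_size = 29)
  expect_error(trim_border(v, 1000), "consumes")
})

test_that("two-Gaussian fit recovers generator parameters within 1 gray", {
  sp <- synthetic_spec(grid_shape = c(64, 64, 64),
                       pore_population = list(list(shape = "sphere",
                                                   radius = 250, count = 8)),
                       gray_model = c(mean_solid = 160, sd_solid = 15,
                                      mean_void = 60, sd_void = 12),
                       rng_seed = 17)
  tr <- generate_phase_volume(sp, footprint = FALSE)
  fit <- fit_two_gaussians(render_grayscale(tr))
  expect_false(fit$degenerate)
  expect_lt(abs(fit$mu1 - 60), 1)
  expect_lt(abs(fit$mu2 - 160), 1)
  expect_lt(abs(fit$sigma1 - 12), 1)
  expect_lt(abs(fit$sigma2 - 15), 1)
})

test_that("an equal-weight equal-sigma mixture fits symmetrically", {
  set.seed(5)
  n <- 2e5
  gray <- c(rnorm(n / 2, 80, 10), rnorm(n / 2, 180, 10))
  gray <- as.integer(pmin(255, pmax(0, round(gray))))
  vol <- core_volume(array(gray, c(50, 100, 40)), 29)
  fit <- fit_two_gaussians(vol)
  expect_lt(abs(fit$amp1 - fit$amp2) / max(fit$amp1, fit$amp2), 0.05)
  expect_lt(abs(fit$sigma1 - fit$sigma2), 0.5)
})

test_that("noiseless two-value volumes fall back to the midpoint", {
  vol <- array(60L, c(12, 12, 12))
  vol[1:6, , ] <- 160L
  expect_warning(fit <- fit_two_gaussians(core_volume(vol, 29)),
                 "degenerate")
  expect_true(fit$degenerate)
  expect_identical(minimum_error_threshold(fit), 110L)
})

test_that("symmetric components put the threshold at the midpoint", {
  fit <- make_histfit(1000, 60, 12, 1000, 160, 12)
  expect_identical(minimum_error_threshold(fit), 110L)
})

test_that("threshold equals the exhaustive 256-level scan", {
  cases <- list(c(1000, 60, 10, 1000, 160, 30),
                c(500, 40, 8, 5000, 170, 20),
                c(3000, 90, 25, 800, 200, 12))
  for (p in cases) {
    fit <- make_histfit(p[1], p[2], p[3], p[4], p[5], p[6])
    expect_identical(minimum_error_threshold(fit),
                     oracle_min_error_scan(p[1], p[2], p[3],
                                           p[4], p[5], p[6]))
  }
})

test_that("a minority component pulls the threshold toward its mean", {
  sym <- minimum_error_threshold(make_histfit(1000, 60, 12, 1000, 160, 12))
  skew <- minimum_error_threshold(make_histfit(100, 60, 12, 1000, 160, 12))
  expect_lt(skew, sym)  # air+liquid minority: t moves toward mu1
  skew2 <- minimum_error_threshold(make_histfit(1000, 60, 12, 100, 160, 12))
  expect_gt(skew2, sym)
})

test_that("shifting both means shifts the threshold by the same amount", {
  base <- make_histfit(800, 70, 10, 2000, 150, 18)
  t0 <- minimum_error_threshold(base)
  for (k in c(10, 25)) {
    shifted <- make_histfit(800, 70 + k, 10, 2000, 150 + k, 18)
    expect_lte(abs(minimum_error_threshold(shifted) - (t0 + k)), 1)
  }
})

test_that("segmentation recovers phases and conserves the voxel balance", {
  sp <- synthetic_spec(grid_shape = c(64, 64, 64),
                       pore_population = list(list(shape = "sphere",
                                                   radius = 250, count = 8)),
                       rng_seed = 23)
  tr <- generate_phase_volume(sp, footprint = FALSE)
  # no denoising here: the volume is clean and the median filter would
  # erode curved phase boundaries, which is a filter property, not a
  # segmentation one
  vol <- render_grayscale(tr)
  fit <- fit_two_gaussians(vol)
  thr <- minimum_error_threshold(fit)
  seg <- segment_volume(vol, thr)
  truth_lab <- ifelse(tr$phase == 1L, 1L, 2L)
  agree <- mean(seg$labels == truth_lab)
  expect_gte(agree, 0.999)
  # voxel balance: pore fraction within 0.5 percentage points of truth
  expect_lt(abs(image_porosity(seg) - tr$image_porosity), 0.005)
  # purity: identical on repeat
  expect_identical(segment_volume(vol, thr)$labels, seg$labels)
})

test_that("segment handles extreme thresholds and POM masks", {
  vol <- core_volume(array(sample.int(200, 1000, TRUE), c(10, 10, 10)), 29)
  seg <- segment_volume(vol, 255)
  expect_true(all(seg$labels == 1L))           # everything pore

  pom <- array(FALSE, c(10, 10, 10))
  pom[1:3, 1, 1] <- TRUE
  seg2 <- segment_volume(vol, 100, pom_mask = pom)
  expect_true(all(seg2$labels[pom] == 3L))
  seg3 <- segment_volume(vol, 100)
  expect_setequal(unique(as.vector(seg3$labels)), c(1L, 2L))

  expect_error(segment_volume(vol, 100, pom_mask = array(TRUE, c(2, 2, 2))),
               "mismatch")
  expect_error(segment_volume(vol, 900), "range")
})

test_that("16-bit volumes are rescaled consistently for fit and segment", {
  set.seed(6)
  gray16 <- as.integer(round(c(rnorm(4000, 20000, 1500),
                               rnorm(4000, 45000, 1500))))
  vol <- core_volume(array(sample(gray16), c(20, 20, 20)), 29,
                     bit_depth = 16L)
  fit <- fit_two_gaussians(vol)
  thr <- minimum_error_threshold(fit)
  seg <- segment_volume(vol, thr)
  # pore fraction ~ half (the two populations are equal sized)
  expect_lt(abs(image_porosity(seg) - 0.5), 0.02)
})
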