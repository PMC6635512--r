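test_that("spec validation rejects impossible geometries and parameters", {
  expect_error(synthetic_spec(grid_shape = c(10, 10, 10),
                              pore_population = list(list(shape = "sphere",
                                                          radius = 300,
                                                          count = 1))),
               "grid too small")
  expect_error(synthetic_spec(gray_model = c(mean_solid = 60, sd_solid = 5,
                                             mean_void = 160, sd_void = 5)),
               "darker")
  expect_error(synthetic_spec(slice_spacing = 10), "at least one voxel")
  expect_error(synthetic_spec(pore_population = list(list(shape = "cube",
                                                          radius = 50,
                                                          count = 1))),
               "sphere")
  expect_error(synthetic_spec(enzyme_effects = list(bogus = 1)),
               "pore_classes")
})

test_that("single-sphere porosity equals the voxelized sphere volume", {
  sp <- synthetic_spec(grid_shape = c(64, 64, 64), voxel_size = 29,
                       pore_population = list(list(shape = "sphere",
                                                   radius = 150, count = 1)),
                       rng_seed = 11)
  tr <- generate_phase_volume(sp)
  # brute voxel-in-sphere count for the placed center
  ctr <- tr$shapes[[1]]$center
  g <- as.matrix(expand.grid(1:64, 1:64, 1:64))
  d2 <- (g[, 1] - ctr[1])^2 + (g[, 2] - ctr[2])^2 + (g[, 3] - ctr[3])^2
  n_sphere <- sum(d2 <= (150 / 29)^2)
  expect_identical(sum(tr$phase == 1L), n_sphere)
  expect_equal(tr$image_porosity, n_sphere / 64^3)
  # radius map defined exactly on void voxels, with the generative radius
  expect_identical(which(!is.na(tr$radius_um)), which(tr$phase == 1L))
  expect_true(all(tr$radius_um[tr$phase == 1L] == 150))
})

test_that("empty spec gives zero porosity and an empty footprint", {
  sp <- synthetic_spec(grid_shape = c(24, 24, 24), rng_seed = 1)
  tr <- generate_phase_volume(sp)
  expect_equal(tr$image_porosity, 0)
  expect_false(any(tr$footprint))
  expect_true(all(tr$phase == 0L))
})

test_that("phase counts always partition the grid", {
  sp <- synthetic_spec(grid_shape = c(40, 40, 40), voxel_size = 29,
                       pore_population = list(
                         list(shape = "sphere", radius = 100, count = 5),
                         list(shape = "tube", radius = 60, count = 2)),
                       pom_count = 2, pom_radius = 150, rng_seed = 4)
  tr <- generate_phase_volume(sp, footprint = FALSE)
  expect_identical(sum(tr$phase == 0L) + sum(tr$phase == 1L) +
                     sum(tr$phase == 2L), length(tr$phase))
  expect_identical(sum(tr$phase == 2L) > 0L, TRUE)
})

test_that("two disjoint spheres carry their own size classes", {
  # seed chosen so the 60 and 200 um spheres land apart; disjointness is
  # verified via the voxel count below, not assumed
  sp <- synthetic_spec(grid_shape = c(48, 48, 48), voxel_size = 29,
                       pore_population = list(
                         list(shape = "sphere", radius = 60, count = 1),
                         list(shape = "sphere", radius = 200, count = 1)),
                       rng_seed = 2)
  tr <- generate_phase_volume(sp, footprint = FALSE)
  count_for <- function(r) {
    rr <- floor(r / 29)
    off <- expand.grid(-rr:rr, -rr:rr, -rr:rr)
    sum(off[, 1]^2 + off[, 2]^2 + off[, 3]^2 <= (r / 29)^2)
  }
  expect_identical(sum(tr$phase == 1L), count_for(60) + count_for(200))
  cls <- tr$class_map[tr$phase == 1L]
  expect_setequal(unique(cls), c(2L, 4L))  # p30_150 and p180_plus
  expect_identical(sum(cls == 2L), count_for(60))
  expect_identical(sum(cls == 4L), count_for(200))
})

test_that("generation is deterministic and doubling counts scales porosity", {
  sp <- synthetic_spec(grid_shape = c(40, 40, 40),
                       pore_population = list(list(shape = "sphere",
                                                   radius = 90, count = 6)),
                       rng_seed = 9)
  t1 <- generate_phase_volume(sp)
  t2 <- generate_phase_volume(sp)
  expect_identical(t1$phase, t2$phase)
  expect_identical(t1$radius_um, t2$radius_um)
  expect_identical(t1$footprint, t2$footprint)
  v1 <- render_grayscale(t1)
  v2 <- render_grayscale(t2)
  expect_identical(v1$voxels, v2$voxels)
  z1 <- generate_zymogram(t1, sp, 0)
  z2 <- generate_zymogram(t2, sp, 0)
  expect_identical(z1$pixels, z2$pixels)

  # doubling the sphere count at low density ~doubles porosity
  sp2 <- synthetic_spec(grid_shape = c(40, 40, 40),
                        pore_population = list(list(shape = "sphere",
                                                    radius = 90,
                                                    count = 12)),
                        rng_seed = 9)
  p1 <- generate_phase_volume(sp, footprint = FALSE)$image_porosity
  p2 <- generate_phase_volume(sp2, footprint = FALSE)$image_porosity
  expect_lt(abs(p2 - 2 * p1), 0.01)
})

test_that("noiseless rendering yields exactly two gray values", {
  sp <- synthetic_spec(grid_shape = c(24, 24, 24),
                       pore_population = list(list(shape = "sphere",
                                                   radius = 100, count = 2)),
                       gray_model = c(mean_solid = 160, sd_solid = 0,
                                      mean_void = 60, sd_void = 0),
                       rng_seed = 3)
  tr <- generate_phase_volume(sp, footprint = FALSE)
  vol <- render_grayscale(tr)
  expect_setequal(unique(as.vector(vol$voxels)), c(60L, 160L))
  expect_true(all(vol$voxels[tr$phase == 1L] == 60L))
})

test_that("rendered per-phase gray moments match the model at 128^3", {
  sp <- synthetic_spec(grid_shape = c(128, 128, 128),
                       pore_population = list(list(shape = "sphere",
                                                   radius = 300,
                                                   count = 30)),
                       rng_seed = 21)
  tr <- generate_phase_volume(sp, footprint = FALSE)
  vol <- render_grayscale(tr)
  void_mean <- mean(vol$voxels[tr$phase == 1L])
  solid_mean <- mean(vol$voxels[tr$phase == 0L])
  expect_lt(abs(void_mean - 60), 1)
  expect_lt(abs(solid_mean - 160), 1)
  expect_lt(abs(sd(vol$voxels[tr$phase == 1L]) - 12), 1)
  expect_lt(abs(sd(vol$voxels[tr$phase == 0L]) - 15), 1)
})

test_that("null enzyme effects give pure noise around the baseline", {
  sp <- synthetic_spec(grid_shape = c(80, 80, 40), voxel_size = 25,
                       pore_population = list(list(shape = "sphere",
                                                   radius = 80, count = 20)),
                       activity_baseline = 5, activity_noise_sd = 0.5,
                       rng_seed = 31)
  tr <- generate_phase_volume(sp, footprint = FALSE)
  z <- generate_zymogram(tr, sp, 0)
  expect_lt(abs(mean(z$cell_truth$activity) - 5), 3 * 0.5 / 2)
  expect_true(all(z$cell_truth$effect == 0))
})

test_that("injected class effects raise activity over matching micro-sites", {
  sp <- association_study_spec(rng_seed = 41, grid_shape = c(170, 170, 110))
  tr <- generate_phase_volume(sp, footprint = FALSE)
  z <- generate_zymogram(tr, sp, 0)
  ct <- z$cell_truth
  expect_true(all(c("p30_150", "unresolved_matrix") %in%
                    ct$dominant_class))
  m_pore <- mean(ct$activity_noiseless[ct$dominant_class == "p30_150"])
  m_mat <- mean(ct$activity_noiseless[ct$dominant_class ==
                                        "unresolved_matrix"])
  expect_equal(m_pore - m_mat, 0.7)
})

test_that("fresh-input incubation scenario sharpens the class contrast", {
  base <- association_study_spec(rng_seed = 43,
                                 grid_shape = c(170, 170, 110))
  incub <- base
  incub$enzyme_effects <- list(unresolved_matrix = 0.3, p30_150 = 1.0)
  base$enzyme_effects <- list(unresolved_matrix = 0.3, p30_150 = 0.5)
  tr <- generate_phase_volume(base, footprint = FALSE)
  contrast <- function(spec, inc) {
    z <- generate_zymogram(tr, spec, 0, incubated = inc, seed = 99)
    ct <- z$cell_truth
    mean(ct$activity[ct$dominant_class == "p30_150"]) -
      mean(ct$activity[ct$dominant_class == "unresolved_matrix"])
  }
  expect_gt(contrast(incub, TRUE), contrast(base, FALSE))
})

test_that("cut planes outside the volume are rejected", {
  sp <- synthetic_spec(grid_shape = c(40, 40, 40), rng_seed = 1)
  tr <- generate_phase_volume(sp, footprint = FALSE)
  expect_error(generate_zymogram(tr, sp, slice_index = 5), "outside")
  expect_error(generate_zymogram(tr, sp, slice_index = -1), "outside")
})

test_that("truth footprint sits on solid voxels near qualifying pores only", {
  sp <- synthetic_spec(grid_shape = c(40, 40, 40), voxel_size = 29,
                       pore_population = list(list(shape = "sphere",
                                                   radius = 90, count = 3)),
                       rng_seed = 13)
  tr <- generate_phase_volume(sp)
  expect_true(all(tr$phase[tr$footprint] == 0L))
  expect_gt(sum(tr$footprint), 0)
})
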