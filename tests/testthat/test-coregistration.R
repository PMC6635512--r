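# small perfectly-registered synthetic pair used by several tests:
# voxel_size 25 um so 1-mm cells are exactly 40 voxels / 10 zymogram pixels
make_pair <- function(seed = 1, effects = list(), noise = 0,
                      grid = c(120, 120, 50)) {
  sp <- synthetic_spec(grid_shape = grid, voxel_size = 25,
                       pore_population = list(list(shape = "sphere",
                                                   radius = 75,
                                                   count = 30)),
                       enzyme_effects = effects,
                       activity_noise_sd = noise, pixel_noise_sd = 0,
                       slice_spacing = 1000, rng_seed = seed)
  tr <- generate_phase_volume(sp, footprint = FALSE)
  seg <- as_segmented(tr)
  psm <- local_thickness(seg)
  cm <- classify_pores(psm, seg)
  list(sp = sp, tr = tr, seg = seg, psm = psm, cm = cm)
}

test_that("1-mm cells aggregate exactly 100 zymogram pixels", {
  p <- make_pair()
  z <- generate_zymogram(p$tr, p$sp, 0)
  rec <- build_grid(z, p$seg, p$cm)
  expect_true(all(rec$n_pixels == 100))
  expect_identical(nrow(rec), 9L)   # 3 x 3 cells of 40 voxels in 120
})

test_that("uniform inputs give identical records", {
  p <- make_pair()
  z <- zymogram(matrix(42, 30, 30), mm_per_pixel = 0.1,
                core_id = p$sp$core_id)
  lab <- array(2L, c(120, 120, 50))
  seg <- segmented_volume(lab, voxel_size = 25)
  expect_warning(psm <- local_thickness(seg), "no pore")
  cm <- classify_pores(psm, seg)
  rec <- build_grid(z, seg, cm)
  expect_equal(nrow(unique(rec[, c("ab_unresolved_matrix", "ab_p30_150",
                                   "mean_activity")])), 1L)
})

test_that("cell abundances equal the generator truth exactly", {
  p <- make_pair(seed = 3)
  z <- generate_zymogram(p$tr, p$sp, 0)
  rec <- build_grid(z, p$seg, p$cm)
  cv <- 40L
  for (i in seq_len(nrow(rec))) {
    xs <- ((rec$cell_x[i] - 1) * cv + 1):(rec$cell_x[i] * cv)
    ys <- ((rec$cell_y[i] - 1) * cv + 1):(rec$cell_y[i] * cv)
    cell_cls <- p$tr$class_map[xs, ys, 1:cv]
    expect_equal(rec$ab_p30_150[i], mean(cell_cls == 2L))
    expect_equal(rec$ab_unresolved_matrix[i], mean(cell_cls == 1L))
  }
})

test_that("slice-standardized cell activities are centered", {
  p <- make_pair(seed = 5, effects = list(p30_150 = 1), noise = 0.3)
  z <- generate_zymogram(p$tr, p$sp, 0)
  rec <- build_grid(z, p$seg, p$cm)
  ok <- !is.na(rec$mean_activity_z)
  expect_gt(sum(ok), 2)
  expect_lt(abs(mean(rec$mean_activity_z[ok])), 1e-9)
  expect_lt(abs(sd(rec$mean_activity_z[ok]) - 1), 1e-9)
})

test_that("low-coverage cells lose their activity but keep pore data", {
  p <- make_pair(seed = 2, noise = 0.4)
  z <- generate_zymogram(p$tr, p$sp, 0)
  z$contact_mask[1:12, ] <- FALSE   # kills all of column-1 cells' pixels
  rec <- build_grid(z, p$seg, p$cm, min_coverage = 0.5)
  dead <- rec$cell_x == 1
  expect_true(all(is.na(rec$mean_activity_z[dead])))
  expect_false(any(is.na(rec$ab_p30_150[dead])))
  expect_false(any(is.na(rec$mean_activity_z[!dead])))
})

test_that("off-lattice slice depths are rejected when a lattice is given", {
  p <- make_pair(grid = c(120, 120, 90))
  z <- generate_zymogram(p$tr, p$sp, 1)
  expect_silent(rec <- build_grid(z, p$seg, p$cm,
                                  slice_spacing_um = 1000))
  z$slice_depth_um <- 1500
  expect_error(build_grid(z, p$seg, p$cm, slice_spacing_um = 1000),
               "lattice")
})

test_that("percentile selection keeps exactly the top tail", {
  set.seed(11)
  n <- 100
  rec <- data.frame(core_id = "c1", slice_index = 1,
                    ab_unresolved_matrix = runif(n), ab_p30_150 = runif(n),
                    ab_p150_180 = 0, ab_p180_plus = 0,
                    mean_activity_z = rnorm(n))
  sel <- percentile_select(rec, q = 0.95)
  got <- sel$selected_class
  # per class, exactly floor(0.05 n) records exceed the type-1 quantile;
  # overlaps resolve to the larger class
  top_m <- order(rec$ab_unresolved_matrix, decreasing = TRUE)[1:5]
  top_p <- order(rec$ab_p30_150, decreasing = TRUE)[1:5]
  expect_setequal(which(got == "p30_150"), top_p)
  expect_setequal(which(got == "unresolved_matrix"),
                  setdiff(top_m, top_p))
  # uneven n still yields floor((1-q) n) exceedances
  for (n2 in c(99, 101, 57)) {
    ab <- runif(n2)
    thr <- quantile(ab, 0.95, type = 1)
    expect_identical(sum(ab > thr), as.integer(floor(0.05 * n2)))
  }
})

test_that("multiply-qualifying cells resolve to the larger class", {
  rec <- data.frame(core_id = "c1", slice_index = 1,
                    ab_unresolved_matrix = 0,
                    ab_p30_150 = c(rep(0.1, 20), 0.9),
                    ab_p150_180 = 0,
                    ab_p180_plus = c(rep(0.1, 20), 0.9),
                    mean_activity_z = 0)
  sel <- percentile_select(rec, q = 0.95,
                           classes = c("p30_150", "p180_plus"))
  expect_identical(sel$selected_class[21], "p180_plus")
  expect_true(all(is.na(sel$selected_class[1:20])))
})

test_that("tied abundances select nothing", {
  rec <- data.frame(core_id = "c1", slice_index = 1,
                    ab_unresolved_matrix = 0.5, ab_p30_150 = 0.2,
                    ab_p150_180 = 0, ab_p180_plus = 0,
                    mean_activity_z = rnorm(30))
  sel <- percentile_select(rec)
  expect_true(all(is.na(sel$selected_class)))
  expect_warning(percentile_select(rec[1:5, ]), "unstable")
})

test_that("association tables summarize selected records faithfully", {
  rec <- data.frame(
    core_id = rep(c("a", "b"), each = 6),
    slice_index = rep(1:2, 6),
    selected_class = rep(c("p30_150", "unresolved_matrix", NA), 4),
    mean_activity_z = c(1, 0, 5, 2, -1, 5, 3, 0.5, 5, 2, 0.5, 5),
    system_label = "s")
  tab <- associate(rec)
  expect_identical(sort(as.character(tab$pore_class)),
                   sort(c("p30_150", "unresolved_matrix")))
  p <- tab[tab$pore_class == "p30_150", ]
  expect_equal(p$mean_z, mean(c(1, 2, 3, 2)))
  expect_equal(p$sem, sd(c(1, 2, 3, 2)) / 2)
  expect_identical(p$n_cells, 4L)
  expect_identical(p$n_cores, 2L)
  # permuting record order changes nothing
  tab2 <- associate(rec[sample(nrow(rec)), ])
  expect_equal(tab, tab2)
  # single-record groups report no sem
  one <- associate(rec[c(1, 2), ])
  expect_true(all(is.na(one$sem) == (one$n_cells == 1L)))
})

test_that("the permutation contrast is seeded, null-calibrated and picky", {
  # mirror-symmetric data: observed difference is exactly zero -> p = 1
  rec <- data.frame(core_id = rep(c("a", "b"), each = 8),
                    selected_class = rep(c("p30_150",
                                           "unresolved_matrix"), 8),
                    mean_activity_z = rep(c(1, 1, -1, -1), 4))
  pc <- permutation_contrast(rec, "p30_150", "unresolved_matrix",
                             n_perm = 999, seed = 1)
  expect_equal(pc$estimate, 0)
  expect_equal(pc$p_value, 1)

  pc2 <- permutation_contrast(rec, "p30_150", "unresolved_matrix",
                              n_perm = 999, seed = 1)
  expect_identical(pc$p_value, pc2$p_value)

  expect_error(permutation_contrast(rec, "p30_150", "p180_plus", seed = 1),
               "absent")
  expect_error(permutation_contrast(rec, "p30_150", "unresolved_matrix",
                                    n_perm = 10), ">= 999")
})

test_that("a strong injected effect is detected by the permutation test", {
  set.seed(21)
  rec <- data.frame(
    core_id = rep(c("a", "b", "c"), each = 40),
    selected_class = rep(c("p30_150", "unresolved_matrix"), 60),
    mean_activity_z = rnorm(120, 0, 1))
  shift <- rec$selected_class == "p30_150"
  rec$mean_activity_z[shift] <- rec$mean_activity_z[shift] + 1
  pc <- permutation_contrast(rec, "p30_150", "unresolved_matrix",
                             n_perm = 1999, seed = 3)
  expect_lt(pc$p_value, 0.01)
  expect_gt(pc$estimate, 0.5)
})
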