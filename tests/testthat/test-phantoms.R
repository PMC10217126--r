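# Phantom generator: geometric sampling, class targeting, tumor placement,
# dielectric ranges, determinism.

test_that("grid spec reproduces the reference pixel size and validates input", {
  g <- grid_spec(15, 108)
  expect_equal(g$pixel_size, 15 / 108, tolerance = 1e-12)
  expect_equal(g$pixel_size, 0.1389, tolerance = 1e-3)
  expect_length(g$x, 108)
  # pixel centres are symmetric about the origin
  expect_equal(g$x, -rev(g$x))
  expect_error(grid_spec(15, 4), class = "mwtomo_bad_grid")
})

test_that("outer-shape sampling covers its configured ranges uniformly", {
  cfg <- small_config()
  draws <- with_seed_wrap(1, replicate(2000, {
    e <- sample_outer_shape(cfg)
    c(2 * e$semi_a, 2 * e$semi_b, e$phi)
  }))
  axes <- c(draws[1, ], draws[2, ])
  expect_true(all(axes >= 6.5 & axes <= 12))
  expect_true(all(draws[3, ] >= 0 & draws[3, ] <= 2 * pi))
  # Kolmogorov-Smirnov against the uniform law on each margin
  expect_gt(stats::ks.test(axes, "punif", 6.5, 12)$p.value, 0.01)
  expect_gt(stats::ks.test(draws[3, ], "punif", 0, 2 * pi)$p.value, 0.01)
})

test_that("degenerate axis/orientation ranges give the requested circle", {
  cfg <- small_config()
  cfg$ellipse_axis_range <- c(8, 8)
  cfg$orientation_range <- c(0, 0)
  e <- sample_outer_shape(cfg, seed = 5)
  expect_equal(e$semi_a, 4)
  expect_equal(e$semi_b, 4)
  expect_equal(e$phi, 0)
  expect_equal(c(e$cx, e$cy), c(0, 0))
})

test_that("an impossible axis range is rejected at config time", {
  expect_error(generator_config(grid = small_grid(),
                                ellipse_axis_range = c(16, 20)),
               class = "mwtomo_bad_config")
})

test_that("outer-shape sampling is deterministic under a fixed seed", {
  cfg <- small_config()
  expect_identical(sample_outer_shape(cfg, seed = 11),
                   sample_outer_shape(cfg, seed = 11))
})

test_that("tissue maps hit the target class bin and mask the exterior", {
  cfg <- small_config()
  for (cl in c("A", "B", "C", "D")) {
    e <- sample_outer_shape(cfg, seed = 20 + match(cl, LETTERS))
    lab <- generate_tissue_map(e, cl, cfg, seed = 30 + match(cl, LETTERS))
    interior <- lab != 0L
    fr <- sum(lab == 3L) / sum(interior)
    bin <- cfg$class_bins[[cl]]
    expect_gte(fr, bin[1])
    if (cl == "D") expect_lte(fr, bin[2]) else expect_lt(fr, bin[2])
    # every interior pixel is one of the three healthy tissues
    expect_true(all(lab[interior] %in% 1:3))
    # exterior pixels carry the background label
    co <- mwtomo:::grid_coords(cfg$grid)
    outside <- mwtomo:::elliptical_radius(e, co$x, co$y) > 1
    expect_true(all(lab[outside] == 0L))
  }
})

test_that("density-class assignment follows the bin convention", {
  cfg <- small_config()
  fake_map <- function(frac) {
    # 1000 interior pixels, `frac` of them fibro-glandular
    lab <- matrix(0L, 40, 40)
    lab[1:1000] <- 1L
    lab[seq_len(round(1000 * frac))] <- 3L
    lab
  }
  expect_equal(assign_density_class(fake_map(0.25), cfg), "B")
  expect_equal(assign_density_class(fake_map(0.05), cfg), "A")
  expect_equal(assign_density_class(fake_map(0.199), cfg), "A")
  expect_equal(assign_density_class(fake_map(0.20), cfg), "B")
  expect_equal(assign_density_class(fake_map(0.65), cfg), "D")
  expect_error(assign_density_class(fake_map(0.80), cfg),
               class = "mwtomo_class_out_of_range")
  expect_error(assign_density_class(fake_map(0.02), cfg),
               class = "mwtomo_class_out_of_range")
})

test_that("tumor rasterisation realises the drawn area to within one pixel", {
  # target 0.2 cm^2 on the 108-grid: 0.2 / 0.0193 ~ 10.4 pixels
  cfg <- small_config(108)
  cfg$tumor_area_range <- c(0.2, 0.2)
  cfg$tumor_count_probs <- c(1, 0, 0)
  e <- sample_outer_shape(cfg, seed = 1)
  lab <- generate_tissue_map(e, "C", cfg, seed = 2)
  ins <- insert_tumors(lab, cfg, pathological = TRUE, seed = 3)
  dA <- cfg$grid$pixel_size^2
  n_px <- sum(ins$label_map == 4L)
  expect_true(n_px %in% c(10L, 11L))
  expect_lte(abs(n_px * dA - 0.2), dA)
  expect_equal(ins$tumors[[1]]$n_pixels, n_px)
})

test_that("healthy profiles pass through tumor insertion unchanged", {
  cfg <- small_config()
  e <- sample_outer_shape(cfg, seed = 1)
  lab <- generate_tissue_map(e, "B", cfg, seed = 2)
  ins <- insert_tumors(lab, cfg, pathological = FALSE, seed = 3)
  expect_identical(ins$label_map, lab)
  expect_length(ins$tumors, 0)
})

test_that("tumors are connected and strictly inside fibro-glandular tissue", {
  cfg <- small_config()
  for (s in 1:25) {
    e <- sample_outer_shape(cfg, seed = s)
    lab <- generate_tissue_map(e, sample(c("B", "C", "D"), 1), cfg, seed = s + 100)
    ins <- insert_tumors(lab, cfg, pathological = TRUE, seed = s + 200)
    tumor <- ins$label_map == 4L
    expect_gt(sum(tumor), 0)
    # tumor pixels were fibro-glandular before insertion
    expect_true(all(lab[tumor] == 3L))
    # non-tumor pixels are untouched
    expect_identical(ins$label_map[!tumor], lab[!tumor])
  }
})

test_that("dielectric draws respect every tissue's interval and the background", {
  cfg <- small_config()
  tt <- tissue_table()
  # all-background map
  maps0 <- sample_dielectric_maps(matrix(0L, 20, 20), cfg, seed = 1)
  expect_true(all(maps0$eps_map == 15))
  expect_true(all(maps0$sigma_map == 0))
  # a map holding every label
  lab <- matrix(0L, 40, 40)
  lab[2:12, ] <- 1L; lab[13:22, ] <- 2L; lab[23:32, ] <- 3L; lab[33:39, ] <- 4L
  maps <- sample_dielectric_maps(lab, cfg, seed = 2)
  for (k in seq_len(nrow(tt))) {
    m <- lab == tt$label[k]
    expect_true(all(maps$eps_map[m] >= tt$eps_min[k] &
                    maps$eps_map[m] <= tt$eps_max[k]), info = tt$tissue[k])
    expect_true(all(maps$sigma_map[m] >= tt$sigma_min[k] &
                    maps$sigma_map[m] <= tt$sigma_max[k]), info = tt$tissue[k])
  }
  expect_error(sample_dielectric_maps(matrix(9L, 5, 5), cfg),
               class = "mwtomo_bad_input")
})

test_that("tumor areas drawn over many phantoms are uniform on their range", {
  cfg <- small_config()
  cfg$tumor_count_probs <- c(1, 0, 0)
  areas <- with_seed_wrap(7, replicate(400, {
    runif(1, cfg$tumor_area_range[1], cfg$tumor_area_range[2])
  }))
  expect_gt(stats::ks.test(areas, "punif", 0.2, 9)$p.value, 0.01)
})

test_that("generate_phantom composes all invariants and is reproducible", {
  cfg <- small_config()
  ph <- generate_phantom(cfg, "B", pathological = TRUE, seed = 77)
  expect_s3_class(ph, "mwt_phantom")
  expect_equal(ph$density_class, "B")
  expect_true(ph$is_pathological)
  expect_gte(length(ph$tumors), 1)
  expect_gt(sum(ph$label_map == 4L), 0)
  # healthy twin has zero tumor pixels
  ph0 <- generate_phantom(cfg, "A", pathological = FALSE, seed = 78)
  expect_equal(sum(ph0$label_map == 4L), 0)
  expect_length(ph0$tumors, 0)
  # bit-identical regeneration from the same seed
  expect_identical(generate_phantom(cfg, "B", TRUE, seed = 77), ph)
})

test_that("dataset generation balances cells and stratifies the split", {
  cfg <- small_config(36)
  ds <- generate_dataset(cfg, n_per_cell = 25, seed = 3)
  man <- ds$manifest
  expect_equal(nrow(man), 200)
  expect_equal(unname(table(man$split)[c("train", "val", "test")]),
               c(160L, 20L, 20L), ignore_attr = TRUE)
  # every (class, pathology) cell holds exactly 25 profiles
  expect_true(all(table(man$class, man$pathological) == 25))
  # per-cell train counts equal 20 (80% of 25)
  tr <- man[man$split == "train", ]
  expect_true(all(table(tr$class, tr$pathological) == 20))
  expect_error(generate_dataset(cfg, n_per_cell = 0), class = "mwtomo_bad_config")
})

test_that("dataset generation is reproducible from the master seed", {
  cfg <- small_config(36)
  d1 <- generate_dataset(cfg, n_per_cell = 2, seed = 9)
  d2 <- generate_dataset(cfg, n_per_cell = 2, seed = 9)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(d1$phantoms[[5]]$eps_map, d2$phantoms[[5]]$eps_map)
})
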