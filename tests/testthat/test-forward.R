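# Forward solver: incident field, Green operator (FFT vs dense), state
# equation solvers, scattered-field evaluation, scattering-matrix assembly.

test_that("incident field matches an independent Hankel evaluation to 1e-12", {
  # reference values computed with an independent special-function library
  ref <- rbind(
    c(0.0, 0.0, -0.029626538068758774, 0.056584526645779676),
    c(1.25, -2.5, -0.06350724233787443, 0.020033549886454675),
    c(-3.3, 4.1, 0.026855160360675236, -0.04869380982730586),
    c(5.0, 5.0, 0.007800377815048876, -0.07498819646668986),
    c(-6.2, -0.7, -0.05130506772109032, -0.007587346305661293),
    c(2.0, 0.3, -0.0602021957550363, -0.03558402734623188),
    c(-1.1, 6.3, 0.058042627843437965, -0.00044846013477361227),
    c(7.0, -7.0, 0.007800377815048876, -0.07498819646668986),
    c(0.05, 0.05, -0.03196261078739451, 0.055451975169180275),
    c(-4.8, 2.9, -0.024646141249777376, -0.0476016927933252))
  geom <- ref_geometry()
  k_b <- geom$k_b
  expect_equal(k_b, 0.8117172866250582, tolerance = 1e-12)
  for (i in seq_len(nrow(ref))) {
    d <- sqrt((ref[i, 1] - 12)^2 + ref[i, 2]^2)
    v <- (-1i / 4) * mwtomo:::hankel2(k_b * d)
    expect_equal(Re(v), ref[i, 3], tolerance = 1e-12)
    expect_equal(Im(v), ref[i, 4], tolerance = 1e-12)
  }
})

test_that("incident field decays cylindrically and is radially symmetric", {
  g <- small_grid()
  geom <- ref_geometry()
  Ei <- incident_field(c(12, 0), g, geom$k_b)
  co <- mwtomo:::grid_coords(g)
  d <- sqrt((co$x - 12)^2 + co$y^2)
  # 1/sqrt(r) spreading: |Ei| * sqrt(d) approximately constant far away
  far <- d > 10
  spread <- abs(Ei[far]) * sqrt(d[far])
  expect_lt(stats::sd(spread) / mean(spread), 0.02)
  # equidistant points get equal field values (mirror symmetry about y = 0)
  i1 <- which(abs(co$y - co$y[20, 20]) < 1e-9 & abs(co$x - co$x[20, 20]) < 1e-9)
  mirror <- which(abs(co$y + co$y[20, 20]) < 1e-9 & abs(co$x - co$x[20, 20]) < 1e-9)
  expect_equal(Ei[i1], Ei[mirror], tolerance = 1e-13)
  expect_error(incident_field(c(12, 0), g, -1), class = "mwtomo_bad_input")
})

test_that("FFT operator application equals the dense MoM matrix on small grids", {
  geom <- ref_geometry()
  for (n in c(8L, 12L, 16L)) {
    g <- grid_spec(15, n)
    op <- green_operator(g, geom$k_b)
    Gd <- green_matrix_dense(g, geom$k_b)
    set.seed(n)
    w <- matrix(complex(real = rnorm(n^2), imaginary = rnorm(n^2)), n, n)
    via_fft <- apply_green_operator(op, w)
    via_dense <- matrix(Gd %*% as.vector(w), n, n)
    expect_lt(max(abs(via_fft - via_dense)), 1e-10)
    # kernel symmetry g(r, r') = g(r', r)
    expect_lt(max(abs(Gd - t(Gd))), 1e-14)
  }
  # linearity: zero in, zero out
  g <- grid_spec(15, 8)
  op <- green_operator(g, geom$k_b)
  expect_true(all(apply_green_operator(op, matrix(0i, 8, 8)) == 0))
})

test_that("zero contrast returns the incident field and zero scattered field", {
  geom <- ref_geometry()
  ph <- background_phantom(36)
  ctr <- contrast_map(ph, geom)
  Ei <- incident_field(c(12, 0), ph$grid, geom$k_b)
  fs <- solve_total_field(ctr, Ei)
  expect_identical(fs$Et, Ei)
  expect_equal(fs$iterations, 0L)
  Es <- scattered_field_at_receivers(ctr, fs$Et, geom$x, geom$y)
  expect_true(all(Es == 0))
  S <- assemble_scattering_matrix(ph, geom)$S
  # null scatterer: |S| below 1e-12 of the incident-field scale (~0.05)
  expect_lt(max(abs(S)), 1e-12 * 0.05)
})

test_that("a single-pixel scatterer radiates the point-source Born pattern", {
  n <- 36L
  g <- grid_spec(15, n)
  geom <- ref_geometry()
  chi <- matrix(0i, n, n)
  chi[18, 20] <- 1e-6 + 0i   # weak: Born limit exact to O(chi^2)
  ctr <- structure(list(chi = chi, k_b = geom$k_b, grid = g), class = "mwt_contrast")
  Ei <- incident_field(c(12, 0), g, geom$k_b)
  fs <- solve_total_field(ctr, Ei)
  Es <- scattered_field_at_receivers(ctr, fs$Et, geom$x, geom$y)
  # closed form: cell-integrated Green coefficient x chi x Et at the pixel
  co <- mwtomo:::grid_coords(g)
  a <- g$pixel_size / sqrt(pi)
  d <- sqrt((geom$x - co$x[18, 20])^2 + (geom$y - co$y[18, 20])^2)
  pred <- -(1i * pi * geom$k_b * a / 2) * besselJ(geom$k_b * a, 1) *
    mwtomo:::hankel2(geom$k_b * d) * chi[18, 20] * fs$Et[18, 20]
  expect_equal(Es, pred, tolerance = 1e-10)
})

test_that("CGNR and direct solves agree and satisfy the state equation", {
  geom <- ref_geometry()
  ph <- generate_phantom(small_config(), "B", TRUE, seed = 5)
  ctr <- contrast_map(ph, geom)
  op <- green_operator(ph$grid, geom$k_b)
  Ei <- incident_field(c(12, 0), ph$grid, geom$k_b)
  fd <- solve_total_field(ctr, Ei, method = "direct", op = op)
  fc <- solve_total_field(ctr, Ei, method = "cgnr", tol = 1e-8, op = op)
  expect_lt(sqrt(sum(abs(fd$Et - fc$Et)^2) / sum(abs(fd$Et)^2)), 1e-6)
  expect_lt(fd$residual, 1e-12)
  expect_lte(fc$residual, 1e-8)
  # non-convergence raises
  expect_error(solve_total_field(ctr, Ei, method = "cgnr", tol = 1e-12,
                                 max_iter = 3L, op = op),
               class = "mwtomo_nonconvergence")
})

test_that("Born linearisation error scales quadratically with contrast", {
  n <- 36L
  geom <- ref_geometry()
  ph <- cylinder_phantom(n, radius = 3, eps = 20, sigma = 0.2)
  ctr0 <- contrast_map(ph, geom)
  op <- green_operator(ph$grid, geom$k_b)
  Ei <- incident_field(c(12, 0), ph$grid, geom$k_b)
  rel_err <- sapply(c(1e-1, 1e-2, 1e-3), function(s) {
    ctr <- ctr0; ctr$chi <- ctr0$chi * s
    full <- solve_total_field(ctr, Ei, method = "direct", op = op)$Et
    born <- Ei + apply_green_operator(op, ctr$chi * Ei)
    sqrt(sum(abs(full - born)^2) / sum(abs(full)^2))
  })
  ratios <- rel_err[-3] / rel_err[-1]
  # halving the log-contrast decade should divide the error by ~100
  expect_gt(min(ratios), 30)
  expect_lt(max(ratios), 300)
})

test_that("scattering matrices are reciprocal and support both precisions", {
  geom <- ref_geometry()
  cfg <- small_config()
  op <- forward_operator(cfg$grid, geom)
  ph <- generate_phantom(cfg, "C", TRUE, seed = 8)
  s_dbl <- assemble_scattering_matrix(ph, geom, op = op, check_residual = FALSE)
  s_sgl <- assemble_scattering_matrix(ph, geom, op = op, precision = "single",
                                      check_residual = FALSE)
  rel <- function(S) sqrt(sum(abs(S - t(S))^2) / sum(abs(S)^2))
  expect_lt(rel(s_dbl$S), 1e-10)
  expect_lt(rel(s_sgl$S), 1e-5)
  expect_lt(sqrt(sum(abs(s_dbl$S - s_sgl$S)^2) / sum(abs(s_dbl$S)^2)), 1e-5)
  # the fast path agrees with the residual-checked path
  s_full <- assemble_scattering_matrix(ph, geom, op = op)
  expect_lt(sqrt(sum(abs(s_full$S - s_dbl$S)^2) / sum(abs(s_full$S)^2)), 1e-12)
  expect_lt(s_full$residual, 1e-10)
})

test_that("receivers inside the contrast support are rejected", {
  geom <- ref_geometry()
  ph <- cylinder_phantom(36)
  ctr <- contrast_map(ph, geom)
  Ei <- incident_field(c(12, 0), ph$grid, geom$k_b)
  fs <- solve_total_field(ctr, Ei)
  expect_error(scattered_field_at_receivers(ctr, fs$Et, 0.5, 0.5),
               class = "mwtomo_bad_input")
})
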