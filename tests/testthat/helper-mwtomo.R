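# shared fixtures: small grids and geometries keep the suite fast

# cross-file carrier for the miniature end-to-end study
.mwtomo_test_env <- new.env(parent = emptyenv())

small_grid <- function(n = 54) grid_spec(15, n)

small_config <- function(n = 54) generator_config(grid = small_grid(n))

ref_geometry <- function() acquisition_geometry(30L, 12, 1e9, 15, 0)

# homogeneous circular cylinder phantom (radius cm) centred at the origin
cylinder_phantom <- function(n, radius = 3, eps = 20, sigma = 0.2) {
  g <- grid_spec(15, n)
  co <- mwtomo:::grid_coords(g)
  inside <- sqrt(co$x^2 + co$y^2) <= radius
  eps_map <- matrix(15, n, n); sigma_map <- matrix(0, n, n)
  lab <- matrix(0L, n, n)
  eps_map[inside] <- eps; sigma_map[inside] <- sigma; lab[inside] <- 3L
  structure(list(eps_map = eps_map, sigma_map = sigma_map, label_map = lab,
                 density_class = "C", is_pathological = FALSE, tumors = list(),
                 grid = g, rng_seed = 0L),
            class = "mwt_phantom")
}

# background-only phantom (zero contrast everywhere)
background_phantom <- function(n) {
  g <- grid_spec(15, n)
  structure(list(eps_map = matrix(15, n, n), sigma_map = matrix(0, n, n),
                 label_map = matrix(0L, n, n), density_class = "A",
                 is_pathological = FALSE, tumors = list(), grid = g,
                 rng_seed = 0L),
            class = "mwt_phantom")
}

with_seed_wrap <- function(seed, expr) { set.seed(seed); expr }

# quick random scattering-matrix stand-in for metric/noise/encoding tests
random_smatrix <- function(n = 30, seed = 1) {
  set.seed(seed)
  matrix(complex(real = rnorm(n * n), imaginary = rnorm(n * n)), n, n)
}
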