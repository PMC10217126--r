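# Method-of-Moments forward solver for the 2D TM volume integral equations
#
#   data  equation:  Es = Ae(chi, Et)    (field at the receivers)
#   state equation:  Et = Ei + Ai(chi, Et)   (field on the imaging grid)
#
# Discretisation: pulse basis / point matching on the square pixel grid,
# with each cell replaced by the equal-area circle (Richmond's scheme).
# Under the exp(+j omega t) convention the 2D outgoing Green's function is
# g(r, r') = (-j/4) H0^(2)(k_b |r - r'|), and the discrete internal
# operator has entries (including the k_b^2 factor)
#   C[m, n] = -(j pi k a / 2) J1(k a) H0^(2)(k rho_mn)     (m != n)
#   C[m, m] = -(j pi k a / 2) H1^(2)(k a) - 1              (self cell)
# with a = pixel_size / sqrt(pi) the equal-area radius.

# H_n^(2) for real argument
hankel2 <- function(x, nu = 0) besselJ(x, nu) - 1i * besselY(x, nu)

#' Incident field of a line source
#'
#' Unit-strength 2D line source at `src` (cm): `Ei(r) = (-j/4) H0^(2)(k_b
#' |r - src|)` under the `exp(+j omega t)` convention.
#'
#' @param src length-2 numeric (x, y) in cm.
#' @param grid an [grid_spec()].
#' @param k_b background wavenumber (1/cm), > 0.
#' @return complex matrix over the grid.
#' @export
incident_field <- function(src, grid, k_b) {
  if (k_b <= 0) abort("`k_b` must be positive.", class = "mwtomo_bad_input")
  co <- grid_coords(grid)
  d <- sqrt((co$x - src[1])^2 + (co$y - src[2])^2)
  if (any(d < 1e-9))
    abort("source coincides with a grid sample point.", class = "mwtomo_bad_input")
  (-1i / 4) * hankel2(k_b * d)
}

# Toeplitz table of internal-operator coefficients: entry (di+1, dj+1)
# holds C for pixel offset (di, dj); (1,1) is the self term.
green_coeff_table <- function(grid, k_b) {
  n <- grid$n_pixels
  a <- grid$pixel_size / sqrt(pi)
  d <- grid$pixel_size * sqrt(outer((0:(n - 1))^2, (0:(n - 1))^2, "+"))
  tab <- matrix(0i, n, n)
  tab[-1] <- -(1i * pi * k_b * a / 2) * besselJ(k_b * a, 1) * hankel2(k_b * d[-1])
  tab[1, 1] <- -(1i * pi * k_b * a / 2) * (besselJ(k_b * a, 1) - 1i * besselY(k_b * a, 1)) - 1
  tab
}

#' FFT-ready internal radiation operator
#'
#' Precomputes the block-Toeplitz kernel of the discrete internal operator
#' `Ai` on a uniform square grid and its FFT on the circulant embedding, so
#' one application to a contrast-source array costs one zero-padded 2D FFT
#' convolution pair.
#'
#' @param grid an [grid_spec()].
#' @param k_b background wavenumber (1/cm).
#' @return an `mwt_green_operator` with the coefficient table, its embedded
#'   FFT, and grid metadata.
#' @export
green_operator <- function(grid, k_b) {
  n <- grid$n_pixels
  tab <- green_coeff_table(grid, k_b)
  m <- 2L * n
  emb <- matrix(0i, m, m)
  idx <- c(1:n, (m - n + 2):m)     # offsets 0..n-1 then -(n-1)..-1
  src <- c(1:n, n:2)               # |offset| + 1
  emb[idx, idx] <- tab[src, src]
  structure(list(grid = grid, k_b = k_b, table = tab, fft_kernel = stats::fft(emb)),
            class = "mwt_green_operator")
}

#' Apply the internal radiation operator
#'
#' Computes `Ai w` for a contrast-source array `w` (complex `n x n` matrix,
#' or `n x n x T` array for a batch) via zero-padded FFT convolution.
#'
#' @param op an [green_operator()].
#' @param w complex matrix or 3D array.
#' @return same shape as `w`.
#' @export
apply_green_operator <- function(op, w) {
  n <- op$grid$n_pixels
  m <- 2L * n
  one <- function(wm) {
    wp <- matrix(0i, m, m)
    wp[1:n, 1:n] <- wm
    out <- stats::fft(op$fft_kernel * stats::fft(wp), inverse = TRUE) / m^2
    out[1:n, 1:n]
  }
  if (length(dim(w)) == 3L) {
    out <- w
    for (t in seq_len(dim(w)[3])) out[, , t] <- one(w[, , t])
    out
  } else one(w)
}

#' Dense matrix of the internal operator (oracle)
#'
#' Assembles the full `n^2 x n^2` discrete internal operator. Intended for
#' small grids as the brute-force cross-check of the FFT application.
#'
#' @param grid an [grid_spec()] (square, uniform).
#' @param k_b background wavenumber (1/cm).
#' @return complex matrix, pixels in column-major order.
#' @export
green_matrix_dense <- function(grid, k_b) {
  n <- grid$n_pixels
  tab <- green_coeff_table(grid, k_b)
  ii <- rep(seq_len(n), times = n); jj <- rep(seq_len(n), each = n)
  di <- abs(outer(ii, ii, "-")) + 1L
  dj <- abs(outer(jj, jj, "-")) + 1L
  matrix(tab[cbind(as.vector(di), as.vector(dj))], n * n, n * n)
}

# operator coefficients from external points (receivers) to grid pixels:
# B[m, p] = -(j pi k a / 2) J1(k a) H0^(2)(k |r_m - r_p|)
receiver_coeff_matrix <- function(points_x, points_y, grid, k_b) {
  a <- grid$pixel_size / sqrt(pi)
  co <- grid_coords(grid)
  px <- as.vector(co$x); py <- as.vector(co$y)
  d <- sqrt(outer(points_x, px, "-")^2 + outer(points_y, py, "-")^2)
  -(1i * pi * k_b * a / 2) * besselJ(k_b * a, 1) * hankel2(k_b * d)
}

#' Solve the state equation for the total field
#'
#' Solves `(I - Ai diag(chi)) Et = Ei` for one or several incident fields.
#' Two equivalent paths are provided: `"cgnr"` iterates conjugate gradients
#' on the normal equations of the FFT-applied operator (the operator is
#' non-Hermitian, so plain CG does not apply), stopping when the relative
#' state-equation residual drops below `tol`; `"direct"` performs an exact
#' LU solve of the same discrete system restricted to the support of `chi`
#' (the state equation closes on the support because `chi = 0` elsewhere),
#' which is faster for desk-scale grids.
#'
#' @param contrast an [contrast_map()].
#' @param Ei complex `n x n` matrix or `n x n x T` array of incident fields.
#' @param method `"direct"` or `"cgnr"`.
#' @param tol relative residual tolerance (cgnr).
#' @param max_iter iteration cap (cgnr).
#' @param op optional precomputed [green_operator()].
#' @param precision `"double"` (default) or `"single"`: LU factorisation
#'   precision of the direct path (single is ~2x faster; adequate when the
#'   result is noise-corrupted or feeds the single-precision detector).
#' @return an `mwt_field_state`: `Et` (same shape as `Ei`), `Ei`,
#'   `residual` (max over transmitters of the state-equation relative
#'   residual), `iterations`, `method`.
#' @export
solve_total_field <- function(contrast, Ei, method = c("direct", "cgnr"),
                              tol = 1e-6, max_iter = 2000L, op = NULL,
                              precision = c("double", "single")) {
  method <- match.arg(method)
  precision <- match.arg(precision)
  if (tol <= 0) abort("`tol` must be positive.", class = "mwtomo_bad_input")
  chi <- contrast$chi
  n <- contrast$grid$n_pixels
  single <- length(dim(Ei)) != 3L
  E <- if (single) array(Ei, c(n, n, 1L)) else Ei
  nt <- dim(E)[3]
  if (is.null(op)) op <- green_operator(contrast$grid, contrast$k_b)

  Emat <- matrix(E, n * n, nt)          # pixels x transmitters
  chiv <- as.vector(chi)
  supp <- which(chiv != 0)

  if (length(supp) == 0L) {
    return(structure(list(Et = Ei, Ei = Ei, residual = 0, iterations = 0L,
                          method = method), class = "mwt_field_state"))
  }

  apply_C <- function(wmat) { # dense pixel x T matrix -> operator applied per column
    w <- array(0i, c(n, n, ncol(wmat)))
    w[] <- wmat
    matrix(apply_green_operator(op, w), n * n, ncol(wmat))
  }

  if (method == "direct") {
    Et_s <- mom_support_solve(op$table, (supp - 1L) %% n, (supp - 1L) %/% n,
                              chiv[supp], Emat[supp, , drop = FALSE],
                              use_float = (precision == "single"))
    W <- matrix(0i, n * n, nt)
    W[supp, ] <- Et_s * chiv[supp]
    Etmat <- Emat + apply_C(W)
    Etmat[supp, ] <- Et_s  # exact on the support; elsewhere via radiation
    res <- state_residual(Etmat, Emat, chiv, apply_C)
    iters <- 0L
  } else {
    Aop <- function(x) x - apply_C(x * chiv)
    Ahop <- function(y) y - Conj(chiv) * Conj(apply_C(Conj(y)))
    b <- Emat
    x <- b                      # Et = Ei start (zero-contrast solution)
    r <- b - Aop(x)
    z <- Ahop(r)
    p <- z
    bnorm <- sqrt(colSums(abs(b)^2))
    znorm2 <- colSums(abs(z)^2)
    iters <- 0L
    repeat {
      rnorm <- sqrt(colSums(abs(r)^2))
      if (all(rnorm / bnorm <= tol)) break
      if (iters >= max_iter)
        abort(sprintf("CGNR did not converge in %d iterations (max relative residual %.3g).",
                      max_iter, max(rnorm / bnorm)), class = "mwtomo_nonconvergence")
      w <- Aop(p)
      alpha <- znorm2 / colSums(abs(w)^2)
      x <- x + sweep(p, 2, alpha, "*")
      r <- r - sweep(w, 2, alpha, "*")
      z <- Ahop(r)
      znew <- colSums(abs(z)^2)
      beta <- znew / znorm2
      znorm2 <- znew
      p <- z + sweep(p, 2, beta, "*")
      iters <- iters + 1L
    }
    Etmat <- x
    res <- max(sqrt(colSums(abs(b - Aop(x))^2)) / bnorm)
  }

  Et <- array(Etmat, c(n, n, nt))
  if (single) Et <- Et[, , 1]
  structure(list(Et = Et, Ei = Ei, residual = res, iterations = iters,
                 method = method), class = "mwt_field_state")
}

state_residual <- function(Etmat, Eimat, chiv, apply_C) {
  r <- Etmat - Eimat - apply_C(Etmat * chiv)
  max(sqrt(colSums(abs(r)^2)) / sqrt(colSums(abs(Eimat)^2)))
}

#' Scattered field at external receivers
#'
#' Evaluates the data equation `Es(r_m) = Ae(chi, Et)` at external points:
#' the radiation of the contrast sources `chi * Et` through the same
#' cell-integrated Green's function used on the grid.
#'
#' @param contrast an [contrast_map()].
#' @param Et total field (`n x n` matrix or `n x n x T` array).
#' @param rx,ry receiver coordinates (cm), outside the support of `chi`.
#' @param B optional precomputed [receiver_coeff_matrix] for these receivers.
#' @return complex vector (one transmitter) or `T x n_rx` matrix.
#' @export
scattered_field_at_receivers <- function(contrast, Et, rx, ry, B = NULL) {
  grid <- contrast$grid
  chiv <- as.vector(contrast$chi)
  supp <- which(chiv != 0)
  if (length(supp)) {
    co <- grid_coords(grid)
    px <- as.vector(co$x)[supp]; py <- as.vector(co$y)[supp]
    dmin <- sqrt(min(outer(rx, px, "-")^2 + outer(ry, py, "-")^2))
    if (dmin < grid$pixel_size / 2)
      abort("a receiver lies inside the contrast support.", class = "mwtomo_bad_input")
  }
  if (is.null(B)) B <- receiver_coeff_matrix(rx, ry, grid, contrast$k_b)
  n <- grid$n_pixels
  single <- length(dim(Et)) != 3L
  E <- matrix(Et, n * n, if (single) 1L else dim(Et)[3])
  W <- E * chiv
  Es <- t(B %*% W)    # T x n_rx
  if (single) as.vector(Es) else Es
}

#' Assemble the multistatic scattering matrix of a phantom
#'
#' For each of the `n_antennas` transmitters, solves the state equation for
#' the total field and evaluates the scattered field at all receivers
#' (the transmitting antenna included). Rows index transmitters.
#'
#' @param phantom an `mwt_phantom`.
#' @param geometry an [acquisition_geometry()].
#' @param tol solver tolerance.
#' @param solver `"direct"` or `"cgnr"` (see [solve_total_field()]).
#' @param op optional precomputed [forward_operator()] bundle (reused across
#'   phantoms sharing a grid and geometry).
#' @param precision LU precision of the direct path (see
#'   [solve_total_field()]).
#' @param check_residual verify the state-equation residual on the full grid
#'   (requires the full-grid total field; disable for bulk simulation).
#' @return an `mwt_scattering` object: `S` (complex `n x n`, `S[t, r]`),
#'   `geometry`, `residual`, `iterations`, `solver`.
#' @export
assemble_scattering_matrix <- function(phantom, geometry, tol = 1e-6,
                                       solver = c("direct", "cgnr"), op = NULL,
                                       precision = "double",
                                       check_residual = TRUE) {
  solver <- match.arg(solver)
  if (is.null(op)) op <- forward_operator(phantom$grid, geometry)
  ctr <- contrast_map(phantom, geometry)
  n <- phantom$grid$n_pixels
  if (solver == "direct" && !check_residual) {
    # bulk path: the scattering matrix needs the total field (and hence the
    # contrast sources) on the support of chi only
    chiv <- as.vector(ctr$chi)
    supp <- which(chiv != 0)
    if (length(supp) == 0L) {
      S <- matrix(0i, geometry$n_antennas, geometry$n_antennas)
    } else {
      Et_s <- mom_support_solve(op$green$table, (supp - 1L) %% n, (supp - 1L) %/% n,
                                chiv[supp],
                                matrix(op$Ei, n * n, geometry$n_antennas)[supp, , drop = FALSE],
                                use_float = (precision == "single"))
      S <- t(op$B[, supp, drop = FALSE] %*% (Et_s * chiv[supp]))
    }
    return(structure(list(S = S, geometry = geometry, residual = NA_real_,
                          iterations = 0L, solver = solver),
                     class = "mwt_scattering"))
  }
  fs <- solve_total_field(ctr, op$Ei, method = solver, tol = tol, op = op$green,
                          precision = precision)
  S <- scattered_field_at_receivers(ctr, fs$Et, geometry$x, geometry$y, B = op$B)
  structure(list(S = S, geometry = geometry, residual = fs$residual,
                 iterations = fs$iterations, solver = solver),
            class = "mwt_scattering")
}

#' Precompute grid/geometry-dependent solver tables
#'
#' Bundles the FFT Green's operator, the incident fields of every
#' transmitter, and the receiver radiation matrix, all independent of the
#' phantom, so that simulating many phantoms on a shared grid reuses them.
#'
#' @param grid an [grid_spec()].
#' @param geometry an [acquisition_geometry()].
#' @return list with `green`, `Ei` (`n x n x T`), `B` (`T x n^2`).
#' @export
forward_operator <- function(grid, geometry) {
  green <- green_operator(grid, geometry$k_b)
  n <- grid$n_pixels
  Ei <- array(0i, c(n, n, geometry$n_antennas))
  for (t in seq_len(geometry$n_antennas))
    Ei[, , t] <- incident_field(c(geometry$x[t], geometry$y[t]), grid, geometry$k_b)
  B <- receiver_coeff_matrix(geometry$x, geometry$y, grid, geometry$k_b)
  list(green = green, Ei = Ei, B = B, grid = grid, geometry = geometry)
}

#' Simulate scattering matrices for a whole dataset
#'
#' Runs [assemble_scattering_matrix()] over every phantom of a dataset,
#' reusing the precomputed solver tables.
#'
#' @param dataset an `mwt_dataset`.
#' @param geometry an [acquisition_geometry()].
#' @param tol,solver,precision passed to [assemble_scattering_matrix()].
#' @param progress print a dot every 50 profiles.
#' @param check_residual compute the state-equation residual per profile
#'   (slower; off by default for bulk simulation — the direct solve is exact
#'   to factorisation precision).
#' @return list of `mwt_scattering`, parallel to `dataset$phantoms`.
#' @export
simulate_dataset <- function(dataset, geometry = acquisition_geometry(),
                             tol = 1e-6, solver = "direct", progress = FALSE,
                             precision = "double", check_residual = FALSE) {
  op <- forward_operator(dataset$config$grid, geometry)
  out <- vector("list", length(dataset$phantoms))
  for (i in seq_along(out)) {
    out[[i]] <- assemble_scattering_matrix(dataset$phantoms[[i]], geometry,
                                           tol = tol, solver = solver, op = op,
                                           precision = precision,
                                           check_residual = check_residual)
    if (progress && i %% 50 == 0) cat(".")
  }
  if (progress) cat("\n")
  out
}

#' @export
print.mwt_scattering <- function(x, ...) {
  cat(sprintf("<mwt_scattering> %d x %d, solver %s (residual %.2g)\n",
              nrow(x$S), ncol(x$S), x$solver, x$residual))
  invisible(x)
}
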