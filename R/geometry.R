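#' Multistatic acquisition geometry
#'
#' `n_antennas` antennas equally spaced on a measurement circle, each acting
#' in turn as transmitter while all (including itself) receive. The antenna
#' model is a 2D transverse-magnetic line source of unit strength. The
#' reference configuration is 30 antennas on a 12 cm-radius ring at 1 GHz in
#' a lossless background of relative permittivity 15.
#'
#' @param n_antennas number of antennas.
#' @param ring_radius measurement-circle radius (cm).
#' @param frequency operating frequency (Hz).
#' @param background_eps background relative permittivity.
#' @param background_sigma background conductivity (S/m); the solver's
#'   Green's function requires a lossless background (0).
#' @return an `mwt_geometry` object with antenna positions (cm) and the
#'   background wavenumber `k_b` (1/cm).
#' @export
acquisition_geometry <- function(n_antennas = 30L, ring_radius = 12,
                                 frequency = 1e9, background_eps = 15,
                                 background_sigma = 0) {
  if (background_sigma != 0)
    abort("only a lossless background is supported.", class = "mwtomo_bad_config")
  n_antennas <- as.integer(n_antennas)
  ang <- 2 * pi * (seq_len(n_antennas) - 1L) / n_antennas
  k_b <- 2 * pi * frequency * sqrt(background_eps) / (.c0 * 100) # 1/cm
  structure(
    list(n_antennas = n_antennas, ring_radius = ring_radius,
         frequency = frequency, background_eps = background_eps,
         background_sigma = background_sigma, angles = ang,
         x = ring_radius * cos(ang), y = ring_radius * sin(ang), k_b = k_b),
    class = "mwt_geometry"
  )
}

#' @export
print.mwt_geometry <- function(x, ...) {
  cat(sprintf("<mwt_geometry> %d antennas, ring %g cm, %.3g GHz, eps_b = %g (k_b = %.4f /cm)\n",
              x$n_antennas, x$ring_radius, x$frequency / 1e9, x$background_eps, x$k_b))
  invisible(x)
}

#' Complex contrast map of a phantom
#'
#' The scatterer enters the integral equations through the contrast
#' `chi(r) = (eps_c(r) - eps_cb) / eps_cb`, with complex permittivity
#' `eps_c = eps' - j sigma / (omega eps0)` under the `exp(+j omega t)` time
#' convention. `chi` is exactly zero outside the breast (where the phantom
#' equals the background).
#'
#' @param phantom an `mwt_phantom` (or a list with `eps_map`, `sigma_map`,
#'   `grid`).
#' @param geometry an [acquisition_geometry()].
#' @return an `mwt_contrast` object: `chi` (complex matrix), `k_b`, `grid`.
#' @export
contrast_map <- function(phantom, geometry) {
  omega <- 2 * pi * geometry$frequency
  eps_c <- phantom$eps_map - 1i * phantom$sigma_map / (omega * .eps0)
  eps_cb <- geometry$background_eps - 1i * geometry$background_sigma / (omega * .eps0)
  chi <- (eps_c - eps_cb) / eps_cb
  chi[abs(chi) < 1e-14] <- 0 + 0i
  structure(list(chi = chi, k_b = geometry$k_b, grid = phantom$grid),
            class = "mwt_contrast")
}
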