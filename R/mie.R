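# Analytic scattering by a homogeneous circular cylinder illuminated by a
# 2D line source: the independent validation oracle for the MoM solver.
#
# Under exp(+j omega t), with the source at distance rho_s > a from the
# axis, the incident field expands (addition theorem, rho < rho_s) as
#   Ei = (-j/4) sum_n J_n(k_b rho) H_n^(2)(k_b rho_s) e^{j n (phi - phi_s)}
# and the scattered / interior fields carry modal coefficients b_n / c_n
# fixed by continuity of E_z and dE_z/drho at rho = a.

# J_n(z) for complex z by the ascending series (accurate for moderate |z|;
# all uses here have |z| <~ 10). Vectorised over z.
besselJ_complex <- function(z, nu) {
  nu <- as.integer(abs(nu))
  term <- (z / 2)^nu / factorial(nu)
  s <- term
  for (m in 1:60) {
    term <- term * (-(z / 2)^2) / (m * (m + nu))
    s <- s + term
    if (all(abs(term) <= 1e-18 * (abs(s) + 1e-300))) break
  }
  s
}

besselJp_complex <- function(z, nu) {
  if (nu == 0) -besselJ_complex(z, 1)
  else (besselJ_complex(z, nu - 1) - besselJ_complex(z, nu + 1)) / 2
}

hankel2p <- function(x, nu) {
  if (nu == 0) -hankel2(x, 1)
  else (hankel2(x, nu - 1) - hankel2(x, nu + 1)) / 2
}

#' Analytic cylinder-scattering oracle
#'
#' Exact modal-series solution for a homogeneous circular cylinder of
#' radius `radius` (cm) centred at the origin, with interior relative
#' permittivity `eps` and conductivity `sigma` (S/m), embedded in a
#' lossless background of permittivity `background_eps`, illuminated by a
#' unit line source at `src` (outside the cylinder). Returns the scattered
#' field at exterior evaluation points and the total field at interior
#' points. The series is truncated adaptively once the last mode's relative
#' contribution falls below `series_tol` at every evaluation point.
#'
#' @param radius cylinder radius (cm).
#' @param eps,sigma interior dielectric properties.
#' @param background_eps background relative permittivity.
#' @param src length-2 source position (cm), `|src| > radius`.
#' @param x,y evaluation coordinates (cm), equal length.
#' @param frequency Hz.
#' @param series_tol relative truncation tolerance.
#' @param max_order hard cap on the modal order.
#' @return complex vector: scattered field where `rho > radius`, total
#'   field where `rho <= radius`.
#' @export
mie_cylinder_field <- function(radius, eps, sigma, background_eps, src, x, y,
                               frequency = 1e9, series_tol = 1e-12,
                               max_order = 500L) {
  rho_s <- sqrt(sum(src^2))
  if (rho_s <= radius) abort("source must lie outside the cylinder.",
                             class = "mwtomo_bad_input")
  omega <- 2 * pi * frequency
  k_b <- omega * sqrt(background_eps) / (.c0 * 100)
  k_c <- k_b * sqrt(complex(real = eps, imaginary = -sigma / (omega * .eps0)) /
                      background_eps)
  phi_s <- atan2(src[2], src[1])
  rho <- sqrt(x^2 + y^2)
  phi <- atan2(y, x)
  inside <- rho <= radius
  out <- complex(length(x))
  ka <- k_b * radius; kca <- k_c * radius

  coef <- function(nu) {
    Jb <- besselJ(ka, nu)
    Jbp <- if (nu == 0) -besselJ(ka, 1) else (besselJ(ka, nu - 1) - besselJ(ka, nu + 1)) / 2
    Hb <- hankel2(ka, nu);  Hbp <- hankel2p(ka, nu)
    Jc <- besselJ_complex(kca, nu); Jcp <- besselJp_complex(kca, nu)
    b_n <- (k_c * Jcp * Jb - k_b * Jc * Jbp) / (k_b * Jc * Hbp - k_c * Jcp * Hb)
    c_n <- (Jb + b_n * Hb) / Jc
    list(b = b_n, c = c_n)
  }

  acc <- complex(length(x))
  ref <- 0
  stalled <- 0L
  for (nu in 0:max_order) {
    cf <- coef(nu)
    Hs <- hankel2(k_b * rho_s, nu)
    ang <- if (nu == 0) rep(1 + 0i, length(x)) else 2 * cos(nu * (phi - phi_s))
    term <- complex(length(x))
    if (any(!inside))
      term[!inside] <- cf$b * hankel2(k_b * rho[!inside], nu) * Hs * ang[!inside]
    if (any(inside))
      term[inside] <- cf$c * besselJ_complex(k_c * rho[inside], nu) * Hs * ang[inside]
    acc <- acc + term
    ref <- max(ref, max(abs(acc)))
    if (max(abs(term)) <= series_tol * max(ref, 1e-300)) {
      stalled <- stalled + 1L
      if (stalled >= 3L) break
    } else stalled <- 0L
    if (nu == max_order)
      abort("cylindrical-harmonics series failed to converge within `max_order` terms.",
            class = "mwtomo_nonconvergence")
  }
  # exterior points carry the scattered field; interior points carry the
  # total field (the interior modal series is the full transmitted field)
  (-1i / 4) * acc
}
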