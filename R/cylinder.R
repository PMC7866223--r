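## Analytic reference solution: scattering of a 2D line source by a
## homogeneous dielectric cylinder in a lossy background (TM polarization).
## Classical harmonic-series solution via the addition theorem; used as the
## independent oracle certifying the discrete-dipole solver's accuracy.

#' Analytic field of a line source scattered by a dielectric cylinder
#'
#' Total field at observation points for an ideal 2D line current of
#' amplitude `|J|` in a homogeneous lossy background containing one
#' homogeneous dielectric cylinder.  The incident field is expanded about the
#' cylinder centre with the Graf addition theorem; matching `E` and its
#' radial derivative at the cylinder surface gives the harmonic reflection
#' coefficients.  Both source and observation points must lie outside the
#' cylinder.
#'
#' @param background,object [dielectric_properties()] of bath and cylinder.
#' @param frequency frequency (Hz).
#' @param center numeric `c(x, y)` cylinder centre (m).
#' @param radius cylinder radius (m).
#' @param source numeric `c(x, y)` line-source position (m).
#' @param obs_x,obs_y observation point coordinates (m).
#' @param amplitude line-current amplitude `|J|`.
#' @param nmax highest harmonic order; the default grows with the electrical
#'   size of the cylinder and converges to machine precision for the
#'   sub-wavelength cylinders used here.
#' @return complex vector of total field values at the observation points.
#' @export
cylinder_field <- function(background, object, frequency, center, radius,
                           source, obs_x, obs_y, amplitude = 1,
                           nmax = NULL) {
  stopifnot(inherits(background, "mwt_props"), inherits(object, "mwt_props"))
  k0 <- .wavenumber(complex_k2(background, frequency))
  k1 <- .wavenumber(complex_k2(object, frequency))
  omega <- 2 * pi * frequency
  if (is.null(nmax)) nmax <- max(12L, ceiling(Mod(k0) * radius) + 12L)

  ## coordinates relative to the cylinder centre
  sx <- source[1] - center[1]; sy <- source[2] - center[2]
  rho_s <- sqrt(sx^2 + sy^2); phi_s <- atan2(sy, sx)
  ox <- obs_x - center[1]; oy <- obs_y - center[2]
  rho_o <- sqrt(ox^2 + oy^2); phi_o <- atan2(oy, ox)
  if (rho_s <= radius) stop("source must lie outside the cylinder")
  if (any(rho_o <= radius)) stop("observation points must lie outside the cylinder")

  amp <- -(omega * MU0 * amplitude / 4)
  d <- sqrt((obs_x - source[1])^2 + (obs_y - source[2])^2)
  Einc <- amp * hankel2_c(k0 * d, 0)

  b0 <- .bessel_seq(k0 * radius, nmax + 1L)
  b1 <- .bessel_seq(k1 * radius, nmax + 1L)
  bs <- .bessel_seq(k0 * rho_s, nmax)
  ## per-observation H_n^(2)(k0 rho_o): rows n = 0..nmax
  Ho <- vapply(rho_o, function(r) .bessel_seq(k0 * r, nmax)$H2,
               complex(nmax + 1L))
  Ho <- matrix(Ho, nmax + 1L)

  idx <- function(n) n + 1L
  dJ0 <- function(n) {   # J_n'(k0 a)
    if (n == 0) -b0$J[idx(1L)] else (b0$J[idx(n - 1L)] - b0$J[idx(n + 1L)]) / 2
  }
  dJ1 <- function(n) {
    if (n == 0) -b1$J[idx(1L)] else (b1$J[idx(n - 1L)] - b1$J[idx(n + 1L)]) / 2
  }
  dH0 <- function(n) {
    if (n == 0) -b0$H2[idx(1L)] else (b0$H2[idx(n - 1L)] - b0$H2[idx(n + 1L)]) / 2
  }

  Escat <- complex(length(rho_o))
  for (n in 0:nmax) {
    num <- k1 * dJ1(n) * b0$J[idx(n)] - k0 * dJ0(n) * b1$J[idx(n)]
    den <- k0 * b1$J[idx(n)] * dH0(n) - k1 * dJ1(n) * b0$H2[idx(n)]
    Rn <- num / den
    if (!is.finite(Re(Rn))) next
    ## incident harmonic coefficient: amp * H_n^(2)(k0 rho_s) e^(-j n phi_s)
    base <- amp * bs$H2[idx(n)] * Rn * Ho[idx(n), ]
    if (n == 0) {
      Escat <- Escat + base
    } else {
      ## +n and -n terms combined (coefficients are even in n)
      Escat <- Escat + base * (exp(1i * n * (phi_o - phi_s)) +
                                 exp(-1i * n * (phi_o - phi_s)))
    }
  }
  Einc + Escat
}
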