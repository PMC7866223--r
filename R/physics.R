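## Background physics: lossy-medium wavenumber, 2D Helmholtz kernel, cell
## self-term, and line-source incident fields.  Time convention exp(+j omega t)
## throughout, so outgoing waves carry H^(2) and passive media have
## Im(k^2) <= 0.

#' Dielectric properties of a medium
#'
#' @param eps_r relative permittivity (>= 1).
#' @param sigma conductivity (S/m, >= 0).
#' @return an object of class `mwt_props`.
#' @examples
#' dielectric_properties(20.9, 1.35)   # 80:20 glycerin-water bath at 1.5 GHz
#' @export
dielectric_properties <- function(eps_r, sigma) {
  if (!is.numeric(eps_r) || length(eps_r) != 1L || eps_r < 1)
    stop("eps_r must be a scalar >= 1")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma < 0)
    stop("sigma must be a nonnegative scalar (S/m)")
  structure(list(eps_r = eps_r, sigma = sigma), class = "mwt_props")
}

#' @export
print.mwt_props <- function(x, ...) {
  cat(sprintf("Dielectric properties: eps_r = %g, sigma = %g S/m\n",
              x$eps_r, x$sigma))
  invisible(x)
}

#' Complex squared wavenumber of a lossy medium
#'
#' \deqn{k^2 = \omega^2 \mu_0 (\epsilon_0 \epsilon_r - j \sigma / \omega)}
#' in units of m^-2; the imaginary part is non-positive for passive media
#' under the `exp(+j omega t)` convention.  `k^2` is the reconstruction
#' variable: both permittivity and conductivity images are carried in one
#' complex number per node.
#'
#' @param props a [dielectric_properties()] object.
#' @param frequency frequency in Hz.
#' @return complex scalar (m^-2).
#' @examples
#' complex_k2(dielectric_properties(22, 1), 1300e6)
#' @export
complex_k2 <- function(props, frequency) {
  stopifnot(inherits(props, "mwt_props"))
  if (!is.numeric(frequency) || length(frequency) != 1L || frequency <= 0)
    stop("frequency must be a positive scalar (Hz)")
  omega <- 2 * pi * frequency
  omega^2 * MU0 * complex(real = EPS0 * props$eps_r,
                          imaginary = -props$sigma / omega)
}

## principal square root keeps Re(k) >= 0 and, for Im(k2) <= 0, Im(k) <= 0
.wavenumber <- function(k2) sqrt(as.complex(k2))

## inverse of complex_k2: recover (eps_r, sigma) images from k^2 values
.k2_to_props <- function(k2, frequency) {
  omega <- 2 * pi * frequency
  list(eps_r = Re(k2) / (omega^2 * MU0 * EPS0),
       sigma = -Im(k2) / (omega * MU0))
}

#' 2D outgoing Green's function of the Helmholtz equation
#'
#' \deqn{G(d) = \frac{1}{4j} H_0^{(2)}(k_b d)}, the solution of
#' \eqn{(\nabla^2 + k_b^2) G = -\delta} that radiates outward (and decays,
#' for lossy `k_b`) under the `exp(+j omega t)` convention.
#'
#' @param k_b complex background wavenumber (m^-1), `Im(k_b) <= 0`.
#' @param distance vector of source-observation distances (m), all > 0.
#' @return complex vector.
#' @export
greens_function <- function(k_b, distance) {
  if (any(distance <= 0)) stop("greens_function: distance must be positive")
  hankel2_c(as.complex(k_b) * distance, 0) / 4i
}

#' Self-term of a square cell (equivalent-circle integration)
#'
#' The diagonal coefficient of the discrete-dipole system is the integral of
#' the Green's function over the cell containing the collocation point.  The
#' square cell of side `h` is replaced by the circle of equal area (radius
#' `a = h / sqrt(pi)`), for which the integral has the closed form
#' \deqn{C_{self} = -\frac{j \pi a}{2 k_b} H_1^{(2)}(k_b a) - \frac{1}{k_b^2}.}
#'
#' @param k_b complex background wavenumber (m^-1).
#' @param h cell side (m).  A warning is issued if the cell is coarser than a
#'   tenth of the background phase wavelength (`Re(k_b) h > 2 pi / 10`), the
#'   usual sub-wavelength sampling criterion.
#' @return complex scalar (m^2), independent of cell position.
#' @export
self_term <- function(k_b, h) {
  k_b <- as.complex(k_b)
  if (!is.numeric(h) || length(h) != 1L || h <= 0)
    stop("h must be a positive scalar (m)")
  if (Re(k_b) * h > 2 * pi / 10)
    warning("self_term: cell coarser than lambda/10; accuracy degrades")
  a <- h / sqrt(pi)
  -1i * pi * a / (2 * k_b) * hankel2_c(k_b * a, 1) - 1 / k_b^2
}

#' Incident field of a transmitting antenna
#'
#' The field of an ideal 2D line current of amplitude `|J|` at the antenna
#' position, in the homogeneous background:
#' \deqn{E_{inc}(r) = -\frac{\omega \mu_0 |J|}{4} H_0^{(2)}(k_b |r - r_s|).}
#'
#' @param array an [mwt_array][build_antenna_array] object.
#' @param s transmitter index (1-based).
#' @param px,py coordinates of the observation points (m).
#' @param k_b complex background wavenumber (m^-1).
#' @param frequency frequency (Hz).
#' @return complex vector of field values at the observation points.
#' @export
incident_field <- function(array, s, px, py, k_b, frequency) {
  stopifnot(inherits(array, "mwt_array"))
  if (s < 1 || s > array$n) stop("transmitter index out of range")
  d <- sqrt((px - array$x[s])^2 + (py - array$y[s])^2)
  if (any(d == 0)) stop("observation point coincides with the source antenna")
  omega <- 2 * pi * frequency
  if (array$amplitude == 0) return(complex(length(d)))
  -(omega * MU0 * array$amplitude / 4) * hankel2_c(as.complex(k_b) * d, 0)
}
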