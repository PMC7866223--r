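## Complex-argument cylinder functions.
##
## Base R's besselJ/besselY accept real arguments only, but a lossy coupling
## bath makes the background wavenumber complex, so every kernel evaluation
## needs J and Y (equivalently the outgoing Hankel function H^(2)) at complex
## argument.  Orders 0 and 1 are computed directly (ascending series for
## |z| <= 12, Hankel asymptotic expansion beyond); higher integer orders, used
## by the analytic-cylinder reference solution, come from Miller downward
## recurrence (J_n) and stable upward recurrence (H_n^(2)).
##
## Accuracy note: in the series region the functions are assembled from J and
## Y, so the relative accuracy of the exponentially small H^(2) degrades like
## eps * e^(2|Im z|).  For passive media with moderate loss tangent
## (|Im z| <~ 0.35 |z|, the regime of glycerin-water baths) the worst-case
## relative error is ~1e-12; arguments approaching the imaginary axis with
## |Im z| ~ 10 lose accuracy and are outside the intended domain.

.series_terms <- 42L

.j0_series <- function(z) {
  q <- -(z * z) / 4
  term <- rep(1 + 0i, length(z))
  s <- term
  for (k in seq_len(.series_terms)) {
    term <- term * q / (k * k)
    s <- s + term
  }
  s
}

.j1_series <- function(z) {
  q <- -(z * z) / 4
  term <- rep(1 + 0i, length(z))
  s <- term
  for (k in seq_len(.series_terms)) {
    term <- term * q / (k * (k + 1))
    s <- s + term
  }
  s * z / 2
}

.y0_series <- function(z) {
  q <- -(z * z) / 4
  term <- rep(1 + 0i, length(z))
  s <- 0i
  Hk <- 0
  for (k in seq_len(.series_terms)) {
    term <- term * q / (k * k)
    Hk <- Hk + 1 / k
    s <- s - term * Hk            # sum_{k>=1} (-1)^(k+1) H_k (z^2/4)^k/(k!)^2
  }
  (2 / pi) * ((log(z / 2) + EULER_GAMMA) * .j0_series(z) + s)
}

.y1_series <- function(z) {
  q <- -(z * z) / 4
  term <- rep(1 + 0i, length(z))    # q^k / (k! (k+1)!) at k = 0
  s <- term * (1 - 2 * EULER_GAMMA) # psi(1) + psi(2)
  Hk <- 0
  Hk1 <- 1
  for (k in seq_len(.series_terms)) {
    term <- term * q / (k * (k + 1))
    Hk <- Hk + 1 / k
    Hk1 <- Hk1 + 1 / (k + 1)
    s <- s + term * (Hk + Hk1 - 2 * EULER_GAMMA)
  }
  (2 / pi) * log(z / 2) * .j1_series(z) - 2 / (pi * z) - (z / (2 * pi)) * s
}

## Asymptotic expansion of H_nu^(1,2)(z) for large |z| (Hankel's expansion).
.hankel_asym <- function(z, nu, kind) {
  sgn <- if (kind == 2L) -1i else 1i
  om <- z - nu * pi / 2 - pi / 4
  fournu2 <- 4 * nu^2
  term <- rep(1 + 0i, length(z))
  s <- term
  for (k in 1:24) {
    term <- term * (fournu2 - (2 * k - 1)^2) / (8 * k) * (sgn / z)
    s <- s + term
  }
  sqrt(2 / (pi * z)) * exp(sgn * om) * s
}

.series_cut <- 12

#' Hankel function of the second kind for complex argument
#'
#' Computes \eqn{H^{(2)}_\nu(z) = J_\nu(z) - j Y_\nu(z)} for complex `z` and
#' order 0 or 1.  Under the `exp(+j omega t)` time convention this is the
#' outgoing-wave cylinder function; for `Im(z) < 0` (propagation in a lossy
#' medium) it decays with distance.
#'
#' @param z complex (or numeric) vector of arguments; `z = 0` is a pole.
#' @param nu order, 0 or 1.
#' @return complex vector of the same length as `z`.
#' @seealso [besselj_c()] for \eqn{J_\nu}; [greens_function()] for the 2D
#'   Helmholtz kernel built on this function.
#' @examples
#' hankel2_c(1.5, 0)                       # real argument: J0(x) - 1i*Y0(x)
#' hankel2_c(complex(real = 5, imaginary = -2), 1)
#' @export
hankel2_c <- function(z, nu = 0) {
  stopifnot(nu %in% c(0, 1))
  z <- as.complex(z)
  if (any(z == 0)) stop("hankel2_c: argument must be nonzero")
  out <- complex(length(z))
  small <- Mod(z) <= .series_cut
  if (any(small)) {
    zs <- z[small]
    out[small] <- if (nu == 0) .j0_series(zs) - 1i * .y0_series(zs)
    else .j1_series(zs) - 1i * .y1_series(zs)
  }
  if (any(!small)) out[!small] <- .hankel_asym(z[!small], nu, 2L)
  out
}

#' Bessel function of the first kind for complex argument
#'
#' @inheritParams hankel2_c
#' @return complex vector \eqn{J_\nu(z)}.
#' @export
besselj_c <- function(z, nu = 0) {
  stopifnot(nu %in% c(0, 1))
  z <- as.complex(z)
  out <- complex(length(z))
  small <- Mod(z) <= .series_cut
  if (any(small)) {
    zs <- z[small]
    out[small] <- if (nu == 0) .j0_series(zs) else .j1_series(zs)
  }
  if (any(!small)) {
    zl <- z[!small]
    out[!small] <- (.hankel_asym(zl, nu, 1L) + .hankel_asym(zl, nu, 2L)) / 2
  }
  out
}

## J_0..J_nmax and H^(2)_0..H^(2)_nmax at a single complex argument.
## J by Miller downward recurrence normalized against the order-0 value;
## H^(2) by upward recurrence (dominant solution, stable upward).
.bessel_seq <- function(z, nmax) {
  z <- as.complex(z)
  stopifnot(length(z) == 1L, nmax >= 1)
  nstart <- nmax + 15L + ceiling(Mod(z))
  jj <- complex(nstart + 2L)
  jj[nstart + 2L] <- 0i
  jj[nstart + 1L] <- 1e-30 + 0i
  for (n in nstart:1) {            # J_(n-1) = (2n/z) J_n - J_(n+1)
    jj[n] <- (2 * n / z) * jj[n + 1L] - jj[n + 2L]
    if (Mod(jj[n]) > 1e250) jj <- jj / 1e250   # avoid overflow
  }
  scale <- besselj_c(z, 0) / jj[1L]
  J <- jj[seq_len(nmax + 1L)] * scale
  H <- complex(nmax + 1L)
  H[1L] <- hankel2_c(z, 0)
  H[2L] <- hankel2_c(z, 1)
  if (nmax >= 2) {
    for (n in 1:(nmax - 1L)) H[n + 2L] <- (2 * n / z) * H[n + 1L] - H[n]
  }
  list(J = J, H2 = H)
}
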