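## Forward solver: node-collocated volume-integral (discrete-dipole) method
## for the 2D TM scattering problem.  Each in-zone node owns an h x h square;
## the collocation system over the np in-zone nodes is
##   E_n = E_inc,n + sum_m C_nm chi_m E_m,
## with C_nm = h^2 G(p_n, p_m) for n != m, C_nn the equivalent-circle
## self-term, and chi = k^2 - k_b^2 the contrast (zero outside the zone).
## Receiver values follow by one more application of the same kernel.

#' Property map over the imaging zone
#'
#' The unknown image: a complex squared wavenumber `k^2` per in-zone node.
#' Freshly constructed maps are homogeneous at the background value; use
#' [make_property_map()] to place inclusions.
#'
#' @param zone an [mwt_zone][select_imaging_zone] object.
#' @param background [dielectric_properties()] of the coupling bath.
#' @param frequency operating frequency (Hz).
#' @return an object of class `mwt_pmap`: `k2` (complex, length `n_nodes`),
#'   `k2_bg`, `frequency`, `background`.
#' @export
property_map <- function(zone, background, frequency) {
  stopifnot(inherits(zone, "mwt_zone"))
  k2b <- complex_k2(background, frequency)
  structure(list(
    k2 = rep(k2b, zone$n_nodes),
    k2_bg = k2b,
    frequency = frequency,
    background = background
  ), class = "mwt_pmap")
}

#' @export
print.mwt_pmap <- function(x, ...) {
  pr <- .k2_to_props(x$k2, x$frequency)
  cat(sprintf("Property map: %d nodes at %.4g MHz; eps_r in [%.3g, %.3g], sigma in [%.3g, %.3g] S/m\n",
              length(x$k2), x$frequency / 1e6,
              min(pr$eps_r), max(pr$eps_r), min(pr$sigma), max(pr$sigma)))
  invisible(x)
}

#' Coupling matrix of the discrete-dipole system
#'
#' The dense np x np matrix `C` with `C[n, m] = h^2 G(p_n, p_m)` off the
#' diagonal and the [self_term()] on it.  It depends only on the geometry and
#' the background wavenumber, so it can be computed once and reused across
#' transmitters and reconstruction iterations.  The uniform grid makes `C`
#' depend on index offsets only; the kernel is evaluated on a small offset
#' table and gathered.
#'
#' @param zone an [mwt_zone][select_imaging_zone] object.
#' @param k_b complex background wavenumber (m^-1).
#' @return complex matrix.
#' @export
coupling_matrix <- function(zone, k_b) {
  stopifnot(inherits(zone, "mwt_zone"))
  h <- zone$grid$h
  ii <- zone$node_i
  jj <- zone$node_j
  Ri <- max(ii) - min(ii)
  Rj <- max(jj) - min(jj)
  off2_i <- (-Ri:Ri)^2
  off2_j <- (-Rj:Rj)^2
  D <- h * sqrt(outer(off2_i, off2_j, "+"))
  Gtab <- matrix(0i, length(off2_i), length(off2_j))
  Gtab[D > 0] <- h * h * greens_function(k_b, D[D > 0])
  Gtab[D == 0] <- self_term(k_b, h)
  idx <- outer(ii, ii, "-") + Ri + 1L +
    (outer(jj, jj, "-") + Rj) * nrow(Gtab)
  matrix(Gtab[idx], zone$n_nodes, zone$n_nodes)
}

## receiver coupling: n_antennas x np matrix h^2 G(r_a, p_m)
.antenna_coupling <- function(zone, array, k_b) {
  h <- zone$grid$h
  d <- sqrt(outer(array$x, zone$node_x, "-")^2 +
            outer(array$y, zone$node_y, "-")^2)
  matrix(h * h * greens_function(k_b, d), array$n, zone$n_nodes)
}

## unpreconditioned BiCGSTAB for the (well-conditioned, diagonally dominant)
## collocation system; matrix-free apart from the stored kernel coefficients
.bicgstab <- function(matvec, b, tol = 1e-12, maxit = 1000L) {
  x <- complex(length(b))
  r <- b
  rhat <- r
  rho <- alpha <- omega <- 1 + 0i
  v <- p <- complex(length(b))
  bnorm <- sqrt(sum(Mod(b)^2))
  if (bnorm == 0) return(x)
  for (it in seq_len(maxit)) {
    rho1 <- sum(Conj(rhat) * r)
    beta <- (rho1 / rho) * (alpha / omega)
    rho <- rho1
    p <- r + beta * (p - omega * v)
    v <- matvec(p)
    alpha <- rho / sum(Conj(rhat) * v)
    s <- r - alpha * v
    t <- matvec(s)
    omega <- sum(Conj(t) * s) / sum(Mod(t)^2)
    x <- x + alpha * p + omega * s
    r <- s - omega * t
    if (sqrt(sum(Mod(r)^2)) / bnorm < tol) return(x)
  }
  warning("bicgstab: not converged to tol within maxit")
  x
}

## workhorse: fields for a set of transmitters sharing one factorization
.forward_fields <- function(pmap, zone, array, transmitters,
                            method = c("direct", "iterative"),
                            coupling = NULL, tol = 1e-12) {
  method <- match.arg(method)
  .validate_scene(zone, array)
  np <- zone$n_nodes
  k_b <- .wavenumber(pmap$k2_bg)
  chi <- pmap$k2 - pmap$k2_bg
  if (is.null(coupling)) coupling <- coupling_matrix(zone, k_b)

  Einc <- vapply(transmitters, function(s)
    incident_field(array, s, zone$node_x, zone$node_y, k_b, pmap$frequency),
    complex(np))
  Einc <- matrix(Einc, np)

  if (method == "direct") {
    A <- diag(1 + 0i, np) - coupling * matrix(chi, np, np, byrow = TRUE)
    ## solve() reports the reciprocal condition number if the system is
    ## computationally singular
    E <- solve(A, Einc)
  } else {
    matvec <- function(x) x - coupling %*% (chi * x)
    E <- matrix(0i, np, length(transmitters))
    for (k in seq_along(transmitters))
      E[, k] <- .bicgstab(matvec, Einc[, k], tol = tol)
  }
  .count("forward_solves", length(transmitters))

  Gant <- .antenna_coupling(zone, array, k_b)
  sols <- vector("list", length(transmitters))
  for (k in seq_along(transmitters)) {
    s <- transmitters[k]
    others <- setdiff(seq_len(array$n), s)
    Einc_ant <- complex(array$n)
    Einc_ant[others] <- incident_field(array, s, array$x[others],
                                       array$y[others], k_b, pmap$frequency)
    Einc_ant[s] <- NA_complex_          # self-field of the source is singular
    Eant <- Einc_ant + as.vector(Gant %*% (chi * E[, k]))
    sols[[k]] <- structure(list(
      s = s,
      E_nodes = E[, k],
      E_inc_nodes = Einc[, k],
      E_antennas = Eant,
      E_inc_antennas = Einc_ant
    ), class = "mwt_field")
  }
  sols
}

#' Solve the total field for one transmitter
#'
#' Solves the discrete-dipole collocation system for the total field at every
#' in-zone node and fills in the field at all antenna positions (the entry at
#' the transmitting antenna itself is `NA`: the self-field of a line source is
#' singular and never measured).
#'
#' @param pmap a [property_map()] (possibly with inclusions).
#' @param zone,array scene geometry.
#' @param s transmitter index.
#' @param method `"direct"` (dense LU, default) or `"iterative"` (matrix-free
#'   BiCGSTAB applied to the same kernel coefficients).
#' @param coupling optional precomputed [coupling_matrix()].
#' @return an object of class `mwt_field` with `E_nodes`, `E_inc_nodes`,
#'   `E_antennas`, `E_inc_antennas`, `s`.
#' @export
solve_total_field <- function(pmap, zone, array, s,
                              method = c("direct", "iterative"),
                              coupling = NULL) {
  .forward_fields(pmap, zone, array, s, method = method,
                  coupling = coupling)[[1L]]
}

#' @export
print.mwt_field <- function(x, ...) {
  cat(sprintf("Field solution, transmitter #%d: %d node values, %d antenna values\n",
              x$s, length(x$E_nodes), length(x$E_antennas)))
  invisible(x)
}

## assemble the ordered (s, r) measurement table from per-transmitter fields
.measurements_from_fields <- function(fields, array, pmap) {
  n <- array$n
  s <- rep(seq_len(n), each = n - 1L)
  r <- as.vector(vapply(seq_len(n), function(k) setdiff(seq_len(n), k),
                        integer(n - 1L)))
  value <- complex(length(s))
  for (f in fields) value[s == f$s] <- f$E_antennas[setdiff(seq_len(n), f$s)]
  m <- data.frame(s = s, r = r)
  m$value <- value
  structure(m, class = c("mwt_measurements", "data.frame"),
            frequency = pmap$frequency,
            n_antennas = n,
            array_diameter = array$diameter,
            amplitude = array$amplitude,
            eps_r = pmap$background$eps_r,
            sigma = pmap$background$sigma)
}

#' Forward sweep over all transmitters
#'
#' Solves the forward problem once per antenna (one factorization shared by
#' all right-hand sides) and assembles the measurement table of complex
#' transmission values for every ordered `(s, r)` pair, `s` ascending and `r`
#' ascending with `r = s` skipped: `n (n - 1)` rows in total.
#'
#' @inheritParams solve_total_field
#' @return list with `fields` (one `mwt_field` per transmitter) and
#'   `measurements` (an `mwt_measurements` data frame: columns `s`, `r`,
#'   complex `value`, with acquisition metadata in attributes).
#' @examples
#' \donttest{
#' g <- build_grid(0.25, 24)
#' z <- select_imaging_zone(g, 0.0698)
#' a <- build_antenna_array(8, 0.152)
#' pm <- property_map(z, dielectric_properties(20.9, 1.35), 1500e6)
#' sweep <- forward_sweep(pm, z, a)
#' nrow(sweep$measurements)   # 8 * 7 = 56
#' }
#' @export
forward_sweep <- function(pmap, zone, array,
                          method = c("direct", "iterative"),
                          coupling = NULL) {
  fields <- .forward_fields(pmap, zone, array, seq_len(array$n),
                            method = method, coupling = coupling)
  list(fields = fields,
       measurements = .measurements_from_fields(fields, array, pmap))
}
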