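## Nodal-adjoint Jacobian.  Because the forward-solution grid and the
## parameter grid are the same uniform grid with nodal basis functions, the
## dual-mesh adjoint quadrature collapses: the sensitivity of measurement
## (s, r) to the squared wavenumber at node tau is
##   J[(s,r), tau] = -(1 / (j omega mu0 |Jr|)) * (A_tau / M) * Es(p_tau) * Er(p_tau),
## so an entire row is the element-wise product of the two forward field
## distributions times a constant, and the whole matrix costs ns forward
## solves plus ns*nr vector products -- no extra solves.

#' One Jacobian row by the collapsed nodal-adjoint formula
#'
#' @param Es,Er field solutions ([solve_total_field()]) for the transmitting
#'   and receiving antennas (the receiver acts as the adjoint source; with
#'   equal source amplitudes the row is symmetric in `s` and `r`).
#' @param zone the imaging zone both solutions were computed on.
#' @param frequency frequency (Hz).
#' @param amplitude receive-antenna source amplitude `|Jr|` (> 0).
#' @return complex vector of length `zone$n_nodes`: derivatives of the complex
#'   received field with respect to `k^2` at each node (units m^2 per unit
#'   field).
#' @export
jacobian_row_collapsed <- function(Es, Er, zone, frequency, amplitude = 1) {
  stopifnot(inherits(Es, "mwt_field"), inherits(Er, "mwt_field"),
            inherits(zone, "mwt_zone"))
  if (length(Es$E_nodes) != zone$n_nodes || length(Er$E_nodes) != zone$n_nodes)
    stop("field solutions do not match the imaging zone")
  if (amplitude <= 0) stop("amplitude must be positive")
  omega <- 2 * pi * frequency
  .count("jacobian_rows")
  ## multiply in canonical transmitter order: reciprocal rows come out
  ## bitwise identical (complex multiplication is commutative mathematically
  ## but not bit-for-bit in C99 arithmetic)
  if (Er$s < Es$s) { tmp <- Es; Es <- Er; Er <- tmp }
  -(1 / (1i * omega * MU0 * amplitude)) * (zone$node_area / zone$M) *
    Es$E_nodes * Er$E_nodes
}

#' Full Jacobian matrix from one forward sweep
#'
#' Assembles all `ns * nr` rows of the sensitivity matrix from the `ns` field
#' solutions of a single [forward_sweep()] -- one vector-vector product per
#' row, zero additional forward solves.  Rows follow the measurement order
#' (`s` ascending, `r` ascending skipping `r = s`); columns follow the zone's
#' node ordering.
#'
#' @param fields list of `mwt_field` objects, one per antenna, as returned in
#'   `forward_sweep()$fields`.
#' @param zone the imaging zone.
#' @param array the antenna array (supplies `|Jr|`).
#' @param frequency frequency (Hz).
#' @return an object of class `mwt_jacobian`: complex matrix of dimension
#'   `(ns * (ns - 1)) x n_nodes` with attributes `pairs` (the row index table)
#'   and `domain = "complex-field"`.
#' @export
jacobian_matrix <- function(fields, zone, array, frequency) {
  stopifnot(inherits(zone, "mwt_zone"), inherits(array, "mwt_array"))
  n <- array$n
  if (length(fields) != n)
    stop("need one field solution per antenna")
  by_s <- integer(n)
  for (k in seq_along(fields)) by_s[fields[[k]]$s] <- k
  if (any(by_s == 0L)) stop("missing field solutions for some antennas")
  s <- rep(seq_len(n), each = n - 1L)
  r <- as.vector(vapply(seq_len(n), function(k) setdiff(seq_len(n), k),
                        integer(n - 1L)))
  J <- matrix(0i, length(s), zone$n_nodes)
  for (row in seq_along(s)) {
    J[row, ] <- jacobian_row_collapsed(fields[[by_s[s[row]]]],
                                       fields[[by_s[r[row]]]],
                                       zone, frequency, array$amplitude)
  }
  structure(J, class = c("mwt_jacobian", class(J)),
            pairs = data.frame(s = s, r = r),
            domain = "complex-field")
}

#' @export
print.mwt_jacobian <- function(x, ...) {
  cat(sprintf("Nodal-adjoint Jacobian: %d rows (ordered s/r pairs) x %d nodes, %s domain\n",
              nrow(x), ncol(x), attr(x, "domain")))
  invisible(x)
}

#' One Jacobian row by the general dual-mesh quadrature
#'
#' Reference implementation of the uncollapsed adjoint quadrature: a loop over
#' the parameter elements supporting node `tau` and over their vertices, with
#' weight `A_e / M` and the nodal basis function evaluated at each vertex
#' (1 at `tau`, 0 elsewhere).  On coinciding grids this must reproduce
#' [jacobian_row_collapsed()] to machine precision; it exists as the
#' independent verification path, not for production use.
#'
#' @inheritParams jacobian_row_collapsed
#' @return complex vector of length `zone$n_nodes`.
#' @export
jacobian_row_general <- function(Es, Er, zone, frequency, amplitude = 1) {
  stopifnot(inherits(Es, "mwt_field"), inherits(Er, "mwt_field"),
            inherits(zone, "mwt_zone"))
  omega <- 2 * pi * frequency
  const <- -(1 / (1i * omega * MU0 * amplitude))
  h2 <- zone$grid$h^2
  row <- complex(zone$n_nodes)
  for (tau in seq_len(zone$n_nodes)) {
    acc <- 0i
    for (e in node_cell_adjacency(zone, tau)) {
      ## the 4 vertex nodes of cell e, in zone numbering
      vi <- c(zone$cell_i[e], zone$cell_i[e] + 1L,
              zone$cell_i[e], zone$cell_i[e] + 1L)
      vj <- c(zone$cell_j[e], zone$cell_j[e],
              zone$cell_j[e] + 1L, zone$cell_j[e] + 1L)
      vtx <- zone$node_index[.node_id(vi, vj, zone$grid$n) + 1L]
      for (v in vtx) {
        phi <- as.numeric(v == tau)      # nodal basis at the vertex
        if (phi != 0)
          acc <- acc + (h2 / zone$M) * phi * Es$E_nodes[v] * Er$E_nodes[v]
      }
    }
    row[tau] <- const * acc
  }
  row
}

#' Transform a Jacobian to the log-magnitude/phase domain
#'
#' Divides each row by the complex field received for that row's `(s, r)`
#' pair: by the chain rule for the complex logarithm, the real part of the
#' transformed row is the sensitivity of `ln |E|` and the imaginary part the
#' sensitivity of the phase.
#'
#' @param J an `mwt_jacobian` in the `"complex-field"` domain.
#' @param received complex vector of received fields, one per row, in row
#'   order (the model-predicted measurements of the same sweep).
#' @return an `mwt_jacobian` with `domain = "log-transformed"`.
#' @export
log_transform_jacobian <- function(J, received) {
  stopifnot(inherits(J, "mwt_jacobian"))
  if (identical(attr(J, "domain"), "log-transformed"))
    stop("Jacobian is already log-transformed")
  if (length(received) != nrow(J))
    stop("need one received field value per Jacobian row")
  bad <- which(received == 0 | !is.finite(Re(received)))
  if (length(bad))
    stop("zero or non-finite received field for row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         "; cannot form log-domain sensitivities")
  out <- J / received
  attr(out, "pairs") <- attr(J, "pairs")
  attr(out, "domain") <- "log-transformed"
  class(out) <- class(J)
  out
}

#' Finite-difference Jacobian column (verification oracle)
#'
#' Central difference of all measurements with respect to `k^2` at one node:
#' two full forward sweeps per column.  This is the brute-force check of the
#' adjoint construction and plays no part in reconstruction.
#'
#' @param pmap property map at which to differentiate.
#' @param zone,array scene geometry.
#' @param tau node index (1-based, must be in the zone).
#' @param delta perturbation of `k^2` (m^-2); should be small against
#'   `|k_b^2|`.
#' @param domain `"field"` for derivatives of the complex received field,
#'   `"log"` for derivatives of `ln E` (log magnitude + j phase).
#' @param coupling optional precomputed [coupling_matrix()].
#' @return complex vector of length `ns * (ns - 1)` in measurement row order.
#' @export
finite_difference_jacobian_column <- function(pmap, zone, array, tau, delta,
                                              domain = c("field", "log"),
                                              coupling = NULL) {
  domain <- match.arg(domain)
  stopifnot(inherits(pmap, "mwt_pmap"))
  if (!is.numeric(tau) || length(tau) != 1L || tau < 1 || tau > zone$n_nodes)
    stop("tau outside the imaging zone")
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0)
    stop("delta must be a positive perturbation of k^2")
  bump <- function(sgn) {
    p <- pmap
    p$k2[tau] <- p$k2[tau] + sgn * delta
    forward_sweep(p, zone, array, coupling = coupling)$measurements$value
  }
  up <- bump(1)
  dn <- bump(-1)
  if (domain == "log") {
    up <- log(up)    # principal branch; the difference is small, no unwrap
    dn <- log(dn)
  }
  (up - dn) / (2 * delta)
}
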