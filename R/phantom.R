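## Synthetic phantom experiments.  The shipped default emulates a cylindrical
## dielectric phantom in a glycerin-water tank surrounded by a 16-element
## monopole array: measurements are simulated on a grid refined by
## `fine_factor` (so the inversion never sees its own discretization -- the
## standard inverse-crime precaution) and perturbed by i.i.d. complex
## Gaussian noise relative to each measurement's magnitude.

#' Specify a synthetic phantom experiment
#'
#' @param background bath [dielectric_properties()].
#' @param inclusions list of inclusions, each a list with `center` (numeric
#'   `c(x, y)`, m), `radius` (m), `eps_r`, `sigma`.
#' @param frequency operating frequency (Hz).
#' @param noise_level relative standard deviation of the complex Gaussian
#'   measurement noise.
#' @param fine_factor grid-refinement factor for data simulation (integer
#'   >= 1; >= 2 recommended to avoid the inverse crime).
#' @param seed RNG seed for the noise (byte-identical outputs under a fixed
#'   seed).
#' @return an object of class `mwt_phantom`.
#' @examples
#' ph <- phantom_spec(
#'   background = dielectric_properties(20.9, 1.35),
#'   inclusions = list(list(center = c(-0.039, 0.026), radius = 0.02,
#'                          eps_r = 16.9, sigma = 1.15)),
#'   frequency = 1500e6)
#' @export
phantom_spec <- function(background, inclusions = list(), frequency,
                         noise_level = 0.01, fine_factor = 2L, seed = 1L) {
  stopifnot(inherits(background, "mwt_props"))
  for (inc in inclusions) {
    if (!all(c("center", "radius", "eps_r", "sigma") %in% names(inc)))
      stop("each inclusion needs center, radius, eps_r, sigma")
    if (inc$radius <= 0) stop("inclusion radius must be positive")
  }
  if (fine_factor < 1 || fine_factor != round(fine_factor))
    stop("fine_factor must be a positive integer")
  structure(list(background = background, inclusions = inclusions,
                 frequency = frequency, noise_level = noise_level,
                 fine_factor = as.integer(fine_factor),
                 seed = as.integer(seed)),
            class = "mwt_phantom")
}

#' @export
print.mwt_phantom <- function(x, ...) {
  cat(sprintf("Synthetic phantom at %.4g MHz: bath eps_r = %g, sigma = %g S/m; %d inclusion(s)\n",
              x$frequency / 1e6, x$background$eps_r, x$background$sigma,
              length(x$inclusions)))
  for (inc in x$inclusions)
    cat(sprintf("  disk r = %.3g cm at (%.3g, %.3g) cm: eps_r = %g, sigma = %g S/m\n",
                inc$radius * 100, inc$center[1] * 100, inc$center[2] * 100,
                inc$eps_r, inc$sigma))
  cat(sprintf("  noise %.3g (relative), simulation grid refined x%d, seed %d\n",
              x$noise_level, x$fine_factor, x$seed))
  invisible(x)
}

#' Property map of a phantom on an imaging zone
#'
#' With the default `membership = "node"`, a node takes an inclusion's
#' properties if and only if it lies inside that inclusion's disk (staircase
#' transitions, matching the step-wise zone).  With `membership = "area"`,
#' each node's contrast is weighted by the area fraction of its owned
#' `h x h` square inside the disk -- the discretization of choice when a
#' smooth scatterer must be represented accurately (it restores second-order
#' boundary convergence of the volume-integral solver and is what the
#' analytic-cylinder verification uses).
#'
#' @param spec an [phantom_spec()] object.
#' @param zone the imaging zone to discretize on.
#' @param membership `"node"` (staircase, default) or `"area"`
#'   (area-fraction weighting of boundary cells).
#' @return an `mwt_pmap`.
#' @export
make_property_map <- function(spec, zone, membership = c("node", "area")) {
  stopifnot(inherits(spec, "mwt_phantom"), inherits(zone, "mwt_zone"))
  membership <- match.arg(membership)
  pmap <- property_map(zone, spec$background, spec$frequency)
  h <- zone$grid$h
  for (inc in spec$inclusions) {
    if (sqrt(sum(inc$center^2)) + inc$radius > zone$radius)
      stop("inclusion extends outside the imaging zone")
    k2_inc <- complex_k2(dielectric_properties(inc$eps_r, inc$sigma),
                         spec$frequency)
    d2 <- (zone$node_x - inc$center[1])^2 +
      (zone$node_y - inc$center[2])^2
    if (membership == "node") {
      pmap$k2[d2 <= inc$radius^2] <- k2_inc
    } else {
      ## 8x8 subsampling of each node-owned square; only squares straddling
      ## the boundary need it
      rin <- max(inc$radius - h, 0)
      frac <- as.numeric(d2 <= rin^2)
      edge <- which(d2 < (inc$radius + h)^2 & d2 > rin^2)
      m <- 8L
      off <- ((seq_len(m) - 0.5) / m - 0.5) * h
      for (t in edge) {
        xs <- zone$node_x[t] + off
        ys <- zone$node_y[t] + off
        frac[t] <- mean(outer(xs - inc$center[1], ys - inc$center[2],
                              function(u, v) u^2 + v^2) <= inc$radius^2)
      }
      pmap$k2 <- pmap$k2 + frac * (k2_inc - pmap$k2_bg)
    }
  }
  pmap
}

## i.i.d. complex Gaussian noise, relative to per-measurement magnitude
.add_complex_noise <- function(value, level) {
  if (level == 0) return(value)
  n <- length(value)
  value + level * Mod(value) *
    complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)) / sqrt(2)
}

#' Simulate a phantom measurement experiment
#'
#' Simulates the two measured conditions of a tank experiment -- homogeneous
#' (bath only) and inhomogeneous (bath + phantom) -- with the discrete-dipole
#' solver on a grid refined by `spec$fine_factor`, then adds relative complex
#' Gaussian noise under `spec$seed`.
#'
#' @param spec an [phantom_spec()] object.
#' @param grid the reconstruction grid (the simulation grid is this grid
#'   refined by `spec$fine_factor`, same physical extent).
#' @param zone the reconstruction imaging zone (the simulation zone uses the
#'   same target radius on the fine grid).
#' @param array the antenna array.
#' @return list with `inhomog` and `homog` (`mwt_measurements`) and `truth`
#'   (the phantom's `mwt_pmap` on the reconstruction zone, for recovery
#'   scoring).
#' @export
simulate_measurements <- function(spec, grid, zone, array) {
  stopifnot(inherits(spec, "mwt_phantom"), inherits(grid, "mwt_grid"),
            inherits(zone, "mwt_zone"), inherits(array, "mwt_array"))
  fine_grid <- build_grid(grid$side, grid$n * spec$fine_factor)
  fine_zone <- select_imaging_zone(fine_grid, zone$radius)
  pm_inh <- make_property_map(spec, fine_zone)
  pm_hom <- property_map(fine_zone, spec$background, spec$frequency)
  k_b <- .wavenumber(pm_hom$k2_bg)
  C <- coupling_matrix(fine_zone, k_b)
  inhomog <- forward_sweep(pm_inh, fine_zone, array, coupling = C)$measurements
  homog <- forward_sweep(pm_hom, fine_zone, array, coupling = C)$measurements
  set.seed(spec$seed)
  inhomog$value <- .add_complex_noise(inhomog$value, spec$noise_level)
  homog$value <- .add_complex_noise(homog$value, spec$noise_level)
  list(inhomog = inhomog, homog = homog,
       truth = make_property_map(spec, zone))
}

#' Score the recovery of a single-inclusion phantom
#'
#' Compares a reconstruction against the phantom that generated its data:
#' the mean recovered permittivity over the true inclusion footprint, and the
#' distance (in cells) between the true inclusion centre and the centroid of
#' the recovered anomaly.  The centroid is the standard half-maximum
#' localization estimate: permittivity deviations with the true contrast's
#' sign, thresholded at half their peak (which rejects low-level ringing away
#' from the object), weight the node positions.
#'
#' @param fit an [mwt_reconstruct()] result.
#' @param spec the [phantom_spec()] that generated the data (single
#'   inclusion).
#' @return list with `mean_eps_footprint`, `true_eps`, `rel_error_eps`,
#'   `centroid` (m), `centroid_error_cells`.
#' @export
score_recovery <- function(fit, spec) {
  stopifnot(inherits(fit, "mwt_recon"), inherits(spec, "mwt_phantom"))
  if (length(spec$inclusions) != 1L)
    stop("score_recovery expects a single-inclusion phantom")
  inc <- spec$inclusions[[1L]]
  zone <- fit$zone
  foot <- (zone$node_x - inc$center[1])^2 +
    (zone$node_y - inc$center[2])^2 <= inc$radius^2
  mean_eps <- mean(fit$eps_r[foot])
  sgn <- sign(inc$eps_r - spec$background$eps_r)
  w <- pmax(sgn * (fit$eps_r - spec$background$eps_r), 0)
  w[w < max(w) / 2] <- 0               # half-maximum support

  if (sum(w) == 0) {
    centroid <- c(NA_real_, NA_real_)
    cent_err <- Inf
  } else {
    centroid <- c(sum(w * zone$node_x), sum(w * zone$node_y)) / sum(w)
    cent_err <- sqrt(sum((centroid - inc$center)^2)) / zone$grid$h
  }
  list(mean_eps_footprint = mean_eps,
       true_eps = inc$eps_r,
       rel_error_eps = (mean_eps - inc$eps_r) / inc$eps_r,
       centroid = centroid,
       centroid_error_cells = cent_err)
}
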