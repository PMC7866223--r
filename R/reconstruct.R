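## Gauss-Newton image reconstruction in log-magnitude/phase form.
## The data vector is gamma = ln|E| + j*phi (phase unwrapped along the
## receiver sequence of each transmitter); measured data are calibrated by
## subtracting the homogeneous-tank measurement in the log domain and
## re-basing onto the model's homogeneous prediction.  Updates solve the
## Levenberg-Marquardt-regularized normal equations in complex arithmetic,
## and iteration stops when the relative residual decrease falls below
## `stop_delta` (default 1e-3).

#' Log-magnitude/phase transform of a measurement set
#'
#' Maps each complex transmission value to `ln|E| + j phi`, with the phase
#' unwrapped along the receiver sequence of each transmitter (2-pi jump
#' correction; [signal::unwrap()]).
#'
#' @param m an `mwt_measurements` data frame ([forward_sweep()],
#'   [read_measurements()]).
#' @return complex vector in measurement row order.
#' @export
log_measurements <- function(m) {
  stopifnot(inherits(m, "mwt_measurements"))
  if (any(Mod(m$value) == 0))
    stop("zero-magnitude measurement; cannot take logarithm")
  gamma <- complex(nrow(m))
  for (s in unique(m$s)) {
    idx <- which(m$s == s)
    v <- m$value[idx]
    gamma[idx] <- complex(real = log(Mod(v)),
                          imaginary = signal::unwrap(Arg(v)))
  }
  gamma
}

#' Calibrate phantom measurements against the homogeneous tank
#'
#' Forms the calibrated log-domain data
#' `gamma_cal = [log(inhomog) - log(homog)] + log(computed_homog)`:
#' the measured perturbation caused by the phantom, re-based onto the model's
#' prediction for the homogeneous tank, so that antenna and system factors
#' common to both measured conditions cancel.
#'
#' @param inhomog measured data with the phantom present.
#' @param homog measured data for the homogeneous tank.
#' @param computed_homog the model's prediction for the homogeneous tank
#'   (same geometry and background used to reconstruct).
#' @return an object of class `mwt_caldata`: `gamma` (complex vector),
#'   `pairs` (the `(s, r)` table), and acquisition metadata.
#' @export
calibrate <- function(inhomog, homog, computed_homog) {
  for (m in list(inhomog, homog, computed_homog))
    stopifnot(inherits(m, "mwt_measurements"))
  if (!identical(inhomog[c("s", "r")], homog[c("s", "r")]) ||
      !identical(inhomog[c("s", "r")], computed_homog[c("s", "r")]))
    stop("measurement sets must share one (s, r) ordering")
  gamma <- log_measurements(inhomog) - log_measurements(homog) +
    log_measurements(computed_homog)
  structure(list(
    gamma = gamma,
    pairs = inhomog[c("s", "r")],
    frequency = attr(inhomog, "frequency"),
    n_antennas = attr(inhomog, "n_antennas")
  ), class = "mwt_caldata")
}

#' @export
print.mwt_caldata <- function(x, ...) {
  cat(sprintf("Calibrated log-domain data: %d (s, r) pairs, %d antennas\n",
              length(x$gamma), x$n_antennas))
  invisible(x)
}

#' Regularized Gauss-Newton update
#'
#' Solves the Levenberg-Marquardt normal equations
#' `(J^H J + lambda * scale * I) delta = J^H residual`, where `scale` is the
#' mean diagonal of `J^H J` so that `lambda` is a relative regularization
#' level.
#'
#' @param J_log log-transformed Jacobian ([log_transform_jacobian()]).
#' @param residual complex residual vector `gamma_cal - gamma_computed`.
#' @param lambda relative regularization parameter (> 0 in practice; at 0 the
#'   normal matrix of an underdetermined problem is singular and the solve
#'   fails with a conditioning diagnostic).
#' @return complex update vector `delta k^2` over the zone nodes.
#' @export
gauss_newton_update <- function(J_log, residual, lambda) {
  stopifnot(inherits(J_log, "mwt_jacobian"))
  if (!identical(attr(J_log, "domain"), "log-transformed"))
    stop("gauss_newton_update expects a log-transformed Jacobian")
  if (length(residual) != nrow(J_log))
    stop("residual length must equal the number of Jacobian rows")
  if (lambda < 0) stop("lambda must be nonnegative")
  Jh <- Conj(t(unclass(J_log)))
  H <- Jh %*% unclass(J_log)
  scale <- mean(Re(diag(H)))
  as.vector(solve(H + diag(lambda * scale, ncol(J_log)), Jh %*% residual))
}

#' Relative residual-error sequence
#'
#' Normalizes a sequence of residual L2 norms to its first entry, the
#' convergence diagnostic tracked across reconstruction iterations.
#'
#' @param residual_norms numeric vector of per-iteration residual norms.
#' @return numeric vector with first element 1.
#' @export
relative_error <- function(residual_norms) {
  if (!length(residual_norms)) stop("empty residual-norm sequence")
  if (residual_norms[1] == 0) stop("zero first-iteration residual norm")
  residual_norms / residual_norms[1]
}

#' Reconstruction control parameters
#'
#' @param max_iterations iteration cap.
#' @param stop_delta stop when the decrease in relative error between
#'   consecutive iterations falls below this value (default `1e-3`).
#' @param lambda0 initial relative Levenberg-Marquardt parameter.
#' @param lm_decay geometric decay factor applied to lambda each iteration
#'   (in (0, 1]).
#' @param step_clamp optional bound on `max |delta k^2| / |k_b^2|` per
#'   iteration; `NULL` disables clamping.
#' @return list of class `mwt_control`.
#' @export
mwt_control <- function(max_iterations = 25L, stop_delta = 1e-3,
                        lambda0 = 0.1, lm_decay = 0.9, step_clamp = NULL) {
  stopifnot(max_iterations >= 1, stop_delta > 0, lambda0 >= 0,
            lm_decay > 0, lm_decay <= 1)
  structure(list(max_iterations = as.integer(max_iterations),
                 stop_delta = stop_delta, lambda0 = lambda0,
                 lm_decay = lm_decay, step_clamp = step_clamp),
            class = "mwt_control")
}

## project k^2 back to the physical cone: eps_r >= 1, sigma >= 0
.clamp_k2 <- function(k2, frequency) {
  pr <- .k2_to_props(k2, frequency)
  omega <- 2 * pi * frequency
  complex(real = omega^2 * MU0 * EPS0 * pmax(pr$eps_r, 1),
          imaginary = -omega * MU0 * pmax(pr$sigma, 0))
}

#' Gauss-Newton microwave tomographic reconstruction
#'
#' Iteratively fits the complex squared-wavenumber image over the imaging
#' zone to calibrated log-magnitude/phase data.  Each iteration performs one
#' forward sweep (`ns` solves sharing one factorization), assembles the
#' nodal-adjoint Jacobian from the same field solutions (one vector product
#' per row), log-transforms it, and applies a Levenberg-Marquardt-regularized
#' Gauss-Newton update.  The starting image is the homogeneous background.
#'
#' @param calibrated an [calibrate()]d data object (`mwt_caldata`).
#' @param zone,array scene geometry (the same used for the model prediction
#'   inside the calibration).
#' @param frequency frequency (Hz).
#' @param background bath [dielectric_properties()]; also the starting image.
#' @param control an [mwt_control()] list.
#' @return an object of class `mwt_recon` with, among others, `eps_r` and
#'   `sigma` (final images over zone nodes), `errors` (relative residual per
#'   iteration, first = 1), `iterations`, `converged`, `history`
#'   (per-iteration images), and the final log-domain residual.  Standard
#'   methods are available: [print()], [summary()], [coef()], [predict()],
#'   [residuals()], [fitted()], [plot()], [simulate()].
#' @export
mwt_reconstruct <- function(calibrated, zone, array, frequency, background,
                            control = mwt_control()) {
  stopifnot(inherits(calibrated, "mwt_caldata"), inherits(zone, "mwt_zone"),
            inherits(array, "mwt_array"), inherits(control, "mwt_control"))
  .validate_scene(zone, array)
  if (length(calibrated$gamma) != array$n * (array$n - 1L))
    stop("calibrated data size does not match the antenna array")

  pmap <- property_map(zone, background, frequency)
  k_b <- .wavenumber(pmap$k2_bg)
  C <- coupling_matrix(zone, k_b)
  lambda <- control$lambda0
  errors <- numeric(0)
  norms <- numeric(0)
  history <- list()
  converged <- FALSE
  diverged <- FALSE
  n_increase <- 0L
  sw <- NULL

  for (i in seq_len(control$max_iterations)) {
    sw <- forward_sweep(pmap, zone, array, coupling = C)
    gamma_comp <- log_measurements(sw$measurements)
    resid <- calibrated$gamma - gamma_comp
    norms[i] <- sqrt(sum(Mod(resid)^2))
    if (norms[1L] == 0) {          # data identical to the starting model
      errors <- numeric(i)
      converged <- TRUE
      break
    }
    errors <- relative_error(norms)
    if (i > 1L) {
      if (abs(errors[i] - errors[i - 1L]) < control$stop_delta) {
        converged <- TRUE
        break
      }
      if (errors[i] > errors[i - 1L]) {
        n_increase <- n_increase + 1L
        if (n_increase >= 3L) {
          diverged <- TRUE
          warning("reconstruction diverging: relative error grew for 3 consecutive iterations")
          break
        }
      } else n_increase <- 0L
    }
    if (norms[i] == 0) { converged <- TRUE; break }

    J <- jacobian_matrix(sw$fields, zone, array, frequency)
    J_log <- log_transform_jacobian(J, sw$measurements$value)
    delta <- gauss_newton_update(J_log, resid, lambda)
    if (!is.null(control$step_clamp)) {
      mx <- max(Mod(delta)) / Mod(pmap$k2_bg)
      if (mx > control$step_clamp) delta <- delta * control$step_clamp / mx
    }
    pmap$k2 <- .clamp_k2(pmap$k2 + delta, frequency)
    lambda <- lambda * control$lm_decay
    pr <- .k2_to_props(pmap$k2, frequency)
    history[[i]] <- list(eps_r = pr$eps_r, sigma = pr$sigma)
  }

  ## make fitted values refer to the final image (a last sweep is needed only
  ## if the loop ended right after an update)
  updated_since_sweep <- length(history) == length(errors)
  if (updated_since_sweep) {
    sw <- forward_sweep(pmap, zone, array, coupling = C)
    gamma_comp <- log_measurements(sw$measurements)
    resid <- calibrated$gamma - gamma_comp
  }

  pr <- .k2_to_props(pmap$k2, frequency)
  structure(list(
    eps_r = pr$eps_r,
    sigma = pr$sigma,
    k2 = pmap$k2,
    errors = errors,
    iterations = length(errors),
    converged = converged,
    diverged = diverged,
    history = history,
    fitted_log = gamma_comp,
    residual_log = resid,
    measurements_fit = sw$measurements,
    calibrated = calibrated,
    zone = zone,
    array = array,
    frequency = frequency,
    background = background,
    control = control,
    call = match.call()
  ), class = "mwt_recon")
}

#' @export
print.mwt_recon <- function(x, ...) {
  cat("Microwave tomographic reconstruction (log-magnitude/phase Gauss-Newton)\n")
  cat(sprintf("  %d antennas, %d unknown nodes, %.4g MHz\n",
              x$array$n, x$zone$n_nodes, x$frequency / 1e6))
  cat(sprintf("  %d iterations; %s; relative error %.4g\n",
              x$iterations,
              if (x$converged) "converged (stopping rule met)"
              else if (x$diverged) "DIVERGED" else "stopped at iteration cap",
              x$errors[x$iterations]))
  cat(sprintf("  eps_r in [%.3g, %.3g]; sigma in [%.3g, %.3g] S/m\n",
              min(x$eps_r), max(x$eps_r), min(x$sigma), max(x$sigma)))
  invisible(x)
}

#' @export
summary.mwt_recon <- function(object, ...) {
  structure(list(
    iterations = object$iterations,
    converged = object$converged,
    diverged = object$diverged,
    errors = object$errors,
    eps_r = summary(object$eps_r),
    sigma = summary(object$sigma),
    n_nodes = object$zone$n_nodes,
    n_measurements = length(object$calibrated$gamma),
    frequency = object$frequency,
    background = object$background
  ), class = "summary.mwt_recon")
}

#' @export
print.summary.mwt_recon <- function(x, ...) {
  cat(sprintf("Reconstruction of %d nodes from %d measurements at %.4g MHz\n",
              x$n_nodes, x$n_measurements, x$frequency / 1e6))
  cat(sprintf("Background: eps_r = %g, sigma = %g S/m\n",
              x$background$eps_r, x$background$sigma))
  cat(sprintf("%d iterations (%s)\n", x$iterations,
              if (x$converged) "converged" else if (x$diverged) "diverged"
              else "iteration cap"))
  cat("Relative error by iteration:\n")
  print(round(x$errors, 4))
  cat("Recovered eps_r:\n"); print(x$eps_r)
  cat("Recovered sigma (S/m):\n"); print(x$sigma)
  invisible(x)
}

#' @export
coef.mwt_recon <- function(object, ...) {
  cbind(eps_r = object$eps_r, sigma = object$sigma)
}

#' @export
fitted.mwt_recon <- function(object, ...) object$fitted_log

#' @export
residuals.mwt_recon <- function(object, ...) object$residual_log

#' Predicted measurements of a fitted reconstruction
#'
#' @param object an `mwt_recon` fit.
#' @param type `"log"` for the complex log-domain prediction (default),
#'   `"field"` for the raw complex transmission values.
#' @param ... unused.
#' @return for `"log"`, a complex vector in measurement order; for
#'   `"field"`, the `mwt_measurements` data frame predicted by the final
#'   image.
#' @export
predict.mwt_recon <- function(object, type = c("log", "field"), ...) {
  type <- match.arg(type)
  if (type == "log") object$fitted_log else object$measurements_fit
}

#' Plot reconstructed property images
#'
#' Draws the relative permittivity and conductivity images on the grid
#' (out-of-zone pixels blank), using base graphics.
#'
#' @param x an `mwt_recon` fit.
#' @param which `"both"`, `"eps_r"` or `"sigma"`.
#' @param ... passed to [graphics::image()].
#' @export
plot.mwt_recon <- function(x, which = c("both", "eps_r", "sigma"), ...) {
  which <- match.arg(which)
  panels <- if (which == "both") c("eps_r", "sigma") else which
  if (length(panels) == 2L) {
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old))
  }
  n <- x$zone$grid$n
  coords <- x$zone$grid$node_coord
  for (p in panels) {
    img <- matrix(NA_real_, n + 1L, n + 1L)
    img[cbind(x$zone$node_i + 1L, x$zone$node_j + 1L)] <- x[[p]]
    graphics::image(coords, coords, img, asp = 1,
                    xlab = "x (m)", ylab = "y (m)",
                    main = if (p == "eps_r") "Relative permittivity"
                    else "Conductivity (S/m)",
                    col = grDevices::hcl.colors(64, "viridis"), ...)
    graphics::points(x$array$x, x$array$y, pch = 4)
  }
  invisible(x)
}

#' Simulate measurement sets from a fitted image
#'
#' Runs the forward model at the reconstructed property map and adds i.i.d.
#' complex Gaussian noise relative to each measurement magnitude, giving
#' parametric-bootstrap style replicates of the experiment.
#'
#' @param object an `mwt_recon` fit.
#' @param nsim number of replicate measurement sets.
#' @param seed optional RNG seed.
#' @param noise_level relative noise standard deviation.
#' @param ... unused.
#' @return list of `mwt_measurements` data frames.
#' @export
simulate.mwt_recon <- function(object, nsim = 1, seed = NULL,
                               noise_level = 0.01, ...) {
  if (!is.null(seed)) set.seed(seed)
  base <- object$measurements_fit
  lapply(seq_len(nsim), function(k) {
    out <- base
    out$value <- .add_complex_noise(base$value, noise_level)
    out
  })
}
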