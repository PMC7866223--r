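# Log-domain measurement transform, homogeneous-tank calibration, the
# regularized Gauss-Newton update, and full iterative reconstructions on
# synthetic data.

test_that("relative error normalizes to the first iteration", {
  expect_equal(relative_error(c(4, 2, 1)), c(1, 0.5, 0.25))
  expect_equal(relative_error(c(3, 3, 3)), c(1, 1, 1))
  set.seed(2)
  x <- runif(6, 0.1, 5)
  expect_equal(relative_error(x)[1], 1)
  expect_error(relative_error(numeric(0)), "empty")
  expect_error(relative_error(c(0, 1)), "zero")
})

test_that("log transform of measurements unwraps phase per transmitter", {
  sc <- tiny_scene()
  m <- tiny_homog_sweep()$measurements
  gamma <- log_measurements(m)
  expect_equal(Re(gamma), log(Mod(m$value)), tolerance = 1e-12)
  # unwrapped phase never jumps by more than pi between adjacent receivers
  for (s in 1:8) {
    ph <- Im(gamma[m$s == s])
    expect_true(all(abs(diff(ph)) <= pi + 1e-9))
  }
  # hand-built set: unit values map to zero, modulus e to unit log magnitude
  mm <- m[m$s == 1, ]
  mm$value <- rep(exp(1) + 0i, nrow(mm))
  attr(mm, "n_antennas") <- 8L
  class(mm) <- class(m)
  expect_equal(Re(log_measurements(mm)), rep(1, nrow(mm)), tolerance = 1e-12)
  expect_equal(Im(log_measurements(mm)), rep(0, nrow(mm)), tolerance = 1e-12)
  mm$value[3] <- 0i
  expect_error(log_measurements(mm), "zero")
})

test_that("calibration identities: no phantom, and a perfect model", {
  m <- tiny_homog_sweep()$measurements
  set.seed(5)
  pert <- m
  pert$value <- m$value * exp(complex(real = rnorm(nrow(m), 0, 0.05),
                                      imaginary = rnorm(nrow(m), 0, 0.05)))
  # inhomog == homog: calibrated data is exactly the model's prediction
  expect_identical(calibrate(pert, pert, m)$gamma, log_measurements(m))
  # computed == homog: calibrated data is exactly the measured inhomog
  expect_equal(calibrate(pert, m, m)$gamma, log_measurements(pert),
               tolerance = 1e-12)
  bad <- m[order(m$r, m$s), ]
  class(bad) <- class(m)
  expect_error(calibrate(pert, bad, m), "ordering")
})

test_that("Gauss-Newton update: zero residual, ridge limit, scalar closed form", {
  sc <- tiny_scene()
  fs <- tiny_homog_sweep()
  J <- jacobian_matrix(fs$fields, sc$zone, sc$array, sc$frequency)
  Jlog <- log_transform_jacobian(J, fs$measurements$value)
  expect_equal(gauss_newton_update(Jlog, complex(nrow(J)), 0.1),
               complex(ncol(J)), tolerance = 1e-15)
  set.seed(3)
  r <- complex(real = rnorm(nrow(J)), imaginary = rnorm(nrow(J)))
  norms <- vapply(c(0.1, 1, 10, 100, 1e4),
                  function(l) sqrt(sum(Mod(gauss_newton_update(Jlog, r, l))^2)),
                  numeric(1))
  expect_true(all(diff(norms) < 0))
  # single measurement, single unknown: delta = conj(J) r / (|J|^2 (1 + lambda))
  j1 <- structure(matrix(0.3 - 0.4i, 1, 1), class = c("mwt_jacobian", "matrix"),
                  domain = "log-transformed")
  lam <- 0.25
  got <- gauss_newton_update(j1, 2 + 1i, lam)
  expect_equal(got, Conj(0.3 - 0.4i) * (2 + 1i) / (Mod(0.3 - 0.4i)^2 * (1 + lam)),
               tolerance = 1e-12)
})

test_that("data from the homogeneous background stop immediately at the background image", {
  sc <- tiny_scene()
  m <- tiny_homog_sweep()$measurements
  cal <- calibrate(m, m, m)
  fit <- suppressWarnings(
    mwt_reconstruct(cal, sc$zone, sc$array, sc$frequency, sc$background))
  expect_true(fit$converged)
  expect_identical(fit$iterations, 1L)
  expect_equal(fit$eps_r, rep(sc$background$eps_r, sc$zone$n_nodes),
               tolerance = 1e-9)
  expect_equal(fit$sigma, rep(sc$background$sigma, sc$zone$n_nodes),
               tolerance = 1e-9)
})

test_that("noiseless same-grid data are reconstructed below 5% error within 20 iterations", {
  # deliberate inverse crime, exercising the full loop machinery
  bg <- dielectric_properties(20.9, 1.35)
  f <- 1500e6
  g <- build_grid(0.25, 32)
  z <- select_imaging_zone(g, 0.0698)
  a <- build_antenna_array(16, 0.152)
  ph <- phantom_spec(bg, list(list(center = c(-0.03, 0.02), radius = 0.02,
                                   eps_r = 19, sigma = 1.25)), f,
                     noise_level = 0, fine_factor = 1L, seed = 9)
  pm <- make_property_map(ph, z)
  inh <- suppressWarnings(forward_sweep(pm, z, a))$measurements
  hom <- suppressWarnings(
    forward_sweep(property_map(z, bg, f), z, a))$measurements
  cal <- calibrate(inh, hom, hom)
  reset_counters()
  fit <- suppressWarnings(
    mwt_reconstruct(cal, z, a, f, bg, mwt_control(max_iterations = 20)))
  expect_lt(min(fit$errors), 0.05)
  expect_equal(fit$errors[1], 1)
  # per-iteration cost: ns solves per sweep, ns*nr Jacobian rows per update
  cnt <- mwt_counters()
  # one sweep per iteration, plus a final one only if the loop ended on an update
  n_sweeps <- fit$iterations + as.integer(length(fit$history) == fit$iterations)
  expect_identical(cnt$forward_solves, 16L * n_sweeps)
  expect_identical(cnt$jacobian_rows, 240L * length(fit$history))
  # recovery of the low-contrast inclusion
  sc2 <- score_recovery(fit, ph)
  expect_lt(abs(sc2$rel_error_eps), 0.05)
  expect_lt(sc2$centroid_error_cells, 1)
})

test_that("diverging iterations abort with a diagnostic", {
  sc <- tiny_scene()
  m <- tiny_homog_sweep()$measurements
  # corrupt the calibrated data so no consistent image exists at huge contrast
  cal <- calibrate(m, m, m)
  set.seed(1)
  cal$gamma <- cal$gamma + complex(real = rnorm(length(cal$gamma), 0, 3),
                                   imaginary = rnorm(length(cal$gamma), 0, 3))
  fit <- suppressWarnings(
    mwt_reconstruct(cal, sc$zone, sc$array, sc$frequency, sc$background,
                    mwt_control(max_iterations = 12, lambda0 = 1e-4)))
  expect_true(fit$diverged || fit$converged || fit$iterations == 12L)
  expect_true(all(is.finite(fit$errors)))
})

test_that("fit object methods expose coefficients, residuals and predictions coherently", {
  bg <- dielectric_properties(20.9, 1.35)
  f <- 1500e6
  g <- build_grid(0.25, 24)
  z <- select_imaging_zone(g, 0.0698)
  a <- build_antenna_array(8, 0.152)
  ph <- phantom_spec(bg, list(list(center = c(-0.025, 0.02), radius = 0.018,
                                   eps_r = 19.5, sigma = 1.3)), f,
                     noise_level = 0, fine_factor = 1L, seed = 4)
  pm <- make_property_map(ph, z)
  inh <- suppressWarnings(forward_sweep(pm, z, a))$measurements
  hom <- suppressWarnings(
    forward_sweep(property_map(z, bg, f), z, a))$measurements
  cal <- calibrate(inh, hom, hom)
  fit <- suppressWarnings(
    mwt_reconstruct(cal, z, a, f, bg, mwt_control(max_iterations = 8)))
  cf <- coef(fit)
  expect_equal(dim(cf), c(z$n_nodes, 2L))
  expect_identical(colnames(cf), c("eps_r", "sigma"))
  expect_true(all(cf[, "eps_r"] >= 1) && all(cf[, "sigma"] >= 0))
  expect_equal(residuals(fit), cal$gamma - fitted(fit), tolerance = 1e-12)
  expect_identical(predict(fit), fitted(fit))
  pm_fit <- predict(fit, type = "field")
  expect_s3_class(pm_fit, "mwt_measurements")
  expect_equal(log_measurements(pm_fit), fitted(fit), tolerance = 1e-9)
  sims <- suppressWarnings(simulate(fit, nsim = 2, seed = 10, noise_level = 0.02))
  expect_length(sims, 2L)
  expect_false(identical(sims[[1]]$value, sims[[2]]$value))
  expect_output(print(fit), "iterations")
  expect_output(print(summary(fit)), "Relative error")
  tf <- tempfile(fileext = ".png")
  grDevices::png(tf); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tf))
  unlink(tf)
})
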