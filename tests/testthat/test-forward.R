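# Discrete-dipole forward solver: exact identities (no scatterer,
# reciprocity, linearity), agreement between the dense and matrix-free
# solution paths, measurement bookkeeping, and accuracy against the analytic
# dielectric-cylinder series.

test_that("zero contrast returns the incident field exactly, at nodes and antennas", {
  sw <- tiny_homog_sweep()
  for (f in sw$fields[c(1, 4)]) {
    expect_identical(f$E_nodes, f$E_inc_nodes)
    expect_identical(f$E_antennas, f$E_inc_antennas)
  }
})

test_that("measurement table covers every ordered pair once, in s-then-r order", {
  sw <- tiny_homog_sweep()
  m <- sw$measurements
  expect_equal(nrow(m), 8 * 7)
  expect_true(all(m$s != m$r))
  expect_identical(m$s, rep(1:8, each = 7L))
  expect_false(any(duplicated(paste(m$s, m$r))))
  # 3 antennas give n(n-1) = 6 rows
  sc <- tiny_scene()
  a3 <- build_antenna_array(3, 0.152)
  pm <- property_map(sc$zone, sc$background, sc$frequency)
  m3 <- suppressWarnings(forward_sweep(pm, sc$zone, a3))$measurements
  expect_equal(nrow(m3), 6)
})

test_that("measurements are reciprocal for a random phantom and scale linearly with amplitude", {
  sc <- tiny_scene()
  set.seed(7)
  pm <- property_map(sc$zone, sc$background, sc$frequency)
  # random smooth-ish contrast bounded by ~20% of background
  pm$k2 <- pm$k2 * (1 + 0.2 * complex(real = runif(sc$zone$n_nodes, -1, 1),
                                      imaginary = runif(sc$zone$n_nodes, -1, 0)))
  m <- suppressWarnings(forward_sweep(pm, sc$zone, sc$array))$measurements
  swap <- match(paste(m$r, m$s), paste(m$s, m$r))
  expect_lt(max_rel(m$value, m$value[swap]), 1e-10)
  a2 <- build_antenna_array(sc$array$n, sc$array$diameter, amplitude = 2)
  m2 <- suppressWarnings(forward_sweep(pm, sc$zone, a2))$measurements
  expect_lt(max_rel(m2$value, 2 * m$value), 1e-12)
})

test_that("matrix-free iterative solve agrees with the dense factorization", {
  sc <- tiny_scene()
  ph <- phantom_spec(sc$background,
                     list(list(center = c(-0.03, 0.02), radius = 0.02,
                               eps_r = 18, sigma = 1.2)),
                     sc$frequency)
  pm <- make_property_map(ph, sc$zone)
  fd <- suppressWarnings(solve_total_field(pm, sc$zone, sc$array, 2,
                                           method = "direct"))
  fi <- suppressWarnings(solve_total_field(pm, sc$zone, sc$array, 2,
                                           method = "iterative"))
  expect_lt(max_rel(fi$E_nodes, fd$E_nodes), 1e-8)
  expect_lt(max_rel(fi$E_antennas[-2], fd$E_antennas[-2]), 1e-8)
})

test_that("scattered field of a dielectric cylinder matches the analytic series within 2%", {
  # tank-experiment condition; default grid is ~lambda/10 in the bath
  bg <- dielectric_properties(20.9, 1.35)
  obj <- dielectric_properties(16.9, 1.15)
  f <- 1500e6
  g <- build_grid(0.25, 64)
  z <- select_imaging_zone(g, 0.0698)
  a <- build_antenna_array(16, 0.152)
  ctr <- c(-0.025, 0.015)
  ph <- phantom_spec(bg, list(list(center = ctr, radius = 0.02,
                                   eps_r = obj$eps_r, sigma = obj$sigma)), f)
  pm <- make_property_map(ph, z, membership = "area")
  s <- 1
  sol <- solve_total_field(pm, z, a, s)
  k_b <- mwtomo:::.wavenumber(complex_k2(bg, f))
  inc <- incident_field(a, s, a$x[-s], a$y[-s], k_b, f)
  ana <- cylinder_field(bg, obj, f, ctr, 0.02, c(a$x[s], a$y[s]),
                        a$x[-s], a$y[-s])
  expect_lt(rel_l2(sol$E_antennas[-s] - inc, ana - inc), 0.02)
  # oracle self-check: with zero contrast the analytic total field is incident
  ana0 <- cylinder_field(bg, bg, f, ctr, 0.02, c(a$x[s], a$y[s]),
                         a$x[-s], a$y[-s])
  expect_lt(max_rel(ana0, inc), 1e-10)
})

test_that("halving the cell size reduces the cylinder discrepancy", {
  bg <- dielectric_properties(20.9, 1.35)
  obj <- dielectric_properties(16.9, 1.15)
  f <- 1500e6
  a <- build_antenna_array(16, 0.152)
  ctr <- c(-0.025, 0.015)
  ph <- phantom_spec(bg, list(list(center = ctr, radius = 0.02,
                                   eps_r = obj$eps_r, sigma = obj$sigma)), f)
  k_b <- mwtomo:::.wavenumber(complex_k2(bg, f))
  s <- 1
  inc_ref <- NULL
  errs <- vapply(c(48L, 96L), function(n) {
    g <- build_grid(0.25, n)
    z <- select_imaging_zone(g, 0.0698)
    pm <- suppressWarnings(make_property_map(ph, z, membership = "area"))
    sol <- suppressWarnings(solve_total_field(pm, z, a, s))
    inc <- incident_field(a, s, a$x[-s], a$y[-s], k_b, f)
    ana <- cylinder_field(bg, obj, f, ctr, 0.02, c(a$x[s], a$y[s]),
                          a$x[-s], a$y[-s])
    rel_l2(sol$E_antennas[-s] - inc, ana - inc)
  }, numeric(1))
  expect_lt(errs[2], errs[1] / 2)
})
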