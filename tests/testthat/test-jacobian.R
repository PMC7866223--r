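# Collapsed nodal-adjoint Jacobian: equivalence with the general dual-mesh
# quadrature, agreement with central finite differences, reciprocity,
# bilinearity, the log-domain transform, and the operation-count structure.

fig_sweep <- function() {
  if (is.null(.cache$fig_sweep)) {
    sc <- tiny_scene()
    cond <- fig_condition()
    pm <- property_map(sc$zone, cond$background, cond$frequency)
    .cache$fig_sweep <- list(
      pm = pm,
      sweep = suppressWarnings(forward_sweep(pm, sc$zone, sc$array)))
  }
  .cache$fig_sweep
}

test_that("collapsed rows equal the general quadrature rows to machine precision", {
  sc <- tiny_scene()
  fs <- fig_sweep()
  f <- fig_condition()$frequency
  for (pair in list(c(1, 2), c(3, 7), c(5, 4))) {
    rc <- jacobian_row_collapsed(fs$sweep$fields[[pair[1]]],
                                 fs$sweep$fields[[pair[2]]], sc$zone, f)
    rg <- jacobian_row_general(fs$sweep$fields[[pair[1]]],
                               fs$sweep$fields[[pair[2]]], sc$zone, f)
    expect_lt(max_rel(rg, rc), 1e-12)
  }
})

test_that("adjoint entries match central finite differences of the received field", {
  sc <- tiny_scene()
  fs <- fig_sweep()
  f <- fig_condition()$frequency
  J <- jacobian_matrix(fs$sweep$fields, sc$zone, sc$array, f)
  interior <- which(abs(sc$zone$node_area - 4 * sc$grid$h^2) < 1e-18)
  set.seed(11)
  taus <- sample(interior, 4)
  delta <- 1e-4 * Mod(fs$pm$k2_bg)
  for (tau in taus) {
    fd <- suppressWarnings(
      finite_difference_jacobian_column(fs$pm, sc$zone, sc$array, tau, delta))
    expect_lt(max_rel(J[, tau], fd), 1e-3)
  }
  expect_error(
    finite_difference_jacobian_column(fs$pm, sc$zone, sc$array,
                                      sc$zone$n_nodes + 5L, delta),
    "outside")
})

test_that("finite differences converge at second order in the step size", {
  sc <- tiny_scene()
  fs <- fig_sweep()
  f <- fig_condition()$frequency
  interior <- which(abs(sc$zone$node_area - 4 * sc$grid$h^2) < 1e-18)
  tau <- interior[20]
  J <- jacobian_matrix(fs$sweep$fields, sc$zone, sc$array, f)
  deltas <- c(1e-2, 1e-3) * Mod(fs$pm$k2_bg)
  errs <- vapply(deltas, function(d) {
    fd <- suppressWarnings(
      finite_difference_jacobian_column(fs$pm, sc$zone, sc$array, tau, d))
    max(Mod(fd - J[, tau]))
  }, numeric(1))
  order <- log10(errs[1] / errs[2])
  expect_gt(order, 1.6)
  expect_lt(order, 2.4)
})

test_that("rows are reciprocal bitwise and bilinear in the two fields", {
  sc <- tiny_scene()
  fs <- fig_sweep()
  f <- fig_condition()$frequency
  Es <- fs$sweep$fields[[2]]
  Er <- fs$sweep$fields[[6]]
  expect_identical(jacobian_row_collapsed(Es, Er, sc$zone, f),
                   jacobian_row_collapsed(Er, Es, sc$zone, f))
  # zero field gives a zero row; scaling both fields scales the row by c^2
  E0 <- Es; E0$E_nodes <- complex(sc$zone$n_nodes)
  expect_identical(jacobian_row_collapsed(E0, Er, sc$zone, f),
                   complex(sc$zone$n_nodes))
  E2s <- Es; E2s$E_nodes <- 3 * Es$E_nodes
  E2r <- Er; E2r$E_nodes <- 3 * Er$E_nodes
  expect_equal(jacobian_row_general(E2s, E2r, sc$zone, f),
               9 * jacobian_row_general(Es, Er, sc$zone, f),
               tolerance = 1e-12)
})

test_that("full matrix has measurement-ordered rows built without extra forward solves", {
  sc <- tiny_scene()
  fs <- fig_sweep()
  f <- fig_condition()$frequency
  reset_counters()
  J <- jacobian_matrix(fs$sweep$fields, sc$zone, sc$array, f)
  cnt <- mwt_counters()
  expect_identical(cnt$forward_solves, 0L)                 # no hidden solves
  expect_identical(cnt$jacobian_rows, 8L * 7L)             # one product per row
  expect_equal(dim(J), c(56L, sc$zone$n_nodes))
  pr <- attr(J, "pairs")
  m <- fs$sweep$measurements
  expect_identical(pr$s, m$s)
  expect_identical(pr$r, m$r)
  # row for (s, r) equals the directly computed collapsed row
  i <- which(pr$s == 4 & pr$r == 7)
  expect_identical(J[i, ],
                   jacobian_row_collapsed(fs$sweep$fields[[4]],
                                          fs$sweep$fields[[7]], sc$zone, f))
})

test_that("sensitivity is largest inside the band joining the antenna pair", {
  # the transmit/receive sensitivity map concentrates between the antennas
  sc <- default_scene()
  cond <- fig_condition()
  pm <- property_map(sc$zone, cond$background, cond$frequency)
  sw <- forward_sweep(pm, sc$zone, sc$array)
  for (pair in list(c(1, 8), c(5, 13))) {
    row <- jacobian_row_collapsed(sw$fields[[pair[1]]], sw$fields[[pair[2]]],
                                  sc$zone, cond$frequency)
    tau <- which.max(Mod(row))
    p1 <- c(sc$array$x[pair[1]], sc$array$y[pair[1]])
    p2 <- c(sc$array$x[pair[2]], sc$array$y[pair[2]])
    u <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
    v <- c(sc$zone$node_x[tau], sc$zone$node_y[tau]) - p1
    along <- sum(v * u)
    perp <- abs(v[1] * u[2] - v[2] * u[1])
    expect_gt(along, 0)
    expect_lt(along, sqrt(sum((p2 - p1)^2)))
    expect_lt(perp, 0.015)        # within 1.5 cm of the chord
  }
})

test_that("log transform divides rows by the received field and cancels source amplitude", {
  sc <- tiny_scene()
  fs <- fig_sweep()
  f <- fig_condition()$frequency
  J <- jacobian_matrix(fs$sweep$fields, sc$zone, sc$array, f)
  # unit received field leaves the matrix unchanged
  J1 <- log_transform_jacobian(J, rep(1 + 0i, nrow(J)))
  expect_equal(unclass(J1), unclass(J), ignore_attr = TRUE, tolerance = 1e-15)
  expect_identical(attr(J1, "domain"), "log-transformed")
  expect_error(log_transform_jacobian(J1, rep(1 + 0i, nrow(J))), "already")
  expect_error(log_transform_jacobian(J, complex(nrow(J))), "zero")
  # log-domain finite differences
  Jlog <- log_transform_jacobian(J, fs$sweep$measurements$value)
  interior <- which(abs(sc$zone$node_area - 4 * sc$grid$h^2) < 1e-18)
  tau <- interior[10]
  fdl <- suppressWarnings(
    finite_difference_jacobian_column(fs$pm, sc$zone, sc$array, tau,
                                      1e-4 * Mod(fs$pm$k2_bg), domain = "log"))
  expect_lt(max_rel(Jlog[, tau], fdl), 1e-3)
  # doubling the source amplitude leaves log-domain rows unchanged
  a2 <- build_antenna_array(sc$array$n, sc$array$diameter, amplitude = 2)
  sw2 <- suppressWarnings(forward_sweep(fs$pm, sc$zone, a2))
  J2 <- jacobian_matrix(sw2$fields, sc$zone, a2, f)
  J2log <- log_transform_jacobian(J2, sw2$measurements$value)
  expect_lt(max_rel(unclass(J2log), unclass(Jlog)), 1e-10)
})
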