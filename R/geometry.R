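## Geometry: uniform grid, step-wise circular imaging zone, circular antenna
## array.  All coordinates are in metres, grid indices 0-based, angles measured
## from the +x axis (counter-clockwise positive); the antenna ordering is
## clockwise starting from the bottom-centre element.

#' Build a uniform square grid
#'
#' The forward-solution and parameter grids are one and the same uniform grid
#' of `n_cells_per_side` x `n_cells_per_side` square cells centred on the
#' origin.  Node `(i, j)` (0-based) sits at `((i - n/2) h, (j - n/2) h)` with
#' `h = side_length / n_cells_per_side`, so the centre node of an even grid is
#' exactly at the origin.
#'
#' @param side_length physical side length of the square domain (m).
#' @param n_cells_per_side number of cells along each side (integer >= 2).
#' @return an object of class `mwt_grid`: list with `side`, `n`, `h`, and the
#'   node coordinate vectors `node_coord` (length `n + 1`, shared by x and y).
#' @examples
#' g <- build_grid(0.25, 64)
#' g$h * 1000   # cell size in mm
#' @export
build_grid <- function(side_length, n_cells_per_side) {
  if (!is.numeric(side_length) || length(side_length) != 1L || side_length <= 0)
    stop("side_length must be a positive scalar (m)")
  if (!is.numeric(n_cells_per_side) || length(n_cells_per_side) != 1L ||
      n_cells_per_side < 2 || n_cells_per_side != round(n_cells_per_side))
    stop("n_cells_per_side must be an integer >= 2")
  n <- as.integer(n_cells_per_side)
  h <- side_length / n
  structure(list(
    side = side_length,
    n = n,
    h = h,
    node_coord = (0:n - n / 2) * h
  ), class = "mwt_grid")
}

#' @export
print.mwt_grid <- function(x, ...) {
  cat(sprintf("Uniform grid: %d x %d cells, %.4g x %.4g m, h = %.6g mm, %d nodes\n",
              x$n, x$n, x$side, x$side, x$h * 1000, (x$n + 1L)^2))
  invisible(x)
}

## node linear id (0-based grid indices i = x, j = y); row-major: j outer
.node_id <- function(i, j, n) j * (n + 1L) + i

#' Select the step-wise circular imaging zone
#'
#' A cell belongs to the zone if and only if its centre lies within
#' `zone_radius` of the grid centre.  The unknowns of the inverse problem live
#' on the distinct corner nodes of the selected cells, ordered row-major by
#' node index.  Each node `tau` carries the area `A_tau` of its incident
#' in-zone cells (`4 h^2` in the interior, less on the staircase boundary),
#' which enters the nodal-adjoint Jacobian as the quadrature weight
#' `A_tau / M` with `M = 4` vertices per square cell.
#'
#' @param grid an [mwt_grid][build_grid] object.
#' @param zone_radius radius of the target circle (m); the selected cells must
#'   stay clear of the domain boundary.
#' @return an object of class `mwt_zone`: cell indices (`cell_i`, `cell_j`,
#'   0-based) and centres, node indices (`node_i`, `node_j`), node coordinates
#'   (`node_x`, `node_y`), per-node areas `node_area`, counts `n_cells`,
#'   `n_nodes`, the vertex count `M = 4`, `effective_diameter` of the
#'   equal-area circle, and a full-grid lookup `node_index` mapping node id to
#'   unknown column (NA outside the zone).
#' @examples
#' g <- build_grid(0.25, 64)
#' z <- select_imaging_zone(g, 0.0698)
#' c(z$n_cells, z$n_nodes)   # 1012 cells, 1085 unknowns
#' @export
select_imaging_zone <- function(grid, zone_radius) {
  stopifnot(inherits(grid, "mwt_grid"))
  if (!is.numeric(zone_radius) || length(zone_radius) != 1L ||
      zone_radius <= 0 || zone_radius >= grid$side / 2)
    stop("zone_radius must lie strictly between 0 and side_length/2")
  n <- grid$n
  h <- grid$h
  cc <- (0:(n - 1L) + 0.5 - n / 2) * h          # cell-centre coordinate
  sel <- which(outer(cc^2, cc^2, "+") <= zone_radius^2, arr.ind = TRUE)
  if (nrow(sel) == 0L) {
    ci <- integer(0); cj <- integer(0)
  } else {
    ci <- sel[, 1L] - 1L                        # x index of cell
    cj <- sel[, 2L] - 1L
  }
  if (length(ci) && (min(ci, cj) == 0L || max(ci, cj) == n - 1L))
    stop("imaging zone touches the domain boundary; shrink zone_radius")

  ## corner nodes of every selected cell, deduplicated, row-major order
  corner_i <- c(ci, ci + 1L, ci, ci + 1L)
  corner_j <- c(cj, cj, cj + 1L, cj + 1L)
  ids <- .node_id(corner_i, corner_j, n)
  area <- tapply(rep(h * h, length(ids)), ids, sum)  # A_tau
  uid <- sort(as.integer(names(area)))
  area <- as.numeric(area[as.character(uid)])
  node_i <- uid %% (n + 1L)
  node_j <- uid %/% (n + 1L)

  node_index <- rep(NA_integer_, (n + 1L)^2)
  node_index[uid + 1L] <- seq_along(uid)

  structure(list(
    grid = grid,
    radius = zone_radius,
    cell_i = ci, cell_j = cj,
    cell_x = (ci + 0.5 - n / 2) * h,
    cell_y = (cj + 0.5 - n / 2) * h,
    node_id = uid,
    node_i = node_i, node_j = node_j,
    node_x = (node_i - n / 2) * h,
    node_y = (node_j - n / 2) * h,
    node_area = area,
    n_cells = length(ci),
    n_nodes = length(uid),
    M = 4L,
    effective_diameter = 2 * sqrt(length(ci) * h * h / pi),
    node_index = node_index
  ), class = "mwt_zone")
}

#' @export
print.mwt_zone <- function(x, ...) {
  cat(sprintf("Step-wise circular imaging zone: %d cells, %d nodes (unknowns)\n",
              x$n_cells, x$n_nodes))
  cat(sprintf("  target radius %.4g mm, effective diameter %.4g mm\n",
              x$radius * 1000, x$effective_diameter * 1000))
  invisible(x)
}

#' In-zone cells incident to a node
#'
#' Returns the indices (into the zone's cell vectors) of the 1-4 in-zone cells
#' touching a given in-zone node; their total area is the node's quadrature
#' weight `A_tau`.
#'
#' @param zone an [mwt_zone][select_imaging_zone] object.
#' @param node unknown index (1-based position in the zone's node ordering).
#' @return integer vector of cell positions.
#' @export
node_cell_adjacency <- function(zone, node) {
  stopifnot(inherits(zone, "mwt_zone"))
  if (!is.numeric(node) || length(node) != 1L || node < 1 || node > zone$n_nodes)
    stop("node outside the imaging zone")
  ni <- zone$node_i[node]
  nj <- zone$node_j[node]
  which((zone$cell_i == ni | zone$cell_i == ni - 1L) &
        (zone$cell_j == nj | zone$cell_j == nj - 1L))
}

## number of boundary edges of the union of in-zone cells (for the Euler
## relation |nodes| = |cells| + B/2 + 1 on a simply connected cell union)
.zone_boundary_edge_count <- function(zone) {
  n <- zone$grid$n
  ci <- zone$cell_i; cj <- zone$cell_j
  ## horizontal edges: between (i,j)-(i+1,j); key by left node id and orientation
  hkey <- c(.node_id(ci, cj, n), .node_id(ci, cj + 1L, n))
  vkey <- c(.node_id(ci, cj, n), .node_id(ci + 1L, cj, n))
  count_once <- function(keys) sum(table(keys) == 1L)
  count_once(hkey) + count_once(vkey)
}

#' Build the circular antenna array
#'
#' Antennas are ideal 2D line sources / point receivers equally spaced on a
#' circle concentric with the grid.  Antenna #1 sits at the bottom centre
#' (angle -90 degrees) and the numbering proceeds clockwise.
#'
#' @param n number of antennas (>= 3).
#' @param diameter array circle diameter (m).
#' @param amplitude equivalent line-current source amplitude `|J|` (default 1).
#' @return an object of class `mwt_array` with positions `x`, `y` (m),
#'   `n`, `diameter`, `amplitude`.
#' @examples
#' a <- build_antenna_array(16, 0.152)
#' round(c(a$x[1], a$y[1]) * 1000, 1)   # antenna #1 at (0, -76) mm
#' @export
build_antenna_array <- function(n, diameter, amplitude = 1) {
  if (!is.numeric(n) || length(n) != 1L || n < 3 || n != round(n))
    stop("n must be an integer >= 3")
  if (!is.numeric(diameter) || length(diameter) != 1L || diameter <= 0)
    stop("diameter must be a positive scalar (m)")
  if (!is.numeric(amplitude) || length(amplitude) != 1L || amplitude < 0)
    stop("amplitude must be a nonnegative scalar")
  n <- as.integer(n)
  theta <- -pi / 2 - (seq_len(n) - 1L) * 2 * pi / n   # clockwise from bottom
  structure(list(
    n = n,
    diameter = diameter,
    amplitude = amplitude,
    x = diameter / 2 * cos(theta),
    y = diameter / 2 * sin(theta)
  ), class = "mwt_array")
}

#' @export
print.mwt_array <- function(x, ...) {
  cat(sprintf("Antenna array: %d elements on a %.4g cm circle, |J| = %g\n",
              x$n, x$diameter * 100, x$amplitude))
  invisible(x)
}

## sanity checks tying grid, zone and array together
.validate_scene <- function(zone, array) {
  stopifnot(inherits(zone, "mwt_zone"), inherits(array, "mwt_array"))
  r <- array$diameter / 2
  if (r <= zone$radius)
    stop("antenna circle must lie outside the imaging zone")
  if (r >= zone$grid$side / 2)
    stop("antenna circle must lie inside the grid domain")
  invisible(TRUE)
}
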