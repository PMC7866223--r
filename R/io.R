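## Plain-text file formats: measurement sets and gridded property images.
## Both carry their acquisition metadata in '#'-prefixed header lines, are
## diffable, and round-trip at full double precision.

.fmt_g <- function(x) sprintf("%.17g", x)

#' Write a measurement set to a delimited text file
#'
#' One row per ordered `(s, r)` pair: `s`, `r`, `Re(E)`, `Im(E)`,
#' tab-separated, preceded by header lines recording frequency, background
#' properties and array geometry.
#'
#' @param m an `mwt_measurements` data frame.
#' @param path output file path.
#' @export
write_measurements <- function(m, path) {
  stopifnot(inherits(m, "mwt_measurements"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(frequency_hz = attr(m, "frequency"),
           n_antennas = attr(m, "n_antennas"),
           array_diameter_m = attr(m, "array_diameter"),
           amplitude = attr(m, "amplitude"),
           eps_r = attr(m, "eps_r"),
           sigma_s_per_m = attr(m, "sigma"))
  writeLines(c("# mwtomo measurement set",
               sprintf("# %s=%s", names(hdr), .fmt_g(unname(hdr))),
               "s\tr\tre\tim"), con)
  writeLines(sprintf("%d\t%d\t%s\t%s", m$s, m$r,
                     .fmt_g(Re(m$value)), .fmt_g(Im(m$value))), con)
  invisible(path)
}

#' Read a measurement set
#'
#' Parses the format written by [write_measurements()] and validates the
#' `(s, r)` coverage: every ordered pair of distinct antennas exactly once,
#' no `s = r` rows; violations are reported with their line numbers.
#'
#' @param path input file path.
#' @return an `mwt_measurements` data frame.
#' @export
read_measurements <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  meta <- list()
  for (l in hdr) {
    kv <- regmatches(l, regexec("^#\\s*([A-Za-z_]+)=(.*)$", l))[[1L]]
    if (length(kv) == 3L) meta[[kv[2L]]] <- as.numeric(kv[3L])
  }
  body_ln <- which(!is_hdr)
  body <- lines[body_ln]
  if (!length(body) || body[1L] != "s\tr\tre\tim")
    stop("missing column header line 's\\tr\\tre\\tim'")
  rows_ln <- body_ln[-1L]
  rows <- body[-1L]
  parts <- strsplit(rows, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad))
    stop("malformed measurement row at line ", rows_ln[bad[1L]])
  tab <- matrix(as.numeric(unlist(parts)), ncol = 4L, byrow = TRUE)
  if (anyNA(tab))
    stop("non-numeric measurement value at line ",
         rows_ln[which(rowSums(is.na(tab)) > 0)[1L]])
  s <- as.integer(tab[, 1L]); r <- as.integer(tab[, 2L])
  n <- meta$n_antennas
  if (is.null(n)) stop("header missing n_antennas")
  eq <- which(s == r)
  if (length(eq))
    stop("measurement with s = r at line ", rows_ln[eq[1L]])
  key <- paste(s, r)
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (s, r) pair at line ", rows_ln[dup[1L]])
  want <- outer(seq_len(n), seq_len(n), function(a, b) paste(a, b))
  want <- want[row(want) != col(want)]
  miss <- setdiff(want, key)
  if (length(miss))
    stop("missing (s, r) pair(s): ", paste(utils::head(miss, 5L), collapse = "; "))
  ord <- order(s, r)
  m <- data.frame(s = s[ord], r = r[ord])
  m$value <- complex(real = tab[ord, 3L], imaginary = tab[ord, 4L])
  structure(m, class = c("mwt_measurements", "data.frame"),
            frequency = meta$frequency_hz,
            n_antennas = as.integer(n),
            array_diameter = meta$array_diameter_m,
            amplitude = meta$amplitude,
            eps_r = meta$eps_r,
            sigma = meta$sigma_s_per_m)
}

#' Write a gridded property image
#'
#' Writes relative permittivity and conductivity node values as delimited
#' text over the full grid, one row per node (`i`, `j`, `x`, `y`, `eps_r`,
#' `sigma`), with out-of-zone nodes marked by the sentinel `NA`.
#'
#' @param eps_r,sigma numeric vectors over zone nodes (zone ordering).
#' @param zone the imaging zone.
#' @param path output file path.
#' @param frequency frequency (Hz) recorded in the header.
#' @param iteration optional iteration index recorded in the header.
#' @export
write_image <- function(eps_r, sigma, zone, path, frequency, iteration = NULL) {
  stopifnot(inherits(zone, "mwt_zone"),
            length(eps_r) == zone$n_nodes, length(sigma) == zone$n_nodes)
  n <- zone$grid$n
  full_eps <- rep(NA_real_, (n + 1L)^2)
  full_sig <- rep(NA_real_, (n + 1L)^2)
  full_eps[zone$node_id + 1L] <- eps_r
  full_sig[zone$node_id + 1L] <- sigma
  id <- 0:((n + 1L)^2 - 1L)
  i <- id %% (n + 1L); j <- id %/% (n + 1L)
  coord <- zone$grid$node_coord
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# mwtomo property image",
               sprintf("# n_cells=%d", n),
               sprintf("# domain_size_m=%s", .fmt_g(zone$grid$side)),
               sprintf("# zone_radius_m=%s", .fmt_g(zone$radius)),
               sprintf("# frequency_hz=%s", .fmt_g(frequency)),
               if (!is.null(iteration)) sprintf("# iteration=%d", iteration),
               "i\tj\tx\ty\teps_r\tsigma"), con)
  val <- function(v) ifelse(is.na(v), "NA", .fmt_g(v))
  writeLines(sprintf("%d\t%d\t%s\t%s\t%s\t%s", i, j,
                     .fmt_g(coord[i + 1L]), .fmt_g(coord[j + 1L]),
                     val(full_eps), val(full_sig)), con)
  invisible(path)
}

#' Read a gridded property image
#'
#' @param path file written by [write_image()].
#' @return list with `table` (data frame over all grid nodes; out-of-zone
#'   rows have `NA` properties) and `meta` (header key-value list).
#' @export
read_image <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  meta <- list()
  for (l in lines[is_hdr]) {
    kv <- regmatches(l, regexec("^#\\s*([A-Za-z_]+)=(.*)$", l))[[1L]]
    if (length(kv) == 3L) meta[[kv[2L]]] <- as.numeric(kv[3L])
  }
  body <- lines[!is_hdr]
  tab <- utils::read.table(text = body[-1L], sep = "\t",
                           col.names = strsplit(body[1L], "\t")[[1L]])
  list(table = tab, meta = meta)
}
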