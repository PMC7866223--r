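# Shared fixtures, built in code and cached per test file.
# The "tiny" scene (24-cell grid, 8 antennas) is deliberately coarser than
# lambda/10 -- property tests (identities, reciprocity, operation counts) do
# not depend on discretization accuracy -- so coupling construction is
# wrapped in suppressWarnings; accuracy-sensitive tests use the full
# 64-cell default grid.

.cache <- new.env()

tiny_scene <- function() {
  if (is.null(.cache$tiny)) {
    g <- build_grid(0.25, 24)
    .cache$tiny <- list(
      grid = g,
      zone = select_imaging_zone(g, 0.0698),
      array = build_antenna_array(8, 0.152),
      background = dielectric_properties(20.9, 1.35),
      frequency = 1500e6
    )
  }
  .cache$tiny
}

# homogeneous-background sweep on the tiny scene (shared by several tests)
tiny_homog_sweep <- function() {
  if (is.null(.cache$tiny_sweep)) {
    sc <- tiny_scene()
    pm <- property_map(sc$zone, sc$background, sc$frequency)
    .cache$tiny_sweep <- suppressWarnings(
      forward_sweep(pm, sc$zone, sc$array))
  }
  .cache$tiny_sweep
}

# the sensitivity-map / first-iteration condition: 1300 MHz, bath
# eps_r = 22, sigma = 1 S/m, homogeneous start
fig_condition <- function() {
  list(background = dielectric_properties(22, 1), frequency = 1300e6)
}

default_scene <- function() {
  if (is.null(.cache$default)) .cache$default <- scene_from_config(default_config())
  .cache$default
}

rel_l2 <- function(x, ref) sqrt(sum(Mod(x - ref)^2) / sum(Mod(ref)^2))

max_rel <- function(x, ref) max(Mod(x - ref) / Mod(ref))
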