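## Run configuration: a flat YAML file of named, unit-suffixed keys covering
## geometry, physics, simulation and reconstruction.  Unknown keys are
## rejected; missing keys fall back to the defaults of the shipped tank
## scenario (16 monopoles on a 15.2 cm circle, 25 cm / 64-cell grid,
## glycerin-water bath, 4 cm cylindrical inclusion at 1500 MHz).

#' Default run configuration
#'
#' The shipped scenario: a 64 x 64-cell grid over 25 x 25 cm, a step-wise
#' circular imaging zone of 1012 cells / 1085 node unknowns (selection radius
#' 69.8 mm, giving an equal-area "effective" diameter of 14.0 cm),
#' 16 antennas on a 15.2 cm circle, a 1500 MHz glycerin-water bath
#' (`eps_r = 20.9`, `sigma = 1.35` S/m) and a 4 cm diameter cylindrical
#' inclusion (`eps_r = 16.9`, `sigma = 1.15` S/m) placed off-centre in front
#' of antennas #6 and #7 (at 2/3 of the zone radius along their bisector when
#' `inclusion_center_m` is `NULL`).
#'
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(
    domain_size_m = 0.25,
    n_cells = 64L,
    zone_radius_m = 0.0698,
    n_antennas = 16L,
    array_diameter_m = 0.152,
    source_amplitude = 1,
    frequency_hz = 1500e6,
    bath_eps_r = 20.9,
    bath_sigma_s_per_m = 1.35,
    object_eps_r = 16.9,
    object_sigma_s_per_m = 1.15,
    inclusion_radius_m = 0.02,
    inclusion_center_m = NULL,
    noise_level = 0.01,
    fine_factor = 2L,
    rng_seed = 1L,
    max_iterations = 25L,
    stop_delta = 1e-3,
    regularization_lambda = 0.1,
    lm_decay = 0.9
  )
}

#' Read and validate a run configuration
#'
#' Reads a flat YAML file, rejects unknown keys with a diagnostic, and fills
#' unspecified keys from [default_config()].
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return validated configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  cfg$n_cells <- as.integer(cfg$n_cells)
  cfg$n_antennas <- as.integer(cfg$n_antennas)
  cfg$fine_factor <- as.integer(cfg$fine_factor)
  cfg$rng_seed <- as.integer(cfg$rng_seed)
  cfg$max_iterations <- as.integer(cfg$max_iterations)
  cfg
}

#' Write a run configuration
#'
#' @param cfg configuration list.
#' @param path output YAML path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], path)
  invisible(path)
}

## default inclusion placement: 2/3 of the zone radius along the bisector of
## antennas #6 and #7 of the 16-element array -- a fixed direction in space
## (5.5 clockwise steps of 22.5 degrees from the bottom), so it stays valid
## for any antenna count
.default_inclusion_center <- function(zone, array) {
  theta <- -pi / 2 - 2 * pi * 5.5 / 16
  (2 / 3) * zone$radius * c(cos(theta), sin(theta))
}

#' Build the full scene described by a configuration
#'
#' @param cfg configuration list ([default_config()], [read_config()]).
#' @return list with `grid`, `zone`, `array`, `background`, `frequency`,
#'   `phantom` ([phantom_spec()]) and `control` ([mwt_control()]).
#' @examples
#' sc <- scene_from_config(default_config())
#' sc$zone
#' @export
scene_from_config <- function(cfg) {
  grid <- build_grid(cfg$domain_size_m, cfg$n_cells)
  zone <- select_imaging_zone(grid, cfg$zone_radius_m)
  array <- build_antenna_array(cfg$n_antennas, cfg$array_diameter_m,
                               cfg$source_amplitude)
  .validate_scene(zone, array)
  background <- dielectric_properties(cfg$bath_eps_r, cfg$bath_sigma_s_per_m)
  center <- cfg$inclusion_center_m
  if (is.null(center)) center <- .default_inclusion_center(zone, array)
  phantom <- phantom_spec(
    background = background,
    inclusions = list(list(center = as.numeric(center),
                           radius = cfg$inclusion_radius_m,
                           eps_r = cfg$object_eps_r,
                           sigma = cfg$object_sigma_s_per_m)),
    frequency = cfg$frequency_hz,
    noise_level = cfg$noise_level,
    fine_factor = cfg$fine_factor,
    seed = cfg$rng_seed)
  control <- mwt_control(max_iterations = cfg$max_iterations,
                         stop_delta = cfg$stop_delta,
                         lambda0 = cfg$regularization_lambda,
                         lm_decay = cfg$lm_decay)
  list(grid = grid, zone = zone, array = array, background = background,
       frequency = cfg$frequency_hz, phantom = phantom, control = control)
}
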