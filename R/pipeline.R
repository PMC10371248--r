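# End-to-end pipeline: configuration, presets, orchestration and outputs.

#' Run configuration
#'
#' Assembles and validates the configuration for [run_pipeline()].
#' Defaults encode the standard study conditions: atmospheric
#' transmittance 0.7, 4 x 13 layout with 55/15 cm spacings, 110 x 75 cm
#' scoring region, hourly diurnal course.
#'
#' @param preset architecture preset for the synthetic plants ("erect",
#'   "spread" or "toy-flat"), ignored when `plants` is supplied.
#' @param plants optional list of [plant_vector_model()] objects.
#' @param n_plants distinct plant individuals cycled over the grid.
#' @param layout a [canopy_layout()].
#' @param date,latitude,longitude,transmittance site and sky settings.
#' @param hours local solar hours of the diurnal course.
#' @param spad,variety leaf optics source (SPAD conversion), or give
#'   `optics` directly.
#' @param optics optional [leaf_optics()].
#' @param photosynthesis named list of [light_response_params()]
#'   (`up`, `bottom`).
#' @param rays_per_m2,max_bounces ray-tracer settings.
#' @param seeds named list of integer seeds (`plant`, `canopy`, `trace`).
#' @param output_dir directory for CSV/JSON outputs, or `NULL`.
#' @return validated `RunConfig` object.
#' @export
run_config <- function(preset = "erect", plants = NULL, n_plants = 4L,
                       layout = canopy_layout(), date = "2020-08-27",
                       latitude = 30.93, longitude = 121.13,
                       transmittance = 0.7, hours = 5:20,
                       spad = 45, variety = "W64A", optics = NULL,
                       photosynthesis = default_photosynthesis_params(),
                       rays_per_m2 = 1e4, max_bounces = 5L,
                       seeds = list(plant = 1L, canopy = 1L, trace = 1L),
                       output_dir = NULL) {
  if (!inherits(layout, "CanopyLayout")) stopf("config field 'layout' invalid")
  if (transmittance <= 0 || transmittance > 1)
    stopf("config field 'transmittance' must be in (0, 1]")
  if (!length(hours) || any(hours < 0 | hours > 24))
    stopf("config field 'hours' must be within 0..24")
  if (rays_per_m2 <= 0) stopf("config field 'rays_per_m2' must be positive")
  if (is.null(photosynthesis$up) || is.null(photosynthesis$bottom))
    stopf("config field 'photosynthesis' needs 'up' and 'bottom' parameter sets")
  for (s in c("plant", "canopy", "trace"))
    if (is.null(seeds[[s]])) stopf("config field 'seeds$%s' missing", s)
  if (is.null(optics)) optics <- spad_to_optics(spad, variety)
  structure(list(preset = preset, plants = plants, n_plants = as.integer(n_plants),
                 layout = layout, date = date, latitude = latitude,
                 longitude = longitude, transmittance = transmittance,
                 hours = hours, spad = spad, variety = variety,
                 optics = optics, photosynthesis = photosynthesis,
                 rays_per_m2 = rays_per_m2, max_bounces = as.integer(max_bounces),
                 seeds = seeds, output_dir = output_dir),
            class = "RunConfig")
}

#' Default layer-specific light-response parameter sets
#'
#' Synthetic maize-like parameter values (up layer more capable than the
#' shaded bottom layer); use measured fits for real studies.
#'
#' @return named list with `up` and `bottom` [light_response_params()].
#' @export
default_photosynthesis_params <- function() {
  list(up = light_response_params(32, 0.055, 0.75, 1.8, layer = "up"),
       bottom = light_response_params(24, 0.050, 0.70, 1.4, layer = "bottom"))
}

#' Read a run configuration from YAML or JSON
#'
#' Scalar fields mirror the [run_config()] arguments; `layout` is given as
#' a mapping of [canopy_layout()] arguments and `photosynthesis` as
#' per-layer mappings of [light_response_params()] arguments.
#'
#' @param path YAML (.yml/.yaml) or JSON file.
#' @return a `RunConfig`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  args <- raw
  if (!is.null(raw$layout)) args$layout <- do.call(canopy_layout, raw$layout)
  if (!is.null(raw$photosynthesis))
    args$photosynthesis <- lapply(raw$photosynthesis, function(p)
      do.call(light_response_params, p))
  if (!is.null(raw$hours)) args$hours <- as.numeric(raw$hours)
  do.call(run_config, args)
}

#' Run the full canopy photosynthesis pipeline
#'
#' Generates (or takes) the plants, meshes them, builds the canopy, traces
#' the diurnal light course, integrates canopy photosynthesis, and (when
#' `config$output_dir` is set) writes `hourly_canopy_photosynthesis.csv`,
#' `daily_summary.csv`, `plant_traits.csv` and a `manifest.json` holding
#' every seed and setting needed to reproduce the run bit-identically.
#'
#' @param config a [run_config()].
#' @return list with the scene, hourly absorption, hourly/daily
#'   photosynthesis, traits and the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  plants <- config$plants
  if (is.null(plants)) {
    pp <- architecture_preset(config$preset)
    plants <- lapply(seq_len(config$n_plants), function(i)
      generate_synthetic_plant(pp, rng_seed = config$seeds$plant + i - 1L))
  }
  meshes <- lapply(plants, mesh_plant)
  scene <- build_canopy(meshes, config$layout, rng_seed = config$seeds$canopy)
  absorptions <- diurnal_trace(
    scene, list(date = config$date, latitude = config$latitude,
                longitude = config$longitude,
                transmittance = config$transmittance),
    optics = config$optics, hours = config$hours,
    rays_per_m2 = config$rays_per_m2, max_bounces = config$max_bounces,
    rng_seed = config$seeds$trace)
  daily <- diurnal_canopy_A(absorptions, config$photosynthesis, scene)
  traits <- do.call(rbind, lapply(seq_along(plants), function(i) {
    tr <- measure_traits(plants[[i]])
    cbind(plant = i, tr)
  }))
  manifest <- list(
    package = "canophot",
    version = as.character(utils::packageVersion("canophot")),
    preset = config$preset, n_plants = config$n_plants,
    layout = unclass(config$layout), date = as.character(config$date),
    latitude = config$latitude, longitude = config$longitude,
    transmittance = config$transmittance, hours = config$hours,
    spad = config$spad, variety = config$variety,
    optics = list(R = config$optics$reflectance, T = config$optics$transmittance),
    photosynthesis = lapply(config$photosynthesis, function(p)
      p[c("Pmax", "phi", "theta", "Rd")]),
    rays_per_m2 = config$rays_per_m2, max_bounces = config$max_bounces,
    seeds = config$seeds,
    lai_scored = compute_lai(scene), A_cd = daily$A_cd)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    outfile <- function(f) file.path(config$output_dir, f)
    write.csv(daily$hourly, outfile("hourly_canopy_photosynthesis.csv"),
              row.names = FALSE)
    write.csv(data.frame(A_cd_mol_m2_day = daily$A_cd,
                         lai_scored = manifest$lai_scored,
                         leaf_area_m2 = sum(vapply(meshes, total_leaf_area,
                                                   numeric(1))) / 1e4),
              outfile("daily_summary.csv"), row.names = FALSE)
    write.csv(traits, outfile("plant_traits.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, outfile("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(scene = scene, absorptions = absorptions, daily = daily,
                 traits = traits, manifest = manifest))
}
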