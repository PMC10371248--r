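# R interface to the Monte-Carlo canopy ray tracer.

#' Trace direct and diffuse light through a canopy scene
#'
#' Launches the direct beam from a stratified-jittered grid on the top
#' plane along the solar direction and diffuse sky light from
#' cosine-weighted downward directions (uniform overcast). On a facet hit
#' the fraction 1-R-T of the ray's power is absorbed and scored; survival
#' is decided by single-ray Russian roulette (reflect with probability R,
#' transmit with probability T, terminate otherwise) with Lambertian
#' redistribution about the facet normal (or its inverse for
#' transmission). Facets are scored on both sides per unit one-sided
#' facet area. Lateral boundaries are periodic (a ray exiting one side
#' re-enters the opposite side), the ground absorbs, rays leaving through
#' the top escape. Deterministic for a fixed seed.
#'
#' `direct_ppfd` and `diffuse_ppfd` of `sky` are fluxes on a horizontal
#' plane (umol m-2 s-1).
#'
#' @param scene a [build_canopy()] scene.
#' @param sky a [incident_ppfd()] / [sky_condition()] result.
#' @param optics per-leaf optical properties: a single [leaf_optics()]
#'   object, a per-plant list, a data frame (plant, leaf, R, T), or `NULL`
#'   for black leaves.
#' @param rays_per_m2 rays per square metre of ground for each light
#'   component (>= 1e4 recommended for production runs).
#' @param max_bounces scattering-path cap (default 5).
#' @param rng_seed integer seed.
#' @return a `FacetAbsorption` object: `facets` data frame (facet, plant,
#'   leaf, layer, area, scored, absorbed PPFD per unit facet area) and
#'   `totals` (emitted, absorbed by leaves/stem, ground, escaped flux in
#'   umol s-1 over the tile, ray count, seed).
#' @export
trace <- function(scene, sky, optics = NULL, rays_per_m2 = 1e4,
                  max_bounces = 5L, rng_seed = 1L) {
  stopifnot(inherits(scene, "CanopyScene"))
  if (rays_per_m2 <= 0) stopf("rays_per_m2 must be positive")
  fl <- flatten_scene(scene, optics)
  tile_m2 <- diff(scene$domain[c("xmin", "xmax")]) *
    diff(scene$domain[c("ymin", "ymax")]) / 1e4
  direct <- if (sky$zenith >= 90) 0 else sky$direct_ppfd
  diffuse <- sky$diffuse_ppfd
  n_rays <- max(1L, as.integer(round(rays_per_m2 * tile_m2)))
  if (direct + diffuse <= 0)
    return(zero_absorption(fl, rng_seed, sky))
  n_direct <- if (direct > 0) n_rays else 0L
  if (n_direct > 0) {
    gx <- ceiling(sqrt(n_direct))
    n_direct <- as.integer(gx * ceiling(n_direct / gx))  # perfect launch grid
  }
  n_diffuse <- if (diffuse > 0) n_rays else 0L
  zen <- deg2rad(sky$zenith)
  azi <- deg2rad(sky$azimuth)
  sun <- c(-sin(zen) * sin(azi), -sin(zen) * cos(azi), -cos(zen))
  res <- .cpp_trace(fl$tri, fl$facets$R, fl$facets$T,
                    as.numeric(scene$domain[c("xmin", "xmax", "ymin", "ymax",
                                              "zmin", "zmax")]),
                    sun,
                    n_direct, if (n_direct) direct * tile_m2 / n_direct else 0,
                    n_diffuse, if (n_diffuse) diffuse * tile_m2 / n_diffuse else 0,
                    as.integer(max_bounces), as.numeric(rng_seed))
  facets <- fl$facets
  facets$absorbed_flux <- res$absorbed                      # umol s-1
  facets$absorbed_ppfd <- res$absorbed / (facets$area_cm2 / 1e4)
  leafy <- facets$leaf > 0
  structure(list(facets = facets,
                 totals = list(emitted = res$emitted,
                               absorbed_leaf = sum(res$absorbed[leafy]),
                               absorbed_stem = sum(res$absorbed[!leafy]),
                               ground = res$ground, escaped = res$escaped,
                               lost = res$lost, ray_count = res$n_rays,
                               rng_seed = rng_seed),
                 sky = sky),
            class = "FacetAbsorption")
}

zero_absorption <- function(fl, rng_seed, sky) {
  facets <- fl$facets
  facets$absorbed_flux <- 0
  facets$absorbed_ppfd <- 0
  structure(list(facets = facets,
                 totals = list(emitted = 0, absorbed_leaf = 0,
                               absorbed_stem = 0, ground = 0, escaped = 0,
                               lost = 0, ray_count = 0, rng_seed = rng_seed),
                 sky = sky),
            class = "FacetAbsorption")
}

#' @export
print.FacetAbsorption <- function(x, ...) {
  t <- x$totals
  cat(sprintf(paste0("FacetAbsorption: %d facets, emitted %.1f umol/s ",
                     "(leaves %.0f%%, ground %.0f%%, escaped %.0f%%)\n"),
              nrow(x$facets), t$emitted,
              100 * t$absorbed_leaf / max(t$emitted, 1e-12),
              100 * t$ground / max(t$emitted, 1e-12),
              100 * t$escaped / max(t$emitted, 1e-12)))
  invisible(x)
}

#' Hourly light distributions over a day
#'
#' One [trace()] per requested hour using that hour's clear-sky condition;
#' night hours yield zero fields without tracing.
#'
#' @param scene a [build_canopy()] scene.
#' @param day list with `date`, `latitude`, optional `longitude` and
#'   `transmittance` (default 0.7).
#' @param optics as in [trace()].
#' @param hours local solar hours to simulate (default 5:20).
#' @param ... passed to [trace()] (`rays_per_m2`, `max_bounces`).
#' @param rng_seed base seed; hour h uses `rng_seed + h`.
#' @return named list of `FacetAbsorption`, one per hour.
#' @export
diurnal_trace <- function(scene, day, optics = NULL, hours = 5:20,
                          rng_seed = 1L, ...) {
  tau <- if (is.null(day$transmittance)) 0.7 else day$transmittance
  out <- lapply(hours, function(h) {
    sky <- sky_condition(day$date, h, day$latitude, day$longitude,
                         transmittance = tau)
    if (sky$direct_ppfd + sky$diffuse_ppfd <= 0)
      zero_absorption(flatten_scene(scene, optics), rng_seed + h, sky)
    else trace(scene, sky, optics, rng_seed = rng_seed + h, ...)
  })
  names(out) <- sprintf("%05.2f", hours)
  out
}
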