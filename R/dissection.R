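# Factorial inclusion-exclusion dissection of canopy photosynthesis:
# 8 scenario canopies built from all combinations of three trait groups
# (S = plant architecture, P = leaf photosynthesis, C = chlorophyll-derived
# leaf optics) taken from a base or a donor variety, plus the sensitivity
# sweeps over photosynthetic parameters and architectural traits.

#' Bundle of the three trait groups of one variety
#'
#' @param label variety name (also selects the SPAD reflectance model when
#'   it is "W64A" or "A619"; otherwise supply `optics` directly).
#' @param architecture list of [plant_vector_model()] plants.
#' @param photosynthesis named list of [light_response_params()]
#'   (`up`, `bottom`).
#' @param spad mean SPAD reading used to derive leaf optics (ignored when
#'   `optics` is given).
#' @param optics optional [leaf_optics()] overriding the SPAD conversion.
#' @return object of class `VarietyBundle`.
#' @export
variety_bundle <- function(label, architecture, photosynthesis, spad = NULL,
                           optics = NULL) {
  if (!length(architecture)) stopf("missing trait group: architecture")
  if (is.null(photosynthesis$up) || is.null(photosynthesis$bottom))
    stopf("missing trait group: photosynthesis (need up and bottom layers)")
  if (is.null(spad) && is.null(optics))
    stopf("missing trait group: chlorophyll (spad or optics)")
  if (is.null(optics)) {
    variety <- if (label %in% c("W64A", "A619")) label else "W64A"
    optics <- spad_to_optics(spad, variety)
  }
  structure(list(label = label, architecture = architecture,
                 photosynthesis = photosynthesis, spad = spad,
                 optics = optics),
            class = "VarietyBundle")
}

#' Simulation configuration for dissection and sweeps
#'
#' Defaults match the standard study conditions: atmospheric transmittance
#' 0.7, 4 x 13 layout with 55/15 cm spacings and the 110 x 75 cm scoring
#' region, hourly intervals 05:00-20:00 local solar time.
#'
#' @param layout a [canopy_layout()].
#' @param date simulation date.
#' @param latitude,longitude site coordinates (degrees).
#' @param transmittance atmospheric transmittance.
#' @param hours local solar hours of the diurnal course.
#' @param rays_per_m2,max_bounces ray-tracing settings.
#' @param vary_placement replicate seeds also reshuffle plant azimuths
#'   (TRUE) or only the ray-tracing streams (FALSE).
#' @return a `DissectionConfig` list.
#' @export
dissect_config <- function(layout = canopy_layout(), date = "2020-08-27",
                           latitude = 30.93, longitude = 121.13,
                           transmittance = 0.7, hours = 5:20,
                           rays_per_m2 = 1e4, max_bounces = 5L,
                           vary_placement = TRUE) {
  structure(list(layout = layout, date = date, latitude = latitude,
                 longitude = longitude, transmittance = transmittance,
                 hours = hours, rays_per_m2 = rays_per_m2,
                 max_bounces = max_bounces, vary_placement = vary_placement),
            class = "DissectionConfig")
}

dissection_scenarios <- function() {
  list(O   = c(S = "base",  P = "base",  C = "base"),
       S   = c(S = "donor", P = "base",  C = "base"),
       P   = c(S = "base",  P = "donor", C = "base"),
       C   = c(S = "base",  P = "base",  C = "donor"),
       SP  = c(S = "donor", P = "donor", C = "base"),
       SC  = c(S = "donor", P = "base",  C = "donor"),
       PC  = c(S = "base",  P = "donor", C = "donor"),
       SPC = c(S = "donor", P = "donor", C = "donor"))
}

# default backend: the full diurnal pipeline for one scenario combination
pipeline_backend <- function(base, donor, sim) {
  mesh_cache <- new.env(parent = emptyenv())
  meshes_of <- function(which) {
    if (is.null(mesh_cache[[which]])) {
      bundle <- if (which == "base") base else donor
      mesh_cache[[which]] <- lapply(bundle$architecture, mesh_plant)
    }
    mesh_cache[[which]]
  }
  function(combo, rep_seed) {
    arch <- meshes_of(combo[["S"]])
    photo <- (if (combo[["P"]] == "base") base else donor)$photosynthesis
    opt <- (if (combo[["C"]] == "base") base else donor)$optics
    placement_seed <- if (isTRUE(sim$vary_placement)) rep_seed else 1L
    scene <- build_canopy(arch, sim$layout, rng_seed = placement_seed)
    abs_h <- diurnal_trace(scene,
                           list(date = sim$date, latitude = sim$latitude,
                                longitude = sim$longitude,
                                transmittance = sim$transmittance),
                           optics = opt, hours = sim$hours,
                           rays_per_m2 = sim$rays_per_m2,
                           max_bounces = sim$max_bounces,
                           rng_seed = rep_seed * 100L)
    diurnal_canopy_A(abs_h, photo, scene)$A_cd
  }
}

#' Factorial dissection of canopy photosynthesis differences
#'
#' Builds the eight scenario canopies combining architecture (S), leaf
#' photosynthesis (P) and chlorophyll-derived optics (C) from the base or
#' the donor bundle, computes the daily canopy CO2 uptake of each, and
#' derives main-effect and interaction contributions by
#' inclusion-exclusion:
#' c(S) = A(S) - A(O), c(SP) = A(SP) - A(S) - A(P) + A(O), ...,
#' c(SPC) = A(SPC) - A(SP) - A(SC) - A(PC) + A(S) + A(P) + A(C) - A(O).
#' All eight scenarios in one replicate share the same RNG seed so Monte
#' Carlo noise differences out of the contrasts; replicates use distinct
#' seeds.
#'
#' @param base,donor [variety_bundle()] objects; contributions are
#'   expressed relative to the base scenario A(O).
#' @param sim a [dissect_config()].
#' @param replicates number of model-calculation replicates (default 5).
#' @param rng_seed base seed.
#' @param backend optional simulator override, a
#'   `function(combo, rep_seed)` returning a daily A_cd for a combination
#'   `c(S=, P=, C=)` of "base"/"donor"; used for testing and for analytic
#'   toy canopies.
#' @return a `DissectionResult`: per-scenario A_cd matrix, contribution
#'   table (absolute, mol m-2 day-1, and relative, % of A(O)).
#' @export
run_dissection <- function(base, donor, sim = dissect_config(),
                           replicates = 5L, rng_seed = 1L, backend = NULL) {
  stopifnot(inherits(base, "VarietyBundle") || !is.null(backend),
            inherits(donor, "VarietyBundle") || !is.null(backend))
  if (replicates < 1) stopf("replicates must be >= 1")
  if (is.null(backend)) backend <- pipeline_backend(base, donor, sim)
  scen <- dissection_scenarios()
  A <- matrix(NA_real_, length(scen), replicates,
              dimnames = list(names(scen), NULL))
  for (r in seq_len(replicates)) {
    rep_seed <- rng_seed + 1000L * (r - 1L)
    for (s in names(scen)) A[s, r] <- backend(scen[[s]], rep_seed)
  }
  contrib <- function(a) c(
    S = a["S"] - a["O"],
    P = a["P"] - a["O"],
    C = a["C"] - a["O"],
    SP = a["SP"] - a["S"] - a["P"] + a["O"],
    SC = a["SC"] - a["S"] - a["C"] + a["O"],
    PC = a["PC"] - a["P"] - a["C"] + a["O"],
    SPC = a["SPC"] - a["SP"] - a["SC"] - a["PC"] +
      a["S"] + a["P"] + a["C"] - a["O"])
  cons <- apply(A, 2, contrib)
  rownames(cons) <- c("S", "P", "C", "SP", "SC", "PC", "SPC")
  rel <- sweep(cons, 2, A["O", ], "/") * 100
  contributions <- data.frame(
    term = rownames(cons),
    absolute = rowMeans(cons), absolute_sd = apply(cons, 1, sd),
    relative_pct = rowMeans(rel), relative_pct_sd = apply(rel, 1, sd),
    row.names = NULL)
  structure(list(A_cd = A, contributions = contributions,
                 replicates = replicates,
                 identity_residual = max(abs(
                   (A["SPC", ] - A["O", ]) - colSums(cons)) /
                     pmax(abs(A["SPC", ] - A["O", ]), 1e-300))),
            class = "DissectionResult")
}

#' @export
print.DissectionResult <- function(x, ...) {
  cat(sprintf("DissectionResult (%d replicates)\n", x$replicates))
  cat(sprintf("  A_cd(O) = %.4f, A_cd(SPC) = %.4f mol m-2 day-1\n",
              mean(x$A_cd["O", ]), mean(x$A_cd["SPC", ])))
  print(x$contributions, digits = 4)
  invisible(x)
}

#' Sensitivity sweep over one photosynthetic parameter
#'
#' Scales one NRH parameter by each factor and recomputes the daily canopy
#' photosynthesis. Geometry and optics do not change, so the hourly
#' absorption fields are traced once per replicate and reused across
#' factors. Theta scalings that exceed 1 are clipped with a warning.
#'
#' @param bundle a [variety_bundle()].
#' @param parameter one of "Pmax", "phi", "theta", "Rd".
#' @param layer "up", "bottom" or "both".
#' @param factors multiplicative factors (default 0.6 to 1.4).
#' @param sim a [dissect_config()].
#' @param replicates,rng_seed replication settings.
#' @return data frame (factor, A_cd, A_cd_sd).
#' @export
sweep_photosynthesis <- function(bundle, parameter = c("Pmax", "phi", "theta", "Rd"),
                                 layer = c("both", "up", "bottom"),
                                 factors = seq(0.6, 1.4, by = 0.2),
                                 sim = dissect_config(), replicates = 1L,
                                 rng_seed = 1L) {
  parameter <- match.arg(parameter)
  layer <- match.arg(layer)
  if (any(factors <= 0)) stopf("factors must be > 0")
  meshes <- lapply(bundle$architecture, mesh_plant)
  A <- matrix(NA_real_, length(factors), replicates)
  for (r in seq_len(replicates)) {
    rep_seed <- rng_seed + 1000L * (r - 1L)
    scene <- build_canopy(meshes, sim$layout,
                          rng_seed = if (isTRUE(sim$vary_placement)) rep_seed else 1L)
    abs_h <- diurnal_trace(scene,
                           list(date = sim$date, latitude = sim$latitude,
                                longitude = sim$longitude,
                                transmittance = sim$transmittance),
                           optics = bundle$optics, hours = sim$hours,
                           rays_per_m2 = sim$rays_per_m2,
                           max_bounces = sim$max_bounces,
                           rng_seed = rep_seed * 100L)
    for (i in seq_along(factors)) {
      params <- lapply(bundle$photosynthesis, function(p) p)
      for (k in if (layer == "both") c("up", "bottom") else layer) {
        v <- params[[k]][[parameter]] * factors[i]
        if (parameter == "theta" && v > 1) {
          warnf("theta scaled above 1; clipped")
          v <- 1
        }
        params[[k]][[parameter]] <- v
      }
      A[i, r] <- diurnal_canopy_A(abs_h, params, scene)$A_cd
    }
  }
  data.frame(factor = factors, A_cd = rowMeans(A),
             A_cd_sd = apply(A, 1, sd))
}

default_sweep_values <- function(trait) {
  switch(trait,
         LW = seq(0.6, 2.0, by = 0.2), LL = seq(0.6, 2.0, by = 0.2),
         LN = seq(-4L, 8L, by = 2L), LC = seq(-180, 180, by = 45),
         LA = seq(-20, 40, by = 10))
}

trait_range <- function(trait) {
  switch(trait, LW = c(0.6, 2), LL = c(0.6, 2), LN = c(-4, 8),
         LC = c(-180, 180), LA = c(-20, 40))
}

#' Sensitivity sweep over one architectural trait
#'
#' Applies a [trait_adjustment()] per sweep value (LW/LL multiplicative,
#' LN additive count, LC/LA additive degrees), re-meshes, re-traces, and
#' reports daily canopy photosynthesis with the scored-region LAI per
#' value plus the location of the optimum. Failing adjustments (e.g. LN
#' below the leaf count) are recorded as NA and the sweep continues.
#'
#' @param bundle a [variety_bundle()].
#' @param trait one of "LW", "LL", "LN", "LC", "LA".
#' @param values sweep values; defaults cover the standard ranges
#'   (0.6-2.0 for LW/LL, -4..+8 for LN, -180..180 for LC, -20..40 for LA);
#'   a warning is issued outside them.
#' @param sim a [dissect_config()].
#' @param replicates,rng_seed replication settings.
#' @return list with `table` (value, A_cd, A_cd_sd, lai) and `optimum`
#'   (sweep value maximizing mean A_cd).
#' @export
sweep_architecture <- function(bundle, trait = c("LW", "LL", "LN", "LC", "LA"),
                               values = NULL, sim = dissect_config(),
                               replicates = 1L, rng_seed = 1L) {
  trait <- match.arg(trait)
  if (is.null(values)) values <- default_sweep_values(trait)
  rg <- trait_range(trait)
  if (any(values < rg[1] | values > rg[2]))
    warnf("%s values outside the standard range [%g, %g]", trait, rg[1], rg[2])
  A <- matrix(NA_real_, length(values), replicates)
  lai <- rep(NA_real_, length(values))
  for (i in seq_along(values)) {
    adj <- switch(trait,
                  LW = trait_adjustment(lw_factor = values[i]),
                  LL = trait_adjustment(ll_factor = values[i]),
                  LN = trait_adjustment(ln_delta = values[i]),
                  LC = trait_adjustment(lc_delta_deg = values[i]),
                  LA = trait_adjustment(la_delta_deg = values[i]))
    meshes <- tryCatch(
      lapply(bundle$architecture, function(p) mesh_plant(apply_adjustment(p, adj))),
      error = function(e) NULL)
    if (is.null(meshes)) next
    for (r in seq_len(replicates)) {
      rep_seed <- rng_seed + 1000L * (r - 1L)
      scene <- build_canopy(meshes, sim$layout,
                            rng_seed = if (isTRUE(sim$vary_placement)) rep_seed else 1L)
      if (r == 1L) lai[i] <- compute_lai(scene)
      abs_h <- diurnal_trace(scene,
                             list(date = sim$date, latitude = sim$latitude,
                                  longitude = sim$longitude,
                                  transmittance = sim$transmittance),
                             optics = bundle$optics, hours = sim$hours,
                             rays_per_m2 = sim$rays_per_m2,
                             max_bounces = sim$max_bounces,
                             rng_seed = rep_seed * 100L)
      A[i, r] <- diurnal_canopy_A(abs_h, bundle$photosynthesis, scene)$A_cd
    }
  }
  tab <- data.frame(value = values, A_cd = rowMeans(A),
                    A_cd_sd = apply(A, 1, sd), lai = lai)
  list(table = tab,
       optimum = if (all(is.na(tab$A_cd))) NA else
         values[which.max(tab$A_cd)])
}
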