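# Row-grid canopy assembly. Rows run along y; row positions step along x.
# Defaults follow a 4-row by 13-plant grid with 55 cm between rows and
# 15 cm between plants, and a central 110 x 75 cm scoring region (2 rows by
# 5 plants) used for flux accounting to avoid boundary effects.

#' Canopy layout configuration
#'
#' @param rows number of rows (default 4).
#' @param plants_per_row plants per row (default 13).
#' @param row_spacing_cm distance between rows (default 55).
#' @param plant_spacing_cm within-row distance between plants (default 15).
#' @param region_cm scoring-region extents `c(across_rows, along_row)` in
#'   cm (default `c(110, 75)`, covering 2 rows x 5 plants).
#' @param azimuth_random randomize each instance's azimuth over
#'   0/90/180/270 degrees (default TRUE) to avoid artificial alignment of
#'   repeated plants.
#' @return a `CanopyLayout` list.
#' @export
canopy_layout <- function(rows = 4L, plants_per_row = 13L,
                          row_spacing_cm = 55, plant_spacing_cm = 15,
                          region_cm = c(110, 75), azimuth_random = TRUE) {
  if (rows < 1) stopf("layout$rows must be >= 1")
  if (plants_per_row < 1) stopf("layout$plants_per_row must be >= 1")
  if (row_spacing_cm <= 0 || plant_spacing_cm <= 0)
    stopf("layout spacings must be > 0")
  if (length(region_cm) != 2 || any(region_cm <= 0))
    stopf("layout$region_cm must be two positive extents")
  structure(list(rows = as.integer(rows),
                 plants_per_row = as.integer(plants_per_row),
                 row_spacing_cm = row_spacing_cm,
                 plant_spacing_cm = plant_spacing_cm,
                 region_cm = region_cm, azimuth_random = azimuth_random),
            class = "CanopyLayout")
}

#' Assemble plant meshes into a field canopy scene
#'
#' Plants are cycled over the row grid in deterministic order; the seed
#' controls only the per-instance azimuth rotations (uniform over
#' 0/90/180/270 degrees when `layout$azimuth_random`). Instances whose base
#' falls inside the central scoring region are flagged `scored`. The
#' lateral domain box equals the planted footprint
#' (rows x row spacing by plants x plant spacing) and acts as the periodic
#' tile during ray tracing.
#'
#' @param plants list of [mesh_plant()] meshes (>= 1), cycled over the grid.
#' @param layout a [canopy_layout()].
#' @param rng_seed seed for the azimuth draws.
#' @param ceiling_cm optional domain ceiling; a warning is issued when a
#'   plant exceeds it.
#' @return a `CanopyScene`: plant meshes, per-instance placements, scoring
#'   region and domain box.
#' @export
build_canopy <- function(plants, layout = canopy_layout(), rng_seed = 1L,
                         ceiling_cm = NULL) {
  if (!length(plants)) stopf("need at least one plant mesh")
  if (inherits(plants, "PlantMesh")) plants <- list(plants)
  n_inst <- layout$rows * layout$plants_per_row
  rows <- rep(seq_len(layout$rows), each = layout$plants_per_row)
  cols <- rep(seq_len(layout$plants_per_row), times = layout$rows)
  x <- (rows - (layout$rows + 1) / 2) * layout$row_spacing_cm
  y <- (cols - (layout$plants_per_row + 1) / 2) * layout$plant_spacing_cm
  plant_idx <- ((seq_len(n_inst) - 1L) %% length(plants)) + 1L
  az <- if (isTRUE(layout$azimuth_random))
    with_seed(rng_seed, sample(c(0, 90, 180, 270), n_inst, replace = TRUE))
  else rep(0, n_inst)
  region <- c(xmin = -layout$region_cm[1] / 2, xmax = layout$region_cm[1] / 2,
              ymin = -layout$region_cm[2] / 2, ymax = layout$region_cm[2] / 2)
  scored <- x >= region["xmin"] & x <= region["xmax"] &
            y >= region["ymin"] & y <= region["ymax"]
  footprint <- c(layout$rows * layout$row_spacing_cm,
                 layout$plants_per_row * layout$plant_spacing_cm)
  if (layout$region_cm[1] > footprint[1] || layout$region_cm[2] > footprint[2])
    warnf("scoring region exceeds the planted footprint")
  zmax <- max(vapply(plants, function(m) max(m$vertices[, 3]), numeric(1)))
  if (!is.null(ceiling_cm) && zmax > ceiling_cm)
    warnf("plant height %.1f cm exceeds the domain ceiling %.1f cm", zmax, ceiling_cm)
  domain <- c(xmin = -footprint[1] / 2, xmax = footprint[1] / 2,
              ymin = -footprint[2] / 2, ymax = footprint[2] / 2,
              zmin = 0, zmax = zmax + 1)
  structure(list(plants = plants,
                 instances = data.frame(instance = seq_len(n_inst),
                                        plant = plant_idx, x = x, y = y,
                                        azimuth_deg = az, scored = scored),
                 layout = layout, region = region, domain = domain,
                 rng_seed = rng_seed),
            class = "CanopyScene")
}

#' @export
print.CanopyScene <- function(x, ...) {
  cat(sprintf("CanopyScene: %d instances (%d scored), %d distinct plants, LAI %.2f\n",
              nrow(x$instances), sum(x$instances$scored), length(x$plants),
              compute_lai(x)))
  invisible(x)
}

#' Leaf area index of a canopy scene
#'
#' LAI = one-sided leaf area of the in-scope plants divided by the
#' corresponding ground area: the scoring region for `scope = "scored"`,
#' the full planted footprint for `scope = "all"`.
#'
#' @param scene a [build_canopy()] scene.
#' @param scope "scored" or "all".
#' @return dimensionless scalar.
#' @export
compute_lai <- function(scene, scope = c("scored", "all")) {
  scope <- match.arg(scope)
  leaf_area <- vapply(scene$plants, total_leaf_area, numeric(1))
  if (scope == "scored") {
    sel <- scene$instances$scored
    ground <- unname(diff(scene$region[c("xmin", "xmax")]) *
                       diff(scene$region[c("ymin", "ymax")]))
  } else {
    sel <- rep(TRUE, nrow(scene$instances))
    ground <- unname(diff(scene$domain[c("xmin", "xmax")]) *
                       diff(scene$domain[c("ymin", "ymax")]))
  }
  if (ground <= 0) stopf("zero ground area")
  sum(leaf_area[scene$instances$plant[sel]]) / ground
}

# Flatten a scene into world-space triangles plus a per-facet attribute
# table; per-leaf reflectance/transmittance resolved from `optics`.
flatten_scene <- function(scene, optics = NULL) {
  tri_list <- vector("list", nrow(scene$instances))
  fac_list <- vector("list", nrow(scene$instances))
  for (i in seq_len(nrow(scene$instances))) {
    inst <- scene$instances[i, ]
    mesh <- scene$plants[[inst$plant]]
    v <- rotate_z(mesh$vertices, inst$azimuth_deg)
    v[, 1] <- v[, 1] + inst$x
    v[, 2] <- v[, 2] + inst$y
    t0 <- v[mesh$triangles[, 1], , drop = FALSE]
    t1 <- v[mesh$triangles[, 2], , drop = FALSE]
    t2 <- v[mesh$triangles[, 3], , drop = FALSE]
    tri_list[[i]] <- cbind(t0, t1, t2)
    fac_list[[i]] <- data.frame(instance = inst$instance, plant = inst$plant,
                                leaf = mesh$facet_leaf,
                                layer = mesh$facet_layer,
                                area_cm2 = mesh$facet_area,
                                scored = inst$scored)
  }
  facets <- do.call(rbind, fac_list)
  facets$facet <- seq_len(nrow(facets))
  rt <- resolve_optics(facets, optics)
  facets$R <- rt$R
  facets$T <- rt$T
  list(tri = do.call(rbind, tri_list), facets = facets)
}

# optics: NULL (black leaves), a single leaf_optics, a list of per-plant
# optics (each a single leaf_optics or a per-leaf list), or a data frame
# with columns plant, leaf, R, T.
resolve_optics <- function(facets, optics) {
  n <- nrow(facets)
  R <- numeric(n)
  T <- numeric(n)
  leafy <- facets$leaf > 0
  if (is.null(optics)) {
  } else if (inherits(optics, "LeafOpticalProperties")) {
    R[leafy] <- optics$reflectance
    T[leafy] <- optics$transmittance
  } else if (is.data.frame(optics)) {
    key <- paste(facets$plant, facets$leaf)
    m <- match(key, paste(optics$plant, optics$leaf))
    if (anyNA(m[leafy])) stopf("optics table misses some (plant, leaf) pairs")
    R[leafy] <- optics$R[m[leafy]]
    T[leafy] <- optics$T[m[leafy]]
  } else if (is.list(optics)) {
    for (i in which(leafy)) {
      po <- optics[[facets$plant[i]]]
      o <- if (inherits(po, "LeafOpticalProperties")) po else po[[facets$leaf[i]]]
      R[i] <- o$reflectance
      T[i] <- o$transmittance
    }
  } else stopf("unsupported optics specification")
  if (any(R + T > 1 + 1e-12)) stopf("R + T > 1 for at least one leaf")
  list(R = R, T = T)
}
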