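# Parametric maize-like plant generation and mesh-surface point sampling.
# The generator emulates the two contrasting architectures used throughout
# the package examples: "erect" (compact, upright leaves) and "spread"
# (fewer, longer, droopier leaves), plus a "toy-flat" architecture of flat
# horizontal rectangular leaves for analytic checks.

#' Architecture parameter presets
#'
#' Returns a parameter set for [generate_synthetic_plant()]. Values are
#' synthetic but chosen to span realistic maize ranges (8-16 leaves, leaf
#' length 40-90 cm, width 4-10 cm): `erect` has many short upright leaves,
#' `spread` fewer, longer, more pendulous leaves, `toy-flat` a small plant
#' of flat horizontal rectangular leaves for analytic tests.
#'
#' @param name one of "erect", "spread", "toy-flat".
#' @return named list of generator parameters.
#' @export
architecture_preset <- function(name = c("erect", "spread", "toy-flat")) {
  name <- match.arg(name)
  switch(name,
    erect = list(n_leaves = 12L, leaf_length = c(45, 70), leaf_width = c(5.5, 8),
                 stem_height = 110, stem_radius = 1.2,
                 insertion_angle_deg = 22, curvature_deg = 30,
                 base_height_frac = c(0.10, 0.95), phyllotaxis = "alternate",
                 width_profile = "maize", azimuth_jitter_deg = 12,
                 length_jitter = 0.05, angle_jitter_deg = 4, stations = 31L),
    spread = list(n_leaves = 10L, leaf_length = c(55, 88), leaf_width = c(6, 9.5),
                  stem_height = 100, stem_radius = 1.2,
                  insertion_angle_deg = 52, curvature_deg = 65,
                  base_height_frac = c(0.10, 0.95), phyllotaxis = "alternate",
                  width_profile = "maize", azimuth_jitter_deg = 12,
                  length_jitter = 0.05, angle_jitter_deg = 5, stations = 31L),
    `toy-flat` = list(n_leaves = 4L, leaf_length = 40, leaf_width = 6,
                      stem_height = 50, stem_radius = 0.8,
                      insertion_angle_deg = 90, curvature_deg = 0,
                      base_height_frac = c(0.3, 0.9), phyllotaxis = "alternate",
                      width_profile = "rect", azimuth_jitter_deg = 0,
                      length_jitter = 0, angle_jitter_deg = 0, stations = 31L))
}

# relative half-width profile along relative arc length s in [0,1]
width_profile_fun <- function(profile) {
  switch(profile,
         rect = function(s) rep(1, length(s)),
         # wide at the collar (~55% of max, as for a real blade emerging
         # from its sheath), widest near 40% of the length, tapering tip
         maize = function(s) sin(pi * (0.12 + 0.88 * pmin(pmax(s, 0), 1)))^0.6,
         stopf("unknown width profile '%s'", profile))
}

# expand a scalar or range c(min, max) to per-leaf values peaking mid-stem
profile_values <- function(x, n) {
  if (length(x) == 1) return(rep(x, n))
  if (length(x) == n) return(x)
  if (length(x) == 2) {
    # longest leaves around 60% of the stack, shorter at the extremes
    pos <- (seq_len(n) - 0.5) / n
    shape <- sin(pi * pos^0.8)
    return(x[1] + (x[2] - x[1]) * shape)
  }
  stopf("parameter must be a scalar, a range, or one value per leaf")
}

#' Generate a synthetic maize-like plant
#'
#' Builds a [plant_vector_model()] from an architecture parameter set.
#' Leaves are attached with alternating (180 degree) or spiral phyllotaxis,
#' start at `insertion_angle_deg` from the vertical and droop progressively
#' by `curvature_deg` from base to tip. Deterministic for a fixed seed.
#'
#' @param params parameter list, see [architecture_preset()]. Required
#'   fields: `n_leaves`, `leaf_length`, `leaf_width`, `stem_height`;
#'   remaining fields default to the `erect` preset values.
#' @param rng_seed integer seed controlling the jitter draws.
#' @return a `PlantVectorModel`.
#' @export
generate_synthetic_plant <- function(params, rng_seed = 1L) {
  p <- modifyList(architecture_preset("erect"), params)
  if (p$n_leaves < 1) stopf("invalid parameters: need at least one leaf")
  if (any(unlist(p[c("leaf_length", "leaf_width", "stem_height",
                     "stem_radius")]) <= 0))
    stopf("invalid parameters: lengths must be positive")
  n <- as.integer(p$n_leaves)
  len <- profile_values(p$leaf_length, n)
  wid <- profile_values(p$leaf_width, n)
  ins <- profile_values(p$insertion_angle_deg, n)
  curv <- profile_values(p$curvature_deg, n)
  hfrac <- seq(p$base_height_frac[1], p$base_height_frac[2], length.out = n)
  wfun <- width_profile_fun(p$width_profile)
  s <- as.integer(p$stations)
  with_seed(rng_seed, {
    len <- len * (1 + rnorm(n, 0, p$length_jitter))
    ins <- ins + rnorm(n, 0, p$angle_jitter_deg)
    az0 <- runif(1, 0, 360)
    az <- switch(p$phyllotaxis,
                 alternate = az0 + 180 * (seq_len(n) - 1),
                 spiral = az0 + 137.5 * (seq_len(n) - 1),
                 stopf("unknown phyllotaxis '%s'", p$phyllotaxis))
    az <- az + rnorm(n, 0, p$azimuth_jitter_deg)
    leaves <- vector("list", n)
    for (k in seq_len(n)) {
      leaves[[k]] <- build_parametric_leaf(
        base = c(p$stem_radius * sin(deg2rad(az[k])),
                 p$stem_radius * cos(deg2rad(az[k])),
                 hfrac[k] * p$stem_height),
        azimuth_deg = az[k], length_cm = len[k], width_cm = wid[k],
        insertion_deg = ins[k], curvature_deg = curv[k],
        stations = s, wfun = wfun, leaf_index = k)
    }
  })
  top <- max(vapply(leaves, function(l) max(l$axis[, 3]), numeric(1)),
             p$stem_height)
  mid <- top / 2
  for (k in seq_len(n))
    leaves[[k]]$layer <- if (leaves[[k]]$axis[1, 3] > mid) 2L else 1L
  stem <- cbind(0, 0, seq(0, p$stem_height, length.out = 8))
  plant_vector_model(leaves, stem, p$stem_radius)
}

build_parametric_leaf <- function(base, azimuth_deg, length_cm, width_cm,
                                  insertion_deg, curvature_deg, stations,
                                  wfun, leaf_index) {
  a <- deg2rad(azimuth_deg)
  u_az <- c(sin(a), cos(a), 0)                 # horizontal leaf direction
  w_dir <- c(cos(a), -sin(a), 0)               # width direction (horizontal)
  ds <- length_cm / (stations - 1)
  srel <- (seq_len(stations) - 1) / (stations - 1)
  # tangent angle from vertical grows linearly from insertion to +curvature
  theta <- deg2rad(insertion_deg + curvature_deg * srel)
  axis <- matrix(0, stations, 3)
  axis[1, ] <- base
  for (i in seq_len(stations - 1)) {
    th <- (theta[i] + theta[i + 1]) / 2
    axis[i + 1, ] <- axis[i, ] + ds * (sin(th) * u_az + c(0, 0, cos(th)))
  }
  hw <- width_cm / 2 * wfun(srel)
  left <- -outer(hw, w_dir)
  right <- outer(hw, w_dir)
  leaf_vector_model(axis, left, right, layer = 1L, leaf_index = leaf_index)
}

#' Sample a labelled point cloud from a plant mesh
#'
#' Draws points uniformly on the mesh surface (facet areas as weights,
#' uniform barycentric coordinates within facets), labelled with the facet
#' organ. Optionally adds isotropic Gaussian jitter and a ground plane.
#'
#' @param mesh a [mesh_plant()] result (or a `PlantVectorModel`, which is
#'   meshed first).
#' @param points_per_cm2 sampling density (points per cm2 of surface).
#' @param noise_sd_cm isotropic Gaussian jitter (cm).
#' @param ground extent (cm) of a square ground plane at z = 0 to add
#'   (sampled at the same density), or `NULL` for none. Ground points are
#'   labelled 0 and tagged "ground" in the cloud's `source` field.
#' @param rng_seed seed; sampling is deterministic for a fixed seed.
#' @return a [labeled_point_cloud()] with a per-point `source` tag
#'   ("leaf", "stem" or "ground").
#' @export
sample_point_cloud <- function(mesh, points_per_cm2 = 4, noise_sd_cm = 0,
                               ground = NULL, rng_seed = 1L) {
  if (inherits(mesh, "PlantVectorModel")) mesh <- mesh_plant(mesh)
  nt <- nrow(mesh$triangles)
  n_pts <- max(50L, round(points_per_cm2 * sum(mesh$facet_area)))
  with_seed(rng_seed, {
    fidx <- sample.int(nt, n_pts, replace = TRUE, prob = mesh$facet_area)
    r1 <- runif(n_pts)
    r2 <- runif(n_pts)
    sw <- r1 + r2 > 1
    r1[sw] <- 1 - r1[sw]
    r2[sw] <- 1 - r2[sw]
    v0 <- mesh$vertices[mesh$triangles[fidx, 1], , drop = FALSE]
    v1 <- mesh$vertices[mesh$triangles[fidx, 2], , drop = FALSE]
    v2 <- mesh$vertices[mesh$triangles[fidx, 3], , drop = FALSE]
    pts <- v0 + r1 * (v1 - v0) + r2 * (v2 - v0)
    labels <- mesh$facet_leaf[fidx]
    src <- ifelse(labels > 0, "leaf", "stem")
    if (!is.null(ground)) {
      ng <- max(10L, round(points_per_cm2 * ground^2))
      gp <- cbind(runif(ng, -ground / 2, ground / 2),
                  runif(ng, -ground / 2, ground / 2), 0)
      pts <- rbind(pts, gp)
      labels <- c(labels, rep.int(0L, ng))
      src <- c(src, rep.int("ground", ng))
    }
    if (noise_sd_cm > 0)
      pts <- pts + matrix(rnorm(length(pts), 0, noise_sd_cm), nrow(pts), 3)
  })
  layer <- NULL
  leaves <- sort(unique(mesh$facet_leaf[mesh$facet_leaf > 0]))
  if (length(leaves)) {
    layer <- vapply(leaves, function(k)
      mesh$facet_layer[match(k, mesh$facet_leaf)], integer(1))
    names(layer) <- leaves
  }
  labeled_point_cloud(pts, labels, layer = layer, source = src)
}
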