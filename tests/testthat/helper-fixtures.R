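# Shared fixtures: analytic single-leaf plants and meshes, turbid-medium
# scenes, and small variety bundles. Everything is generated in code.

rot_y <- function(p, ang_deg) {
  a <- ang_deg * pi / 180
  R <- matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  p %*% t(R)
}

# flat rectangular single-leaf plant: axis along +x at height z
flat_leaf_plant <- function(length_cm = 60, width_cm = 8, z = 30,
                            stations = 31) {
  axis <- cbind(seq(0, length_cm, length.out = stations), 0, z)
  hw <- width_cm / 2
  leaf <- leaf_vector_model(axis,
                            cbind(0, rep(-hw, stations), 0),
                            cbind(0, rep(hw, stations), 0),
                            layer = 2L, leaf_index = 1L)
  plant_vector_model(list(leaf), stem = rbind(c(0, 0, 0), c(0, 0, z)),
                     stem_radius = 1)
}

# bare horizontal square leaf mesh (no stem), centred at the origin
square_leaf_mesh <- function(size = 100, z = 50, tilt_deg = 0, leaf = 1L,
                             layer = 2L) {
  v <- rbind(c(-size / 2, -size / 2, 0), c(size / 2, -size / 2, 0),
             c(size / 2, size / 2, 0), c(-size / 2, size / 2, 0))
  if (tilt_deg != 0) v <- rot_y(v, tilt_deg)
  v[, 3] <- v[, 3] + z
  tri <- rbind(c(1L, 2L, 3L), c(1L, 3L, 4L))
  area <- rep(size^2 / 2, 2)
  structure(list(vertices = v, triangles = tri,
                 facet_leaf = rep(leaf, 2), facet_layer = rep(layer, 2),
                 facet_area = area),
            class = "PlantMesh")
}

merge_meshes <- function(...) {
  ms <- list(...)
  off <- 0L
  verts <- NULL; tris <- NULL; fl <- NULL; fy <- NULL; fa <- NULL
  for (m in ms) {
    verts <- rbind(verts, m$vertices)
    tris <- rbind(tris, m$triangles + off)
    off <- off + nrow(m$vertices)
    fl <- c(fl, m$facet_leaf); fy <- c(fy, m$facet_layer)
    fa <- c(fa, m$facet_area)
  }
  structure(list(vertices = verts, triangles = tris, facet_leaf = fl,
                 facet_layer = fy, facet_area = fa), class = "PlantMesh")
}

# homogeneous slab of small randomly oriented facets with total one-sided
# area = lai * tile^2 (turbid-medium analogue, spherical angle distribution)
turbid_mesh <- function(lai, tile = 100, zlo = 20, zhi = 120, facet = 4,
                        seed = 1) {
  n <- ceiling(lai * tile * tile / (0.5 * facet * facet))
  set.seed(seed)
  ctr <- cbind(runif(n, -tile / 2, tile / 2), runif(n, -tile / 2, tile / 2),
               runif(n, zlo, zhi))
  u <- matrix(rnorm(3 * n), n, 3); u <- u / sqrt(rowSums(u^2))
  v <- matrix(rnorm(3 * n), n, 3)
  v <- v - rowSums(v * u) * u; v <- v / sqrt(rowSums(v^2))
  v0 <- ctr; v1 <- ctr + facet * u; v2 <- ctr + facet * v
  structure(list(vertices = rbind(v0, v1, v2),
                 triangles = cbind(1:n, n + (1:n), 2 * n + (1:n)),
                 facet_leaf = rep(1L, n), facet_layer = rep(2L, n),
                 facet_area = rep(0.5 * facet^2, n)),
            class = "PlantMesh")
}

unit_layout <- function(size = 100) {
  canopy_layout(1, 1, size, size, c(size, size), azimuth_random = FALSE)
}

fixed_sky <- function(zenith = 0, azimuth = 180, direct = 1000, diffuse = 0) {
  structure(list(zenith = zenith, azimuth = azimuth, direct_ppfd = direct,
                 diffuse_ppfd = diffuse), class = "SkyCondition")
}

# small two-plant variety bundles for dissection tests
test_bundle <- function(preset, label, spad, up = c(32, 0.055, 0.75, 1.8),
                        bottom = c(24, 0.05, 0.7, 1.4), seed_off = 10L) {
  variety_bundle(
    label,
    lapply(1:2, function(i)
      generate_synthetic_plant(architecture_preset(preset),
                               rng_seed = i + seed_off)),
    list(up = do.call(light_response_params, as.list(up)),
         bottom = do.call(light_response_params, as.list(bottom))),
    spad = spad)
}

small_sim <- function(hours = c(9, 12, 15), rays = 2000) {
  dissect_config(layout = canopy_layout(2, 4, 55, 15, c(60, 40)),
                 hours = hours, rays_per_m2 = rays)
}
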