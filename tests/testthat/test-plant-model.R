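# Leaf/plant vector models: trait measurement, trait adjustment, meshing,
# synthetic generation, and extraction from point clouds.

test_that("rectangular leaf traits are measured exactly", {
  p <- flat_leaf_plant(60, 8, z = 30)
  tr <- measure_traits(p)
  expect_equal(tr$length_cm, 60)
  expect_equal(tr$width_cm, 8)
  expect_equal(tr$base_height_cm, 30)
  expect_equal(tr$area_cm2, 480, tolerance = 0.02)
})

test_that("base heights are reported exactly by construction", {
  leaves <- lapply(seq_along(c(10, 30, 50)), function(i) {
    z <- c(10, 30, 50)[i]
    axis <- cbind(seq(1, 40, length.out = 11), 0, z)
    leaf_vector_model(axis, cbind(0, rep(-2, 11), 0), cbind(0, rep(2, 11), 0),
                      layer = 1L, leaf_index = i)
  })
  p <- plant_vector_model(leaves, rbind(c(0, 0, 0), c(0, 0, 60)), 1.5)
  expect_equal(measure_traits(p)$base_height_cm, c(10, 30, 50))
})

test_that("curved quarter-circle leaf arc length matches the closed form", {
  r <- 40
  th <- seq(0, pi / 2, length.out = 61)
  axis <- cbind(r * sin(th), 0, 50 + r * (cos(th) - 1))  # droops from vertical
  leaf <- leaf_vector_model(axis, cbind(0, rep(-3, 61), 0),
                            cbind(0, rep(3, 61), 0), 2L, 1L)
  p <- plant_vector_model(list(leaf), rbind(c(0, 0, 0), c(0, 0, 50)), 1)
  expect_equal(measure_traits(p)$length_cm, 2 * pi * r / 4, tolerance = 0.02)
})

test_that("identity adjustment is a geometric no-op", {
  p <- generate_synthetic_plant(architecture_preset("spread"), rng_seed = 1)
  p2 <- apply_adjustment(p, trait_adjustment())
  expect_equal(p2$leaves, p$leaves)
  expect_equal(p2$stem, p$stem)
  m1 <- mesh_plant(p)
  m2 <- mesh_plant(p2)
  expect_identical(m1$vertices, m2$vertices)   # mesh determinism
  expect_identical(m1$triangles, m2$triangles)
})

test_that("length scaling doubles length and leaves width unchanged", {
  p <- flat_leaf_plant(60, 8)
  tr <- measure_traits(apply_adjustment(p, trait_adjustment(ll_factor = 2)))
  expect_equal(tr$length_cm, 120)
  expect_equal(tr$width_cm, 8)
  trw <- measure_traits(apply_adjustment(p, trait_adjustment(lw_factor = 1.5)))
  expect_equal(trw$width_cm, 12)
  expect_equal(trw$length_cm, 60)
})

test_that("length adjustments compose multiplicatively", {
  p <- generate_synthetic_plant(architecture_preset("erect"), rng_seed = 2)
  a <- apply_adjustment(apply_adjustment(p, trait_adjustment(ll_factor = 1.2)),
                        trait_adjustment(ll_factor = 1.5))
  b <- apply_adjustment(p, trait_adjustment(ll_factor = 1.8))
  expect_equal(measure_traits(a)$length_cm, measure_traits(b)$length_cm,
               tolerance = 1e-10)
})

test_that("insertion-angle rotation lays a vertical leaf horizontal", {
  # vertical straight leaf along +z
  axis <- cbind(0, 0, seq(20, 80, length.out = 31))
  leaf <- leaf_vector_model(axis, matrix(c(-3, 0, 0), 31, 3, byrow = TRUE),
                            matrix(c(3, 0, 0), 31, 3, byrow = TRUE), 2L, 1L)
  p <- plant_vector_model(list(leaf), rbind(c(0, 0, 0), c(0, 0, 80)), 1)
  # negative delta = less erect; -90 degrees lays it flat
  p2 <- apply_adjustment(p, trait_adjustment(la_delta_deg = -90))
  l2 <- p2$leaves[[1]]
  expect_equal(diff(range(l2$axis[, 3])), 0, tolerance = 1e-8)
  m <- mesh_plant(p2)
  leaf_facets <- m$facet_leaf > 0
  v1 <- m$vertices[m$triangles[leaf_facets, 1], , drop = FALSE]
  v2 <- m$vertices[m$triangles[leaf_facets, 2], , drop = FALSE]
  v3 <- m$vertices[m$triangles[leaf_facets, 3], , drop = FALSE]
  # projected ground footprint of the flat leaf = length x width
  xy <- rbind(v1, v2, v3)[, 1:2]
  footprint <- diff(range(xy[, 1])) * diff(range(xy[, 2]))
  expect_equal(footprint, 60 * 6, tolerance = 0.02)
})

test_that("positive angle delta makes leaves more erect, curvature droops", {
  p <- generate_synthetic_plant(architecture_preset("spread"), rng_seed = 3)
  tip_z <- function(pl) mean(vapply(pl$leaves, function(l)
    l$axis[nrow(l$axis), 3], numeric(1)))
  expect_gt(tip_z(apply_adjustment(p, trait_adjustment(la_delta_deg = 20))),
            tip_z(p))
  expect_lt(tip_z(apply_adjustment(p, trait_adjustment(lc_delta_deg = 60))),
            tip_z(p))
  # LC/LA leave arc length and width untouched
  tr0 <- measure_traits(p)
  tr1 <- measure_traits(apply_adjustment(p, trait_adjustment(lc_delta_deg = 60,
                                                             la_delta_deg = 15)))
  expect_equal(tr1$length_cm, tr0$length_cm, tolerance = 1e-8)
  expect_equal(tr1$width_cm, tr0$width_cm, tolerance = 1e-8)
})

test_that("leaf-number deltas clone from the top and remove from the bottom", {
  p <- generate_synthetic_plant(architecture_preset("erect"), rng_seed = 4)
  n <- length(p$leaves)
  up <- apply_adjustment(p, trait_adjustment(ln_delta = 3))
  expect_equal(length(up$leaves), n + 3)
  base_z0 <- vapply(p$leaves, function(l) l$axis[1, 3], numeric(1))
  base_z1 <- vapply(up$leaves, function(l) l$axis[1, 3], numeric(1))
  expect_gt(min(tail(sort(base_z1), 3)), max(base_z0))  # inserted above top
  dn <- apply_adjustment(p, trait_adjustment(ln_delta = -2))
  expect_equal(length(dn$leaves), n - 2)
  expect_equal(min(vapply(dn$leaves, function(l) l$axis[1, 3], numeric(1))),
               sort(base_z0)[3])                         # lowest two removed
  expect_equal(vapply(dn$leaves, function(l) l$leaf_index, integer(1)),
               seq_len(n - 2))                           # contiguous reindex
  expect_error(apply_adjustment(p, trait_adjustment(ln_delta = -n)),
               "no leaves left")
})

test_that("meshing converges under station refinement", {
  params <- list(n_leaves = 1L, leaf_length = 70, leaf_width = 9,
                 stem_height = 60, insertion_angle_deg = 45,
                 curvature_deg = 80, base_height_frac = c(0.8, 0.8),
                 azimuth_jitter_deg = 0, length_jitter = 0,
                 angle_jitter_deg = 0)
  a31 <- total_leaf_area(mesh_plant(generate_synthetic_plant(
    modifyList(params, list(stations = 31L)), rng_seed = 5)))
  a62 <- total_leaf_area(mesh_plant(generate_synthetic_plant(
    modifyList(params, list(stations = 62L)), rng_seed = 5)))
  expect_lt(abs(a62 / a31 - 1), 0.005)
})

test_that("synthetic generator is deterministic and respects presets", {
  p1 <- generate_synthetic_plant(architecture_preset("erect"), rng_seed = 11)
  p2 <- generate_synthetic_plant(architecture_preset("erect"), rng_seed = 11)
  expect_equal(p1, p2)
  # erect preset: all insertion angles within 30 degrees of vertical
  for (l in p1$leaves) {
    seg <- l$axis[2, ] - l$axis[1, ]
    ang <- acos(seg[3] / sqrt(sum(seg^2))) * 180 / pi
    expect_lte(ang, 30 + 5)   # preset 22 deg + jitter sd 4 deg
  }
  expect_error(generate_synthetic_plant(list(n_leaves = 3, leaf_length = -5,
                                             leaf_width = 5, stem_height = 50)),
               "invalid parameters")
})

test_that("flat-leaf preset area matches count x length x width x shape", {
  params <- list(n_leaves = 12L, leaf_length = 60, leaf_width = 8,
                 stem_height = 110, insertion_angle_deg = 40,
                 curvature_deg = 0, width_profile = "maize",
                 azimuth_jitter_deg = 0, length_jitter = 0,
                 angle_jitter_deg = 0)
  p <- generate_synthetic_plant(params, rng_seed = 6)
  # shape factor = meshed area of one leaf / (L x W)
  single <- generate_synthetic_plant(modifyList(params, list(n_leaves = 1L)),
                                     rng_seed = 6)
  shape <- total_leaf_area(mesh_plant(single)) / (60 * 8)
  expect_equal(total_leaf_area(mesh_plant(p)), 12 * 60 * 8 * shape,
               tolerance = 0.05)
})

test_that("vector-model extraction recovers known leaf dimensions", {
  # synthetic flat rectangular leaf 60 x 8 sampled densely
  cl <- sample_point_cloud(flat_leaf_plant(60, 8, z = 30),
                           points_per_cm2 = 25, rng_seed = 7)
  p <- suppressWarnings(extract_vector_model(cl))  # advisory base-offset note
  tr <- measure_traits(p)
  expect_equal(tr$length_cm, 60, tolerance = 0.02)
  expect_equal(tr$width_cm, 8, tolerance = 0.05)

  # straight vertical leaf: axis monotone in z
  axis <- cbind(0.5, 0, seq(10, 70, length.out = 31))
  leaf <- leaf_vector_model(axis, matrix(c(-3, 0, 0), 31, 3, byrow = TRUE),
                            matrix(c(3, 0, 0), 31, 3, byrow = TRUE), 2L, 1L)
  pv <- plant_vector_model(list(leaf), rbind(c(0, 0, 0), c(0, 0, 70)), 1)
  clv <- sample_point_cloud(pv, points_per_cm2 = 25, rng_seed = 8)
  pe <- extract_vector_model(clv)
  expect_true(all(diff(pe$leaves[[1]]$axis[, 3]) > 0))
})

test_that("extraction errors on fragmented and undersized leaves", {
  a <- sample_point_cloud(flat_leaf_plant(30, 6, z = 20), 10, rng_seed = 9)
  b_pts <- a$points[a$source == "leaf", ] + matrix(rep(c(500, 0, 0),
    each = sum(a$source == "leaf")), ncol = 3)
  frag <- labeled_point_cloud(rbind(a$points, b_pts),
                              c(a$labels, rep(1L, nrow(b_pts))))
  expect_error(extract_vector_model(frag), "fragmented leaf")
  tiny <- labeled_point_cloud(matrix(rnorm(60), 20, 3), rep(1L, 20))
  expect_error(extract_vector_model(tiny), "degenerate leaf")
})

test_that("round trip generate -> cloud -> extract recovers traits", {
  for (preset in c("erect", "spread")) {
    p <- generate_synthetic_plant(architecture_preset(preset), rng_seed = 21)
    tr0 <- measure_traits(p)
    cl <- suppressWarnings(sample_point_cloud(p, points_per_cm2 = 8,
                                              noise_sd_cm = 0.1, rng_seed = 21))
    tr1 <- measure_traits(suppressWarnings(extract_vector_model(cl)))
    expect_lt(max(abs(tr1$length_cm / tr0$length_cm - 1)), 0.03)
    expect_lt(max(abs(tr1$base_height_cm - tr0$base_height_cm) /
                    tr0$base_height_cm), 0.03)
    expect_lt(max(abs(tr1$width_cm / tr0$width_cm - 1)), 0.08)
  }
})
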