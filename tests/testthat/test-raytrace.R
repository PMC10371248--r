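# Monte-Carlo ray tracing: analytic absorption cases, energy accounting,
# turbid-medium agreement, and the diurnal driver.

test_that("a black horizontal leaf absorbs the full vertical beam", {
  scene <- build_canopy(list(square_leaf_mesh(100, 50)), unit_layout(100))
  ab <- trace(scene, fixed_sky(zenith = 0, direct = 1000),
              leaf_optics(0, 0), rays_per_m2 = 1e5, rng_seed = 7)
  expect_equal(sum(ab$facets$absorbed_flux), 1000, tolerance = 0.01)
  expect_equal(ab$facets$absorbed_ppfd, c(1000, 1000), tolerance = 0.02)
})

test_that("absorption follows the cosine law for tilted leaves", {
  scene <- build_canopy(list(square_leaf_mesh(100, 50, tilt_deg = 60)),
                        unit_layout(100))
  ab <- trace(scene, fixed_sky(zenith = 0, direct = 1000),
              leaf_optics(0, 0), rays_per_m2 = 1e5, rng_seed = 7)
  # per unit leaf area: 1000 * cos(60) = 500
  expect_equal(sum(ab$facets$absorbed_flux), 500, tolerance = 0.01)
})

test_that("transmission stacks multiply", {
  mesh <- merge_meshes(square_leaf_mesh(100, 80, leaf = 1L),
                       square_leaf_mesh(100, 30, leaf = 2L, layer = 1L))
  scene <- build_canopy(list(mesh), unit_layout(100))
  optics <- data.frame(plant = 1, leaf = c(1, 2), R = c(0, 0), T = c(0.3, 0))
  ab <- trace(scene, fixed_sky(zenith = 0, direct = 1000), optics,
              rays_per_m2 = 1e5, rng_seed = 7)
  lower <- ab$facets$leaf == 2
  expect_equal(sum(ab$facets$absorbed_flux[lower]), 300, tolerance = 0.03)
  expect_equal(sum(ab$facets$absorbed_flux[!lower]), 700, tolerance = 0.01)
})

test_that("invalid optics and ray counts fail before tracing", {
  scene <- build_canopy(list(square_leaf_mesh(100, 50)), unit_layout(100))
  expect_error(trace(scene, fixed_sky(), leaf_optics(0.6, 0.3),
                     rays_per_m2 = 0), "rays_per_m2")
  bad <- data.frame(plant = 1, leaf = 1, R = 0.7, T = 0.5)
  expect_error(trace(scene, fixed_sky(), bad, rays_per_m2 = 100), "R \\+ T")
})

test_that("energy is conserved within Monte-Carlo tolerance", {
  plants <- lapply(1:2, function(i) mesh_plant(
    generate_synthetic_plant(architecture_preset("erect"), rng_seed = i)))
  scene <- build_canopy(plants, canopy_layout(2, 5, 55, 15, c(80, 60)),
                        rng_seed = 3)
  ab <- trace(scene, fixed_sky(zenith = 35, direct = 1200, diffuse = 300),
              leaf_optics(0.08, 0.07), rays_per_m2 = 2e5, rng_seed = 42)
  t <- ab$totals
  err <- abs(t$emitted - t$absorbed_leaf - t$absorbed_stem - t$ground -
               t$escaped) / t$emitted
  expect_lt(err, 0.005)
})

test_that("black-leaf results are independent of the bounce cap", {
  scene <- build_canopy(list(square_leaf_mesh(100, 50, tilt_deg = 30)),
                        unit_layout(100))
  a1 <- trace(scene, fixed_sky(direct = 800, diffuse = 200), NULL,
              rays_per_m2 = 2e4, max_bounces = 1L, rng_seed = 5)
  a2 <- trace(scene, fixed_sky(direct = 800, diffuse = 200), NULL,
              rays_per_m2 = 2e4, max_bounces = 10L, rng_seed = 5)
  expect_identical(a1$facets$absorbed_flux, a2$facets$absorbed_flux)
})

test_that("Monte-Carlo error shrinks as one over root ray count", {
  m <- mesh_plant(generate_synthetic_plant(architecture_preset("erect"),
                                           rng_seed = 1))
  scene <- build_canopy(list(m), canopy_layout(1, 1, 60, 60, c(60, 60),
                                               azimuth_random = FALSE))
  absorbed <- function(n, s) trace(scene, fixed_sky(zenith = 30),
                                   leaf_optics(0.1, 0.1), rays_per_m2 = n,
                                   rng_seed = s)$totals$absorbed_leaf
  s1 <- sd(vapply(1:12, function(s) absorbed(2000, s), numeric(1)))
  s2 <- sd(vapply(1:12, function(s) absorbed(8000, s), numeric(1)))
  expect_gt(s1 / s2, 1.3)   # expected ratio 2 for 4x rays, wide MC band
  expect_lt(s1 / s2, 3.1)
})

test_that("interception of a random black canopy matches Beer-Lambert", {
  for (L in c(1, 3)) {
    scene <- build_canopy(list(turbid_mesh(L, seed = L)), unit_layout(100))
    ab <- trace(scene, fixed_sky(zenith = 0, direct = 1000), NULL,
                rays_per_m2 = 5e4, rng_seed = 11)
    intercepted <- ab$totals$absorbed_leaf / ab$totals$emitted
    expect_equal(intercepted, 1 - exp(-0.5 * L), tolerance = 0.05)
  }
})

test_that("diurnal tracing handles night, symmetry and single hours", {
  m <- mesh_plant(generate_synthetic_plant(architecture_preset("erect"),
                                           rng_seed = 2))
  scene <- build_canopy(list(m), canopy_layout(1, 2, 60, 30, c(60, 60),
                                               azimuth_random = FALSE))
  day <- list(date = "2020-08-27", latitude = 30.93)
  night <- diurnal_trace(scene, day, NULL, hours = c(0, 2, 23),
                         rays_per_m2 = 1000)
  expect_true(all(vapply(night, function(a) a$totals$emitted, numeric(1)) == 0))
  # hours symmetric about solar noon give symmetric totals on an
  # azimuth-symmetric scene (horizontal leaf)
  flat <- build_canopy(list(square_leaf_mesh(60, 40)), unit_layout(100))
  sym <- diurnal_trace(flat, day, NULL, hours = c(9, 15),
                       rays_per_m2 = 4e4, rng_seed = 3)
  tot <- vapply(sym, function(a) a$totals$absorbed_leaf / a$totals$emitted,
                numeric(1))
  expect_equal(tot[[1]], tot[[2]], tolerance = 0.05)
  # a single diurnal hour equals trace() with that hour's sky and seed
  one <- diurnal_trace(scene, day, NULL, hours = 12, rays_per_m2 = 2000,
                       rng_seed = 5)
  sky12 <- sky_condition("2020-08-27", 12, 30.93)
  direct <- trace(scene, sky12, NULL, rays_per_m2 = 2000, rng_seed = 5 + 12)
  expect_equal(one[[1]]$facets$absorbed_flux, direct$facets$absorbed_flux)
})
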