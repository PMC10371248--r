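# Non-rectangular hyperbola, light-response fitting, canopy integration.

test_that("NRH limits: dark respiration, saturation, Blackman", {
  p <- light_response_params(30, 0.05, 0.7, 1.5)
  expect_equal(leaf_A(0, p), -1.5)
  expect_equal(leaf_A(1e12, p), 30 - 1.5, tolerance = 1e-6)
  # theta -> 1 gives the Blackman limit min(phi I, Pmax) below saturation
  pb <- light_response_params(30, 0.05, 1 - 1e-12, 1.5)
  expect_equal(leaf_A(300, pb), 0.05 * 300 - 1.5, tolerance = 1e-3)
  # theta = 0 falls back to the rectangular hyperbola
  p0 <- light_response_params(30, 0.05, 0, 1.5)
  I <- 400
  expect_equal(leaf_A(I, p0), 0.05 * I * 30 / (0.05 * I + 30) - 1.5)
})

test_that("NRH matches an independent quadratic-root oracle", {
  set.seed(20)
  for (i in 1:200) {
    Pmax <- runif(1, 5, 60); phi <- runif(1, 0.01, 0.12)
    theta <- runif(1, 0.05, 1); Rd <- runif(1, 0, 5); I <- runif(1, 0, 2500)
    p <- light_response_params(Pmax, phi, theta, Rd)
    roots <- Re(polyroot(c(phi * I * Pmax, -(phi * I + Pmax), theta)))
    expect_equal(leaf_A(I, p), min(roots) - Rd, tolerance = 1e-9)
  }
})

test_that("NRH is nondecreasing and concave in light", {
  I <- seq(0, 2500, by = 10)
  for (theta in c(0.1, 0.5, 0.9, 1)) {
    A <- leaf_A(I, light_response_params(35, 0.06, theta, 2))
    expect_true(all(diff(A) >= -1e-12))
    expect_true(all(diff(diff(A)) <= 1e-9))
  }
})

test_that("noiseless fits recover the generating parameters", {
  grid <- c(2000, 1500, 1000, 800, 600, 400, 300, 200, 150, 100, 50, 0)
  truth <- light_response_params(31.4, 0.057, 0.72, 1.65)
  f <- fit_light_response(grid, leaf_A(grid, truth))
  expect_true(f$converged)
  expect_equal(f$params$Pmax, 31.4, tolerance = 1e-4)
  expect_equal(f$params$phi, 0.057, tolerance = 1e-4)
  expect_equal(f$params$theta, 0.72, tolerance = 1e-4)
  expect_equal(f$params$Rd, 1.65, tolerance = 1e-4)
})

test_that("fits under noise have small median bias for Pmax and phi", {
  grid <- c(2000, 1500, 1000, 800, 600, 400, 300, 200, 150, 100, 50, 0)
  truth <- light_response_params(30, 0.05, 0.7, 1.5)
  set.seed(30)
  errs <- t(replicate(100, {
    A <- leaf_A(grid, truth) + rnorm(length(grid), 0, 0.5)
    f <- fit_light_response(grid, A)
    c(f$params$Pmax / 30 - 1, f$params$phi / 0.05 - 1)
  }))
  expect_lt(abs(median(errs[, 1])), 0.03)
  expect_lt(abs(median(errs[, 2])), 0.03)
})

test_that("degenerate light-response data is flagged, not thrown", {
  grid <- c(2000, 1500, 1000, 800, 600, 400, 300, 200, 150, 100, 50, 0)
  f <- fit_light_response(grid, rep(0, 12))
  expect_false(f$converged)
  expect_error(fit_light_response(c(0, 100, 200), c(-1, 3, 5)), "6 distinct")
  expect_error(fit_light_response(grid[-12], leaf_A(grid[-12],
    light_response_params(30, 0.05, 0.7, 1.5))), "dark")
})

test_that("quantum yield slope uses exactly the four low-light levels", {
  I <- c(2000, 1000, 400, 200, 150, 100, 50, 0)
  expect_equal(quantum_yield_slope(I, 0.06 * I - 1), 0.06)
  # curvature bias: slope below phi but above 90% of it for mild curvature
  p <- light_response_params(35, 0.06, 0.9, 1)
  sl <- quantum_yield_slope(I, leaf_A(I, p))
  expect_lt(sl, 0.06)
  expect_gt(sl, 0.9 * 0.06)
  # symmetric duplicates leave the slope unchanged
  I2 <- c(I, 50, 200)
  A2 <- c(0.06 * I - 1, 0.06 * 50 - 1, 0.06 * 200 - 1)
  expect_equal(quantum_yield_slope(I2, A2), 0.06)
  expect_error(quantum_yield_slope(c(50, 100, 150), c(1, 2, 3)),
               "missing PPFD levels: 200")
})

test_that("single-facet canopy photosynthesis equals the leaf model", {
  scene <- build_canopy(list(square_leaf_mesh(100, 50)), unit_layout(100))
  ab <- trace(scene, fixed_sky(zenith = 0, direct = 1000), NULL,
              rays_per_m2 = 1e5, rng_seed = 1)
  prm <- list(up = light_response_params(30, 0.05, 0.7, 1.5),
              bottom = light_response_params(24, 0.05, 0.7, 1.4))
  res <- canopy_A(ab, prm, scene)
  # absorbed ppfd is 1000 within MC error on each facet of the 1 m2 leaf
  expect_equal(res$A_c, leaf_A(1000, prm$up), tolerance = 0.01)
})

test_that("dark canopies respire in proportion to LAI", {
  mesh <- merge_meshes(square_leaf_mesh(100, 60),
                       square_leaf_mesh(100, 30, leaf = 2L, layer = 1L))
  scene <- build_canopy(list(mesh), unit_layout(100))
  dark <- trace(scene, fixed_sky(zenith = 120, direct = 0, diffuse = 0), NULL,
                rays_per_m2 = 100, rng_seed = 1)
  prm <- list(up = light_response_params(30, 0.05, 0.7, 1.5),
              bottom = light_response_params(24, 0.05, 0.7, 1.5))
  res <- canopy_A(dark, prm, scene)
  expect_equal(res$A_c, -1.5 * compute_lai(scene))
})

test_that("canopy photosynthesis is invariant to facet subdivision", {
  # same 1 m2 leaf as 2 or 8 facets: equal absorbed PPFD => equal A_c
  quad <- square_leaf_mesh(100, 50)
  sub <- merge_meshes(square_leaf_mesh(50, 50), square_leaf_mesh(50, 50),
                      square_leaf_mesh(50, 50), square_leaf_mesh(50, 50))
  prm <- list(up = light_response_params(30, 0.05, 0.7, 1.5),
              bottom = light_response_params(24, 0.05, 0.7, 1.4))
  mk <- function(m) {
    scene <- build_canopy(list(m), unit_layout(100))
    ab <- trace(scene, fixed_sky(zenith = 0, direct = 600), NULL,
                rays_per_m2 = 10, rng_seed = 2)
    ab$facets$absorbed_ppfd <- 600    # impose identical absorbed PPFD
    canopy_A(ab, prm, scene)$A_c
  }
  expect_equal(mk(quad), mk(sub))  # same total area split into more facets
  # missing layer parameters raise an error naming the layer
  scene <- build_canopy(list(quad), unit_layout(100))
  ab <- trace(scene, fixed_sky(), NULL, rays_per_m2 = 10, rng_seed = 1)
  expect_error(canopy_A(ab, list(bottom = prm$bottom), scene), "up")
})

test_that("diurnal integration follows the arithmetic definition", {
  # constant A_c = 10 for 12 daylight hours -> 0.432 mol m-2 day-1
  expect_equal(10 * 12 * 3600 / 1e6, 0.432)
  scene <- build_canopy(list(square_leaf_mesh(100, 50)), unit_layout(100))
  prm <- list(up = light_response_params(30, 0.05, 0.7, 1.5),
              bottom = light_response_params(24, 0.05, 0.7, 1.4))
  mk_ab <- function(ppfd) {
    ab <- trace(scene, fixed_sky(direct = max(ppfd, 1)), NULL,
                rays_per_m2 = 10, rng_seed = 1)
    ab$facets$absorbed_ppfd <- ppfd
    ab$totals$emitted <- ppfd
    ab
  }
  hours <- lapply(rep(800, 5), mk_ab)
  res <- diurnal_canopy_A(hours, prm, scene)
  expect_equal(res$A_cd, leaf_A(800, prm$up) * 5 * 3600 / 1e6, tolerance = 1e-9)
  # dark hours excluded by default, included on request
  dark <- lapply(1:3, function(i) {
    a <- mk_ab(0)
    a$totals$emitted <- 0
    a
  })
  res2 <- diurnal_canopy_A(c(hours, dark), prm, scene)
  expect_equal(res2$A_cd, res$A_cd)
  res3 <- diurnal_canopy_A(c(hours, dark), prm, scene, include_night = TRUE)
  expect_equal(res3$A_cd, res$A_cd + 3 * -1.5 * 3600 / 1e6, tolerance = 1e-9)
})
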