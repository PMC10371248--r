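# Point-cloud container, ground-plane removal, denoising, and PLY/XYZ IO.

test_that("labelled cloud validates its invariants", {
  pts <- matrix(rnorm(30), 10, 3)
  cl <- labeled_point_cloud(pts, c(rep(0L, 4), rep(1L, 3), rep(2L, 3)))
  expect_s3_class(cl, "LabeledPointCloud")
  expect_named(cl$layer, c("1", "2"))
  expect_error(labeled_point_cloud(pts, c(rep(0L, 5), rep(2L, 5))),
               "contiguous")
  expect_error(labeled_point_cloud(matrix(c(1, NA, 3), 1, 3), 1L), "finite")
  expect_error(labeled_point_cloud(pts, 1L), "one label per point")
})

test_that("ground plane removal keeps the plant and drops the slab", {
  set.seed(1)
  ng <- 3000
  ground <- cbind(runif(ng, -60, 60), runif(ng, -60, 60), rnorm(ng, 0, 0.2))
  plant <- sample_point_cloud(flat_leaf_plant(z = 40), points_per_cm2 = 3,
                              rng_seed = 2)
  cl <- labeled_point_cloud(rbind(ground, plant$points),
                            c(rep(0L, ng), plant$labels),
                            source = c(rep("ground", ng), plant$source))
  out <- remove_ground_plane(cl, max_distance_cm = 5, rng_seed = 7)
  n_ground_left <- sum(out$source == "ground")
  expect_lt(n_ground_left, 0.01 * ng)               # >= 99% of plane removed
  kept_leaf <- sum(out$source == "leaf")
  orig_leaf_high <- sum(plant$source == "leaf" & plant$points[, 3] > 5)
  expect_equal(kept_leaf, orig_leaf_high)           # no plant points above 5 cm lost
})

test_that("degenerate inputs for plane removal raise 'no ground plane'", {
  empty <- labeled_point_cloud(matrix(numeric(0), 0, 3), integer(0))
  expect_error(remove_ground_plane(empty), "no ground plane")
  expect_error(remove_ground_plane(labeled_point_cloud(rbind(c(0, 0, 0)), 1L)),
               "no ground plane")
})

test_that("denoise drops disconnected clusters and noise, keeps surfaces", {
  plant <- sample_point_cloud(flat_leaf_plant(z = 30), points_per_cm2 = 25,
                              rng_seed = 3)
  leaf_pts <- plant$points[plant$source == "leaf", ]
  set.seed(4)
  # 10 isolated points far from the surface
  iso <- cbind(runif(10, 100, 150), runif(10, 100, 150), runif(10, 60, 90))
  cl <- labeled_point_cloud(rbind(leaf_pts, iso),
                            rep(1L, nrow(leaf_pts) + 10),
                            source = c(rep("leaf", nrow(leaf_pts)),
                                       rep("iso", 10)))
  out <- denoise(cl)
  expect_false(any(out$source == "iso"))

  # dense leaf surface + 100 gaussian-noise points: >= 90 noise removed,
  # <= 1% surface removed. The noise inflates the global spread of the
  # kNN-distance statistic, placing the cut far above the tight
  # distribution of the surface points. A rolled (cylindrical) young-leaf
  # surface is used because it has no free boundary: with the 0.3-SD cut,
  # the elevated kNN distances of blade-edge points would otherwise be
  # clipped along with the noise. A wide clustering radius keeps the cloud
  # connected so the statistical filter does the work.
  set.seed(5)
  nsurf <- 10000    # ~1.2 mm spacing: typical multi-view-stereo density
  th <- runif(nsurf, 0, 2 * pi)
  surf <- cbind(1.5 * cos(th), 1.5 * sin(th), runif(nsurf, 0, 15))
  noise <- surf[sample.int(nsurf, 100), ] + matrix(rnorm(300, 0, 3), 100, 3)
  cl2 <- labeled_point_cloud(rbind(surf, noise), rep(1L, nsurf + 100),
                             source = c(rep("leaf", nsurf),
                                        rep("noise", 100)))
  out2 <- denoise(cl2, cluster_eps_cm = 10)
  expect_lte(sum(out2$source == "noise"), 10)
  expect_gte(sum(out2$source == "leaf"), 0.99 * nsurf)
})

test_that("denoise is the identity (and idempotent) on homogeneous clouds", {
  # points evenly spaced on a circle: every kNN statistic is identical
  ang <- seq(0, 2 * pi, length.out = 201)[-201]
  cl <- labeled_point_cloud(cbind(10 * cos(ang), 10 * sin(ang), 5),
                            rep(1L, 200))
  out <- denoise(cl, cluster_eps_cm = 1, k_neighbors = 20)
  expect_equal(nrow(out$points), 200)
  out2 <- denoise(out, cluster_eps_cm = 1, k_neighbors = 20)
  expect_equal(out2$points, out$points)
})

test_that("denoise label sets are preserved or shrunk, never created", {
  plant <- sample_point_cloud(
    generate_synthetic_plant(architecture_preset("erect"), rng_seed = 6),
    points_per_cm2 = 1, noise_sd_cm = 0.3, rng_seed = 6)
  out <- denoise(plant, cluster_eps_cm = 3, k_neighbors = 30)
  expect_true(all(unique(out$labels) %in% unique(plant$labels)))
  expect_error(denoise(plant, k_neighbors = nrow(plant$points)),
               "too few points")
})

test_that("PLY round-trips labels, layers and coordinates in both formats", {
  plant <- sample_point_cloud(
    generate_synthetic_plant(architecture_preset("erect"), rng_seed = 8),
    points_per_cm2 = 0.3, rng_seed = 8)
  for (binary in c(TRUE, FALSE)) {
    f <- tempfile(fileext = ".ply")
    write_ply_cloud(plant, f, binary = binary)
    back <- read_ply_cloud(f)
    expect_equal(back$points, plant$points, tolerance = 1e-12)
    expect_equal(back$labels, plant$labels)
    expect_equal(back$layer, plant$layer)
    unlink(f)
  }
})

test_that("XYZ/CSV point lists are read with optional labels", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("x,y,z,label", "0,0,0,0", "1,1,10,1", "2,1,11,1"), f)
  cl <- read_xyz_cloud(f)
  expect_equal(nrow(cl$points), 3)
  expect_equal(cl$labels, c(0L, 1L, 1L))
  unlink(f)
})

test_that("layer assignment follows base height against plant mid-height", {
  lo <- flat_leaf_plant(z = 10)
  mesh <- merge_meshes(mesh_plant(lo), square_leaf_mesh(20, 90, leaf = 2L))
  cl <- sample_point_cloud(mesh, points_per_cm2 = 1, rng_seed = 9)
  layer <- assign_layers(cl)
  expect_equal(unname(layer[["1"]]), 1L)
  expect_equal(unname(layer[["2"]]), 2L)
})
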