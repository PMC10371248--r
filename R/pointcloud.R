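#' Labelled plant point cloud
#'
#' Container for a single-plant point cloud in which every point carries an
#' organ label: `0` for the stem, `k` (1..N) for leaf k. Coordinates are in
#' centimetres, Z up, ground near z = 0. Leaves additionally carry a canopy
#' layer tag (1 = bottom layer, 2 = up layer); if not supplied it is derived
#' from leaf base height relative to the plant's mid-height (midpoint
#' between the ground and the highest point of the cloud).
#'
#' @param points numeric matrix (n x 3) of finite XYZ coordinates (cm).
#' @param labels integer vector of per-point organ labels (0 = stem,
#'   1..N = leaves). Leaf labels must form a contiguous set 1..N.
#' @param layer optional named integer vector of per-leaf layer tags
#'   (names = leaf indices, values 1 or 2). Derived from base heights when
#'   `NULL`.
#' @param colors optional numeric matrix (n x 3) of RGB values.
#' @param source optional per-point character tag (e.g. "leaf", "stem",
#'   "ground") carried through filtering operations; useful for synthetic
#'   clouds where ground truth membership is known.
#' @return an object of class `LabeledPointCloud`.
#' @export
labeled_point_cloud <- function(points, labels, layer = NULL, colors = NULL,
                                source = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stopf("points must be an n x 3 matrix")
  if (nrow(points) > 0 && !all(is.finite(points))) stopf("coordinates must be finite")
  labels <- as.integer(labels)
  if (length(labels) != nrow(points)) stopf("one label per point required")
  if (anyNA(labels) || any(labels < 0)) stopf("labels must be >= 0 (0 = stem)")
  leaves <- sort(unique(labels[labels > 0]))
  if (length(leaves) && !identical(leaves, seq_len(max(leaves))))
    stopf("leaf labels must form a contiguous set 1..N, got: %s",
          paste(leaves, collapse = ", "))
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    if (!identical(dim(colors), dim(points))) stopf("colors must match points")
  }
  if (!is.null(source) && length(source) != nrow(points))
    stopf("source must have one entry per point")
  if (!is.null(layer) && is.null(names(layer)))
    names(layer) <- seq_along(layer)
  cloud <- structure(
    list(points = unname(points), labels = labels, layer = layer,
         colors = colors, source = source),
    class = "LabeledPointCloud")
  if (is.null(layer) && length(leaves)) cloud$layer <- assign_layers(cloud)
  cloud
}

#' @export
print.LabeledPointCloud <- function(x, ...) {
  nl <- length(unique(x$labels[x$labels > 0]))
  cat(sprintf("LabeledPointCloud: %d points, %d leaves, %d stem points\n",
              nrow(x$points), nl, sum(x$labels == 0)))
  invisible(x)
}

#' Assign canopy layers to leaves by base height
#'
#' A leaf whose base point (its lowest point) lies above the plant
#' mid-height -- the midpoint between the ground (minimum z of the cloud)
#' and the highest point -- is an up-layer leaf (2); otherwise bottom (1).
#'
#' @param cloud a [labeled_point_cloud()].
#' @return named integer vector of layer tags per leaf index.
#' @export
assign_layers <- function(cloud) {
  z <- cloud$points[, 3]
  mid <- (min(z) + max(z)) / 2
  leaves <- sort(unique(cloud$labels[cloud$labels > 0]))
  layer <- vapply(leaves, function(k) {
    base_z <- min(z[cloud$labels == k])
    if (base_z > mid) 2L else 1L
  }, integer(1))
  names(layer) <- leaves
  layer
}

subset_cloud <- function(cloud, keep) {
  labeled_point_cloud(cloud$points[keep, , drop = FALSE],
                      relabel_contiguous(cloud$labels[keep]),
                      layer = NULL,
                      colors = if (!is.null(cloud$colors)) cloud$colors[keep, , drop = FALSE],
                      source = if (!is.null(cloud$source)) cloud$source[keep])
}

# compact leaf labels to 1..N after points of some leaves were removed
relabel_contiguous <- function(labels) {
  leaves <- sort(unique(labels[labels > 0]))
  if (!length(leaves)) return(labels)
  map <- integer(max(leaves))
  map[leaves] <- seq_along(leaves)
  out <- labels
  out[labels > 0] <- map[labels[labels > 0]]
  out
}

#' Remove the dominant ground plane from a point cloud
#'
#' Fits the dominant plane by RANSAC (random 3-point hypotheses scored by
#' inlier count, followed by a least-squares refit on the inliers) and
#' removes all points within `max_distance_cm` of it.
#'
#' @param cloud a [labeled_point_cloud()].
#' @param max_distance_cm allowable point-to-plane distance (default 5 cm).
#' @param rng_seed seed for the RANSAC hypothesis draws.
#' @param n_iter number of RANSAC hypotheses.
#' @return the cloud minus the plane points, leaf labels re-indexed.
#' @export
remove_ground_plane <- function(cloud, max_distance_cm = 5, rng_seed = 1L,
                                n_iter = 300L) {
  if (max_distance_cm <= 0) stopf("max_distance_cm must be > 0")
  n <- nrow(cloud$points)
  if (n < 3) stopf("no ground plane")
  P <- cloud$points
  best <- NULL
  best_inliers <- 0L
  with_seed(rng_seed, {
    for (i in seq_len(n_iter)) {
      tri <- P[sample.int(n, 3L), , drop = FALSE]
      nvec <- c(
        (tri[2, 2] - tri[1, 2]) * (tri[3, 3] - tri[1, 3]) - (tri[2, 3] - tri[1, 3]) * (tri[3, 2] - tri[1, 2]),
        (tri[2, 3] - tri[1, 3]) * (tri[3, 1] - tri[1, 1]) - (tri[2, 1] - tri[1, 1]) * (tri[3, 3] - tri[1, 3]),
        (tri[2, 1] - tri[1, 1]) * (tri[3, 2] - tri[1, 2]) - (tri[2, 2] - tri[1, 2]) * (tri[3, 1] - tri[1, 1]))
      if (vnorm(nvec) < 1e-12) next
      nvec <- unit(nvec)
      d <- abs((P - matrix(tri[1, ], n, 3, byrow = TRUE)) %*% nvec)
      ninl <- sum(d <= max_distance_cm)
      if (ninl > best_inliers) {
        best_inliers <- ninl
        best <- list(point = tri[1, ], normal = nvec)
      }
    }
  })
  if (is.null(best) || best_inliers < 3L) stopf("no ground plane")
  # least-squares refit on the inliers
  d <- abs((P - matrix(best$point, n, 3, byrow = TRUE)) %*% best$normal)
  inl <- which(d <= max_distance_cm)
  ctr <- colMeans(P[inl, , drop = FALSE])
  sv <- svd(sweep(P[inl, , drop = FALSE], 2, ctr))
  nvec <- unit(sv$v[, 3])
  dist_all <- abs((P - matrix(ctr, n, 3, byrow = TRUE)) %*% nvec)
  keep <- dist_all > max_distance_cm
  subset_cloud(cloud, keep)
}

#' Denoise a point cloud by clustering and statistical outlier removal
#'
#' Two passes: (a) Euclidean clustering at `cluster_eps_cm`; every cluster
#' not connected to the largest component is dropped; (b) statistical
#' outlier removal: a point is dropped when its mean distance to its
#' `k_neighbors` nearest neighbours exceeds the global mean of that
#' statistic by more than `sd_threshold` global standard deviations.
#'
#' @param cloud a [labeled_point_cloud()].
#' @param cluster_eps_cm Euclidean clustering distance threshold
#'   (default 0.5 cm, i.e. 5 mm).
#' @param sd_threshold standard-deviation multiple for the outlier filter
#'   (default 0.3).
#' @param k_neighbors neighbourhood size for the distance statistic
#'   (default 50).
#' @return the filtered cloud.
#' @export
denoise <- function(cloud, cluster_eps_cm = 0.5, sd_threshold = 0.3,
                    k_neighbors = 50L) {
  n <- nrow(cloud$points)
  if (k_neighbors >= n) stopf("too few points")
  comp <- .cpp_radius_components(cloud$points, cluster_eps_cm)
  main <- as.integer(names(which.max(table(comp))))
  cloud <- subset_cloud(cloud, comp == main)
  n <- nrow(cloud$points)
  if (k_neighbors >= n) stopf("too few points")
  md <- .cpp_knn_mean_dist(cloud$points, as.integer(k_neighbors))
  # small relative slack so clouds with an exactly constant statistic
  # (sd = 0) are passed through unchanged despite floating-point noise
  keep <- md <= mean(md) + sd_threshold * sd(md) + 1e-9 * mean(md)
  subset_cloud(cloud, keep)
}
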