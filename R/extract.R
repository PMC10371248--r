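# Extraction of leaf vector models from labelled point clouds: a k-NN graph
# over each leaf's points, a shortest (Dijkstra) path from the leaf base to
# the graph-farthest point as the midrib, and cutting planes perpendicular
# to the local tangent to measure midrib-to-edge half-width vectors.

#' Extract a plant vector model from a labelled point cloud
#'
#' For every leaf: builds a k-nearest-neighbour graph over the leaf points,
#' takes the point closest to the stem (lowest point when no stem points
#' exist) as the base, the graph-farthest point as the tip, and their
#' shortest path as the midrib main path. The path is smoothed, resampled
#' to `stations` equal-arc-length stations, and at each station the leaf is
#' cut with a plane perpendicular to the local tangent; the extreme
#' projected offsets in the plane give the left/right half-width vectors.
#'
#' @param cloud a [labeled_point_cloud()] with at least one leaf.
#' @param stations number of axis stations per leaf (default 31).
#' @param k_graph neighbours per point in the leaf graph.
#' @param min_leaf_points leaves with fewer points raise an error.
#' @return a [plant_vector_model()].
#' @export
extract_vector_model <- function(cloud, stations = 31L, k_graph = 8L,
                                 min_leaf_points = 200L) {
  leaves_idx <- sort(unique(cloud$labels[cloud$labels > 0]))
  if (!length(leaves_idx)) stopf("cloud has no leaf labels")
  stem_pts <- cloud$points[cloud$labels == 0, , drop = FALSE]
  leaves <- lapply(leaves_idx, function(k) {
    pts <- cloud$points[cloud$labels == k, , drop = FALSE]
    if (nrow(pts) < min_leaf_points)
      stopf("degenerate leaf: leaf %d has only %d points", k, nrow(pts))
    layer <- if (!is.null(cloud$layer)) {
      lv <- cloud$layer[as.character(k)]
      if (is.na(lv)) 1L else as.integer(lv)
    } else 1L
    extract_leaf(pts, stem_pts, stations, k_graph, k, layer)
  })
  stem <- extract_stem(stem_pts, leaves)
  plant_vector_model(leaves, stem$polyline, stem$radius)
}

extract_leaf <- function(pts, stem_pts, stations, k_graph, leaf_index, layer) {
  n <- nrow(pts)
  nn <- .cpp_knn_indices(pts, as.integer(min(k_graph, n - 1)))
  from <- rep(seq_len(n), ncol(nn))
  to <- as.vector(nn)
  ok <- !is.na(to)
  from <- from[ok]; to <- to[ok]
  w <- sqrt(rowSums((pts[from, , drop = FALSE] - pts[to, , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  igraph::E(g)$weight <- w
  if (igraph::count_components(g) > 1)
    stopf("fragmented leaf: leaf %d point graph is disconnected", leaf_index)
  base <- if (nrow(stem_pts)) {
    # lowest leaf point among those hugging the stem: the sheath attachment
    ds <- .min_cross_dist(pts, stem_pts)
    near <- which(ds <= min(ds) + 1.5)
    near[which.min(pts[near, 3])]
  } else which.min(pts[, 3])
  dist_from_base <- igraph::distances(g, v = base)[1, ]
  tip <- which.max(dist_from_base)
  vpath <- igraph::shortest_paths(g, from = base, to = tip,
                                  output = "vpath")$vpath[[1]]
  path <- pts[as.integer(vpath), , drop = FALSE]
  # smoothing window ~ one station spacing of path vertices irons out the
  # point-to-point zigzag of the graph geodesic without shortening the path
  path <- smooth_polyline(path, window = max(5L, ceiling(nrow(path) / stations)))
  axis <- resample_polyline(path, stations)
  if (nrow(axis) < 3) stopf("degenerate leaf: leaf %d main path too short", leaf_index)
  # the graph geodesic can drift off the midrib toward a blade edge, which
  # tilts the cutting planes and inflates widths; re-centre each station at
  # the midpoint between the detected edges and cut again
  for (pass in 1:2) {
    cs <- cut_sections(pts, axis)
    if (pass == 1) {
      correction <- smooth_polyline((cs$left + cs$right) / 2, window = 5L)
      correction[c(1, nrow(correction)), ] <- 0  # keep base and tip anchored
      axis <- resample_polyline(smooth_polyline(axis + correction, 5L), stations)
    }
  }
  # station-to-station smoothing suppresses slab-discretisation jitter in
  # the edge estimates (the max-over-stations width statistic is otherwise
  # biased upward by single-station spikes)
  left <- smooth_polyline(cs$left, window = 3L)
  right <- smooth_polyline(cs$right, window = 3L)
  leaf_vector_model(axis, left, right, layer = layer, leaf_index = leaf_index)
}

# cut a leaf cloud with planes perpendicular to the axis tangents and
# return midrib-to-edge vectors per station
cut_sections <- function(pts, axis) {
  stations <- nrow(axis)
  tang <- axis_tangents(axis)
  spacing <- sum(sqrt(rowSums(diff(axis)^2))) / (stations - 1)
  half_slab <- 0.5 * spacing
  left <- matrix(0, stations, 3)
  right <- matrix(0, stations, 3)
  w_prev <- NULL
  for (i in seq_len(stations)) {
    rel <- sweep(pts, 2, axis[i, ])
    t_off <- rel %*% tang[i, ]
    sel <- abs(t_off) <= half_slab
    if (sum(sel) >= 3) {
      q <- rel[sel, , drop = FALSE] - t_off[sel] %*% t(tang[i, ])
      # principal in-plane direction = width direction at this station
      sv <- svd(q, nu = 0, nv = 1)
      wdir <- sv$v[, 1]
      wdir <- wdir - sum(wdir * tang[i, ]) * tang[i, ]
      if (vnorm(wdir) < 1e-9) next
      wdir <- unit(wdir)
      if (!is.null(w_prev) && sum(wdir * w_prev) < 0) wdir <- -wdir
      w_prev <- wdir
      off <- q %*% wdir
      # near-extreme quantiles resist single-point scan-noise outliers
      left[i, ] <- min(quantile(off, 0.005), 0) * wdir
      right[i, ] <- max(quantile(off, 0.995), 0) * wdir
    }
  }
  list(left = left, right = right)
}

# minimum distance from each row of A to any row of B (chunked)
.min_cross_dist <- function(A, B) {
  nb <- nrow(B)
  if (nb > 2000) B <- B[seq(1, nb, length.out = 2000), , drop = FALSE]
  b2 <- rowSums(B^2)
  apply(A, 1, function(p) sqrt(max(0, min(b2 - 2 * (B %*% p) + sum(p^2)))))
}

smooth_polyline <- function(p, window = 5L) {
  n <- nrow(p)
  if (n <= window) return(p)
  half <- window %/% 2
  out <- p
  for (i in seq_len(n)) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    out[i, ] <- colMeans(p[lo:hi, , drop = FALSE])
  }
  # keep the exact endpoints: base and tip anchor length measurements
  out[1, ] <- p[1, ]
  out[n, ] <- p[n, ]
  out
}

resample_polyline <- function(p, m) {
  seglen <- sqrt(rowSums(diff(p)^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  if (total <= 0) return(p[rep(1, m), , drop = FALSE])
  s <- seq(0, total, length.out = m)
  cbind(approx(cum, p[, 1], xout = s)$y,
        approx(cum, p[, 2], xout = s)$y,
        approx(cum, p[, 3], xout = s)$y)
}

extract_stem <- function(stem_pts, leaves) {
  if (nrow(stem_pts) >= 10) {
    zr <- range(stem_pts[, 3])
    brk <- seq(zr[1], zr[2], length.out = 9)
    bins <- findInterval(stem_pts[, 3], brk, rightmost.closed = TRUE)
    ctr <- t(vapply(sort(unique(bins)), function(b)
      colMeans(stem_pts[bins == b, , drop = FALSE]), numeric(3)))
    if (nrow(ctr) < 2) ctr <- rbind(ctr, ctr + c(0, 0, 1e-3))
    radius <- mean(sqrt(rowSums((stem_pts[, 1:2, drop = FALSE] -
      matrix(colMeans(stem_pts)[1:2], nrow(stem_pts), 2, byrow = TRUE))^2)))
    list(polyline = ctr, radius = max(radius, 0.2))
  } else {
    bases <- t(vapply(leaves, function(l) l$axis[1, ], numeric(3)))
    xy <- colMeans(bases)[1:2]
    top <- max(vapply(leaves, function(l) max(l$axis[, 3]), numeric(1)))
    list(polyline = rbind(c(xy, 0), c(xy, top)), radius = 1)
  }
}
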