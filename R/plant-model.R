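#' Leaf vector model
#'
#' The editable representation of one leaf: an ordered midrib axis from
#' base to tip plus, at every axis station, a pair of vectors from the
#' midrib to the left and right leaf edge. All coordinates in centimetres.
#'
#' @param axis numeric matrix (s x 3), s >= 3, axis points base -> tip.
#' @param left,right numeric matrices (s x 3): midrib-to-edge vectors.
#' @param layer leaf layer, 1 (bottom) or 2 (up).
#' @param leaf_index positive integer leaf number.
#' @return object of class `LeafVectorModel`.
#' @export
leaf_vector_model <- function(axis, left, right, layer = 1L, leaf_index = 1L) {
  axis <- as.matrix(axis)
  left <- as.matrix(left)
  right <- as.matrix(right)
  if (nrow(axis) < 3) stopf("leaf axis needs >= 3 stations")
  if (!all(dim(left) == dim(axis)) || !all(dim(right) == dim(axis)))
    stopf("half-width matrices must match the axis stations")
  if (!all(is.finite(axis)) || !all(is.finite(left)) || !all(is.finite(right)))
    stopf("leaf geometry must be finite")
  seg <- diff(axis)
  if (any(rowSums(seg^2) == 0)) stopf("degenerate leaf axis segment")
  # width vectors approximately perpendicular to the local tangent (30 deg)
  tang <- axis_tangents(axis)
  for (hw in list(left, right)) {
    len <- sqrt(rowSums(hw^2))
    nz <- len > 1e-9
    if (any(nz)) {
      cosang <- abs(rowSums(hw[nz, , drop = FALSE] * tang[nz, , drop = FALSE])) / len[nz]
      if (any(cosang > sin(deg2rad(30)) + 1e-6))
        warnf("leaf %d: width vectors deviate more than 30 degrees from perpendicular",
              leaf_index)
    }
  }
  structure(list(axis = unname(axis), left = unname(left),
                 right = unname(right), layer = as.integer(layer),
                 leaf_index = as.integer(leaf_index)),
            class = "LeafVectorModel")
}

# unit tangents at stations by central differences
axis_tangents <- function(axis) {
  s <- nrow(axis)
  t <- rbind(axis[2, ] - axis[1, ],
             (axis[seq(3, s), , drop = FALSE] - axis[seq(1, s - 2), , drop = FALSE]),
             axis[s, ] - axis[s - 1, ])
  t / pmax(sqrt(rowSums(t^2)), 1e-12)
}

#' Plant vector model
#'
#' @param leaves list of [leaf_vector_model()] objects with unique indices.
#' @param stem numeric matrix (>= 2 x 3), stem polyline base -> top.
#' @param stem_radius stem radius (cm).
#' @return object of class `PlantVectorModel`.
#' @export
plant_vector_model <- function(leaves, stem, stem_radius = 1.2) {
  stem <- as.matrix(stem)
  if (nrow(stem) < 2 || ncol(stem) != 3) stopf("stem must be a polyline (>= 2 x 3)")
  idx <- vapply(leaves, function(l) l$leaf_index, integer(1))
  if (anyDuplicated(idx)) stopf("leaf_index must be unique")
  for (l in leaves) {
    d <- min(point_polyline_distance(l$axis[1, ], stem))
    if (d > stem_radius + 1)
      warnf("leaf %d base is %.1f cm from the stem polyline", l$leaf_index, d)
  }
  structure(list(leaves = leaves[order(idx)], stem = unname(stem),
                 stem_radius = stem_radius),
            class = "PlantVectorModel")
}

point_polyline_distance <- function(p, poly) {
  n <- nrow(poly)
  d <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    a <- poly[i, ]; b <- poly[i + 1, ]
    ab <- b - a
    t <- sum((p - a) * ab) / max(sum(ab^2), 1e-12)
    t <- min(max(t, 0), 1)
    d[i] <- vnorm(p - (a + t * ab))
  }
  d
}

#' @export
print.PlantVectorModel <- function(x, ...) {
  tr <- measure_traits(x)
  cat(sprintf("PlantVectorModel: %d leaves, stem %.1f cm, mean leaf length %.1f cm\n",
              nrow(tr), max(x$stem[, 3]), mean(tr$length_cm)))
  invisible(x)
}

#' Trait adjustment for a plant vector model
#'
#' Multiplicative leaf length (LL) and width (LW) factors, additive leaf
#' number (LN), and additive leaf curvature (LC) and insertion angle (LA)
#' changes in degrees. Sign conventions: positive `la_delta_deg` rotates
#' leaves toward the vertical (more erect); positive `lc_delta_deg` adds
#' droop (cumulative bending away from the vertical along the axis).
#'
#' @param ll_factor,lw_factor multiplicative length/width factors (> 0).
#' @param ln_delta signed integer change in leaf number.
#' @param lc_delta_deg additive curvature change (degrees).
#' @param la_delta_deg additive insertion-angle change (degrees).
#' @return object of class `TraitAdjustment`.
#' @export
trait_adjustment <- function(ll_factor = 1, lw_factor = 1, ln_delta = 0L,
                             lc_delta_deg = 0, la_delta_deg = 0) {
  if (ll_factor <= 0 || lw_factor <= 0) stopf("length/width factors must be > 0")
  structure(list(ll_factor = ll_factor, lw_factor = lw_factor,
                 ln_delta = as.integer(ln_delta),
                 lc_delta_deg = lc_delta_deg, la_delta_deg = la_delta_deg),
            class = "TraitAdjustment")
}

#' Measure architectural traits of a plant vector model
#'
#' Per leaf: length (axis arc length), width (maximum over stations of the
#' summed left+right half-widths), base height (z of the first axis point)
#' and one-sided area (sum of lofted mesh facet areas). Plant-level
#' summaries are attached as attributes (`leaf_count`, `stem_height_cm`,
#' `mean_length_cm`, `max_length_cm`, `mean_width_cm`, `max_width_cm`).
#'
#' @param plant a [plant_vector_model()].
#' @return data frame with one row per leaf.
#' @export
measure_traits <- function(plant) {
  rows <- lapply(plant$leaves, function(l) {
    len <- sum(sqrt(rowSums(diff(l$axis)^2)))
    wid <- max(sqrt(rowSums(l$left^2)) + sqrt(rowSums(l$right^2)))
    mesh <- mesh_leaf(l)
    data.frame(leaf = l$leaf_index, layer = l$layer, length_cm = len,
               width_cm = wid, base_height_cm = l$axis[1, 3],
               area_cm2 = sum(mesh$facet_area))
  })
  out <- do.call(rbind, rows)
  attr(out, "leaf_count") <- nrow(out)
  attr(out, "stem_height_cm") <- max(plant$stem[, 3]) - min(plant$stem[, 3])
  attr(out, "mean_length_cm") <- mean(out$length_cm)
  attr(out, "max_length_cm") <- max(out$length_cm)
  attr(out, "mean_width_cm") <- mean(out$width_cm)
  attr(out, "max_width_cm") <- max(out$width_cm)
  out
}

# horizontal rotation axis for in-plane (vertical) leaf rotations, oriented
# so that a positive Rodrigues rotation about it raises the leaf tip
leaf_bend_axis <- function(leaf) {
  wd <- colMeans(rbind(leaf$right, -leaf$left))
  h <- c(wd[1], wd[2], 0)
  if (vnorm(h) < 1e-9) {
    span <- leaf$axis[nrow(leaf$axis), ] - leaf$axis[1, ]
    h <- c(-span[2], span[1], 0)
  }
  if (vnorm(h) < 1e-9) h <- c(1, 0, 0)
  h <- unit(h)
  span <- leaf$axis[nrow(leaf$axis), ] - leaf$axis[1, ]
  lifted <- rotate_about_axis(span, h, deg2rad(1))
  if (lifted[3] < span[3]) h <- -h
  h
}

adjust_leaf <- function(leaf, adj) {
  axis <- leaf$axis
  left <- leaf$left
  right <- leaf$right
  base <- axis[1, ]
  if (adj$ll_factor != 1)
    axis <- sweep(sweep(axis, 2, base) * adj$ll_factor, 2, base, `+`)
  if (adj$lw_factor != 1) {
    left <- left * adj$lw_factor
    right <- right * adj$lw_factor
  }
  if (adj$lc_delta_deg != 0) {
    h <- leaf_bend_axis(leaf)
    s <- nrow(axis)
    segs <- diff(axis)
    # progressive bending: segment i rotated by (i-1)/(nseg-1) * delta so the
    # tangent turns by exactly delta between base and tip; positive = droop
    nseg <- s - 1
    phis <- if (nseg > 1) (seq_len(nseg) - 1) / (nseg - 1) * -deg2rad(adj$lc_delta_deg)
            else rep(0, nseg)
    newaxis <- matrix(0, s, 3)
    newaxis[1, ] <- axis[1, ]
    for (i in seq_len(nseg))
      newaxis[i + 1, ] <- newaxis[i, ] + rotate_about_axis(segs[i, ], h, phis[i])
    stat_phi <- c(phis[1], phis)
    for (i in seq_len(s)) {
      left[i, ] <- rotate_about_axis(left[i, ], h, stat_phi[i])
      right[i, ] <- rotate_about_axis(right[i, ], h, stat_phi[i])
    }
    axis <- newaxis
  }
  if (adj$la_delta_deg != 0) {
    h <- leaf_bend_axis(leaf)
    a <- deg2rad(adj$la_delta_deg)
    axis <- sweep(rotate_about_axis(sweep(axis, 2, base), h, a), 2, base, `+`)
    left <- rotate_about_axis(left, h, a)
    right <- rotate_about_axis(right, h, a)
  }
  leaf_vector_model(axis, left, right, layer = leaf$layer,
                    leaf_index = leaf$leaf_index)
}

#' Apply a trait adjustment to a plant vector model
#'
#' LL scales each leaf axis about its base; LW scales the half-width
#' vectors; LA rigidly rotates each leaf about the horizontal axis through
#' its base (positive = more erect); LC distributes the curvature change
#' progressively along the axis stations (positive = droopier); LN > 0
#' clones existing leaves (cycled from the top, phyllotaxis rotated 180
#' degrees, stacked above the current top leaf at the plant's mean
#' internode spacing), LN < 0 removes leaves from the bottom up. Leaf
#' layers are re-derived from base heights after a leaf-number change.
#' The identity adjustment returns a geometrically identical plant.
#'
#' @param plant a [plant_vector_model()].
#' @param adj a [trait_adjustment()].
#' @param rng_seed unused by the deterministic rules; kept so callers can
#'   thread one seed through every pipeline stage.
#' @return the adjusted `PlantVectorModel`.
#' @export
apply_adjustment <- function(plant, adj, rng_seed = 1L) {
  stopifnot(inherits(plant, "PlantVectorModel"), inherits(adj, "TraitAdjustment"))
  leaves <- plant$leaves
  n <- length(leaves)
  if (adj$ln_delta <= -n) stopf("no leaves left")
  if (adj$ll_factor != 1 || adj$lw_factor != 1 ||
      adj$lc_delta_deg != 0 || adj$la_delta_deg != 0)
    leaves <- lapply(leaves, adjust_leaf, adj = adj)
  stem <- plant$stem
  if (adj$ln_delta != 0) {
    base_z <- vapply(leaves, function(l) l$axis[1, 3], numeric(1))
    ord <- order(base_z)
    if (adj$ln_delta < 0) {
      leaves <- leaves[-ord[seq_len(-adj$ln_delta)]]
    } else {
      spacing <- if (n > 1) mean(diff(sort(base_z))) else 10
      top_desc <- rev(ord)
      top_z <- max(base_z)
      stem_xy <- stem[which.max(stem[, 3]), 1:2]
      for (j in seq_len(adj$ln_delta)) {
        src <- leaves[[top_desc[((j - 1) %% n) + 1]]]
        dz <- top_z + j * spacing - src$axis[1, 3]
        shift <- function(m) {
          m2 <- sweep(m, 2, c(stem_xy, 0))
          m2 <- rotate_z(m2, 180)
          sweep(m2, 2, c(stem_xy, dz), `+`)
        }
        leaves[[length(leaves) + 1]] <- leaf_vector_model(
          shift(src$axis), rotate_z(src$left, 180), rotate_z(src$right, 180),
          layer = src$layer, leaf_index = n + j)
      }
      new_top <- max(vapply(leaves, function(l) l$axis[1, 3], numeric(1)))
      if (new_top > max(stem[, 3]))
        stem <- rbind(stem, c(stem[which.max(stem[, 3]), 1:2], new_top))
    }
    for (i in seq_along(leaves)) leaves[[i]]$leaf_index <- i
    # re-derive layers against the new plant mid-height
    top <- max(vapply(leaves, function(l) max(l$axis[, 3]), numeric(1)),
               max(stem[, 3]))
    mid <- (min(stem[, 3]) + top) / 2
    for (i in seq_along(leaves))
      leaves[[i]]$layer <- if (leaves[[i]]$axis[1, 3] > mid) 2L else 1L
  }
  plant_vector_model(leaves, stem, plant$stem_radius)
}
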