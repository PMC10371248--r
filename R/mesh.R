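# Lofted triangle meshing of plant vector models. Leaves become two
# triangle strips (left and right of the midrib) between consecutive
# station cross-sections; the stem becomes a closed triangulated tube.

# loft one leaf; returns vertices plus 0-based triangles
mesh_leaf <- function(leaf) {
  s <- nrow(leaf$axis)
  vl <- leaf$axis + leaf$left
  vm <- leaf$axis
  vr <- leaf$axis + leaf$right
  verts <- rbind(vl, vm, vr)          # rows: 1..s left, s+1..2s mid, 2s+1..3s right
  tri <- matrix(0L, 0, 3)
  for (i in seq_len(s - 1)) {
    l0 <- i; l1 <- i + 1L
    m0 <- s + i; m1 <- s + i + 1L
    r0 <- 2L * s + i; r1 <- 2L * s + i + 1L
    tri <- rbind(tri,
                 c(l0, m0, m1), c(l0, m1, l1),    # left side quad
                 c(m0, r0, r1), c(m0, r1, m1))    # right side quad
  }
  list(vertices = verts, triangles = tri,
       facet_area = triangle_areas(verts[tri[, 1], , drop = FALSE],
                                   verts[tri[, 2], , drop = FALSE],
                                   verts[tri[, 3], , drop = FALSE]))
}

mesh_stem <- function(stem, radius, sides = 8L) {
  n <- nrow(stem)
  ang <- seq(0, 2 * pi, length.out = sides + 1L)[-(sides + 1L)]
  ring <- cbind(cos(ang), sin(ang), 0) * radius
  verts <- do.call(rbind, lapply(seq_len(n), function(i)
    sweep(ring, 2, stem[i, ], `+`)))
  tri <- matrix(0L, 0, 3)
  for (i in seq_len(n - 1)) {
    a <- (i - 1L) * sides
    b <- i * sides
    for (j in seq_len(sides)) {
      j2 <- (j %% sides) + 1L
      tri <- rbind(tri, c(a + j, b + j, b + j2), c(a + j, b + j2, a + j2))
    }
  }
  list(vertices = verts, triangles = tri)
}

#' Mesh a plant vector model
#'
#' Lofts every leaf into triangle strips between consecutive station
#' cross-sections (two triangles per quad on each side of the midrib) and
#' the stem into a closed tube. Degenerate facets (area below 1e-4 cm2 or
#' edge aspect ratio above 100) are removed.
#'
#' @param plant a [plant_vector_model()].
#' @param stem_sides number of sides of the stem tube cross-section.
#' @return object of class `PlantMesh`: `vertices` (cm), `triangles`
#'   (1-based vertex triplets), `facet_leaf` (0 = stem), `facet_layer`,
#'   `facet_area` (cm2).
#' @export
mesh_plant <- function(plant, stem_sides = 8L) {
  verts <- matrix(numeric(0), 0, 3)
  tris <- matrix(integer(0), 0, 3)
  leaf_id <- integer(0)
  layer_id <- integer(0)
  add <- function(v, t, leaf, layer) {
    off <- nrow(verts)
    verts <<- rbind(verts, v)
    tris <<- rbind(tris, t + off)
    leaf_id <<- c(leaf_id, rep.int(leaf, nrow(t)))
    layer_id <<- c(layer_id, rep.int(layer, nrow(t)))
  }
  st <- mesh_stem(plant$stem, plant$stem_radius, stem_sides)
  add(st$vertices, st$triangles, 0L, 0L)
  for (l in plant$leaves) {
    ml <- mesh_leaf(l)
    add(ml$vertices, ml$triangles, l$leaf_index, l$layer)
  }
  v0 <- verts[tris[, 1], , drop = FALSE]
  v1 <- verts[tris[, 2], , drop = FALSE]
  v2 <- verts[tris[, 3], , drop = FALSE]
  area <- triangle_areas(v0, v1, v2)
  emax <- pmax(sqrt(rowSums((v1 - v0)^2)),
               sqrt(rowSums((v2 - v1)^2)),
               sqrt(rowSums((v0 - v2)^2)))
  aspect <- emax^2 / pmax(2 * area, 1e-300)
  keep <- area >= 1e-4 & aspect <= 100
  structure(list(vertices = verts,
                 triangles = tris[keep, , drop = FALSE],
                 facet_leaf = leaf_id[keep],
                 facet_layer = layer_id[keep],
                 facet_area = area[keep]),
            class = "PlantMesh")
}

#' @export
print.PlantMesh <- function(x, ...) {
  cat(sprintf("PlantMesh: %d facets, leaf area %.1f cm2 (%d leaves + stem)\n",
              nrow(x$triangles), total_leaf_area(x),
              length(setdiff(unique(x$facet_leaf), 0L))))
  invisible(x)
}

#' Total one-sided leaf area of a mesh (cm2)
#' @param mesh a [mesh_plant()] result.
#' @return scalar area in cm2.
#' @export
total_leaf_area <- function(mesh) sum(mesh$facet_area[mesh$facet_leaf > 0])

#' Write a plant mesh as Wavefront OBJ with a facet-attribute sidecar CSV
#'
#' OBJ stores only geometry; per-facet leaf index, layer and area go to
#' `<path>.facets.csv` in facet order.
#'
#' @param mesh a `PlantMesh`.
#' @param path output OBJ file.
#' @return `path`, invisibly.
#' @export
write_obj_mesh <- function(mesh, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# canophot plant mesh (cm)", con)
  writeLines(sprintf("v %.6f %.6f %.6f", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$triangles[, 1],
                     mesh$triangles[, 2], mesh$triangles[, 3]), con)
  side <- data.frame(facet = seq_len(nrow(mesh$triangles)),
                     leaf = mesh$facet_leaf, layer = mesh$facet_layer,
                     area_cm2 = mesh$facet_area)
  write.csv(side, paste0(path, ".facets.csv"), row.names = FALSE)
  invisible(path)
}
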