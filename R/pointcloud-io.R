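# PLY and XYZ/CSV input-output for labelled point clouds. PLY files carry
# the organ label and the leaf layer as extra integer per-vertex properties
# (`label`, `layer`), in both ASCII and binary little-endian flavours.

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_is_float <- function(type) type %in% c("float", "float32", "double", "float64")

#' Write a labelled point cloud to PLY
#'
#' @param cloud a [labeled_point_cloud()].
#' @param path output file.
#' @param binary write binary little-endian (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_ply_cloud <- function(cloud, path, binary = TRUE) {
  n <- nrow(cloud$points)
  has_col <- !is.null(cloud$colors)
  layer_pt <- integer(n)
  if (!is.null(cloud$layer)) {
    leafy <- cloud$labels > 0
    layer_pt[leafy] <- as.integer(cloud$layer[as.character(cloud$labels[leafy])])
  }
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           "comment canophot labelled plant point cloud (cm)",
           sprintf("element vertex %d", n),
           "property double x", "property double y", "property double z",
           if (has_col) c("property uchar red", "property uchar green",
                          "property uchar blue"),
           "property int label", "property int layer",
           "end_header")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (binary) {
    for (i in seq_len(n)) {
      writeBin(as.double(cloud$points[i, ]), con, size = 8, endian = "little")
      if (has_col) writeBin(as.raw(round(cloud$colors[i, ])), con)
      writeBin(as.integer(c(cloud$labels[i], layer_pt[i])), con, size = 4,
               endian = "little")
    }
  } else {
    cols <- if (has_col) format(round(cloud$colors), trim = TRUE)
    xyz <- format(cloud$points, trim = TRUE, digits = 17)
    lines <- paste(xyz[, 1], xyz[, 2], xyz[, 3],
                   if (has_col) paste(cols[, 1], cols[, 2], cols[, 3]) else "",
                   cloud$labels, layer_pt)
    lines <- gsub("  +", " ", lines)
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Read a labelled point cloud from PLY
#'
#' Reads ASCII and binary little-endian PLY. Per-vertex properties named
#' `label` (organ label) and `layer` (leaf layer) are honoured; a file
#' without them yields a single-leaf cloud.
#'
#' @param path PLY file.
#' @return a [labeled_point_cloud()].
#' @export
read_ply_cloud <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  read_hdr_line <- function() {
    chars <- character(0)
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (!length(ch) || ch == "\n") break
      if (ch != "\r") chars <- c(chars, ch)
    }
    paste(chars, collapse = "")
  }
  line <- read_hdr_line()
  if (!identical(line, "ply")) stopf("not a PLY file: %s", path)
  fmt <- NULL
  nvert <- NULL
  props <- list()
  in_vertex <- FALSE
  repeat {
    line <- read_hdr_line()
    if (line == "end_header") break
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (!length(tok)) next
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      in_vertex <- tok[2] == "vertex"
      if (in_vertex) nvert <- as.integer(tok[3])
    } else if (tok[1] == "property" && in_vertex) {
      if (tok[2] == "list") stopf("list properties on vertices unsupported")
      props[[tok[3]]] <- tok[2]
    }
  }
  if (is.null(nvert)) stopf("PLY header has no vertex element")
  pnames <- names(props)
  if (identical(fmt, "ascii")) {
    txt <- readLines(con)
    txt <- txt[nzchar(trimws(txt))][seq_len(nvert)]
    vals <- do.call(rbind, lapply(strsplit(trimws(txt), "\\s+"), as.numeric))
    colnames(vals) <- pnames
  } else if (identical(fmt, "binary_little_endian")) {
    vals <- matrix(NA_real_, nvert, length(props), dimnames = list(NULL, pnames))
    for (i in seq_len(nvert)) {
      for (j in seq_along(props)) {
        tp <- props[[j]]
        sz <- ply_type_size[[tp]]
        vals[i, j] <- if (ply_is_float(tp)) {
          readBin(con, "double", 1L, size = sz, endian = "little")
        } else if (tp %in% c("uchar", "uint8")) {
          as.integer(readBin(con, "raw", 1L))
        } else {
          readBin(con, "integer", 1L, size = sz, endian = "little",
                  signed = !startsWith(tp, "u"))
        }
      }
    }
  } else stopf("unsupported PLY format: %s", fmt)
  for (ax in c("x", "y", "z"))
    if (!ax %in% pnames) stopf("PLY vertex element lacks coordinate '%s'", ax)
  pts <- vals[, c("x", "y", "z"), drop = FALSE]
  labels <- if ("label" %in% pnames) as.integer(vals[, "label"]) else
    rep(1L, nvert)
  colors <- if (all(c("red", "green", "blue") %in% pnames))
    vals[, c("red", "green", "blue"), drop = FALSE]
  layer <- NULL
  if ("layer" %in% pnames) {
    lv <- as.integer(vals[, "layer"])
    leaves <- sort(unique(labels[labels > 0]))
    layer <- vapply(leaves, function(k) {
      tag <- unique(lv[labels == k & lv > 0])
      if (length(tag) == 1L) tag else NA_integer_
    }, integer(1))
    names(layer) <- leaves
    if (anyNA(layer)) layer <- NULL
  }
  labeled_point_cloud(pts, labels, layer = layer, colors = colors)
}

#' Read an XYZ/CSV point list
#'
#' Accepts whitespace- or comma-separated files with columns x, y, z and an
#' optional fourth integer column of organ labels.
#'
#' @param path input file.
#' @return a [labeled_point_cloud()].
#' @export
read_xyz_cloud <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  has_header <- grepl("[A-Za-z]", first)
  df <- read.table(path, sep = sep, header = has_header)
  if (ncol(df) < 3) stopf("need at least 3 coordinate columns")
  labels <- if (ncol(df) >= 4) as.integer(df[[4]]) else rep(1L, nrow(df))
  labeled_point_cloud(as.matrix(df[, 1:3]), labels)
}
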