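# Plain-text geometry formats: CTF-style .shape head-shape points and .hdm
# sphere files, OFF / GIfTI triangle meshes, and NIfTI volume export of
# source images.

#' Read / write CTF-style head shape files
#'
#' The `.shape` dialect is ASCII: the first line holds the point count,
#' followed by one `x y z` line per point (cm, head frame). Values are
#' written with 4 decimals.
#'
#' @param path file path.
#' @return `read_shape`: an N x 3 numeric matrix of class `shape_points`.
#' @export
read_shape <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed .shape header (expected point count): ", path)
  body <- lines[-1]
  if (length(body) != n)
    stop("shape header declares ", n, " points but file has ", length(body))
  pts <- do.call(rbind, lapply(body, function(l)
    as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]])))
  if (ncol(pts) != 3 || any(!is.finite(pts)))
    stop("malformed .shape point rows")
  structure(pts, class = c("shape_points", class(pts)))
}

#' @rdname read_shape
#' @param points N x 3 matrix of head-shape points, cm head frame.
#' @export
write_shape <- function(points, path) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  lines <- c(sprintf("%d", nrow(points)),
             apply(points, 1, function(p) sprintf("%.4f %.4f %.4f",
                                                  p[1], p[2], p[3])))
  writeLines(lines, path)
  invisible(path)
}

#' Spherical conductor head model
#'
#' A single default sphere (origin cm head frame + radius cm), optionally
#' with per-channel local spheres for multi-sphere forward modeling.
#'
#' @param origin length-3 sphere origin, cm head frame.
#' @param radius sphere radius, cm.
#' @param channel_spheres optional data frame with columns `name`, `ox`,
#'   `oy`, `oz`, `r` (one row per channel).
#' @param rms_error optional fit residual RMS, cm.
#' @return An object of class `head_model`.
#' @export
head_model <- function(origin, radius, channel_spheres = NULL,
                       rms_error = NA_real_) {
  if (!is.numeric(radius) || radius <= 0) stop("sphere radius must be > 0")
  if (radius <= 3 || radius >= 15)
    warning("sphere radius ", signif(radius, 4),
            " cm is outside the plausible 3-15 cm range")
  structure(list(origin = as.numeric(origin), radius = radius,
                 channel_spheres = channel_spheres, rms_error = rms_error),
            class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat(sprintf("<head_model> origin (%.2f, %.2f, %.2f) cm, radius %.2f cm\n",
              x$origin[1], x$origin[2], x$origin[3], x$radius))
  if (!is.null(x$channel_spheres))
    cat("  per-channel spheres:", nrow(x$channel_spheres), "\n")
  invisible(x)
}

# Sphere parameters that apply to one channel (falls back to the default).
sphere_for_channel <- function(model, channel_name) {
  cs <- model$channel_spheres
  if (!is.null(cs)) {
    i <- match(channel_name, cs$name)
    if (!is.na(i)) return(list(origin = c(cs$ox[i], cs$oy[i], cs$oz[i]),
                               radius = cs$r[i]))
  }
  list(origin = model$origin, radius = model$radius)
}

#' Read / write spherical head model (.hdm) files
#'
#' ASCII key-value dialect: a default record `ORIGIN_X ORIGIN_Y ORIGIN_Z
#' RADIUS` (cm, head frame), plus optional per-channel records
#' `name: ox oy oz r`. Values carry 4 decimals.
#'
#' @param path file path.
#' @return `read_hdm`: a [head_model()].
#' @export
read_hdm <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("empty .hdm file: ", path)
  default <- as.numeric(strsplit(lines[1], "[[:space:]]+")[[1]])
  if (length(default) != 4 || any(!is.finite(default)))
    stop("malformed default sphere record in ", path)
  if (default[4] <= 0) stop("sphere radius must be > 0 in ", path)
  cs <- NULL
  if (length(lines) > 1) {
    recs <- lapply(lines[-1], function(l) {
      parts <- strsplit(l, ":")[[1]]
      if (length(parts) != 2) stop("malformed per-channel record: ", l)
      vals <- as.numeric(strsplit(trimws(parts[2]), "[[:space:]]+")[[1]])
      if (length(vals) != 4 || any(!is.finite(vals)) || vals[4] <= 0)
        stop("malformed per-channel sphere: ", l)
      data.frame(name = trimws(parts[1]), ox = vals[1], oy = vals[2],
                 oz = vals[3], r = vals[4], stringsAsFactors = FALSE)
    })
    cs <- do.call(rbind, recs)
  }
  suppressWarnings(head_model(default[1:3], default[4], channel_spheres = cs))
}

#' @rdname read_hdm
#' @param model a [head_model()].
#' @export
write_hdm <- function(model, path) {
  stopifnot(inherits(model, "head_model"))
  if (model$radius <= 0) stop("sphere radius must be > 0")
  lines <- sprintf("%.4f %.4f %.4f %.4f", model$origin[1], model$origin[2],
                   model$origin[3], model$radius)
  cs <- model$channel_spheres
  if (!is.null(cs))
    lines <- c(lines, sprintf("%s: %.4f %.4f %.4f %.4f",
                              cs$name, cs$ox, cs$oy, cs$oz, cs$r))
  writeLines(lines, path)
  invisible(path)
}

# ---- Triangle meshes -------------------------------------------------------

new_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- as.matrix(vertices); faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (!nrow(vertices)) stop("mesh has no vertices")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("mesh face indices out of range")
  if (is.null(normals)) normals <- vertex_normals(vertices, faces)
  structure(list(vertices = vertices, faces = faces, normals = normals),
            class = "mesh3d_simple")
}

# Area-weighted outward vertex normals. Orientation is made outward with
# respect to the vertex centroid (majority vote).
vertex_normals <- function(vertices, faces) {
  v1 <- vertices[faces[, 1], , drop = FALSE]
  v2 <- vertices[faces[, 2], , drop = FALSE]
  v3 <- vertices[faces[, 3], , drop = FALSE]
  fn <- cross3_rows(v2 - v1, v3 - v1)   # face normal, |fn| = 2 * area
  acc <- rowsum(rbind(fn, fn, fn), group = c(faces[, 1], faces[, 2], faces[, 3]))
  n <- matrix(0, nrow(vertices), 3)
  n[as.integer(rownames(acc)), ] <- acc
  nrm <- row_norms(n)
  nrm[nrm == 0] <- 1
  n <- n / nrm
  ctr <- colMeans(vertices)
  outward <- rowSums(n * sweep(vertices, 2, ctr))
  if (sum(outward < 0) > sum(outward > 0)) n <- -n
  n
}

#' Read a triangle mesh (OFF or GIfTI)
#'
#' Format is chosen by extension: `.off` (ASCII OFF) or `.gii` (GIfTI
#' surface with ASCII-encoded data arrays). Vertex normals are computed
#' (area-weighted, outward) when the file carries none.
#'
#' @param path mesh file.
#' @return list with `vertices` (V x 3), `faces` (F x 3, 1-based),
#'   `normals` (V x 3 unit vectors); class `mesh3d_simple`.
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         off = read_off(path),
         gii = read_gifti_mesh(path),
         stop("unsupported mesh format '.", ext, "' (use .off or .gii)"))
}

read_off <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!identical(toupper(lines[1]), "OFF")) stop("not an OFF file: ", path)
  counts <- as.integer(strsplit(lines[2], "[[:space:]]+")[[1]])
  nv <- counts[1]; nf <- counts[2]
  if (length(lines) < 2 + nv + nf) stop("truncated OFF file: ", path)
  verts <- do.call(rbind, lapply(lines[3:(2 + nv)], function(l)
    as.numeric(strsplit(l, "[[:space:]]+")[[1]][1:3])))
  faces <- do.call(rbind, lapply(lines[(3 + nv):(2 + nv + nf)], function(l) {
    v <- as.integer(strsplit(l, "[[:space:]]+")[[1]])
    if (v[1] != 3) stop("only triangle meshes are supported")
    v[2:4] + 1L
  }))
  new_mesh(verts, faces)
}

#' @rdname read_mesh
#' @param mesh a mesh as returned by [read_mesh()] (or a list with
#'   `vertices` and `faces`).
#' @export
write_off <- function(mesh, path) {
  writeLines(c("OFF",
               sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)),
               apply(mesh$vertices, 1, function(p)
                 sprintf("%.6f %.6f %.6f", p[1], p[2], p[3])),
               apply(mesh$faces, 1, function(f)
                 sprintf("3 %d %d %d", f[1] - 1L, f[2] - 1L, f[3] - 1L))),
             path)
  invisible(path)
}

read_gifti_mesh <- function(path) {
  doc <- xml2::read_xml(path)
  arrays <- xml2::xml_find_all(doc, ".//DataArray")
  verts <- NULL; faces <- NULL
  for (a in arrays) {
    intent <- xml2::xml_attr(a, "Intent")
    enc <- xml2::xml_attr(a, "Encoding")
    if (!identical(enc, "ASCII"))
      stop("only ASCII-encoded GIfTI data arrays are supported")
    vals <- scan(text = xml2::xml_text(xml2::xml_find_first(a, ".//Data")),
                 quiet = TRUE)
    ncol_a <- as.integer(xml2::xml_attr(a, "Dim1"))
    m <- matrix(vals, ncol = ncol_a, byrow = TRUE)
    if (identical(intent, "NIFTI_INTENT_POINTSET")) verts <- m
    if (identical(intent, "NIFTI_INTENT_TRIANGLE")) faces <- m + 1L
  }
  if (is.null(verts) || is.null(faces))
    stop("GIfTI file lacks a pointset/triangle pair: ", path)
  new_mesh(verts, faces)
}

#' @rdname read_mesh
#' @export
write_gifti_mesh <- function(mesh, path) {
  fmt_block <- function(m, fmt) paste(apply(m, 1, function(r)
    paste(sprintf(fmt, r), collapse = " ")), collapse = "\n")
  v <- mesh$vertices; f <- mesh$faces - 1L
  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<GIFTI Version="1.0" NumberOfDataArrays="2">\n',
    '<DataArray Intent="NIFTI_INTENT_POINTSET" DataType="NIFTI_TYPE_FLOAT64"',
    ' ArrayIndexingOrder="RowMajorOrder" Encoding="ASCII" Dimensionality="2"',
    sprintf(' Dim0="%d" Dim1="3">\n<Data>\n', nrow(v)),
    fmt_block(v, "%.17g"), "\n</Data>\n</DataArray>\n",
    '<DataArray Intent="NIFTI_INTENT_TRIANGLE" DataType="NIFTI_TYPE_INT32"',
    ' ArrayIndexingOrder="RowMajorOrder" Encoding="ASCII" Dimensionality="2"',
    sprintf(' Dim0="%d" Dim1="3">\n<Data>\n', nrow(f)),
    fmt_block(f, "%d"), "\n</Data>\n</DataArray>\n</GIFTI>\n")
  writeLines(xml, path, sep = "")
  invisible(path)
}

#' Export a volumetric source image as NIfTI
#'
#' Writes one 3-D (single latency) or 4-D NIfTI volume. The affine maps
#' voxel indices to head-frame millimetres: diagonal = grid step (mm),
#' translation = grid minimum corner, axis order x (posterior-anterior,
#' through nasion), y (right-left), z (inferior-superior) following the
#' head frame.
#'
#' @param image a `source_image` on a regular volumetric grid.
#' @param path output `.nii` path.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(image, path) {
  stopifnot(inherits(image, "source_image"))
  if (!identical(image$grid$type, "volume"))
    stop("surface images cannot be written as NIfTI volumes; ",
         "export the mesh (write_off/write_gifti_mesh) with per-vertex values")
  g <- image$grid
  dims <- g$dims
  nt <- ncol(image$values)
  arr <- array(0, c(dims, nt))
  # grid voxel linear index for each image row
  idx <- g$voxel_index
  for (t in seq_len(nt)) {
    vol <- array(0, dims)
    vol[idx] <- image$values[, t]
    arr[, , , t] <- vol
  }
  if (nt == 1) arr <- array(arr, dims)
  aff <- rbind(cbind(diag(3) * g$step, g$box_min), c(0, 0, 0, 1))
  img <- RNifti::asNifti(arr)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
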