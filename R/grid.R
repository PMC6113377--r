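# Source spaces: regular volumetric grids (head-frame mm) and surface
# vertex sets. Volumetric grids are restricted to the conductor sphere
# interior, where the forward model is defined.

#' Volumetric source grid
#'
#' Regular grid over a bounding box in head-frame millimetres. The default
#' box is x -75..75, y -112..75, z -50..85 at a 4 mm step. When a head
#' model is supplied, only voxels strictly inside the conductor sphere
#' (with a small margin) are retained.
#'
#' @param box_min,box_max length-3 box corners, mm.
#' @param step grid step, mm (default 4).
#' @param model optional [head_model()] used to mask voxels to the sphere
#'   interior.
#' @param margin sphere-interior margin, cm (default 0.4): voxels closer
#'   than this to the sphere surface are dropped to keep lead fields
#'   well-conditioned.
#' @return A list of class `source_grid` with `points` (V x 3, mm),
#'   `dims`, `voxel_index` (linear index of each point in the full box
#'   array), `step`, `box_min`, `type = "volume"`.
#' @export
source_grid <- function(box_min = c(-75, -112, -50), box_max = c(75, 75, 85),
                        step = 4, model = NULL, margin = 0.4) {
  if (step <= 0) stop("grid step must be > 0")
  if (any(box_min >= box_max)) stop("box corners must be ordered")
  ax <- lapply(1:3, function(k) seq(box_min[k], box_max[k], by = step))
  dims <- vapply(ax, length, 0L)
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]],
                               KEEP.OUT.ATTRS = FALSE))
  idx <- seq_len(nrow(pts))
  if (!is.null(model)) {
    d_cm <- row_norms(sweep(pts / 10, 2, model$origin))
    keep <- d_cm < (model$radius - margin) & d_cm > 1e-6
    pts <- pts[keep, , drop = FALSE]
    idx <- idx[keep]
  }
  structure(list(points = pts, dims = dims, voxel_index = idx,
                 step = step, box_min = box_min, box_max = box_max,
                 type = "volume"),
            class = "source_grid")
}

#' Surface source grid from a mesh
#'
#' Sources at mesh vertices (head-frame cm converted to mm), with vertex
#' normals available for normal-constrained beamforming.
#'
#' @param mesh a mesh from [read_mesh()] with vertices in head-frame cm.
#' @return A `source_grid` of `type = "surface"` with `points` (mm),
#'   `normals`, and `faces`.
#' @export
surface_grid <- function(mesh) {
  structure(list(points = mesh$vertices * 10, normals = mesh$normals,
                 faces = mesh$faces, step = NA_real_, type = "surface"),
            class = "source_grid")
}

#' @export
print.source_grid <- function(x, ...) {
  cat(sprintf("<source_grid> %s, %d source points%s\n", x$type,
              nrow(x$points),
              if (x$type == "volume") sprintf(", step %g mm", x$step) else ""))
  invisible(x)
}

new_source_image <- function(values, grid, latencies, units,
                             polarity = "signed", meta = list()) {
  values <- as.matrix(values)
  structure(list(values = values, grid = grid,
                 latencies = latencies, units = units,
                 polarity = polarity, meta = meta),
            class = "source_image")
}

#' @export
print.source_image <- function(x, ...) {
  cat(sprintf("<source_image> %s, %d locations x %d latencies (%s)\n",
              x$grid$type, nrow(x$values), ncol(x$values), x$units))
  invisible(x)
}

# Location (mm) of the global maximum of a latency frame.
image_peak_location <- function(image, frame = which.max(apply(abs(image$values), 2, max))) {
  v <- image$values[, frame]
  image$grid$points[which.max(abs(v)), ]
}
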