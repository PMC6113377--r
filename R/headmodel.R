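# MRI import and spherical conductor model fitting. MRIs are resampled to
# isotropic voxels within a 256^3 volume (trilinear); head-shape points are
# derived from segmented surfaces via the fiducial-defined head frame; the
# conductor is a least-squares sphere (or per-channel local spheres).

#' Import an anatomical MRI and resample to isotropic voxels
#'
#' Non-isotropic input is trilinearly resampled to the smallest input
#' voxel dimension that keeps every output edge within 256 voxels;
#' orientation is normalized to RAS.
#'
#' @param path NIfTI file, or an `niftiImage` already in memory.
#' @return A list of class `mri_volume` with `data` (3-D array), `spacing`
#'   (mm, isotropic), and `affine` (voxel index -> scanner mm, 0-based
#'   indices).
#' @export
import_mri <- function(path) {
  img <- if (inherits(path, "niftiImage")) path else RNifti::readNifti(path)
  if (length(dim(img)) != 3) stop("import_mri requires a 3-D volume")
  RNifti::orientation(img) <- "RAS"
  aff3 <- unclass(RNifti::xform(img))[1:3, 1:3]
  spacing <- sqrt(colSums(aff3^2))
  dims <- dim(img)
  target <- min(spacing)
  # smallest isotropic spacing >= min(spacing) with every edge <= 256
  extents <- spacing * (dims - 1)
  target <- max(target, max(extents) / 255)
  new_dims <- pmin(256L, as.integer(floor(extents / target)) + 1L)
  if (all(abs(spacing - target) < 1e-9) && all(dims <= 256)) {
    arr <- array(as.numeric(img), dims)
    aff <- structure(RNifti::xform(img), code = NULL)
    out <- list(data = arr, spacing = target, affine = unclass(aff)[1:4, 1:4])
    class(out) <- "mri_volume"
    return(out)
  }
  arr <- array(as.numeric(img), dims)
  out_arr <- trilinear_resample(arr, spacing, target, new_dims)
  aff_in <- unclass(RNifti::xform(img))[1:4, 1:4]
  scale <- diag(c(rep(target, 3) / spacing, 1))
  aff_out <- aff_in %*% scale
  structure(list(data = out_arr, spacing = target, affine = aff_out),
            class = "mri_volume")
}

# Trilinear resampling of `arr` (spacing mm per axis) onto an isotropic
# grid of `new_dims` voxels at `target` mm, sharing the origin voxel.
trilinear_resample <- function(arr, spacing, target, new_dims) {
  dims <- dim(arr)
  coord <- lapply(1:3, function(k) {
    x <- (seq_len(new_dims[k]) - 1) * target / spacing[k]  # input voxel units
    pmin(pmax(x, 0), dims[k] - 1)
  })
  i0 <- lapply(1:3, function(k) pmin(floor(coord[[k]]), dims[k] - 2))
  fr <- lapply(1:3, function(k) coord[[k]] - i0[[k]])
  out <- array(0, new_dims)
  gx <- i0[[1]] + 1L; gy <- i0[[2]] + 1L; gz <- i0[[3]] + 1L
  fx <- fr[[1]]; fy <- fr[[2]]; fz <- fr[[3]]
  for (dz in 0:1) {
    wz <- if (dz == 0) 1 - fz else fz
    for (dy in 0:1) {
      wy <- if (dy == 0) 1 - fy else fy
      slab <- arr[, gy + dy, gz + dz, drop = FALSE]  # x, ny_new, nz_new
      # interpolate along x for all (y,z) at once
      a0 <- slab[gx, , , drop = FALSE]
      a1 <- slab[gx + 1L, , , drop = FALSE]
      interp_x <- a0 * (1 - fx) + a1 * fx
      w <- outer(wy, wz)
      out <- out + interp_x * rep(w, each = new_dims[1])
    }
  }
  out
}

#' Convert a segmented surface mesh to head-shape points
#'
#' Maps mesh vertices given in MRI voxel coordinates through the volume
#' affine into scanner millimetres, then through the fiducial-defined
#' rigid transform into head coordinates, returned in cm as required by
#' the `.shape` dialect.
#'
#' @param mesh a mesh (list with `vertices` in MRI voxel coordinates,
#'   0-based) as from [read_mesh()].
#' @param mri an `mri_volume` from [import_mri()].
#' @param transform the MRI-mm -> head-frame `rigid_transform`, e.g. from
#'   [head_transform_from_fiducials()] applied to fiducial positions in
#'   scanner mm.
#' @return A `shape_points` matrix (N x 3, cm, head frame).
#' @export
surface_to_shape <- function(mesh, mri, transform) {
  v <- mesh$vertices
  if (is.null(v) || !nrow(v)) stop("mesh has no vertices")
  mm <- cbind(v, 1) %*% t(mri$affine)
  head_mm <- apply_transform(transform, mm[, 1:3, drop = FALSE])
  structure(head_mm / 10, class = c("shape_points", "matrix"))
}

#' Fit a single-sphere conductor model to head-shape points
#'
#' Algebraic (Coope) least-squares sphere fit followed by Gauss-Newton
#' geometric refinement of the orthogonal distances; the residual RMS is
#' reported in the returned model.
#'
#' @param points N x 3 head-shape points, cm head frame (N >= 4,
#'   non-coplanar).
#' @return A [head_model()] with `rms_error` set.
#' @export
fit_sphere <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 4) stop("sphere fitting requires at least 4 points")
  if (any(!is.finite(points))) stop("shape points must be finite")
  # coplanarity check via PCA thickness
  ctr <- colMeans(points)
  sv <- svd(sweep(points, 2, ctr), nu = 0, nv = 0)$d
  if (sv[3] < 1e-9 * max(sv[1], 1))
    stop("shape points are coplanar; cannot fit a sphere")
  # algebraic fit: |p|^2 = 2 p.c + (r^2 - |c|^2)
  A <- cbind(2 * points, 1)
  b <- rowSums(points^2)
  sol <- qr.solve(A, b)
  centre <- sol[1:3]
  radius <- sqrt(sol[4] + sum(centre^2))
  # geometric refinement (Gauss-Newton on orthogonal distances)
  for (iter in 1:50) {
    d <- sweep(points, 2, centre)
    dist <- row_norms(d)
    resid <- dist - radius
    J <- cbind(-d / dist, -1)
    step <- tryCatch(qr.solve(J, -resid), error = function(e) rep(0, 4))
    centre <- centre + step[1:3]
    radius <- radius + step[4]
    if (sqrt(sum(step^2)) < 1e-12) break
  }
  dist <- row_norms(sweep(points, 2, centre))
  suppressWarnings(head_model(centre, radius,
                              rms_error = sqrt(mean((dist - radius)^2))))
}

#' Fit per-channel local spheres (multi-sphere model)
#'
#' For each MEG channel, a sphere is fitted to the head-shape points
#' weighted by a Gaussian of their distance to the channel's sensing coil
#' (`scale` cm), giving a local approximation of the head curvature under
#' that sensor. On a spherical head every local sphere equals the global
#' fit.
#'
#' @param points N x 3 head-shape points, cm head frame.
#' @param channels a [channel_info()] table with sensor geometry.
#' @param scale Gaussian proximity scale, cm (default 5).
#' @return A [head_model()] whose `channel_spheres` covers all MEG
#'   channels; the default sphere is the global fit.
#' @export
fit_multisphere <- function(points, channels, scale = 5) {
  if (missing(channels) || is.null(channels) || !nrow(channels))
    stop("sensor geometry (channel table) is required for multi-sphere fits")
  global <- fit_sphere(points)
  use <- which(meg_channel_mask(channels))
  recs <- lapply(use, function(i) {
    sensor <- channels$coil1[i, ]
    w <- exp(-rowSums(sweep(points, 2, sensor)^2) / (2 * scale^2))
    fit <- fit_sphere_weighted(points, w, init = global)
    data.frame(name = channels$name[i], ox = fit$origin[1],
               oy = fit$origin[2], oz = fit$origin[3], r = fit$radius,
               stringsAsFactors = FALSE)
  })
  suppressWarnings(head_model(global$origin, global$radius,
                              channel_spheres = do.call(rbind, recs),
                              rms_error = global$rms_error))
}

# Weighted geometric sphere fit (Gauss-Newton), started from `init`.
fit_sphere_weighted <- function(points, w, init) {
  centre <- init$origin; radius <- init$radius
  sw <- sqrt(w / sum(w))
  for (iter in 1:100) {
    d <- sweep(points, 2, centre)
    dist <- row_norms(d)
    resid <- (dist - radius) * sw
    J <- cbind(-d / dist, -1) * sw
    step <- tryCatch(qr.solve(J, -resid), error = function(e) rep(0, 4))
    # damp steps to keep the local fit near the data
    if (sqrt(sum(step^2)) > 2) step <- step * 2 / sqrt(sum(step^2))
    centre <- centre + step[1:3]
    radius <- radius + step[4]
    if (sqrt(sum(step^2)) < 1e-10) break
  }
  list(origin = centre, radius = radius)
}
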