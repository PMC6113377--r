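# Internal geometry helpers. Head frame follows the CTF convention:
# origin at the midpoint of the ear coils, +x through the nasion,
# +y toward the left ear, +z up; units cm.

MU0_OVER_4PI <- 1e-7      # T m / A
CM_TO_M <- 1e-2
NAM_TO_AM <- 1e-9         # nA m -> A m
FT_TO_T <- 1e-15

vnorm <- function(v) sqrt(sum(v^2))

row_norms <- function(m) sqrt(rowSums(m^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rowwise cross product for n x 3 matrices (or matrix x vector).
cross3_rows <- function(a, b) {
  if (is.null(dim(b))) b <- matrix(b, nrow(a), 3, byrow = TRUE)
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Rigid transform of a head coordinate frame from three fiducial points
#'
#' Builds the rigid transform taking coordinates expressed in the frame of
#' the supplied points (e.g. device or MRI mm) into the head frame defined
#' by the fiducials: origin at the ear-coil midpoint, +x through the nasion,
#' +y toward the left ear, +z completing a right-handed frame.
#'
#' @param nasion,left_ear,right_ear numeric length-3 fiducial positions.
#' @return A list with `rotation` (3x3, rows are the head axes) and
#'   `origin` (length 3); class `rigid_transform`. Apply with
#'   [apply_transform()], invert with [invert_transform()].
#' @export
head_transform_from_fiducials <- function(nasion, left_ear, right_ear) {
  nasion <- as.numeric(nasion); left_ear <- as.numeric(left_ear)
  right_ear <- as.numeric(right_ear)
  origin <- (left_ear + right_ear) / 2
  ex <- unit(nasion - origin)
  ly <- left_ear - origin
  ez_raw <- cross3(ex, ly)
  if (vnorm(ez_raw) < 1e-12) stop("fiducials are collinear")
  ez <- unit(ez_raw)
  ey <- cross3(ez, ex)
  structure(list(rotation = rbind(ex, ey, ez, deparse.level = 0),
                 origin = origin),
            class = "rigid_transform")
}

#' Apply a rigid transform to points
#' @param transform a `rigid_transform`.
#' @param points n x 3 matrix or length-3 vector.
#' @return transformed points, same shape as input.
#' @export
apply_transform <- function(transform, points) {
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, 1, 3) else as.matrix(points)
  out <- sweep(p, 2, transform$origin) %*% t(transform$rotation)
  if (vec) drop(out) else out
}

#' Rotate direction vectors (no translation) by a rigid transform
#' @inheritParams apply_transform
#' @export
apply_rotation <- function(transform, points) {
  vec <- is.null(dim(points))
  p <- if (vec) matrix(points, 1, 3) else as.matrix(points)
  out <- p %*% t(transform$rotation)
  if (vec) drop(out) else out
}

#' @export
invert_transform <- function(transform) {
  structure(list(rotation = t(transform$rotation),
                 origin = -drop(transform$rotation %*% transform$origin)),
            class = "rigid_transform")
}

#' Compose two rigid transforms (apply `first`, then `second`)
#' @export
compose_transforms <- function(second, first) {
  # second(first(x)) = R2 (R1 (x - o1) - o2)
  #                  = (R2 R1) (x - (o1 + R1^-1 o2))
  structure(list(rotation = second$rotation %*% first$rotation,
                 origin = first$origin +
                   drop(t(first$rotation) %*% second$origin)),
            class = "rigid_transform")
}

# Least-squares rigid transform (rotation + translation, no scaling) mapping
# point set `from` onto `to` (n x 3, n >= 3), by orthogonal Procrustes.
procrustes_rigid <- function(from, to) {
  from <- as.matrix(from); to <- as.matrix(to)
  cf <- colMeans(from); ct <- colMeans(to)
  A <- sweep(to, 2, ct)
  B <- sweep(from, 2, cf)
  s <- svd(t(A) %*% B)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  t_vec <- ct - drop(R %*% cf)
  list(R = R, t = t_vec)  # maps x -> R x + t
}

# Deterministic tangential basis at a point relative to a sphere origin.
# The first coordinate axis (lexicographic order x, y, z) that is not
# parallel to the radial direction is projected onto the tangent plane and
# normalized; the second basis vector completes a right-handed triad.
tangential_basis <- function(point, origin) {
  u <- unit(as.numeric(point) - as.numeric(origin))
  axes <- diag(3)
  for (k in 1:3) {
    e <- axes[k, ]
    t1_raw <- e - u * sum(u * e)
    if (vnorm(t1_raw) > 1e-6) {
      t1 <- unit(t1_raw)
      t2 <- cross3(u, t1)
      return(list(t1 = t1, t2 = t2, radial = u))
    }
  }
  stop("degenerate point (at sphere origin)")
}

# Quasi-uniform points on a spherical cap (helmet-like) via a Fibonacci
# lattice. `cap_deg` is the maximum polar angle from +z.
fibonacci_cap <- function(n, radius, center = c(0, 0, 0), cap_deg = 100) {
  golden <- pi * (3 - sqrt(5))
  i <- seq_len(n) - 0.5
  zmin <- cos(cap_deg * pi / 180)
  z <- 1 - (1 - zmin) * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- golden * (seq_len(n) - 1)
  pts <- cbind(r * cos(th), r * sin(th), z) * radius
  sweep(pts, 2, center, `+`)
}
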